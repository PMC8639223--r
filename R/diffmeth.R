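#' Define a two-group contrast
#'
#' @param name contrast label, e.g. `"day23_vs_day0_run1"`.
#' @param groupA,groupB disjoint character vectors of sample ids, each with
#'   at least two samples. Effects are reported as A minus B.
#' @param block optional blocking factor (e.g. donor labels) named by sample
#'   id, used as a covariate in the per-probe model.
#' @return an object of class `"Contrast"`.
#' @export
makeContrast <- function(name, groupA, groupB, block = NULL) {
    if (length(intersect(groupA, groupB)))
        stop("contrast groups must be disjoint")
    if (length(groupA) < 2 || length(groupB) < 2)
        stop("each contrast group needs at least 2 samples")
    if (!is.null(block)) {
        block <- block[c(groupA, groupB)]
        if (anyNA(block)) stop("block must be named by every contrast sample")
    }
    structure(list(name = name, groupA = groupA, groupB = groupB,
                   block = block), class = "Contrast")
}

# Upper-tail probability of a weighted sum of independent chi-square(1)
# variables, Q = sum(a_j X_j), by four-moment matching to a (noncentral)
# chi-square (Liu-Tang-Zhang); exact for a single weight, accurate in the
# far tail where a two-moment Satterthwaite fit is anticonservative.
.wchisqUpperP <- function(a, q) {
    c1 <- sum(a); c2 <- sum(a^2); c3 <- sum(a^3); c4 <- sum(a^4)
    s1 <- c3 / c2^1.5
    s2 <- c4 / c2^2
    if (s1^2 > s2) {
        aa <- 1 / (s1 - sqrt(s1^2 - s2))
        delta <- s1 * aa^3 - aa^2
        l <- aa^2 - 2 * delta
    } else {
        delta <- 0
        l <- 1 / s1^2
    }
    stats::pchisq((q - c1) / sqrt(2 * c2) * sqrt(2 * (l + 2 * delta)) +
                      l + delta,
                  df = l, ncp = delta, lower.tail = FALSE)
}

# Newton inversion of the trigamma function (for the log-variance moment fit)
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in seq_len(50)) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (abs(dif) / y < 1e-8) break
    }
    y
}

# Moment-matching of an F-distribution to observed residual variances on the
# log scale; returns the prior df d0 and prior variance s0^2.
.fitVariancePrior <- function(s2, df) {
    ok <- is.finite(s2) & s2 > 0
    if (sum(ok) < 2) return(list(df0 = 1e6, s02 = mean(s2[ok], na.rm = TRUE)))
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
        df0 <- 2 * .trigammaInverse(evar)
        df0 <- min(df0, 1e6)
        s02 <- exp(mean(e) + digamma(df0 / 2) - log(df0 / 2))
    } else {
        df0 <- 1e6
        s02 <- exp(mean(e))
    }
    list(df0 = df0, s02 = s02)
}

#' Per-CpG moderated differential methylation (DMPs)
#'
#' Fits, per probe, a linear model of M values on the contrast group (plus an
#' optional donor blocking factor), shrinks the residual variances by
#' empirical Bayes — `s2_post = (d0 s0^2 + d s2) / (d0 + d)` with the prior
#' `(d0, s0^2)` moment-matched on log variances — and reports a moderated t
#' with `d0 + d` degrees of freedom, two-sided p, and Benjamini-Hochberg FDR.
#' Effect sizes (`delta_beta`) are computed on the beta scale.
#'
#' @param meM `MethylationExperiment` on the M scale.
#' @param contrast a [makeContrast()] object.
#' @param manifest probe manifest (for chrom/pos columns in the output).
#' @param meBeta optional matching beta-scale object; when omitted the beta
#'   matrix is recovered from the M values with the stored offset.
#' @param fdrThreshold significance threshold on the BH-adjusted p
#'   (default 0.05).
#' @return `data.frame` with one row per probe: `probe_id, chrom, pos,
#'   delta_beta, t_mod, p, fdr, significant`.
#' @export
fitDmps <- function(meM, contrast, manifest, meBeta = NULL,
                    fdrThreshold = 0.05) {
    stopifnot(methods::is(meM, "MethylationExperiment"),
              inherits(contrast, "Contrast"))
    if (methScale(meM) != "M") stop("fitDmps() expects M-scale values")
    samples <- c(contrast$groupA, contrast$groupB)
    if (!all(samples %in% colnames(meM)))
        stop("contrast samples missing from the matrix")
    M <- methValues(meM)[, samples, drop = FALSE]
    beta <- if (is.null(meBeta)) {
        mToBeta(M, S4Vectors::metadata(meM)$mOffset)
    } else {
        if (!identical(rownames(meBeta), rownames(meM)))
            stop("beta and M matrices must cover identical probes")
        methValues(meBeta)[, samples, drop = FALSE]
    }

    grp <- factor(ifelse(samples %in% contrast$groupA, "A", "B"),
                  levels = c("B", "A"))
    X <- if (is.null(contrast$block)) stats::model.matrix(~ grp)
         else stats::model.matrix(~ grp + factor(contrast$block[samples]))
    dfRes <- length(samples) - qr(X)$rank
    if (dfRes <= 0) stop("zero residual degrees of freedom")

    fit <- stats::lm.fit(X, t(M))
    coefA <- fit$coefficients["grpA", ]
    res <- t(M) - X %*% fit$coefficients
    s2 <- colSums(res^2) / dfRes
    cUnsc <- sqrt(chol2inv(chol(crossprod(X)))[2, 2])

    prior <- .fitVariancePrior(s2, dfRes)
    s2post <- (prior$df0 * prior$s02 + dfRes * s2) / (prior$df0 + dfRes)
    tmod <- coefA / (sqrt(s2post) * cUnsc)
    p <- 2 * stats::pt(-abs(tmod), df = prior$df0 + dfRes)

    constant <- apply(M, 1, function(r) stats::sd(r) == 0)
    tmod[constant] <- 0
    p[constant] <- 1

    mIdx <- match(rownames(meM), manifest$probe_id)
    out <- data.frame(
        probe_id = rownames(meM),
        chrom = normalizeChrom(manifest$chrom[mIdx]),
        pos = manifest$pos[mIdx],
        delta_beta = rowMeans(beta[, contrast$groupA, drop = FALSE]) -
            rowMeans(beta[, contrast$groupB, drop = FALSE]),
        t_mod = tmod, p = p,
        row.names = NULL)
    out$fdr <- bhAdjust(out$p)
    out$significant <- out$fdr < fdrThreshold
    attr(out, "contrast") <- contrast$name
    attr(out, "df_prior") <- prior$df0
    attr(out, "s2_prior") <- prior$s02
    attr(out, "df_total") <- prior$df0 + dfRes
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement (thin wrapper over
#' [stats::p.adjust] with input validation).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Kernel smoothing of per-CpG statistics
#'
#' Smooths squared per-CpG statistics along the genome with a Gaussian
#' kernel of bandwidth `sigma = lambda / C`, truncated at `+/- lambda`:
#' `Y_i = sum_j w_ij t_j^2 / sum_j w_ij`. Moderated t statistics are first
#' probit-calibrated to the normal scale (`z = qnorm(pt(t, df))`, exact
#' N(0,1) under the null) so that, under a working independence
#' assumption, each `Y_i` is a weighted sum of chi-square(1) variables; its
#' null is approximated by moment-matching to a (noncentral) chi-square
#' (four moments; exact for an isolated CpG), giving an upper-tail p per
#' CpG.
#'
#' @param dmps DMP table from [fitDmps()]; within each chromosome positions
#'   must be strictly increasing (error otherwise).
#' @param lambda kernel truncation half-width in bp (default 500).
#' @param C bandwidth divisor, `sigma = lambda / C` (default 3).
#' @param df degrees of freedom of the `t_mod` column, used for the probit
#'   calibration; defaults to the `df_total` attribute set by [fitDmps()],
#'   or `Inf` (statistics already on the z scale).
#' @return the input with columns `y_smooth` and `p_smooth` appended.
#' @export
smoothStats <- function(dmps, lambda = 500, C = 3,
                        df = attr(dmps, "df_total")) {
    sigma <- lambda / C
    if (is.null(df)) df <- Inf
    dmps <- dmps[order(dmps$chrom, dmps$pos), , drop = FALSE]
    zAll <- if (is.finite(df)) {
        -stats::qnorm(stats::pt(-abs(dmps$t_mod), df = df, log.p = TRUE),
                      log.p = TRUE)
    } else abs(dmps$t_mod)
    ySm <- pSm <- rep(NA_real_, nrow(dmps))
    for (ch in unique(dmps$chrom)) {
        idx <- which(dmps$chrom == ch)
        pos <- dmps$pos[idx]
        if (any(diff(pos) <= 0))
            stop("positions must be strictly increasing on ", ch)
        t2 <- zAll[idx]^2
        lo <- findInterval(pos - lambda - 0.5, pos) + 1L
        hi <- findInterval(pos + lambda + 0.5, pos)
        for (k in seq_along(idx)) {
            j <- lo[k]:hi[k]
            w <- exp(-(pos[j] - pos[k])^2 / (2 * sigma^2))
            a <- w / sum(w)
            y <- sum(a * t2[j])
            ySm[idx[k]] <- y
            pSm[idx[k]] <- .wchisqUpperP(a, y)
        }
    }
    dmps$y_smooth <- ySm
    dmps$p_smooth <- pSm
    dmps
}

#' Stouffer combination of per-CpG p-values
#'
#' Two-sided p-values are converted to direction-aligned z-scores,
#' `z_i = qnorm(1 - p_i / 2) * s_i` where `s_i` is +1 when the CpG's change
#' agrees with the region direction and -1 otherwise, combined as
#' `Z = sum(z_i) / sqrt(n)`, and returned as the upper-tail (one-sided) p.
#'
#' @param p two-sided p-values in `(0, 1]`.
#' @param directions numeric/integer signs per CpG relative to the region
#'   direction (defaults to all +1). Zeros are treated as +1.
#' @return combined one-sided p-value.
#' @export
stoufferCombine <- function(p, directions = rep(1, length(p))) {
    if (length(p) == 0) stop("no p-values to combine")
    if (any(p < 0 | p > 1)) stop("p-values must lie in (0, 1]")
    p <- pmax(p, 1e-300)   # guard against numerical underflow to 0
    s <- sign(directions)
    s[s == 0] <- 1
    z <- stats::qnorm(pmax(p, 1e-300) / 2, lower.tail = FALSE) * s
    stats::pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
}

#' Call differentially methylated regions
#'
#' CpGs significant after smoothing (BH on the smoothed p below
#' `fdrThreshold`) are grouped into regions whenever consecutive significant
#' CpGs lie within `lambda` bp; regions with fewer than `minCpgs` members are
#' discarded; mixed-direction regions are split at sign changes of the
#' per-CpG `delta_beta` runs; each region's `stouffer_p` combines its member
#' per-CpG DMP p-values (not the smoothed p, which are dependent by
#' construction) and regions at or above `stoufferThreshold` are dropped.
#'
#' @param smoothed output of [smoothStats()].
#' @param lambda maximum gap between consecutive significant CpGs in a
#'   region (bp).
#' @param minCpgs minimum member CpGs per region (default 3).
#' @param stoufferThreshold keep regions with combined p below this
#'   (default 0.05).
#' @param fdrThreshold BH threshold on the smoothed p (default 0.05).
#' @return `data.frame` of regions (0-based half-open `start`/`end`):
#'   `chrom, start, end, n_cpgs, mean_delta_beta, max_delta_beta,
#'   stouffer_p, direction`.
#' @export
callDmrs <- function(smoothed, lambda = 500, minCpgs = 3,
                     stoufferThreshold = 0.05, fdrThreshold = 0.05) {
    smoothed$fdr_smooth <- bhAdjust(smoothed$p_smooth)
    sig <- smoothed[smoothed$fdr_smooth < fdrThreshold, , drop = FALSE]
    out <- list()
    if (nrow(sig)) {
        sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
        newRegion <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                             diff(sig$pos) > lambda)
        regId <- cumsum(newRegion)
        for (r in split(seq_len(nrow(sig)), regId)) {
            block <- sig[r, , drop = FALSE]
            dsign <- sign(block$delta_beta)
            dsign[dsign == 0] <- 1
            runs <- rle(dsign)
            ends <- cumsum(runs$lengths)
            starts <- c(1, utils::head(ends, -1) + 1)
            for (q in seq_along(starts)) {
                seg <- block[starts[q]:ends[q], , drop = FALSE]
                if (nrow(seg) < minCpgs) next
                sp <- stoufferCombine(seg$p)
                if (sp >= stoufferThreshold) next
                out[[length(out) + 1L]] <- data.frame(
                    chrom = seg$chrom[1],
                    start = min(seg$pos) - 1L,
                    end = max(seg$pos),
                    n_cpgs = nrow(seg),
                    mean_delta_beta = mean(seg$delta_beta),
                    max_delta_beta = seg$delta_beta[which.max(abs(seg$delta_beta))],
                    stouffer_p = sp,
                    direction = if (runs$values[q] > 0) "hyper" else "hypo")
            }
        }
    }
    if (!length(out)) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), n_cpgs = integer(),
                          mean_delta_beta = numeric(),
                          max_delta_beta = numeric(),
                          stouffer_p = numeric(), direction = character()))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Write DMRs as BED6
#'
#' Name encodes the contrast and direction, score is `-log10(stouffer_p)`
#' capped at 1000, strand is ".".
#'
#' @param dmrs DMR table from [callDmrs()].
#' @param path output path.
#' @param contrast contrast label embedded in the name field.
#' @return `path`, invisibly.
#' @export
writeDmrBed <- function(dmrs, path, contrast = "contrast") {
    df <- data.frame(
        chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
        name = paste(contrast, dmrs$direction, sep = "|"),
        score = round(pmin(-log10(pmax(dmrs$stouffer_p, 1e-300)), 1000), 3),
        strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
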