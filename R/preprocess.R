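#' Probe quality filtering
#'
#' Removes probes that (i) fail the detection p-value threshold in any
#' sample, (ii) are flagged cross-reactive, (iii) were dropped by the vendor
#' in a manufacturing revision, or (iv) interrogate a CpG within
#' `snpWindow` nucleotides of a known SNP/variant. Reasons are counted with
#' that priority (a probe failing several checks is booked under the first),
#' and the per-reason report is stored in the returned object
#' (`filterReport()`).
#'
#' @param me [MethylationExperiment-class] on the beta scale with a
#'   detection-p assay.
#' @param manifest probe manifest `data.frame` with columns `probe_id`,
#'   `chrom`, `pos` (1-based CpG position) and optionally `snp_distance`,
#'   `cross_reactive`, `dropped_by_vendor`.
#' @param detpThreshold probes with detection p >= this value in any sample
#'   are removed (default 0.05, i.e. keep only p < 0.05 everywhere).
#' @param snpWindow probes with `snp_distance <= snpWindow` are removed
#'   (default 3 nucleotides).
#' @return filtered `MethylationExperiment`; `filterReport()` on it gives a
#'   `data.frame(reason, removed)`.
#' @export
filterProbes <- function(me, manifest, detpThreshold = 0.05, snpWindow = 3) {
    stopifnot(methods::is(me, "MethylationExperiment"))
    if (methScale(me) != "beta")
        stop("filterProbes() expects beta-scale values")
    dp <- detectionP(me)
    if (is.null(dp)) stop("detection p-value matrix is required")
    m <- manifest[match(rownames(me), manifest$probe_id), , drop = FALSE]
    if (anyNA(m$probe_id))
        stop("manifest does not cover all probes in the matrix")

    failDetp <- apply(dp >= detpThreshold, 1, any)
    crossReactive <- if ("cross_reactive" %in% names(m))
        m$cross_reactive %in% TRUE else rep(FALSE, nrow(me))
    vendorDropped <- if ("dropped_by_vendor" %in% names(m))
        m$dropped_by_vendor %in% TRUE else rep(FALSE, nrow(me))
    snpProximal <- if ("snp_distance" %in% names(m))
        !is.na(m$snp_distance) & m$snp_distance <= snpWindow
        else rep(FALSE, nrow(me))

    # priority booking so the report sums to the number of removed probes
    reason <- rep(NA_character_, nrow(me))
    reason[snpProximal] <- "snp_proximal"
    reason[vendorDropped] <- "vendor_dropped"
    reason[crossReactive] <- "cross_reactive"
    reason[failDetp] <- "detection_p"
    keep <- is.na(reason)
    report <- data.frame(
        reason = c("detection_p", "cross_reactive", "vendor_dropped",
                   "snp_proximal"),
        removed = c(sum(reason %in% "detection_p"),
                    sum(reason %in% "cross_reactive"),
                    sum(reason %in% "vendor_dropped"),
                    sum(reason %in% "snp_proximal")))
    if (!any(keep)) {
        dom <- report$reason[which.max(report$removed)]
        stop("no probes left after filtering; dominant removal reason: ", dom)
    }
    out <- me[keep, ]
    S4Vectors::metadata(out)$filterReport <- report
    out
}

#' Remove sex-chromosome probes
#'
#' Drops every probe whose manifest chromosome normalizes to chrX or chrY
#' (labels "X"/"chrX"/"x" etc. are all recognized).
#'
#' @inheritParams filterProbes
#' @return `MethylationExperiment` without sex-chromosome probes.
#' @export
dropSexChromosomes <- function(me, manifest) {
    m <- manifest[match(rownames(me), manifest$probe_id), , drop = FALSE]
    if (anyNA(m$probe_id))
        stop("manifest does not cover all probes in the matrix")
    keep <- !(normalizeChrom(m$chrom) %in% c("chrX", "chrY"))
    me[keep, ]
}

#' Quantile normalization across samples
#'
#' Forces every sample onto the same empirical distribution: after
#' normalization each sample's sorted value vector equals the cross-sample
#' mean of sorted vectors, with ties resolved by average rank. Delegates to
#' [limma::normalizeQuantiles].
#'
#' @param me `MethylationExperiment` on the beta scale, no missing values.
#' @return normalized `MethylationExperiment`.
#' @export
quantileNormalize <- function(me) {
    stopifnot(methods::is(me, "MethylationExperiment"))
    x <- methValues(me)
    if (anyNA(x)) stop("missing values are not supported")
    q <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(q) <- dimnames(x)
    if (methScale(me) == "beta") q <- .clamp(q, 0, 1)
    .replaceMeth(me, q)
}

#' Beta to M conversion and back
#'
#' `betaToM()` computes `M = log2((beta + offset) / (1 - beta + offset))`;
#' the symmetric offset keeps M finite at beta 0 and 1. `mToBeta()` inverts
#' the map with the same offset, so the round trip is exact to numerical
#' precision away from the clipped boundary.
#'
#' @param beta numeric vector/matrix of beta values in `[0, 1]`.
#' @param M numeric vector/matrix of M values.
#' @param offset symmetric offset (default `1e-3`).
#' @return numeric of the same shape.
#' @examples
#' betaToM(0.8, offset = 0)  # log2(4) = 2
#' mToBeta(betaToM(0.3))
#' @export
betaToM <- function(beta, offset = 1e-3) {
    if (any(beta < 0 | beta > 1, na.rm = TRUE))
        stop("beta values must lie in [0, 1]")
    log2((beta + offset) / (1 - beta + offset))
}

#' @rdname betaToM
#' @export
mToBeta <- function(M, offset = 1e-3) {
    r <- 2^M
    .clamp((r * (1 + offset) - offset) / (1 + r), 0, 1)
}

#' Convert a MethylationExperiment between scales
#'
#' @param me `MethylationExperiment`.
#' @param offset M-value offset; defaults to the one stored in the object.
#' @return converted object with its scale flag updated.
#' @export
convertToM <- function(me, offset = S4Vectors::metadata(me)$mOffset) {
    if (methScale(me) == "M") return(me)
    .replaceMeth(me, betaToM(methValues(me), offset), scale = "M")
}

#' @rdname convertToM
#' @export
convertToBeta <- function(me, offset = S4Vectors::metadata(me)$mOffset) {
    if (methScale(me) == "beta") return(me)
    .replaceMeth(me, mToBeta(methValues(me), offset), scale = "beta")
}

#' Empirical-Bayes batch adjustment (location/scale model)
#'
#' Removes additive and multiplicative batch effects from M values while
#' preserving covariate (e.g. day) effects, following the parametric
#' empirical-Bayes location/scale model: per-probe standardization given the
#' covariates, per-batch additive (gamma) and multiplicative (delta) effects
#' shrunk toward moment-matched batch-level priors (normal for gamma,
#' inverse-gamma for delta), then removed and the covariate fit restored.
#'
#' With a single batch the data are returned unchanged. Each batch needs at
#' least two samples, and the batch factor must not be confounded with the
#' covariates (checked by a rank test).
#'
#' @param me `MethylationExperiment` on the M scale.
#' @param batch factor (or column name in the sample sheet) of batch labels.
#' @param covariates optional design matrix of covariates to protect, e.g.
#'   `model.matrix(~ factor(day))`. Include an intercept.
#' @return adjusted `MethylationExperiment`.
#' @export
combatAdjust <- function(me, batch, covariates = NULL) {
    stopifnot(methods::is(me, "MethylationExperiment"))
    if (methScale(me) != "M")
        stop("combatAdjust() expects M-scale values; see convertToM()")
    if (length(batch) == 1 && is.character(batch))
        batch <- sampleSheet(me)[[batch]]
    batch <- droplevels(as.factor(batch))
    M <- methValues(me)
    if (length(batch) != ncol(M)) stop("batch length must match sample count")
    nb <- nlevels(batch)
    if (nb < 2) return(me)
    if (any(table(batch) < 2)) stop("every batch needs at least 2 samples")

    B <- stats::model.matrix(~ 0 + batch)
    if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)
        # the batch dummies span the intercept already
        covariates <- covariates[, apply(covariates, 2, function(x)
            stats::var(x) > 0), drop = FALSE]
        if (!ncol(covariates)) covariates <- NULL
    }
    X <- if (is.null(covariates)) B else cbind(B, covariates)
    if (qr(X)$rank < ncol(X))
        stop("batch is confounded with a covariate (design not full rank)")

    n <- ncol(M)
    fit <- stats::lm.fit(X, t(M))
    Bhat <- fit$coefficients
    nPer <- as.numeric(table(batch))
    grand <- as.numeric(crossprod(nPer / n, Bhat[seq_len(nb), , drop = FALSE]))
    varPooled <- colSums((t(M) - X %*% Bhat)^2) / n
    varPooled[varPooled <= 0] <- min(varPooled[varPooled > 0], 1e-8)

    standMean <- matrix(grand, nrow(M), n)
    if (!is.null(covariates)) {
        tmp <- X
        tmp[, seq_len(nb)] <- 0
        standMean <- standMean + t(tmp %*% Bhat)
    }
    sData <- (M - standMean) / sqrt(varPooled)

    gammaHat <- t(solve(crossprod(B), crossprod(B, t(sData))))  # G x nb
    gammaStar <- deltaStar <- matrix(0, nrow(M), nb)
    for (i in seq_len(nb)) {
        idx <- which(batch == levels(batch)[i])
        ni <- length(idx)
        si <- sData[, idx, drop = FALSE]
        gHat <- gammaHat[, i]
        dHat <- apply(si, 1, stats::var)
        gBar <- mean(gHat); t2 <- stats::var(gHat)
        mD <- mean(dHat); vD <- stats::var(dHat)
        a <- (2 * vD + mD^2) / vD
        b <- (mD * vD + mD^3) / vD
        gOld <- gHat; dOld <- dHat
        for (iter in seq_len(200)) {
            gNew <- (t2 * ni * gHat + dOld * gBar) / (t2 * ni + dOld)
            sum2 <- rowSums((si - gNew)^2)
            dNew <- (0.5 * sum2 + b) / (ni / 2 + a - 1)
            change <- max(abs(gNew - gOld) / (abs(gOld) + 1e-12),
                          abs(dNew - dOld) / dOld)
            gOld <- gNew; dOld <- dNew
            if (change < 1e-4) break
        }
        gammaStar[, i] <- gOld
        deltaStar[, i] <- dOld
    }

    adj <- sData
    for (i in seq_len(nb)) {
        idx <- which(batch == levels(batch)[i])
        adj[, idx] <- (sData[, idx, drop = FALSE] - gammaStar[, i]) /
            sqrt(deltaStar[, i])
    }
    out <- adj * sqrt(varPooled) + standMean
    dimnames(out) <- dimnames(M)
    .replaceMeth(me, out)
}

#' Principal component scores of the methylation profiles
#'
#' Probes are centered, samples projected; components are ordered by
#' decreasing variance and signed so that each component's largest-magnitude
#' probe loading is positive (a fixed, reproducible convention).
#'
#' @param me `MethylationExperiment` (typically on the M scale), no missing
#'   values.
#' @param nComponents number of components to return (at most
#'   `min(samples, probes)`).
#' @return list with `scores` (samples x components matrix) and
#'   `varianceFraction` (fraction of total variance per component).
#' @export
pcaScores <- function(me, nComponents = 2) {
    x <- t(methValues(me))           # samples x probes
    if (anyNA(x)) stop("missing values are not supported")
    maxComp <- min(nrow(x) - 1, ncol(x))
    if (nComponents > maxComp)
        stop("cannot extract ", nComponents, " components from ",
             nrow(x), " samples")
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- seq_len(nComponents)
    flip <- vapply(k, function(j) {
        l <- pc$rotation[, j]
        sign(l[which.max(abs(l))])
    }, numeric(1))
    scores <- sweep(pc$x[, k, drop = FALSE], 2, flip, `*`)
    vf <- (pc$sdev^2 / sum(pc$sdev^2))[k]
    list(scores = scores, varianceFraction = vf)
}
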