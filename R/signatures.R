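#' Median PMD methylation per sample
#'
#' Partially methylated domains lose methylation with accumulated cell
#' divisions; tracking their per-sample median beta against the cumulative
#' expansion rate makes that drift visible.
#'
#' @param meBeta beta-scale `MethylationExperiment`; the sample sheet should
#'   carry `cumulative_expansion_rate`.
#' @param pmdCore `GRanges` of the core PMD set.
#' @param manifest probe manifest.
#' @return `data.frame(sample_id, median_pmd_beta, cumulative_expansion_rate,
#'   log10_expansion, n_probes)`.
#' @export
pmdMedianTrack <- function(meBeta, pmdCore, manifest) {
    stopifnot(methods::is(meBeta, "MethylationExperiment"))
    ids <- intersect(probesInRegions(manifest, pmdCore), rownames(meBeta))
    if (!length(ids)) stop("no probes fall inside the PMD core set")
    beta <- methValues(meBeta)[ids, , drop = FALSE]
    sheet <- sampleSheet(meBeta)
    med <- apply(beta, 2, stats::median)
    er <- if ("cumulative_expansion_rate" %in% names(sheet))
        sheet$cumulative_expansion_rate[match(colnames(beta),
                                              sheet$sample_id)]
        else NA_real_
    data.frame(sample_id = colnames(beta), median_pmd_beta = as.numeric(med),
               cumulative_expansion_rate = er, log10_expansion = log10(er),
               n_probes = length(ids), row.names = NULL)
}

#' Per-CpG two-sample t-tests
#'
#' Student's two-sided two-sample t-test per probe between two sample
#' groups (equal-variance pooled by default, Welch by flag), via
#' [stats::t.test]. Probes constant in both groups with equal means get
#' `t = 0, p = 1` by convention.
#'
#' @param meBeta beta-scale `MethylationExperiment`.
#' @param probes probe ids to test.
#' @param groupA,groupB sample ids, each group >= 2.
#' @param welch use Welch's unequal-variance test (default `FALSE`).
#' @param alpha significance threshold (default 0.05).
#' @return `data.frame(probe_id, mean_A, mean_B, delta, t, p, significant)`.
#' @export
cpgGroupTtest <- function(meBeta, probes, groupA, groupB, welch = FALSE,
                          alpha = 0.05) {
    if (length(groupA) < 2 || length(groupB) < 2)
        stop("both groups need at least 2 samples")
    beta <- methValues(meBeta)
    probes <- intersect(probes, rownames(beta))
    res <- lapply(probes, function(pid) {
        a <- beta[pid, groupA]
        b <- beta[pid, groupB]
        if (stats::sd(a) == 0 && stats::sd(b) == 0) {
            tt <- if (mean(a) == mean(b)) list(statistic = 0, p.value = 1)
                  else list(statistic = sign(mean(a) - mean(b)) * Inf,
                            p.value = 0)
        } else {
            ht <- stats::t.test(a, b, var.equal = !welch)
            tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
        }
        data.frame(probe_id = pid, mean_A = mean(a), mean_B = mean(b),
                   delta = mean(a) - mean(b), t = tt$statistic,
                   p = tt$p.value)
    })
    out <- do.call(rbind, res)
    out$significant <- out$p < alpha
    rownames(out) <- NULL
    out
}

#' Expansion-stability regression for one CpG
#'
#' Ordinary least squares of beta on log10(cumulative expansion rate). A
#' CpG is classified "destabilized" when the fit is both strong
#' (`R^2 > r2Threshold`) and significant (`p < alpha`), the operational
#' definition of expansion-coupled remethylation at Treg-identity loci.
#'
#' @param beta numeric vector of beta values across samples.
#' @param expansion matching vector of cumulative expansion rates (> 0; at
#'   least 3 distinct values).
#' @param r2Threshold R-squared threshold (default 0.4).
#' @param alpha slope p-value threshold (default 0.05).
#' @return `data.frame(slope, intercept, r_squared, p, ci_lo, ci_hi,
#'   classified_destabilized)`; the slope is in beta units per log10
#'   expansion unit.
#' @export
stabilityRegression <- function(beta, expansion, r2Threshold = 0.4,
                                alpha = 0.05) {
    if (length(beta) != length(expansion))
        stop("beta and expansion must have the same length")
    if (any(expansion <= 0)) stop("expansion rates must be positive")
    x <- log10(expansion)
    if (length(unique(x)) < 3 || stats::var(x) == 0)
        stop("need at least 3 distinct expansion values")
    fit <- stats::lm(beta ~ x)
    # degenerate inputs (perfectly linear, constant) are legitimate here
    sm <- suppressWarnings(summary(fit))
    slope <- unname(stats::coef(fit)[2])
    p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else 1
    ci <- tryCatch(suppressWarnings(stats::confint(fit, "x", level = 0.95)),
                   error = function(e) c(NA, NA))
    r2 <- sm$r.squared
    data.frame(slope = slope, intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, p = p, ci_lo = ci[1], ci_hi = ci[2],
               classified_destabilized = r2 > r2Threshold & p < alpha)
}

#' Stability screen over a set of probes
#'
#' Runs [stabilityRegression()] for every probe and, when region labels are
#' supplied, adds a per-locus call: a locus is destabilized when the
#' majority of its member CpGs are.
#'
#' @param meBeta beta-scale `MethylationExperiment` with
#'   `cumulative_expansion_rate` in the sample sheet.
#' @param probes probe ids to screen.
#' @param labels optional named character vector (probe id -> locus label).
#' @param samples optional sample subset (default: all samples).
#' @param ... passed to [stabilityRegression()].
#' @return list with `cpg` (per-CpG results incl. `region`) and `locus`
#'   (per-locus majority calls, `NULL` without labels).
#' @export
stabilityScreen <- function(meBeta, probes, labels = NULL, samples = NULL,
                            ...) {
    sheet <- sampleSheet(meBeta)
    if (is.null(samples)) samples <- sheet$sample_id
    er <- sheet$cumulative_expansion_rate[match(samples, sheet$sample_id)]
    beta <- methValues(meBeta)
    probes <- intersect(probes, rownames(beta))
    res <- do.call(rbind, lapply(probes, function(pid)
        cbind(probe_id = pid,
              stabilityRegression(beta[pid, samples], er, ...))))
    rownames(res) <- NULL
    res$region <- if (is.null(labels)) NA_character_
                  else unname(labels[res$probe_id])
    locus <- NULL
    if (!is.null(labels)) {
        locus <- do.call(rbind, lapply(split(res, res$region), function(d)
            data.frame(region = d$region[1], n_cpgs = nrow(d),
                       mean_slope = mean(d$slope),
                       destabilized = mean(d$classified_destabilized) > 0.5)))
        rownames(locus) <- NULL
    }
    list(cpg = res, locus = locus)
}

#' Cross-tabulate chromatin states between two cell types
#'
#' For each probe, looks up its state label in two chromatin-state
#' segmentations and counts the (state A, state B) pairs; probes outside a
#' segmentation are counted under "unannotated".
#'
#' @param manifest probe manifest (rows define the probes to tabulate).
#' @param statesA,statesB labelled `GRanges` (metadata column `label`).
#' @return contingency `table` of state-in-A x state-in-B.
#' @export
crosstabChromatinStates <- function(manifest, statesA, statesB) {
    lookup <- function(states) {
        pts <- GenomicRanges::GRanges(
            seqnames = normalizeChrom(manifest$chrom),
            ranges = IRanges::IRanges(start = manifest$pos, width = 1L))
        hits <- GenomicRanges::findOverlaps(pts, states,
                                            ignore.strand = TRUE,
                                            select = "first")
        lab <- rep("unannotated", nrow(manifest))
        ok <- !is.na(hits)
        lab[ok] <- as.character(S4Vectors::mcols(states)$label[hits[ok]])
        lab
    }
    table(state_A = lookup(statesA), state_B = lookup(statesB))
}

#' Per-CpG differential methylation from bisulfite counts
#'
#' Joins two per-CpG methylated/total count tables by coordinate, keeps
#' CpGs with total coverage >= `minCoverage` in both groups, and tests each
#' with a pooled two-proportion z-test; `delta` is the methylation-fraction
#' difference A - B, and p-values are BH-adjusted.
#'
#' @param countsA,countsB `data.frame(chrom, start, methylated, total)` with
#'   0-based `start` (replicates already collapsed per group).
#' @param minCoverage coverage floor applied per group (default 10).
#' @return `data.frame(chrom, start, meth_A, total_A, meth_B, total_B,
#'   delta, z, p, fdr)`.
#' @export
wgbsDmps <- function(countsA, countsB, minCoverage = 10) {
    keyA <- paste(normalizeChrom(countsA$chrom), countsA$start)
    keyB <- paste(normalizeChrom(countsB$chrom), countsB$start)
    idx <- match(keyA, keyB)
    ok <- !is.na(idx)
    a <- countsA[ok, , drop = FALSE]
    b <- countsB[idx[ok], , drop = FALSE]
    covOk <- a$total >= minCoverage & b$total >= minCoverage
    if (!any(covOk)) stop("no CpG passes the coverage filter")
    a <- a[covOk, , drop = FALSE]
    b <- b[covOk, , drop = FALSE]
    pA <- a$methylated / a$total
    pB <- b$methylated / b$total
    pPool <- (a$methylated + b$methylated) / (a$total + b$total)
    se <- sqrt(pPool * (1 - pPool) * (1 / a$total + 1 / b$total))
    z <- ifelse(se > 0, (pA - pB) / se, 0)
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(chrom = normalizeChrom(a$chrom), start = a$start,
               meth_A = a$methylated, total_A = a$total,
               meth_B = b$methylated, total_B = b$total,
               delta = pA - pB, z = z, p = p, fdr = bhAdjust(p),
               row.names = NULL)
}

#' DMRs from bisulfite count statistics
#'
#' Applies the same kernel-smoothing, grouping and Stouffer machinery as
#' [callDmrs()] to the squared z statistics of [wgbsDmps()] output; used to
#' derive exhaustion DMRs from WGBS-style data.
#'
#' @param dmps output of [wgbsDmps()].
#' @param lambda,C,minCpgs,stoufferThreshold,fdrThreshold as in
#'   [smoothStats()] / [callDmrs()].
#' @return DMR `data.frame` as from [callDmrs()].
#' @export
wgbsDmrs <- function(dmps, lambda = 500, C = 3, minCpgs = 3,
                     stoufferThreshold = 0.05, fdrThreshold = 0.05) {
    asDmp <- data.frame(
        probe_id = paste0(dmps$chrom, ":", dmps$start),
        chrom = dmps$chrom, pos = dmps$start + 1L,
        delta_beta = dmps$delta, t_mod = dmps$z, p = dmps$p)
    sm <- smoothStats(asDmp, lambda = lambda, C = C)
    callDmrs(sm, lambda = lambda, minCpgs = minCpgs,
             stoufferThreshold = stoufferThreshold,
             fdrThreshold = fdrThreshold)
}

#' Concordance of Late shared DMRs with exhaustion DMRs
#'
#' For each Late shared DMR, checks whether exhaustion DMRs cover at least
#' `minFraction` of its (merged) interval, records both deltas and whether
#' the direction of change agrees, and summarizes: overall overlap
#' fraction, per-direction concordance, and the fraction of
#' concordant-hypermethylated DMRs mapping to promoters (when feature
#' annotation is present).
#'
#' @param lateShared shared-DMR table restricted to Late DMRs (columns
#'   `chrom, start, end, direction, run1_delta, run2_delta`, optional
#'   `feature`).
#' @param exhDmrs DMR table (e.g. from [wgbsDmrs()]).
#' @param minFraction coverage rule on the shared DMR's length
#'   (default 0.5).
#' @return list with `table` (per overlapping DMR) and `summary`.
#' @export
exhConcordance <- function(lateShared, exhDmrs, minFraction = 0.5) {
    n <- nrow(lateShared)
    rows <- list()
    for (i in seq_len(n)) {
        a <- lateShared[i, ]
        cand <- exhDmrs[exhDmrs$chrom == a$chrom, , drop = FALSE]
        if (!nrow(cand)) next
        ov <- pmax(0, pmin(a$end, cand$end) - pmax(a$start, cand$start))
        if (!any(ov > 0)) next
        iv <- IRanges::reduce(IRanges::IRanges(
            pmax(cand$start[ov > 0], a$start) + 1L,
            pmin(cand$end[ov > 0], a$end)))
        frac <- sum(IRanges::width(iv)) / (a$end - a$start)
        if (frac < minFraction) next
        best <- cand[which.max(ov), ]
        sharedDelta <- mean(c(a$run1_delta, a$run2_delta), na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = a$chrom, start = a$start, end = a$end,
            direction = a$direction, shared_delta = sharedDelta,
            exh_delta = best$mean_delta_beta,
            exh_direction = best$direction,
            concordant = sign(sharedDelta) == sign(best$mean_delta_beta),
            feature = if ("feature" %in% names(a)) a$feature
                      else NA_character_)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   direction = character(), shared_delta = numeric(),
                   exh_delta = numeric(), exh_direction = character(),
                   concordant = logical(), feature = character())
    rownames(tab) <- NULL
    hyperExh <- tab[tab$exh_direction %in% "hyper", , drop = FALSE]
    concHyper <- hyperExh[hyperExh$concordant, , drop = FALSE]
    summary <- list(
        n_late = n,
        n_overlapping = nrow(tab),
        overlap_fraction = if (n) nrow(tab) / n else 0,
        concordance_overall = if (nrow(tab)) mean(tab$concordant) else NA_real_,
        concordance_hyper = if (nrow(hyperExh)) mean(hyperExh$concordant)
                            else NA_real_,
        fraction_concordant_hyper_promoter =
            if (nrow(concHyper) && !all(is.na(concHyper$feature)))
                mean(concHyper$feature %in% "promoter") else NA_real_)
    list(table = tab, summary = summary)
}
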