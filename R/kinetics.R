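#' Match shared DMRs across production runs
#'
#' A run-1 DMR is "shared" when at least `minFraction` of its length is
#' covered by run-2 DMRs of the same direction; it is then paired with the
#' single run-2 DMR contributing the largest overlap, and the merged
#' interval is the union of the pair. A run-1 DMR whose best-overlapping
#' run-2 DMR (any overlap) has the opposite direction is excluded and
#' counted as discordant. The coverage denominator is always the run-1
#' DMR's length; set `symmetric = TRUE` to additionally require the
#' reciprocal fraction on the run-2 side.
#'
#' @param run1Dmrs,run2Dmrs DMR tables from [callDmrs()] (same contrast
#'   definition in both runs).
#' @param minFraction minimum covered fraction of the run-1 DMR
#'   (default 0.5).
#' @param symmetric also require >= `minFraction` of the matched run-2 DMR
#'   to be covered (default `FALSE`).
#' @return list with `shared` (one row per shared DMR: run-1 and run-2
#'   coordinates and statistics, merged interval, direction, covered
#'   fraction) and `discordant` (count of direction-discordant run-1 DMRs).
#' @export
matchSharedDmrs <- function(run1Dmrs, run2Dmrs, minFraction = 0.5,
                            symmetric = FALSE) {
    empty <- data.frame(
        chrom = character(), start = integer(), end = integer(),
        direction = character(), fraction_covered = numeric(),
        run1_start = integer(), run1_end = integer(),
        run1_n_cpgs = integer(), run1_delta = numeric(),
        run1_stouffer_p = numeric(),
        run2_start = integer(), run2_end = integer(),
        run2_n_cpgs = integer(), run2_delta = numeric(),
        run2_stouffer_p = numeric())
    if (!nrow(run1Dmrs) || !nrow(run2Dmrs))
        return(list(shared = empty, discordant = 0L))
    shared <- list()
    discordant <- 0L
    for (i in seq_len(nrow(run1Dmrs))) {
        a <- run1Dmrs[i, ]
        cand <- run2Dmrs[run2Dmrs$chrom == a$chrom, , drop = FALSE]
        if (!nrow(cand)) next
        ov <- pmax(0, pmin(a$end, cand$end) - pmax(a$start, cand$start))
        if (!any(ov > 0)) next
        best <- which.max(ov)
        if (cand$direction[best] != a$direction) {
            discordant <- discordant + 1L
            next
        }
        same <- cand[cand$direction == a$direction & ov > 0, , drop = FALSE]
        # union coverage of a by same-direction run-2 DMRs
        iv <- IRanges::reduce(IRanges::IRanges(
            pmax(same$start, a$start) + 1L, pmin(same$end, a$end)))
        frac <- sum(IRanges::width(iv)) / (a$end - a$start)
        if (frac < minFraction) next
        b <- cand[best, ]
        if (symmetric) {
            ovB <- pmax(0, pmin(b$end, run1Dmrs$end) -
                            pmax(b$start, run1Dmrs$start))
            ovB[run1Dmrs$chrom != b$chrom |
                run1Dmrs$direction != b$direction] <- 0
            if (sum(ovB) / (b$end - b$start) < minFraction) next
        }
        shared[[length(shared) + 1L]] <- data.frame(
            chrom = a$chrom,
            start = min(a$start, b$start), end = max(a$end, b$end),
            direction = a$direction, fraction_covered = frac,
            run1_start = a$start, run1_end = a$end,
            run1_n_cpgs = a$n_cpgs, run1_delta = a$mean_delta_beta,
            run1_stouffer_p = a$stouffer_p,
            run2_start = b$start, run2_end = b$end,
            run2_n_cpgs = b$n_cpgs, run2_delta = b$mean_delta_beta,
            run2_stouffer_p = b$stouffer_p)
    }
    shared <- if (length(shared)) do.call(rbind, shared) else empty
    rownames(shared) <- NULL
    list(shared = shared, discordant = discordant)
}

# is the interval (chrom,start,end,direction) present in a DMR set, i.e.
# covered >= minFraction by same-direction DMRs of that set?
.inDmrSet <- function(chrom, start, end, direction, dmrSet,
                      minFraction = 0.5) {
    if (is.null(dmrSet) || !nrow(dmrSet)) return(FALSE)
    cand <- dmrSet[dmrSet$chrom == chrom & dmrSet$direction == direction, ,
                   drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    ov <- pmax(0, pmin(end, cand$end) - pmax(start, cand$start))
    cand <- cand[ov > 0, , drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    iv <- IRanges::reduce(IRanges::IRanges(
        pmax(cand$start, start) + 1L, pmin(cand$end, end)))
    sum(IRanges::width(iv)) / (end - start) >= minFraction
}

#' Early/Late kinetic classification of a DMR
#'
#' A DMR is "early" when it is present (>= `minFraction` same-direction
#' overlap) in both the day-10-vs-day-0 and the day-23-vs-day-0 DMR sets of
#' its run; "late" when present only in the day-23 set; "none" otherwise
#' (including day-10-only, a transient change that did not persist).
#'
#' @param dmr one-row DMR record (needs `chrom`, `start`, `end`,
#'   `direction`).
#' @param day10Dmrs,day23Dmrs DMR tables from the day-10-vs-day-0 and
#'   day-23-vs-day-0 contrasts of the same run.
#' @param minFraction overlap rule for cross-contrast identity
#'   (default 0.5).
#' @return one of `"early"`, `"late"`, `"none"`.
#' @export
classifyKinetics <- function(dmr, day10Dmrs, day23Dmrs, minFraction = 0.5) {
    in10 <- .inDmrSet(dmr$chrom, dmr$start, dmr$end, dmr$direction,
                      day10Dmrs, minFraction)
    in23 <- .inDmrSet(dmr$chrom, dmr$start, dmr$end, dmr$direction,
                      day23Dmrs, minFraction)
    if (in10 && in23) "early" else if (!in10 && in23) "late" else "none"
}

#' Attach per-run kinetic labels to shared DMRs
#'
#' @param shared shared-DMR table from [matchSharedDmrs()].
#' @param run1Day10,run1Day23,run2Day10,run2Day23 DMR tables for the two
#'   contrasts of each run.
#' @param minFraction overlap rule (default 0.5).
#' @return `shared` with `kinetic_run1`, `kinetic_run2` and
#'   `consistent_kinetics` appended.
#' @export
labelSharedKinetics <- function(shared, run1Day10, run1Day23,
                                run2Day10, run2Day23, minFraction = 0.5) {
    n <- nrow(shared)
    k1 <- k2 <- character(n)
    for (i in seq_len(n)) {
        r1 <- data.frame(chrom = shared$chrom[i],
                         start = shared$run1_start[i],
                         end = shared$run1_end[i],
                         direction = shared$direction[i])
        r2 <- data.frame(chrom = shared$chrom[i],
                         start = shared$run2_start[i],
                         end = shared$run2_end[i],
                         direction = shared$direction[i])
        k1[i] <- classifyKinetics(r1, run1Day10, run1Day23, minFraction)
        k2[i] <- classifyKinetics(r2, run2Day10, run2Day23, minFraction)
    }
    shared$kinetic_run1 <- k1
    shared$kinetic_run2 <- k2
    shared$consistent_kinetics <- k1 == k2
    shared
}

#' Composition summary of shared DMRs
#'
#' @param shared shared-DMR table, ideally after [labelSharedKinetics()]
#'   and [annotateDmrs()].
#' @return list with `by_direction`, `by_kinetics` (run-1 label), and when
#'   available `by_feature` count/fraction tables, plus
#'   `fraction_kinetics_differ` (share of DMRs whose two runs disagree on
#'   Early/Late).
#' @export
summarizeShared <- function(shared) {
    n <- nrow(shared)
    tab <- function(x) {
        t <- table(x)
        data.frame(level = names(t), count = as.integer(t),
                   fraction = as.numeric(t) / max(n, 1), row.names = NULL)
    }
    out <- list(n = n, by_direction = tab(shared$direction))
    if ("kinetic_run1" %in% names(shared)) {
        out$by_kinetics <- tab(shared$kinetic_run1)
        out$fraction_kinetics_differ <-
            if (n) mean(!shared$consistent_kinetics) else NA_real_
    }
    if ("feature" %in% names(shared)) out$by_feature <- tab(shared$feature)
    out
}

#' Mean DMR methylation per time point
#'
#' For each shared DMR, averages beta across its member probes and across
#' the samples of each (run, day) group; the long-format result supports
#' methylation time-series plots.
#'
#' @param meBeta beta-scale `MethylationExperiment` whose sample sheet has
#'   `run` and `day` columns.
#' @param shared shared-DMR table (merged intervals are used).
#' @param manifest probe manifest.
#' @return long `data.frame(dmr_id, chrom, start, end, run, day, mean_beta,
#'   n_probes)`; DMRs with no surviving probes are dropped with a warning.
#' @export
meanDmrMethylationTrack <- function(meBeta, shared, manifest) {
    stopifnot(methods::is(meBeta, "MethylationExperiment"))
    sheet <- sampleSheet(meBeta)
    beta <- methValues(meBeta)
    groups <- unique(sheet[, c("run", "day")])
    out <- list()
    dropped <- 0L
    for (i in seq_len(nrow(shared))) {
        gr <- GenomicRanges::GRanges(
            shared$chrom[i],
            IRanges::IRanges(shared$start[i] + 1L, shared$end[i]))
        ids <- probesInRegions(manifest, gr)
        ids <- intersect(ids, rownames(beta))
        if (!length(ids)) { dropped <- dropped + 1L; next }
        for (j in seq_len(nrow(groups))) {
            s <- sheet$sample_id[sheet$run == groups$run[j] &
                                 sheet$day == groups$day[j]]
            out[[length(out) + 1L]] <- data.frame(
                dmr_id = i, chrom = shared$chrom[i],
                start = shared$start[i], end = shared$end[i],
                run = groups$run[j], day = groups$day[j],
                mean_beta = mean(beta[ids, s, drop = FALSE]),
                n_probes = length(ids))
        }
    }
    if (dropped)
        warning(dropped, " shared DMR(s) had no surviving probes and were dropped")
    if (!length(out))
        return(data.frame(dmr_id = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          run = character(), day = integer(),
                          mean_beta = numeric(), n_probes = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
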