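#' Default planted-DMR layout
#'
#' Twenty regions of five CpGs each with an absolute beta change of 0.2 by
#' the final day: 12 hypermethylating / 8 hypomethylating, half with
#' early-saturating and half with late-accelerating kinetics.
#'
#' @param n number of regions.
#' @param nCpgs CpGs per region (>= 3).
#' @param deltaBeta planted effect size in `[0, 0.5]`.
#' @param hyperFraction fraction of regions that gain methylation.
#' @return `data.frame(n_cpgs, direction, kinetics, delta_beta)`.
#' @export
defaultPlantedDmrs <- function(n = 20, nCpgs = 5, deltaBeta = 0.2,
                               hyperFraction = 0.6) {
    nHyper <- round(n * hyperFraction)
    data.frame(
        n_cpgs = rep(nCpgs, n),
        direction = rep(c("hyper", "hypo"), c(nHyper, n - nHyper)),
        kinetics = rep_len(c("early", "late"), n),
        delta_beta = rep(deltaBeta, n))
}

#' Simulation design for an array-style methylation time course
#'
#' Captures the study layout being emulated: a small number of donors taken
#' through two independent manufacturing runs, sampled at day 0, an
#' intermediate day and the final day, with planted differentially
#' methylated regions, partially methylated domains coupled to the
#' cumulative expansion rate, and Treg-identity loci that remethylate with
#' expansion (except for stable anchor loci).
#'
#' @param nProbes total probe count (must be at least 10x the number of
#'   planted regions).
#' @param nChromosomes autosome count the probes are spread over.
#' @param donors,runs character labels.
#' @param days integer day values, ascending and including 0.
#' @param cellsPerGroup replicate samples per donor x run x day.
#' @param plantedDmrs `data.frame` as from [defaultPlantedDmrs()].
#' @param pmdFraction fraction of the autosomal genome inside PMDs.
#' @param tregdrCount number of Treg-identity (Treg-DR) loci; the first two
#'   are expansion-stable anchors (FOXP3-like, TNFRSF1B-like).
#' @param seed integer seed; a fixed seed makes every simulated artifact
#'   byte-identical across runs.
#' @param sigmaM per-entry Gaussian noise SD on the M scale.
#' @param donorSd SD of per-probe donor random intercepts (M scale).
#' @param batchRunSd SD of the per-run mean additive batch shift (M scale).
#' @param batchAddSd SD of per-probe additive batch effects around the run
#'   mean (M scale).
#' @param batchScaleSd SD of the log multiplicative (scale) batch effect.
#' @param pmdSlope beta lost per log10 expansion unit at PMD probes.
#' @param tregdrSlope beta gained per log10 expansion unit at non-anchor
#'   Treg-DR probes.
#' @param tregdrNoiseSd extra beta-scale noise SD at Treg-DR probes
#'   (default 0: all measurement noise is generated on the M scale, the
#'   scale the differential model assumes; nonzero values are a stress knob
#'   for exploring heteroscedastic loci).
#' @param detpFailRate per-entry detection failure rate.
#' @param snpProximalFraction fraction of probes within 3 nt of a SNP.
#' @param crossReactiveFraction,vendorDroppedFraction QC-flag fractions.
#' @param sexProbeFraction fraction of probes placed on chrX/chrY.
#' @return validated list of class `"SimDesign"`.
#' @export
simDesign <- function(nProbes = 10000, nChromosomes = 4,
                      donors = c("D1", "D2", "D3"),
                      runs = c("R1", "R2"), days = c(0, 10, 23),
                      cellsPerGroup = 1,
                      plantedDmrs = defaultPlantedDmrs(),
                      pmdFraction = 0.2, tregdrCount = 6, seed = 1,
                      sigmaM = 0.12, donorSd = 0.08, batchRunSd = 0.2,
                      batchAddSd = 0.15, batchScaleSd = 0.1,
                      pmdSlope = 0.05, tregdrSlope = 0.15,
                      tregdrNoiseSd = 0, detpFailRate = 0.002,
                      snpProximalFraction = 0.02,
                      crossReactiveFraction = 0.01,
                      vendorDroppedFraction = 0.005,
                      sexProbeFraction = 0.02) {
    if (is.unsorted(days, strictly = TRUE) || days[1] != 0)
        stop("days must be strictly ascending and include day 0")
    if (nrow(plantedDmrs) && nProbes < 10 * nrow(plantedDmrs))
        stop("nProbes must be at least 10x the number of planted regions")
    if (nrow(plantedDmrs)) {
        if (any(plantedDmrs$n_cpgs < 3))
            stop("planted regions need at least 3 CpGs")
        if (any(plantedDmrs$delta_beta < 0 | plantedDmrs$delta_beta > 0.5))
            stop("planted delta_beta must lie in [0, 0.5]")
        if (!all(plantedDmrs$direction %in% c("hyper", "hypo")))
            stop("planted direction must be 'hyper' or 'hypo'")
        if (!all(plantedDmrs$kinetics %in% c("early", "late")))
            stop("planted kinetics must be 'early' or 'late'")
    }
    stopifnot(pmdFraction >= 0, pmdFraction < 1, tregdrCount >= 0,
              cellsPerGroup >= 1)
    structure(as.list(environment()), class = "SimDesign")
}

#' @export
print.SimDesign <- function(x, ...) {
    cat("SimDesign:", x$nProbes, "probes,", x$nChromosomes, "autosomes,",
        length(x$donors), "donors x", length(x$runs), "runs x",
        length(x$days), "days;", nrow(x$plantedDmrs), "planted DMRs; seed",
        x$seed, "\n")
    invisible(x)
}

# kinetic response fractions: early saturates (>= 80% of the effect by the
# intermediate day); late models late-onset remodeling - flat through the
# intermediate day (a late region is by definition not yet changed when
# first assayed), then rising quadratically to the full effect at the final
# day
.kineticFraction <- function(day, maxDay, kinetics, onsetDay) {
    ifelse(kinetics == "early",
           (1 - exp(-day / 4)) / (1 - exp(-maxDay / 4)),
           pmax(0, (day - onsetDay) / (maxDay - onsetDay))^2)
}

#' Simulate the probe manifest, gene model and region sets
#'
#' Places probes in CpG-island-like clusters over the autosomes (plus a
#' small chrX/chrY contingent), hosts every planted region in a dedicated
#' cluster, lays out a toy gene model, and derives PMD, Treg-DR,
#' chromatin-state and blacklist region sets consistent with the probe
#' coordinates. QC flags (SNP proximity, cross-reactivity, vendor drops)
#' are sprinkled at the design's fractions.
#'
#' @param design a [simDesign()] object.
#' @return list of class `"ManifestBundle"`: `manifest` (probe table,
#'   1-based `pos`), `geneModel`, `regions` (named `GRanges` list: `pmd`,
#'   `tregdr`, `states_treg`, `states_cd4mem`, `blacklist`), `planted`
#'   (region truth coordinates, 0-based half-open), `probeMeta`,
#'   `chromLengths`, `design`.
#' @export
simulateManifest <- function(design) {
    stopifnot(inherits(design, "SimDesign"))
    set.seed(design$seed)
    planted <- design$plantedDmrs
    nPlanted <- nrow(planted)
    nPlantedProbes <- if (nPlanted) sum(planted$n_cpgs) else 0
    nSex <- round(design$nProbes * design$sexProbeFraction)
    nBg <- design$nProbes - nSex - nPlantedProbes
    if (nBg < design$nChromosomes * 10)
        stop("nProbes too small to host the planted regions")

    autosomes <- paste0("chr", seq_len(design$nChromosomes))
    bgQuota <- rep(nBg %/% design$nChromosomes, design$nChromosomes)
    bgQuota[seq_len(nBg %% design$nChromosomes)] <-
        bgQuota[seq_len(nBg %% design$nChromosomes)] + 1L
    plantedChrom <- if (nPlanted)
        autosomes[(seq_len(nPlanted) - 1L) %% design$nChromosomes + 1L]
        else character()

    probeRows <- list()
    plantedCoords <- list()
    chromLengths <- numeric()
    clusterOfProbe <- integer()
    clusterCounter <- 0L
    for (ci in seq_along(autosomes)) {
        ch <- autosomes[ci]
        sizes <- integer()
        while (sum(sizes) < bgQuota[ci])
            sizes <- c(sizes, 1L + stats::rpois(1, 4))
        sizes[length(sizes)] <- sizes[length(sizes)] -
            (sum(sizes) - bgQuota[ci])
        sizes <- sizes[sizes > 0]
        clusters <- lapply(sizes, function(s) list(type = "bg", n = s))
        pIdx <- which(plantedChrom == ch)
        for (pi in pIdx)
            clusters[[length(clusters) + 1L]] <-
                list(type = "planted", id = pi, n = planted$n_cpgs[pi])
        clusters <- clusters[sample.int(length(clusters))]
        pos <- 0
        for (cl in clusters) {
            clusterCounter <- clusterCounter + 1L
            pos <- pos + 3000 + round(stats::rexp(1, 1 / 20000))
            gaps <- if (cl$type == "planted")
                sample(40:120, cl$n - 1, replace = TRUE)
                else sample(30:300, max(cl$n - 1, 0), replace = TRUE)
            p <- pos + cumsum(c(0, gaps))
            pos <- p[length(p)]
            probeRows[[length(probeRows) + 1L]] <- data.frame(
                chrom = ch, pos = p,
                planted_id = if (cl$type == "planted") cl$id else NA_integer_)
            clusterOfProbe <- c(clusterOfProbe, rep(clusterCounter, cl$n))
            if (cl$type == "planted")
                plantedCoords[[cl$id]] <- data.frame(
                    region_id = cl$id, chrom = ch,
                    start = p[1] - 1L, end = p[length(p)])
        }
        chromLengths[ch] <- pos + 20000
    }
    # sex-chromosome probes (never planted)
    for (ch in c("chrX", "chrY")) {
        n <- if (ch == "chrX") ceiling(nSex * 2 / 3) else nSex - ceiling(nSex * 2 / 3)
        if (n <= 0) { chromLengths[ch] <- 1e5; next }
        p <- sort(sample.int(5e6, n))
        clusterCounter <- clusterCounter + 1L
        probeRows[[length(probeRows) + 1L]] <- data.frame(
            chrom = ch, pos = p, planted_id = NA_integer_)
        clusterOfProbe <- c(clusterOfProbe, rep(clusterCounter, n))
        chromLengths[ch] <- max(p) + 20000
    }
    probes <- do.call(rbind, probeRows)
    ord <- order(match(probes$chrom, c(autosomes, "chrX", "chrY")),
                 probes$pos)
    probes <- probes[ord, ]
    clusterOfProbe <- clusterOfProbe[ord]
    probes$probe_id <- sprintf("cg%08d", seq_len(nrow(probes)))

    # QC flags
    G <- nrow(probes)
    snpNear <- stats::runif(G) < design$snpProximalFraction
    snpFar <- !snpNear & stats::runif(G) < 0.03
    probes$snp_distance <- NA_integer_
    probes$snp_distance[snpNear] <- sample(0:3, sum(snpNear), replace = TRUE)
    probes$snp_distance[snpFar] <- sample(4:100, sum(snpFar), replace = TRUE)
    probes$cross_reactive <- stats::runif(G) < design$crossReactiveFraction
    probes$dropped_by_vendor <- stats::runif(G) < design$vendorDroppedFraction

    plantedDf <- if (nPlanted) {
        cbind(do.call(rbind, plantedCoords),
              planted[, c("n_cpgs", "direction", "kinetics", "delta_beta")])
    } else {
        data.frame(region_id = integer(), chrom = character(),
                   start = integer(), end = integer(), n_cpgs = integer(),
                   direction = character(), kinetics = character(),
                   delta_beta = numeric())
    }

    # Treg-DR loci: background autosomal clusters with >= 3 probes
    tregdrLabels <- c("FOXP3like", "TNFRSF1Blike", "IKZF2like", "IL2RAlike",
                      "IKZF4like", "CTLA4like", "LRRC32like", "TIGITlike")
    tregdr <- GenomicRanges::GRanges()
    probes$tregdr_label <- NA_character_
    if (design$tregdrCount > 0) {
        eligible <- tapply(seq_len(G), clusterOfProbe, function(i) {
            if (length(i) >= 3 && all(is.na(probes$planted_id[i])) &&
                probes$chrom[i[1]] %in% autosomes) i[1:3] else NULL
        })
        eligible <- Filter(Negate(is.null), eligible)
        if (length(eligible) < design$tregdrCount)
            stop("not enough probe clusters to host the Treg-DR loci")
        pick <- sample(seq_along(eligible), design$tregdrCount)
        lab <- rep_len(tregdrLabels, design$tregdrCount)
        iv <- do.call(rbind, lapply(seq_along(pick), function(j) {
            i <- eligible[[pick[j]]]
            probes$tregdr_label[i] <<- lab[j]
            data.frame(chrom = probes$chrom[i[1]],
                       start = min(probes$pos[i]) - 51L,
                       end = max(probes$pos[i]) + 50L, label = lab[j])
        }))
        tregdr <- .df2gr(iv)
        S4Vectors::mcols(tregdr)$label <- iv$label
    }

    # PMD core set: sampled 25-kb grid segments avoiding planted/Treg-DR loci
    special <- suppressWarnings(GenomicRanges::reduce(c(
        GenomicRanges::granges(.df2gr(plantedDf[, c("chrom", "start", "end")])),
        GenomicRanges::granges(tregdr))))
    pmdList <- list()
    for (ch in autosomes) {
        len <- chromLengths[ch]
        gridStart <- seq(0, len - 25000, by = 25000)
        seg <- GenomicRanges::GRanges(ch, IRanges::IRanges(gridStart + 1,
                                                           gridStart + 25000))
        bad <- GenomicRanges::countOverlaps(
            seg, special[GenomicRanges::seqnames(special) == ch]) > 0
        seg <- seg[!bad]
        need <- ceiling(design$pmdFraction * len / 25000)
        if (length(seg) && need > 0) {
            # PMDs are gene-poor while array probes concentrate at genes and
            # CpG islands, so PMD segments are drawn preferring probe-poor
            # stretches: the array under-samples PMDs as real arrays do
            pts <- GenomicRanges::GRanges(ch, IRanges::IRanges(
                probes$pos[probes$chrom == ch], width = 1))
            dens <- GenomicRanges::countOverlaps(seg, pts)
            w <- 1 / (1 + dens)
            pick <- sample(seq_along(seg), min(need, length(seg)),
                           prob = w / sum(w))
            pmdList[[ch]] <- seg[sort(pick)]
        }
    }
    pmd <- if (length(pmdList))
        suppressWarnings(GenomicRanges::reduce(do.call(c, unname(pmdList))))
        else GenomicRanges::GRanges()

    # toy gene model
    genes <- exons <- utrs <- list()
    gi <- 0L
    for (ch in autosomes) {
        pos <- 10000
        while (pos + 25000 < chromLengths[ch]) {
            gi <- gi + 1L
            span <- sample(8000:25000, 1)
            strand <- sample(c("+", "-"), 1)
            gid <- sprintf("GENE%04d", gi)
            genes[[gi]] <- data.frame(
                gene_id = gid, name = gid, chrom = ch, strand = strand,
                start = pos, end = pos + span)
            b <- round(c(0, 0.15, 0.45, 0.6, 0.85, 1) * span) + pos
            ex <- data.frame(gene_id = gid, chrom = ch,
                             start = b[c(1, 3, 5)], end = b[c(2, 4, 6)])
            exons[[gi]] <- ex
            utrs[[gi]] <- data.frame(
                gene_id = gid, chrom = ch,
                start = c(ex$start[1], ex$end[3] - 300),
                end = c(ex$start[1] + 300, ex$end[3]),
                side = if (strand == "+") c("five_utr", "three_utr")
                       else c("three_utr", "five_utr"))
            pos <- pos + span + sample(30000:80000, 1)
        }
    }
    geneModel <- structure(list(genes = do.call(rbind, genes),
                                exons = do.call(rbind, exons),
                                utrs = do.call(rbind, utrs)),
                           class = "GeneModel")
    geneModel$genes$tss <- ifelse(geneModel$genes$strand == "-",
                                  geneModel$genes$end - 1L,
                                  geneModel$genes$start)

    # chromatin-state segmentations for two cell types
    stateLabels <- c("TssA", "Enh", "EnhG", "Tx", "ReprPC", "Quies")
    stateProbs <- c(0.08, 0.15, 0.07, 0.2, 0.15, 0.35)
    mkStates <- function(forced) {
        segs <- list()
        for (ch in autosomes) {
            bounds <- 0
            while (bounds[length(bounds)] < chromLengths[ch])
                bounds <- c(bounds, bounds[length(bounds)] + 2000 +
                                round(stats::rexp(1, 1 / 10000)))
            bounds[length(bounds)] <- chromLengths[ch]
            n <- length(bounds) - 1
            segs[[ch]] <- data.frame(
                chrom = ch, start = bounds[-length(bounds)],
                end = bounds[-1],
                label = sample(stateLabels, n, replace = TRUE,
                               prob = stateProbs))
        }
        df <- do.call(rbind, segs)
        gr <- .df2gr(df)
        S4Vectors::mcols(gr)$label <- df$label
        if (length(tregdr)) {
            hit <- GenomicRanges::countOverlaps(gr, tregdr) > 0
            S4Vectors::mcols(gr)$label[hit] <- forced
        }
        gr
    }
    statesTreg <- mkStates("EnhG")
    statesCd4 <- mkStates("Quies")

    # blacklist: a couple of intervals per autosome
    bl <- do.call(rbind, lapply(autosomes, function(ch) {
        s <- sort(sample.int(chromLengths[ch] - 5000, 2))
        data.frame(chrom = ch, start = s, end = s + sample(2000:5000, 2))
    }))
    blacklist <- .df2gr(bl)

    probeMeta <- data.frame(
        probe_id = probes$probe_id, planted_id = probes$planted_id,
        tregdr_label = probes$tregdr_label,
        anchor = probes$tregdr_label %in% tregdrLabels[1:2],
        pmd = probes$probe_id %in% probesInRegions(probes, pmd))
    manifest <- probes[, c("probe_id", "chrom", "pos", "snp_distance",
                           "cross_reactive", "dropped_by_vendor")]
    rownames(manifest) <- NULL

    structure(list(manifest = manifest, geneModel = geneModel,
                   regions = list(pmd = pmd, tregdr = tregdr,
                                  states_treg = statesTreg,
                                  states_cd4mem = statesCd4,
                                  blacklist = blacklist),
                   planted = plantedDf, probeMeta = probeMeta,
                   chromLengths = chromLengths, design = design),
              class = "ManifestBundle")
}

#' @export
print.ManifestBundle <- function(x, ...) {
    cat("ManifestBundle:", nrow(x$manifest), "probes on",
        length(x$chromLengths), "chromosomes;", nrow(x$planted),
        "planted regions;", length(x$regions$tregdr), "Treg-DR loci\n")
    invisible(x)
}

#' Simulate cumulative expansion rates
#'
#' Per donor x run, fold-expansion grows exponentially with culture day
#' (about three orders of magnitude by the final day, with donor- and
#' run-level lognormal jitter); it equals 1 at day 0 and is non-decreasing
#' within a donor.
#'
#' @param design a [simDesign()] object.
#' @param log10FinalMean,log10FinalSd mean/SD of the log10 final fold
#'   expansion.
#' @return `data.frame(donor, run, day, cumulative_expansion_rate)`.
#' @export
simulateExpansion <- function(design, log10FinalMean = 3,
                              log10FinalSd = 0.3) {
    set.seed(design$seed + 101L)
    maxDay <- max(design$days)
    grid <- expand.grid(donor = design$donors, run = design$runs,
                        stringsAsFactors = FALSE)
    grid$k <- stats::rnorm(nrow(grid), log10FinalMean, log10FinalSd) / maxDay
    out <- merge(grid, data.frame(day = design$days))
    out$cumulative_expansion_rate <- 10^(out$k * out$day)
    out[order(out$run, out$donor, out$day),
        c("donor", "run", "day", "cumulative_expansion_rate")]
}

#' Simulate the methylation time course
#'
#' Draws baseline beta values from a bimodal mixture (low mode near 0.1,
#' high mode near 0.85), applies the planted DMR kinetics, PMD
#' hypomethylation proportional to log10 cumulative expansion, and Treg-DR
#' remethylation (anchor loci stay flat), then adds donor random
#' intercepts, run-specific additive + multiplicative batch effects and
#' Gaussian noise on the M scale before transforming back to beta. A
#' detection-p matrix with the design's failure rate accompanies the beta
#' matrix.
#'
#' @param design a [simDesign()] object.
#' @param bundle the matching [simulateManifest()] output.
#' @param expansion optional expansion series as from [simulateExpansion()]
#'   (generated when `NULL`); must cover every donor x run x day
#'   combination.
#' @return list with `me` (beta-scale [MethylationExperiment-class] with
#'   detection-p and sample sheet), `truth` (planted-region table) and
#'   `expansion`.
#' @export
simulateTimecourse <- function(design, bundle, expansion = NULL) {
    stopifnot(inherits(design, "SimDesign"),
              inherits(bundle, "ManifestBundle"))
    if (is.null(expansion)) expansion <- simulateExpansion(design)
    sheet <- expand.grid(rep = seq_len(design$cellsPerGroup),
                         day = design$days, donor = design$donors,
                         run = design$runs, stringsAsFactors = FALSE)
    key <- paste(sheet$donor, sheet$run, sheet$day)
    eKey <- paste(expansion$donor, expansion$run, expansion$day)
    idx <- match(key, eKey)
    if (anyNA(idx))
        stop("expansion series inconsistent with the sample sheet")
    sheet$cumulative_expansion_rate <- expansion$cumulative_expansion_rate[idx]
    sheet$cell_type <- "TregProduct"
    sheet$sample_id <- sprintf("%s_%s_d%02d%s", sheet$run, sheet$donor,
                               sheet$day,
                               ifelse(design$cellsPerGroup > 1,
                                      paste0("_r", sheet$rep), ""))
    sheet <- sheet[, c("sample_id", "donor", "run", "day", "cell_type",
                       "cumulative_expansion_rate")]

    set.seed(design$seed + 1L)
    meta <- bundle$probeMeta
    G <- nrow(meta)
    S <- nrow(sheet)
    maxDay <- max(design$days)

    # bimodal baseline with the intermediate shoulder real arrays show:
    # ~55% high (~0.85), ~30% low (~0.1), ~15% intermediate
    comp <- stats::runif(G)
    base <- numeric(G)
    base[comp < 0.55] <- stats::rbeta(sum(comp < 0.55), 17, 3)
    base[comp >= 0.55 & comp < 0.85] <-
        stats::rbeta(sum(comp >= 0.55 & comp < 0.85), 2, 18)
    base[comp >= 0.85] <- stats::rbeta(sum(comp >= 0.85), 5, 5)
    base[meta$pmd] <- stats::rbeta(sum(meta$pmd), 13, 7)     # ~0.65
    isTregdr <- !is.na(meta$tregdr_label)
    base[isTregdr] <- 0.05 + stats::runif(sum(isTregdr), 0, 0.05)

    plantedIdx <- which(!is.na(meta$planted_id))
    pid <- meta$planted_id[plantedIdx]
    planted <- bundle$planted
    dirSign <- ifelse(planted$direction == "hyper", 1, -1)[pid]
    deltaV <- planted$delta_beta[pid]
    kinV <- planted$kinetics[pid]
    # keep room for the full planted effect in either direction
    base[plantedIdx] <- .clamp(base[plantedIdx],
                               0.05 + deltaV * (dirSign < 0),
                               0.95 - deltaV * (dirSign > 0))

    mu <- matrix(base, G, S)
    for (s in seq_len(S)) {
        d <- sheet$day[s]
        l10 <- log10(sheet$cumulative_expansion_rate[s])
        if (length(plantedIdx))
            mu[plantedIdx, s] <- mu[plantedIdx, s] +
                dirSign * deltaV *
                .kineticFraction(d, maxDay, kinV, design$days[2])
        mu[meta$pmd, s] <- mu[meta$pmd, s] - design$pmdSlope * l10
        coupled <- isTregdr & !meta$anchor
        mu[coupled, s] <- mu[coupled, s] + design$tregdrSlope * l10
    }
    mu <- .clamp(mu, 0.02, 0.98)

    Mmu <- betaToM(mu)
    donorInt <- matrix(stats::rnorm(G * length(design$donors), 0,
                                    design$donorSd),
                       G, length(design$donors),
                       dimnames = list(NULL, design$donors))
    runMean <- stats::rnorm(length(design$runs), 0, design$batchRunSd)
    gamma <- vapply(seq_along(design$runs), function(r)
        stats::rnorm(G, runMean[r], design$batchAddSd), numeric(G))
    colnames(gamma) <- design$runs
    deltaRun <- exp(stats::rnorm(length(design$runs), 0,
                                 design$batchScaleSd))
    names(deltaRun) <- design$runs

    M <- Mmu
    for (s in seq_len(S)) {
        r <- sheet$run[s]
        M[, s] <- Mmu[, s] + donorInt[, sheet$donor[s]] + gamma[, r] +
            deltaRun[r] * stats::rnorm(G, 0, design$sigmaM)
    }
    beta <- mToBeta(M)
    if (any(isTregdr) && design$tregdrNoiseSd > 0) {
        beta[isTregdr, ] <- .clamp(
            beta[isTregdr, ] + stats::rnorm(sum(isTregdr) * S, 0,
                                            design$tregdrNoiseSd), 0, 1)
    }
    dimnames(beta) <- list(meta$probe_id, sheet$sample_id)

    fail <- matrix(stats::runif(G * S) < design$detpFailRate, G, S)
    detp <- matrix(10^(-stats::runif(G * S, 3, 8)), G, S)
    detp[fail] <- stats::runif(sum(fail), 0.05, 0.9)
    dimnames(detp) <- dimnames(beta)

    me <- MethylationExperiment(beta, detectionP = detp, sampleSheet = sheet)
    list(me = me, truth = planted, expansion = expansion)
}

#' Simulate WGBS-style per-CpG count tables for two groups
#'
#' Per-CpG coverage follows an overdispersed negative-binomial
#' distribution; methylated counts are binomial given the true per-group
#' methylation fraction. Planted differential blocks shift group A by
#' `delta`.
#'
#' @param nCpgs CpG count (one chromosome).
#' @param meanCoverage mean sequencing depth per CpG (>= 1).
#' @param groupEffects optional `data.frame(first_cpg, n_cpgs, delta)` of
#'   planted blocks (indices into the CpG vector; `delta` added to group A).
#' @param seed RNG seed.
#' @param nbSize negative-binomial size (dispersion) parameter.
#' @param chrom chromosome label.
#' @return list with `countsA`, `countsB`
#'   (`data.frame(chrom, start, methylated, total)`, 0-based starts) and
#'   `truth` (planted regions with nonzero delta, 0-based half-open).
#' @export
simulateWgbs <- function(nCpgs, meanCoverage = 30, groupEffects = NULL,
                         seed = 1, nbSize = 5, chrom = "chr1") {
    if (meanCoverage < 1) stop("meanCoverage must be >= 1")
    set.seed(seed)
    # ~100 bp mean spacing, the genome-wide CpG density scale
    start <- cumsum(c(1000L, sample(20:180, nCpgs - 1, replace = TRUE)))
    high <- stats::runif(nCpgs) < 0.6
    p <- ifelse(high, stats::rbeta(nCpgs, 17, 3), stats::rbeta(nCpgs, 2, 18))
    delta <- numeric(nCpgs)
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), delta = numeric(),
                        direction = character())
    if (!is.null(groupEffects) && nrow(groupEffects)) {
        for (i in seq_len(nrow(groupEffects))) {
            j <- groupEffects$first_cpg[i] + seq_len(groupEffects$n_cpgs[i]) - 1L
            if (max(j) > nCpgs) stop("planted block exceeds nCpgs")
            delta[j] <- groupEffects$delta[i]
            if (groupEffects$delta[i] != 0)
                truth <- rbind(truth, data.frame(
                    chrom = chrom, start = start[min(j)],
                    end = start[max(j)] + 1L, delta = groupEffects$delta[i],
                    direction = if (groupEffects$delta[i] > 0) "hyper"
                                else "hypo"))
        }
    }
    # keep room for the full planted effect, as in the array generator
    planted <- delta != 0
    p[planted] <- .clamp(p[planted], 0.05 + pmax(0, -delta[planted]),
                         0.95 - pmax(0, delta[planted]))
    pA <- .clamp(p + delta, 0.02, 0.98)
    pB <- .clamp(p, 0.02, 0.98)
    covA <- stats::rnbinom(nCpgs, size = nbSize, mu = meanCoverage)
    covB <- stats::rnbinom(nCpgs, size = nbSize, mu = meanCoverage)
    list(countsA = data.frame(chrom = chrom, start = start,
                              methylated = stats::rbinom(nCpgs, covA, pA),
                              total = covA),
         countsB = data.frame(chrom = chrom, start = start,
                              methylated = stats::rbinom(nCpgs, covB, pB),
                              total = covB),
         truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the TSV/BED/GFF3 dialects consumed by the pipeline: beta and
#' detection-p matrices, sample sheet, probe manifest (1-based `pos`
#' column, as array manifests use), region BEDs (0-based half-open), the
#' gene model as GFF3, the planted-truth table, and a YAML provenance file
#' echoing every design parameter and seed.
#'
#' @param bundle [simulateManifest()] output.
#' @param tc [simulateTimecourse()] output.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(bundle, tc, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    me <- tc$me
    paths <- c(beta = file.path(dir, "beta.tsv"),
               detp = file.path(dir, "detection_p.tsv"),
               sheet = file.path(dir, "sample_sheet.tsv"),
               manifest = file.path(dir, "manifest.tsv"),
               truth = file.path(dir, "truth.tsv"),
               genes = file.path(dir, "genes.gff3"),
               pmd = file.path(dir, "pmd.bed"),
               tregdr = file.path(dir, "tregdr.bed"),
               states_treg = file.path(dir, "states_treg.bed"),
               states_cd4mem = file.path(dir, "states_cd4mem.bed"),
               blacklist = file.path(dir, "blacklist.bed"),
               provenance = file.path(dir, "provenance.yaml"))
    writeMatrix <- function(m, path) {
        df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    writeMatrix(methValues(me), paths["beta"])
    writeMatrix(detectionP(me), paths["detp"])
    utils::write.table(sampleSheet(me), paths["sheet"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$manifest, paths["manifest"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tc$truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeGeneModelGff3(bundle$geneModel, paths["genes"])
    writeBedRegions(bundle$regions$pmd, paths["pmd"])
    writeBedRegions(bundle$regions$tregdr, paths["tregdr"])
    writeBedRegions(bundle$regions$states_treg, paths["states_treg"])
    writeBedRegions(bundle$regions$states_cd4mem, paths["states_cd4mem"])
    writeBedRegions(bundle$regions$blacklist, paths["blacklist"])
    design <- bundle$design
    prov <- design[!vapply(design, is.data.frame, logical(1))]
    prov$plantedDmrs <- nrow(design$plantedDmrs)
    class(prov) <- NULL
    yaml::write_yaml(prov, paths["provenance"])
    invisible(paths)
}

#' Write a gene model as GFF3 (1-based inclusive)
#'
#' @param model a `GeneModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelGff3 <- function(model, path) {
    g <- model$genes
    lines <- c("##gff-version 3",
               sprintf("%s\tmethexpand\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id,
                       g$name))
    e <- model$exons
    strandOf <- g$strand[match(e$gene_id, g$gene_id)]
    lines <- c(lines, sprintf(
        "%s\tmethexpand\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        e$chrom, e$start + 1L, e$end, strandOf, e$gene_id,
        stats::ave(seq_len(nrow(e)), e$gene_id, FUN = seq_along), e$gene_id))
    u <- model$utrs
    if (nrow(u)) {
        strandOf <- g$strand[match(u$gene_id, g$gene_id)]
        type <- ifelse(u$side == "five_utr", "five_prime_UTR",
                       "three_prime_UTR")
        lines <- c(lines, sprintf(
            "%s\tmethexpand\t%s\t%d\t%d\t.\t%s\t.\tID=%s.u%d;Parent=%s",
            u$chrom, type, u$start + 1L, u$end, strandOf, u$gene_id,
            stats::ave(seq_len(nrow(u)), u$gene_id, FUN = seq_along),
            u$gene_id))
    }
    writeLines(lines, path)
    invisible(path)
}
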