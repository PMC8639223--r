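.defaultParams <- function() {
    list(detp_threshold = 0.05, snp_window = 3, fdr_threshold = 0.05,
         lambda = 500, C = 3, min_cpgs = 3, stouffer_threshold = 0.05,
         shared_overlap = 0.5, wgbs_min_coverage = 10, r2_threshold = 0.4,
         promoter_up = 3000, promoter_down = 3000, downstream_window = 300,
         gsea_permutations = 200)
}

.paramRanges <- list(
    detp_threshold = c(0, 1), snp_window = c(0, 1000),
    fdr_threshold = c(0, 1), lambda = c(1, 1e6), C = c(0.1, 100),
    min_cpgs = c(1, 1000), stouffer_threshold = c(0, 1),
    shared_overlap = c(0, 1), wgbs_min_coverage = c(1, 1e6),
    r2_threshold = c(0, 1), promoter_up = c(0, 1e6),
    promoter_down = c(0, 1e6), downstream_window = c(0, 1e6),
    gsea_permutations = c(10, 1e6))

#' Pipeline configuration
#'
#' Bundles the output directory, the seed, the synthetic design (or paths
#' to user-provided inputs) and every stage parameter. Parameters default
#' to the protocol's stated values: detection-p 0.05, SNP window 3,
#' FDR 0.05, lambda 500, C 3, minimum 3 CpGs per DMR, Stouffer 0.05,
#' shared-DMR overlap 0.5, WGBS coverage 10, R-squared 0.4. Unknown
#' parameter names and out-of-range values are rejected.
#'
#' @param outputDir directory the run writes into.
#' @param seed integer; the single source of randomness for the whole run.
#' @param design [simDesign()] for synthetic mode; its seed is overridden
#'   by `seed`.
#' @param inputs optional named list of file paths (`beta`, `detp`,
#'   `sheet`, `manifest`, `genes`, `pmd`, `tregdr`, `states_treg`,
#'   `states_cd4mem`) for user data; all must exist at run time.
#' @param params named list overriding entries of the default parameter
#'   block.
#' @return object of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(outputDir, seed = 1, design = NULL,
                           inputs = NULL, params = list()) {
    defaults <- .defaultParams()
    unknown <- setdiff(names(params), names(defaults))
    if (length(unknown))
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(params)] <- params
    for (nm in names(defaults)) {
        rg <- .paramRanges[[nm]]
        v <- defaults[[nm]]
        if (!is.numeric(v) || length(v) != 1 || v < rg[1] || v > rg[2])
            stop("parameter '", nm, "' out of range [", rg[1], ", ",
                 rg[2], "]: ", v)
    }
    if (is.null(design) && is.null(inputs)) design <- simDesign(seed = seed)
    if (!is.null(design)) design$seed <- as.integer(seed)
    structure(list(outputDir = outputDir, seed = as.integer(seed),
                   design = design, inputs = inputs, params = defaults),
              class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
    cat("PipelineConfig: seed", x$seed, "->", x$outputDir, "\n")
    cat("  mode:", if (is.null(x$inputs)) "synthetic" else "user inputs", "\n")
    invisible(x)
}

.configHash <- function(config) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    flat <- list(seed = config$seed, params = config$params,
                 design = if (is.null(config$design)) NULL else {
                     d <- config$design
                     d$plantedDmrs <- NULL
                     unclass(d)
                 })
    yaml::write_yaml(flat, tmp)
    unname(tools::md5sum(tmp))
}

# read user-supplied inputs into the same structures synthetic mode builds
.readInputs <- function(inputs) {
    needed <- c("beta", "detp", "sheet", "manifest")
    missing <- vapply(inputs, function(p) !file.exists(p), logical(1))
    if (any(missing))
        stop("missing input file(s): ",
             paste(unlist(inputs[missing]), collapse = ", "))
    if (!all(needed %in% names(inputs)))
        stop("inputs must name at least: ", paste(needed, collapse = ", "))
    readMat <- function(path) {
        df <- utils::read.table(path, sep = "\t", header = TRUE,
                                check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- df[[1]]
        m
    }
    beta <- readMat(inputs$beta)
    detp <- readMat(inputs$detp)
    sheet <- utils::read.table(inputs$sheet, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    manifest <- utils::read.table(inputs$manifest, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    regions <- list()
    for (nm in c("pmd", "tregdr", "states_treg", "states_cd4mem"))
        if (!is.null(inputs[[nm]]))
            regions[[nm]] <- readBedRegions(inputs[[nm]])
    list(me = MethylationExperiment(beta, detp, sheet), manifest = manifest,
         geneModel = if (!is.null(inputs$genes)) loadGeneModel(inputs$genes)
                     else NULL,
         regions = regions)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> differential methylation (per run, day-10 and
#' final-day contrasts) -> annotation -> shared-DMR kinetics -> PMD /
#' Treg-DR / WGBS signature analyses -> enrichment, writing every
#' intermediate table under `outputDir` and a JSON run manifest with
#' per-stage counts. In synthetic mode (the default) the inputs are
#' generated from the config's design with planted ground truth; all
#' randomness flows from the single config seed, so a fixed seed yields a
#' byte-identical result tree.
#'
#' @param config a [pipelineConfig()] object.
#' @return (invisibly) the run manifest: a list with `files`, `counts`,
#'   `config_hash` and key stage outputs (`shared`, `stability`,
#'   `concordance`, ...).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    p <- config$params
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    hash <- .configHash(config)
    counts <- list()
    files <- character()
    outTsv <- function(df, name, coords = "0-based half-open") {
        path <- file.path(config$outputDir, name)
        writeTsv(df, path, configHash = hash, coords = coords)
        files[length(files) + 1L] <<- path
        path
    }

    # --- inputs ------------------------------------------------------------
    synthetic <- is.null(config$inputs)
    if (synthetic) {
        design <- config$design
        bundle <- simulateManifest(design)
        tc <- simulateTimecourse(design, bundle)
        inDir <- file.path(config$outputDir, "input")
        files <- c(files, writeSimulation(bundle, tc, inDir))
        me <- tc$me
        manifest <- bundle$manifest
        geneModel <- bundle$geneModel
        regions <- bundle$regions
        truth <- tc$truth
    } else {
        loaded <- .readInputs(config$inputs)
        me <- loaded$me
        manifest <- loaded$manifest
        geneModel <- loaded$geneModel
        regions <- loaded$regions
        truth <- NULL
    }
    sheet <- sampleSheet(me)
    counts$samples <- ncol(me)
    counts$probes_in <- nrow(me)

    # --- preprocess --------------------------------------------------------
    me <- filterProbes(me, manifest, detpThreshold = p$detp_threshold,
                       snpWindow = p$snp_window)
    outTsv(filterReport(me), "filter_report.tsv", coords = "n/a")
    me <- dropSexChromosomes(me, manifest)
    counts$probes_after_filter <- nrow(me)
    me <- quantileNormalize(me)
    meBeta <- me
    meM <- convertToM(me)
    runs <- sort(unique(sheet$run))
    if (length(runs) > 1) {
        meM <- combatAdjust(meM, batch = sheet$run[match(colnames(meM),
                                                         sheet$sample_id)],
                            covariates = stats::model.matrix(
                                ~ factor(sheet$day[match(colnames(meM),
                                                         sheet$sample_id)])))
    }
    pca <- pcaScores(meM, nComponents = min(4, ncol(meM) - 1))
    outTsv(data.frame(sample_id = rownames(pca$scores), pca$scores,
                      check.names = FALSE), "pca_scores.tsv", coords = "n/a")
    counts$pc1_variance_fraction <- pca$varianceFraction[1]

    # --- differential methylation per run ----------------------------------
    days <- sort(unique(sheet$day))
    midDay <- days[2]
    finalDay <- days[length(days)]
    dmrSets <- list()
    dmpCounts <- list()
    for (r in runs) {
        for (d in c(midDay, finalDay)) {
            g1 <- sheet$sample_id[sheet$run == r & sheet$day == d]
            g0 <- sheet$sample_id[sheet$run == r & sheet$day == 0]
            block <- stats::setNames(sheet$donor, sheet$sample_id)
            ctr <- makeContrast(sprintf("day%d_vs_day0_%s", d, r),
                                g1, g0, block = block)
            dmps <- fitDmps(meM, ctr, manifest, meBeta = meBeta,
                            fdrThreshold = p$fdr_threshold)
            sm <- smoothStats(dmps, lambda = p$lambda, C = p$C)
            dmrs <- callDmrs(sm, lambda = p$lambda, minCpgs = p$min_cpgs,
                             stoufferThreshold = p$stouffer_threshold,
                             fdrThreshold = p$fdr_threshold)
            key <- sprintf("%s_day%d", r, d)
            dmrSets[[key]] <- dmrs
            dmpCounts[[key]] <- sum(dmps$significant)
            outTsv(dmps, sprintf("dmps_%s.tsv", key),
                   coords = "pos 1-based")
            outTsv(dmrs, sprintf("dmrs_%s.tsv", key))
            bed <- file.path(config$outputDir, sprintf("dmrs_%s.bed", key))
            writeDmrBed(dmrs, bed, contrast = ctr$name)
            files <- c(files, bed)
        }
    }
    counts$dmps <- dmpCounts
    counts$dmrs <- lapply(dmrSets, nrow)

    # --- annotation + kinetics ---------------------------------------------
    run1 <- runs[1]
    shared <- NULL
    lateShared <- NULL
    if (length(runs) > 1) {
        run2 <- runs[2]
        ms <- matchSharedDmrs(dmrSets[[sprintf("%s_day%d", run1, finalDay)]],
                              dmrSets[[sprintf("%s_day%d", run2, finalDay)]],
                              minFraction = p$shared_overlap)
        shared <- labelSharedKinetics(
            ms$shared,
            dmrSets[[sprintf("%s_day%d", run1, midDay)]],
            dmrSets[[sprintf("%s_day%d", run1, finalDay)]],
            dmrSets[[sprintf("%s_day%d", run2, midDay)]],
            dmrSets[[sprintf("%s_day%d", run2, finalDay)]],
            minFraction = p$shared_overlap)
        if (!is.null(geneModel))
            shared <- annotateDmrs(shared, geneModel,
                                   promoterUp = p$promoter_up,
                                   promoterDown = p$promoter_down,
                                   downstreamWindow = p$downstream_window)
        outTsv(shared, "shared_dmrs.tsv")
        counts$shared_dmrs <- nrow(shared)
        counts$discordant_dmrs <- ms$discordant
        if (nrow(shared)) {
            sm <- summarizeShared(shared)
            counts$fraction_kinetics_differ <- sm$fraction_kinetics_differ
            track <- meanDmrMethylationTrack(meBeta, shared, manifest)
            outTsv(track, "shared_dmr_tracks.tsv")
        }
        lateShared <- shared[shared$kinetic_run1 == "late" &
                             shared$kinetic_run2 == "late", , drop = FALSE]
    }

    # --- signatures --------------------------------------------------------
    if (!is.null(regions$pmd) && length(regions$pmd)) {
        pmdTrack <- pmdMedianTrack(meBeta, regions$pmd, manifest)
        outTsv(pmdTrack, "pmd_median.tsv", coords = "n/a")
        ok <- is.finite(pmdTrack$log10_expansion)
        counts$pmd_expansion_spearman <- unname(stats::cor(
            pmdTrack$median_pmd_beta[ok], pmdTrack$log10_expansion[ok],
            method = "spearman"))
    }
    if (!is.null(regions$tregdr) && length(regions$tregdr)) {
        ids <- probesInRegions(manifest, regions$tregdr)
        ids <- intersect(ids, rownames(meBeta))
        pts <- GenomicRanges::GRanges(
            normalizeChrom(manifest$chrom[match(ids, manifest$probe_id)]),
            IRanges::IRanges(manifest$pos[match(ids, manifest$probe_id)],
                             width = 1))
        hit <- GenomicRanges::findOverlaps(pts, regions$tregdr,
                                           select = "first")
        labels <- stats::setNames(
            as.character(S4Vectors::mcols(regions$tregdr)$label[hit]), ids)
        run1Samples <- sheet$sample_id[sheet$run == run1]
        stab <- stabilityScreen(meBeta, ids, labels = labels,
                                samples = run1Samples,
                                r2Threshold = p$r2_threshold)
        outTsv(stab$cpg, "tregdr_stability.tsv", coords = "n/a")
        if (!is.null(stab$locus))
            outTsv(stab$locus, "tregdr_stability_locus.tsv", coords = "n/a")
        counts$tregdr_destabilized_cpgs <-
            sum(stab$cpg$classified_destabilized)
        if (!is.null(regions$states_treg) &&
            !is.null(regions$states_cd4mem)) {
            sub <- manifest[manifest$probe_id %in% ids, , drop = FALSE]
            ct <- crosstabChromatinStates(sub, regions$states_treg,
                                          regions$states_cd4mem)
            outTsv(as.data.frame(ct), "tregdr_state_crosstab.tsv",
                   coords = "n/a")
        }
    }
    if (synthetic) {
        wg <- simulateWgbs(2000, meanCoverage = 30,
                           groupEffects = data.frame(
                               first_cpg = c(200, 700, 1200, 1700),
                               n_cpgs = 10,
                               delta = c(0.3, -0.3, 0.3, 0.3)),
                           seed = config$seed + 7L)
        wdmps <- wgbsDmps(wg$countsA, wg$countsB,
                          minCoverage = p$wgbs_min_coverage)
        exhDmrs <- wgbsDmrs(wdmps, lambda = p$lambda, C = p$C,
                            minCpgs = p$min_cpgs,
                            stoufferThreshold = p$stouffer_threshold,
                            fdrThreshold = p$fdr_threshold)
        outTsv(exhDmrs, "exh_dmrs.tsv")
        counts$exh_dmrs <- nrow(exhDmrs)
        if (!is.null(lateShared) && nrow(lateShared)) {
            conc <- exhConcordance(lateShared, exhDmrs,
                                   minFraction = p$shared_overlap)
            outTsv(conc$table, "exh_concordance.tsv")
            counts$exh_overlap_fraction <- conc$summary$overlap_fraction
        }
    }

    # --- enrichment --------------------------------------------------------
    enrich <- NULL
    if (!is.null(geneModel) && !is.null(shared) && nrow(shared)) {
        keptManifest <- manifest[manifest$probe_id %in% rownames(meBeta), ]
        pts <- GenomicRanges::GRanges(
            normalizeChrom(keptManifest$chrom),
            IRanges::IRanges(keptManifest$pos, width = 1))
        gspan <- GenomicRanges::GRanges(
            geneModel$genes$chrom,
            IRanges::IRanges(pmax(geneModel$genes$start + 1L -
                                      p$promoter_up, 1),
                             geneModel$genes$end + p$promoter_up))
        hit <- GenomicRanges::findOverlaps(gspan, pts)
        universe <- unique(geneModel$genes$gene_id[
            unique(S4Vectors::queryHits(hit))])
        query <- intersect(unique(shared$gene_id[!is.na(shared$gene_id)]),
                           universe)
        if (length(query) && length(universe) > length(query)) {
            set.seed(config$seed + 13L)
            sets <- lapply(seq_len(8), function(i)
                sample(universe, min(30, max(5, length(universe) %/% 10))))
            names(sets) <- sprintf("random_set_%02d", seq_along(sets))
            sets$dmr_linked <- unique(c(
                query, sample(universe, min(10, length(universe)))))
            enrich <- oraHypergeometric(query, universe, sets,
                                        fdrThreshold = p$fdr_threshold)
            outTsv(enrich, "ora_shared_dmr_genes.tsv", coords = "n/a")
            counts$enriched_terms <- sum(enrich$significant)
        }
    }

    # --- truth-based evaluation (synthetic mode) ---------------------------
    evaluation <- NULL
    if (synthetic && !is.null(truth) && nrow(truth)) {
        called <- dmrSets[[sprintf("%s_day%d", run1, finalDay)]]
        mask <- suppressWarnings(GenomicRanges::reduce(c(
            GenomicRanges::granges(regions$pmd),
            GenomicRanges::granges(regions$tregdr))))
        evaluation <- evaluateDmrCalls(called, truth, maskRegions = mask)
        outTsv(data.frame(evaluation[c("recall", "precision",
                                       "direction_agreement")]),
               "evaluation.tsv", coords = "n/a")
        counts$recall <- evaluation$recall
        counts$precision <- evaluation$precision
    }

    relFiles <- sort(sub(paste0("^", normalizePath(config$outputDir),
                                 .Platform$file.sep), "",
                         vapply(unname(files), normalizePath, character(1))))
    manifestOut <- list(config_hash = hash, seed = config$seed,
                        counts = counts, files = relFiles)
    jsonPath <- file.path(config$outputDir, "run_manifest.json")
    jsonlite::write_json(manifestOut, jsonPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    logPath <- file.path(config$outputDir, "run_log.jsonl")
    writeLines(vapply(names(counts), function(nm)
        as.character(jsonlite::toJSON(
            list(stage = nm, value = counts[[nm]]), auto_unbox = TRUE,
            digits = NA)), character(1)), logPath)
    invisible(c(manifestOut,
                list(shared = shared, evaluation = evaluation,
                     dmrSets = dmrSets)))
}

#' Compare called DMRs with the planted truth
#'
#' A planted region counts as recovered when at least one called DMR
#' overlaps it; a called DMR is a true positive when it overlaps a planted
#' region. Direction agreement is assessed among true positives. Because
#' the generator also plants genuine non-DMR-table signal (PMD drift,
#' Treg-DR remethylation), calls inside `maskRegions` are excluded from the
#' precision denominator — they detect real planted effects of a different
#' kind, not false positives.
#'
#' @param called DMR table from [callDmrs()].
#' @param truth planted-region table (`chrom, start, end, direction`).
#' @param maskRegions optional `GRanges` of regions carrying other planted
#'   signal (e.g. PMDs, Treg-DR loci).
#' @return list with `recall`, `precision`, `direction_agreement`,
#'   `n_called`, `n_truth`, and the per-truth recovery flags.
#' @export
evaluateDmrCalls <- function(called, truth, maskRegions = NULL) {
    if (!is.null(maskRegions) && nrow(called)) {
        gC <- .df2gr(called)
        inMask <- suppressWarnings(GenomicRanges::countOverlaps(
            gC, maskRegions, ignore.strand = TRUE)) > 0
        called <- called[!inMask, , drop = FALSE]
    }
    if (!nrow(truth))
        return(list(recall = NA_real_, precision = NA_real_,
                    direction_agreement = NA_real_, n_called = nrow(called),
                    n_truth = 0L, recovered = logical()))
    if (!nrow(called))
        return(list(recall = 0, precision = NA_real_,
                    direction_agreement = NA_real_, n_called = 0L,
                    n_truth = nrow(truth),
                    recovered = rep(FALSE, nrow(truth))))
    gT <- .df2gr(truth)
    gC <- .df2gr(called)
    hits <- GenomicRanges::findOverlaps(gC, gT, ignore.strand = TRUE)
    recovered <- seq_len(nrow(truth)) %in% S4Vectors::subjectHits(hits)
    tpCalled <- unique(S4Vectors::queryHits(hits))
    dirOk <- vapply(tpCalled, function(i) {
        j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i][1]
        called$direction[i] == truth$direction[j]
    }, logical(1))
    list(recall = mean(recovered),
         precision = length(tpCalled) / nrow(called),
         direction_agreement = if (length(dirOk)) mean(dirOk) else NA_real_,
         n_called = nrow(called), n_truth = nrow(truth),
         recovered = recovered)
}
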