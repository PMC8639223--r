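# shared fixtures, all built in code

# small fast design for unit tests
smallDesign <- function(seed = 1, ...) {
    simDesign(nProbes = 2000, nChromosomes = 2,
              plantedDmrs = defaultPlantedDmrs(n = 6, nCpgs = 5,
                                               deltaBeta = 0.2),
              tregdrCount = 3, seed = seed, ...)
}

# design with no planted effects of any kind
nullDesign <- function(seed = 1, nProbes = 2000, ...) {
    simDesign(nProbes = nProbes, nChromosomes = 2,
              plantedDmrs = defaultPlantedDmrs(n = 6, deltaBeta = 0),
              pmdSlope = 0, tregdrSlope = 0, tregdrCount = 3,
              seed = seed, ...)
}

# filtered M-scale matrix + bits needed for contrasts
prepSim <- function(design) {
    bundle <- simulateManifest(design)
    tc <- simulateTimecourse(design, bundle)
    me <- dropSexChromosomes(filterProbes(tc$me, bundle$manifest),
                             bundle$manifest)
    sheet <- sampleSheet(me)
    list(bundle = bundle, truth = tc$truth, meBeta = me,
         meM = convertToM(me), sheet = sheet,
         block = stats::setNames(sheet$donor, sheet$sample_id))
}

dayContrast <- function(prep, run, day, day0 = 0) {
    s <- prep$sheet
    makeContrast(sprintf("day%d_vs_day%d_%s", day, day0, run),
                 s$sample_id[s$run == run & s$day == day],
                 s$sample_id[s$run == run & s$day == day0],
                 block = prep$block)
}

# brute-force kernel convolution oracle (independent of smoothStats)
bruteSmooth <- function(pos, z, lambda = 500, C = 3) {
    sigma <- lambda / C
    vapply(seq_along(pos), function(i) {
        num <- den <- 0
        for (j in seq_along(pos)) {
            d <- abs(pos[j] - pos[i])
            if (d <= lambda) {
                w <- exp(-d^2 / (2 * sigma^2))
                num <- num + w * z[j]^2
                den <- den + w
            }
        }
        num / den
    }, numeric(1))
}

# tiny gene model built directly (plus-strand gene 1000..9000 with exons and
# UTRs, minus-strand gene 20000..26000), 0-based half-open
toyGeneModel <- function() {
    structure(list(
        genes = data.frame(
            gene_id = c("gA", "gB"), name = c("gA", "gB"),
            chrom = "chr1", strand = c("+", "-"),
            start = c(1000L, 20000L), end = c(9000L, 26000L),
            tss = c(1000L, 25999L)),
        exons = data.frame(
            gene_id = c("gA", "gA", "gB"), chrom = "chr1",
            start = c(1000L, 6000L, 20000L), end = c(2000L, 9000L, 26000L)),
        utrs = data.frame(
            gene_id = c("gA", "gA"), chrom = "chr1",
            start = c(1000L, 8700L), end = c(1300L, 9000L),
            side = c("five_utr", "three_utr"))),
        class = "GeneModel")
}

randomRegionSet <- function(n, chromLen = 10000, chrom = "chr1") {
    s <- sort(sample.int(chromLen - 50, n))
    w <- sample(10:400, n, replace = TRUE)
    GenomicRanges::reduce(GenomicRanges::GRanges(
        chrom, IRanges::IRanges(s, pmin(s + w, chromLen))))
}

# per-base bitmap membership oracle for interval intersection
bitmapIntersect <- function(sets, chromLen = 10000) {
    inAll <- rep(TRUE, chromLen)
    for (g in sets) {
        mem <- rep(FALSE, chromLen)
        for (i in seq_along(g))
            mem[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- TRUE
        inAll <- inAll & mem
    }
    which(inAll)
}

grBases <- function(gr) {
    if (!length(gr)) return(integer())
    unlist(lapply(seq_along(gr), function(i)
        GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]))
}

randomDmrTable <- function(n, chromLen = 50000, chrom = "chr1") {
    s <- sort(sample.int(chromLen, n))
    w <- sample(50:800, n, replace = TRUE)
    d <- stats::runif(n, -0.3, 0.3)
    data.frame(chrom = chrom, start = s, end = s + w,
               n_cpgs = sample(3:10, n, replace = TRUE),
               mean_delta_beta = d, max_delta_beta = d,
               stouffer_p = stats::runif(n, 0, 0.05),
               direction = ifelse(d > 0, "hyper", "hypo"))
}
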