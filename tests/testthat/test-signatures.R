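test_that("PMD median track reflects planted expansion coupling", {
    prep <- prepSim(smallDesign(seed = 60))
    tr <- pmdMedianTrack(prep$meBeta, prep$bundle$regions$pmd,
                         prep$bundle$manifest)
    expect_equal(nrow(tr), ncol(prep$meBeta))
    rho <- stats::cor(tr$median_pmd_beta, tr$log10_expansion,
                      method = "spearman")
    expect_lte(rho, -0.9)
    # empty PMD probe set is an error
    empty <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10))
    expect_error(pmdMedianTrack(prep$meBeta, empty, prep$bundle$manifest),
                 "no probes")
})

test_that("PMD median ignores non-PMD probe perturbation", {
    beta <- matrix(0.6, 5, 3, dimnames = list(paste0("cg", 1:5),
                                              paste0("s", 1:3)))
    man <- data.frame(probe_id = paste0("cg", 1:5), chrom = "chr1",
                      pos = c(150, 250, 350, 5000, 6000))
    pmd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400))
    me <- MethylationExperiment(beta)
    t1 <- pmdMedianTrack(me, pmd, man)
    expect_true(all(t1$median_pmd_beta == 0.6))
    beta2 <- beta; beta2[4:5, ] <- 0.99
    t2 <- pmdMedianTrack(MethylationExperiment(beta2), pmd, man)
    expect_equal(t2$median_pmd_beta, t1$median_pmd_beta)
})

test_that("per-CpG t-tests match the pooled-variance closed form", {
    # A = (0.1, 0.2, 0.15), B = (0.8, 0.85, 0.9): var = 0.0025 each,
    # t = -0.7 / sqrt(0.0025 * 2/3) = -17.146...
    beta <- matrix(c(0.1, 0.2, 0.15, 0.8, 0.85, 0.9), 1, 6,
                   dimnames = list("cg1", paste0("s", 1:6)))
    me <- MethylationExperiment(beta)
    r <- cpgGroupTtest(me, "cg1", paste0("s", 1:3), paste0("s", 4:6))
    expect_equal(r$t, -0.7 / sqrt(0.0025 * 2 / 3), tolerance = 1e-9)
    ht <- stats::t.test(beta[1, 1:3], beta[1, 4:6], var.equal = TRUE)
    expect_equal(r$t, unname(ht$statistic))
    expect_equal(r$p, ht$p.value)
    # swap groups: t negated, p unchanged
    r2 <- cpgGroupTtest(me, "cg1", paste0("s", 4:6), paste0("s", 1:3))
    expect_equal(r2$t, -r$t)
    expect_equal(r2$p, r$p)
    # identical constant groups -> t = 0, p = 1
    beta3 <- matrix(0.5, 1, 6, dimnames = dimnames(beta))
    r3 <- cpgGroupTtest(MethylationExperiment(beta3), "cg1",
                        paste0("s", 1:3), paste0("s", 4:6))
    expect_equal(r3$t, 0)
    expect_equal(r3$p, 1)
    expect_error(cpgGroupTtest(me, "cg1", "s1", paste0("s", 4:6)),
                 "at least 2")
})

test_that("stability regression matches its closed-form identities", {
    er <- 10^seq(0, 3, length.out = 9)
    # exactly linear -> R^2 = 1
    b <- 0.1 + 0.12 * log10(er)
    r <- stabilityRegression(b, er)
    expect_equal(r$r_squared, 1)
    expect_equal(r$slope, 0.12)
    # constant -> slope 0, R^2 = 0, not destabilized
    r2 <- stabilityRegression(rep(0.3, 9), er)
    expect_equal(r2$slope, 0)
    expect_equal(r2$r_squared, 0)
    expect_false(r2$classified_destabilized)
    # R^2 equals the squared Pearson correlation
    set.seed(61)
    b3 <- 0.2 + 0.05 * log10(er) + rnorm(9, 0, 0.05)
    r3 <- stabilityRegression(b3, er)
    expect_equal(r3$r_squared, stats::cor(b3, log10(er))^2, tolerance = 1e-10)
    expect_error(stabilityRegression(b3, rep(2, 9)), "distinct")
    expect_error(stabilityRegression(b3, -er), "positive")
})

test_that("stability screen separates anchors from expansion-coupled loci", {
    prep <- prepSim(smallDesign(seed = 62))
    b <- prep$bundle
    meta <- b$probeMeta[!is.na(b$probeMeta$tregdr_label), ]
    ids <- intersect(meta$probe_id, rownames(prep$meBeta))
    labels <- stats::setNames(meta$tregdr_label[match(ids, meta$probe_id)],
                              ids)
    r1 <- prep$sheet$sample_id[prep$sheet$run == "R1"]
    sc <- stabilityScreen(prep$meBeta, ids, labels = labels, samples = r1)
    anchors <- c("FOXP3like", "TNFRSF1Blike")
    lc <- sc$locus
    expect_true(all(!lc$destabilized[lc$region %in% anchors]))
    expect_true(all(lc$destabilized[!lc$region %in% anchors]))
})

test_that("chromatin-state crosstab counts every probe exactly once", {
    man <- data.frame(probe_id = paste0("p", 1:4), chrom = "chr1",
                      pos = c(150, 250, 350, 9000))
    mkStates <- function(labels) {
        gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
            c(101, 201, 301), c(200, 300, 400)))
        S4Vectors::mcols(gr)$label <- labels
        gr
    }
    a <- mkStates(c("TssA", "Enh", "Quies"))
    ct <- crosstabChromatinStates(man, a, a)
    expect_equal(sum(ct), 4)
    expect_equal(unname(ct["TssA", "TssA"]), 1)
    expect_equal(unname(ct["unannotated", "unannotated"]), 1)
    # identical sets give a diagonal table
    offDiag <- ct[row(ct) != col(ct)]
    expect_true(all(offDiag == 0))
    # brute-force lookup oracle
    bSet <- mkStates(c("Enh", "Enh", "TssA"))
    ct2 <- crosstabChromatinStates(man, a, bSet)
    lookup <- function(p, gr) {
        i <- which(p >= GenomicRanges::start(gr) & p <= GenomicRanges::end(gr))
        if (length(i)) S4Vectors::mcols(gr)$label[i[1]] else "unannotated"
    }
    for (i in seq_len(nrow(man))) {
        la <- lookup(man$pos[i], a); lb <- lookup(man$pos[i], bSet)
        expect_gte(ct2[la, lb], 1)
    }
    expect_equal(sum(ct2), 4)
})

test_that("WGBS per-CpG tests filter coverage and match proportion tests", {
    cnt <- function(m, t) data.frame(chrom = "chr1",
                                     start = c(100, 200, 300),
                                     methylated = m, total = t)
    a <- cnt(c(50, 5, 30), c(100, 9, 40))   # CpG at 200 has 9x -> excluded
    b <- cnt(c(50, 4, 10), c(100, 12, 40))
    r <- wgbsDmps(a, b, minCoverage = 10)
    expect_equal(r$start, c(100, 300))
    # equal pooled counts -> z = 0, p = 1
    expect_equal(r$z[1], 0)
    expect_equal(r$p[1], 1)
    # z^2 equals the (uncorrected) two-proportion chi-square
    pt <- stats::prop.test(c(30, 10), c(40, 40), correct = FALSE)
    expect_equal(r$z[2]^2, unname(pt$statistic), tolerance = 1e-9)
    # exact enumeration oracle on a small instance: P(|pA - pB| >= obs)
    # under H0 with the pooled rate
    nA <- 25; nB <- 25; xA <- 18; xB <- 9
    rr <- wgbsDmps(data.frame(chrom = "chr1", start = 1, methylated = xA,
                              total = nA),
                   data.frame(chrom = "chr1", start = 1, methylated = xB,
                              total = nB))
    pPool <- (xA + xB) / (nA + nB)
    obs <- abs(xA / nA - xB / nB)
    grid <- expand.grid(i = 0:nA, j = 0:nB)
    pexact <- sum(stats::dbinom(grid$i, nA, pPool) *
                      stats::dbinom(grid$j, nB, pPool) *
                      (abs(grid$i / nA - grid$j / nB) >= obs - 1e-12))
    expect_equal(rr$p, pexact, tolerance = 0.02)
    # group swap flips delta and z
    rs <- wgbsDmps(b, a, minCoverage = 10)
    expect_equal(rs$delta, -r$delta)
    expect_equal(rs$z, -r$z)
    expect_error(wgbsDmps(a, b, minCoverage = 1000), "coverage")
})

test_that("WGBS DMR calling recovers planted blocks and respects min CpGs", {
    w <- simulateWgbs(800, meanCoverage = 30,
                      groupEffects = data.frame(first_cpg = 300, n_cpgs = 10,
                                                delta = 0.3), seed = 63)
    dmrs <- wgbsDmrs(wgbsDmps(w$countsA, w$countsB))
    expect_gte(nrow(dmrs), 1)
    ov <- dmrs$end > w$truth$start & dmrs$start < w$truth$end
    expect_true(any(ov))
    expect_true(all(dmrs$direction[ov] == "hyper"))
    # a 2-CpG block cannot be reported
    w2 <- simulateWgbs(300, meanCoverage = 40,
                       groupEffects = data.frame(first_cpg = 100, n_cpgs = 2,
                                                 delta = 0.5), seed = 64)
    d2 <- wgbsDmrs(wgbsDmps(w2$countsA, w2$countsB))
    ov2 <- d2$end > w2$truth$start & d2$start < w2$truth$end
    if (nrow(d2)) expect_true(all(d2$n_cpgs[ov2] >= 3))
})

test_that("exhaustion concordance summarizes overlaps and directions", {
    shared <- data.frame(chrom = "chr1",
                         start = c(0, 1000, 2000), end = c(100, 1100, 2100),
                         direction = c("hyper", "hyper", "hypo"),
                         run1_delta = c(0.2, 0.15, -0.2),
                         run2_delta = c(0.25, 0.2, -0.15),
                         feature = c("promoter", "intron", "promoter"))
    mkExh <- function(start, end, delta) data.frame(
        chrom = "chr1", start = start, end = end, n_cpgs = 5,
        mean_delta_beta = delta, max_delta_beta = delta, stouffer_p = 1e-5,
        direction = ifelse(delta > 0, "hyper", "hypo"))
    # no overlaps -> fraction 0
    none <- exhConcordance(shared, mkExh(9000, 9100, 0.3))
    expect_equal(none$summary$overlap_fraction, 0)
    # full overlap, same sign -> concordance 1
    exh <- rbind(mkExh(0, 100, 0.3), mkExh(990, 1110, 0.2),
                 mkExh(1990, 2110, -0.3))
    all3 <- exhConcordance(shared, exh)
    expect_equal(all3$summary$overlap_fraction, 1)
    expect_equal(all3$summary$concordance_overall, 1)
    expect_equal(all3$summary$fraction_concordant_hyper_promoter, 0.5)
    # discordant pair detected
    exh2 <- rbind(mkExh(0, 100, -0.3), mkExh(990, 1110, 0.2))
    part <- exhConcordance(shared, exh2)
    expect_equal(part$summary$n_overlapping, 2)
    expect_equal(part$summary$concordance_overall, 0.5)
    # planted concordance fraction recovered on a constructed set
    set.seed(65)
    n <- 60
    sh <- data.frame(chrom = "chr1", start = seq(0, by = 1000, length.out = n))
    sh$end <- sh$start + 200
    sh$direction <- "hyper"; sh$run1_delta <- 0.2; sh$run2_delta <- 0.2
    sh$feature <- "promoter"
    conc <- stats::rbinom(n, 1, 0.7)
    exh3 <- do.call(rbind, lapply(seq_len(n), function(i)
        mkExh(sh$start[i] - 10, sh$end[i] + 10,
              ifelse(conc[i] == 1, 0.3, -0.3))))
    got <- exhConcordance(sh, exh3)
    expect_equal(got$summary$concordance_overall, mean(conc))
})
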