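mkMmat <- function(M) {
    dimnames(M) <- list(sprintf("cg%04d", seq_len(nrow(M))),
                        paste0("s", seq_len(ncol(M))))
    MethylationExperiment(M, scale = "M")
}

simpleManifest <- function(n, spacing = 1000) {
    data.frame(probe_id = sprintf("cg%04d", seq_len(n)), chrom = "chr1",
               pos = seq(100, by = spacing, length.out = n))
}

test_that("contrast construction enforces its invariants", {
    expect_error(makeContrast("c", c("a", "b"), c("b", "c")), "disjoint")
    expect_error(makeContrast("c", "a", c("b", "c")), "at least 2")
    expect_error(makeContrast("c", c("a", "b"), c("c", "d"),
                              block = c(a = "D1", b = "D2", c = "D1")),
                 "named by every")
})

test_that("moderated t behaves at the null and matches the reference EB fit", {
    set.seed(20)
    G <- 400; n <- 8
    M <- matrix(rnorm(G * n, 0, sqrt(rchisq(G, 6) / 6) * 0.4), G, n)
    M[1:40, 1:4] <- M[1:40, 1:4] + 1.5
    me <- mkMmat(M)
    ctr <- makeContrast("c", paste0("s", 1:4), paste0("s", 5:8))
    dm <- fitDmps(me, ctr, simpleManifest(G))

    skip_if_not_installed("limma")
    fit <- limma::eBayes(limma::lmFit(M, cbind(1, grp = rep(c(1, 0),
                                                            each = 4))))
    expect_equal(dm$t_mod, unname(fit$t[, 2]), tolerance = 1e-10)
    expect_equal(attr(dm, "df_prior"), fit$df.prior, tolerance = 1e-6)
    expect_equal(dm$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("group means equal gives near-zero t; groups swap antisymmetrically", {
    set.seed(21)
    M <- matrix(rnorm(100 * 6, 5, 0.3), 100, 6)
    me <- mkMmat(M)
    man <- simpleManifest(100)
    A <- paste0("s", 1:3); B <- paste0("s", 4:6)
    d1 <- fitDmps(me, makeContrast("ab", A, B), man)
    expect_false(any(d1$significant))
    d2 <- fitDmps(me, makeContrast("ba", B, A), man)
    expect_equal(d2$t_mod, -d1$t_mod)
    expect_equal(d2$delta_beta, -d1$delta_beta)
    expect_equal(d2$p, d1$p)
    # column order invariance
    me2 <- mkMmat(M[, c(4, 1, 5, 2, 6, 3)])
    colnames(me2) <- paste0("s", c(4, 1, 5, 2, 6, 3))
    d3 <- fitDmps(me2, makeContrast("ab", A, B), man)
    expect_equal(d3$t_mod, d1$t_mod, tolerance = 1e-12)
})

test_that("constant probes get p = 1 and huge prior df collapses t to z", {
    M <- rbind(matrix(0.3, 2, 6), matrix(rnorm(200 * 6, 0, 0.5), 200, 6))
    me <- mkMmat(M)
    d <- fitDmps(me, makeContrast("c", paste0("s", 1:3), paste0("s", 4:6)),
                 simpleManifest(nrow(M)))
    expect_equal(d$t_mod[1:2], c(0, 0))
    expect_equal(d$p[1:2], c(1, 1))

    # exactly equal residual variances drive the prior df to its cap, where
    # the moderated t collapses to a z-score with the pooled prior variance
    set.seed(22)
    M2 <- matrix(rnorm(500 * 6, 0, 0.5), 500, 6)
    X <- cbind(1, rep(c(1, 0), each = 3))
    fitted <- X %*% solve(crossprod(X), crossprod(X, t(M2)))
    res <- t(M2) - fitted
    res <- sweep(res, 2, sqrt(colSums(res^2) / 4) / 0.5, "/")
    M2 <- t(fitted + res)          # every probe has residual s^2 = 0.25
    me2 <- mkMmat(M2)
    d2 <- fitDmps(me2, makeContrast("c", paste0("s", 1:3), paste0("s", 4:6)),
                  simpleManifest(500))
    expect_gte(attr(d2, "df_prior"), 1e6)
    grpDiff <- rowMeans(M2[, 1:3]) - rowMeans(M2[, 4:6])
    zExp <- grpDiff / (sqrt(attr(d2, "s2_prior")) * sqrt(2 / 3))
    expect_equal(d2$t_mod, zExp, tolerance = 1e-5)
})

test_that("null DMP calls control the false-positive proportion", {
    set.seed(23)
    fdp <- vapply(1:30, function(i) {
        M <- matrix(rnorm(1000 * 6, 0, 0.4), 1000, 6)
        d <- fitDmps(mkMmat(M),
                     makeContrast("c", paste0("s", 1:3), paste0("s", 4:6)),
                     simpleManifest(1000))
        # all probes are null, so FDP = 1{any rejection}
        as.numeric(sum(d$significant) > 0)
    }, numeric(1))
    expect_lte(mean(fdp), 0.05 + 2 * stats::sd(fdp) / sqrt(length(fdp)) + 0.02)
})

test_that("BH adjustment matches the hand-computed step-up rule", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    set.seed(24)
    p <- runif(50)
    q <- bhAdjust(p)
    expect_true(all(q >= p))
    expect_equal(q, stats::p.adjust(p, "BH"))
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("kernel smoothing matches a brute-force convolution", {
    set.seed(25)
    for (i in 1:25) {
        n <- sample(3:20, 1)
        pos <- sort(sample.int(3000, n))
        while (anyDuplicated(pos)) pos <- sort(sample.int(3000, n))
        z <- rnorm(n)
        dm <- data.frame(probe_id = paste0("p", 1:n), chrom = "chr1",
                         pos = pos, delta_beta = z, t_mod = z, p = runif(n))
        sm <- smoothStats(dm, lambda = 500, C = 3)  # df defaults to Inf
        expect_equal(sm$y_smooth, bruteSmooth(pos, z), tolerance = 1e-9)
    }
})

test_that("smoothing handles isolated and coincident-distance CpGs", {
    # isolated CpG: Y = z^2 and p is the chi-square(1) upper tail
    z <- 2.5
    dm <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                     pos = c(100, 10000), delta_beta = 0, t_mod = c(z, 0.3),
                     p = 0.5)
    sm <- smoothStats(dm)
    expect_equal(sm$y_smooth[1], z^2)
    expect_equal(sm$p_smooth[1], stats::pchisq(z^2, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
    # two CpGs one bp apart with t^2 = (1, 3): near-equal weights -> Y ~ 2
    dm2 <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                      pos = c(100, 101), delta_beta = 0,
                      t_mod = c(1, sqrt(3)), p = 0.5)
    expect_equal(smoothStats(dm2)$y_smooth, c(2, 2), tolerance = 1e-4)
    # unsorted input is rejected
    dm3 <- dm2
    dm3$pos <- c(101, 101)
    expect_error(smoothStats(dm3), "strictly increasing")
})

test_that("Stouffer combination matches normal-CDF arithmetic", {
    # two two-sided p of 0.05 (one-sided 0.025, z = 1.96 each):
    # Z = 2 * 1.959964 / sqrt(2) = 2.7718, upper tail ~ 0.002787
    expect_equal(stoufferCombine(c(0.05, 0.05)), 0.002787298,
                 tolerance = 1e-6)
    # single p returns the aligned one-sided p
    expect_equal(stoufferCombine(0.04), 0.02)
    # symmetric null: p = 0.5 with effect signs split evenly -> Z = 0, p = 0.5
    expect_equal(stoufferCombine(rep(0.5, 4), c(1, -1, 1, -1)), 0.5)
    # opposite directions cancel
    expect_equal(stoufferCombine(c(0.05, 0.05), c(1, -1)), 0.5)
    expect_error(stoufferCombine(numeric(0)), "no p-values")
})

test_that("DMR grouping applies the min-CpG, gap and direction rules", {
    mkSm <- function(pos, delta, p, chrom = "chr1") {
        z <- -stats::qnorm(p / 2)
        data.frame(probe_id = paste0("p", seq_along(pos)), chrom = chrom,
                   pos = pos, delta_beta = delta, t_mod = z * sign(delta),
                   p = p, y_smooth = z^2, p_smooth = p)
    }
    # 5 significant CpGs spaced 100 bp, same sign -> one DMR with 5 CpGs
    sm <- mkSm(seq(1000, by = 100, length.out = 5), rep(0.2, 5),
               rep(1e-8, 5))
    d <- callDmrs(sm)
    expect_equal(nrow(d), 1)
    expect_equal(d$n_cpgs, 5)
    expect_equal(d$direction, "hyper")
    expect_equal(d$start, 999)       # 0-based half-open covering the CpGs
    expect_equal(d$end, 1400)

    # 2 significant CpGs only -> no DMR
    d2 <- callDmrs(mkSm(c(1000, 1100), c(0.2, 0.2), c(1e-8, 1e-8)))
    expect_equal(nrow(d2), 0)

    # gap > lambda splits regions
    sm3 <- mkSm(c(1000, 1100, 1200, 3000, 3100, 3200), rep(0.2, 6),
                rep(1e-8, 6))
    expect_equal(nrow(callDmrs(sm3, lambda = 500)), 2)

    # mixed-direction run is split at the sign change
    sm4 <- mkSm(seq(1000, by = 100, length.out = 6),
                c(0.2, 0.2, 0.2, -0.2, -0.2, -0.2), rep(1e-8, 6))
    d4 <- callDmrs(sm4)
    expect_equal(nrow(d4), 2)
    expect_setequal(d4$direction, c("hyper", "hypo"))
})

test_that("planted DMRs are recovered with matching direction", {
    prep <- prepSim(smallDesign(seed = 31))
    dmps <- fitDmps(prep$meM, dayContrast(prep, "R1", 23),
                    prep$bundle$manifest, meBeta = prep$meBeta)
    dmrs <- callDmrs(smoothStats(dmps))
    mask <- suppressWarnings(GenomicRanges::reduce(c(
        GenomicRanges::granges(prep$bundle$regions$pmd),
        GenomicRanges::granges(prep$bundle$regions$tregdr))))
    ev <- evaluateDmrCalls(dmrs, prep$truth, maskRegions = mask)
    expect_gte(ev$recall, 0.8)
    expect_gte(ev$precision, 0.8)
    expect_equal(ev$direction_agreement, 1)
})
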