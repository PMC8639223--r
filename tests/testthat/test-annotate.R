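writeToyGff3 <- function(path) {
    writeLines(c(
        "##gff-version 3",
        "chr1\ttoy\tgene\t101\t9000\t.\t+\t.\tID=gA;Name=gA",
        "chr1\ttoy\texon\t101\t2000\t.\t+\t.\tID=gA.e1;Parent=gA",
        "chr1\ttoy\texon\t6001\t9000\t.\t+\t.\tID=gA.e2;Parent=gA",
        "chr1\ttoy\tfive_prime_UTR\t101\t400\t.\t+\t.\tID=gA.u1;Parent=gA",
        "chr1\ttoy\tgene\t20001\t26000\t.\t-\t.\tID=gB;Name=gB",
        "chr1\ttoy\texon\t20001\t26000\t.\t-\t.\tID=gB.e1;Parent=gB"),
        path)
    path
}

test_that("GFF3 loading converts coordinates and computes strand-aware TSS", {
    gm <- loadGeneModel(writeToyGff3(tempfile(fileext = ".gff3")))
    expect_equal(nrow(gm$genes), 2)
    gA <- gm$genes[gm$genes$gene_id == "gA", ]
    expect_equal(gA$start, 100)          # 1-based 101 -> internal 100
    expect_equal(gA$end, 9000)
    expect_equal(gA$tss, 100)            # plus strand: 5' end
    gB <- gm$genes[gm$genes$gene_id == "gB", ]
    expect_equal(gB$tss, 25999)          # minus strand: interval end - 1
    expect_equal(nrow(gm$exons), 3)
    expect_equal(gm$utrs$side, "five_utr")
})

test_that("BED12 loading derives exons from blocks and TSS from strand", {
    bed <- tempfile(fileext = ".bed")
    # minus-strand gene 1000..9000 (0-based), thick CDS 1500..8500,
    # 2 blocks of 2000 bp at offsets 0 and 6000
    writeLines(paste(c("chr1", 1000, 9000, "gX", 0, "-", 1500, 8500, "0",
                       2, "2000,2000,", "0,6000,"), collapse = "\t"), bed)
    gm <- loadGeneModel(bed)
    g <- gm$genes
    expect_equal(g$start, 1000)
    expect_equal(g$end, 9000)
    expect_equal(g$tss, 8999)            # minus strand
    expect_equal(nrow(gm$exons), 2)
    expect_equal(gm$exons$start, c(1000, 7000))
    expect_equal(gm$exons$end, c(3000, 9000))
    # thick range implies UTRs; for minus strand the left UTR is 3'
    expect_equal(gm$utrs$side[gm$utrs$start == 1000], "three_utr")
})

test_that("written gene models round-trip through the GFF3 reader", {
    gm <- toyGeneModel()
    path <- tempfile(fileext = ".gff3")
    writeGeneModelGff3(gm, path)
    back <- loadGeneModel(path)
    expect_equal(back$genes$start, gm$genes$start)
    expect_equal(back$genes$end, gm$genes$end)
    expect_equal(back$genes$tss, gm$genes$tss)
    expect_equal(nrow(back$exons), nrow(gm$exons))
    expect_setequal(back$utrs$side, gm$utrs$side)
})

test_that("position annotation follows the feature priority and windows", {
    gm <- toyGeneModel()   # gA: +, 1000..9000, TSS 1000; gB: -, 20000..26000
    # at the TSS -> promoter with distance 0
    a <- annotatePosition(gm, "chr1", 1001)
    expect_equal(a$feature, "promoter")
    expect_equal(a$distance_to_tss, 0)
    # inside the gene past the promoter window
    expect_equal(annotatePosition(gm, "chr1", 4501)$feature, "intron")
    expect_equal(annotatePosition(gm, "chr1", 7001)$feature, "exon")
    # 5' UTR beats exon (UTR 1000..1300 is inside the promoter window here,
    # so probe a model without promoter dominance)
    expect_equal(annotatePosition(gm, "chr1", 8901)$feature, "three_utr")
    # 200 bp past the gene end (plus strand) -> downstream; 300 -> not
    expect_equal(annotatePosition(gm, "chr1", 9000 + 200)$feature,
                 "downstream")
    expect_equal(annotatePosition(gm, "chr1", 9000 + 3500)$feature,
                 "distal_intergenic")
    # minus-strand promoter sits upstream of the right end
    expect_equal(annotatePosition(gm, "chr1", 26000 + 500)$feature,
                 "promoter")
    # unknown chromosome is flagged
    u <- annotatePosition(gm, "chr9", 500)
    expect_equal(u$feature, "distal_intergenic")
    expect_true(u$flagged_unknown_chrom)
})

test_that("promoter priority wins over exon across overlapping genes", {
    gm <- toyGeneModel()
    # add a gene whose promoter window covers gA's exon at 7000
    gm$genes <- rbind(gm$genes, data.frame(
        gene_id = "gC", name = "gC", chrom = "chr1", strand = "+",
        start = 8000L, end = 12000L, tss = 8000L))
    a <- annotatePosition(gm, "chr1", 7001)
    expect_equal(a$feature, "promoter")
    expect_equal(a$gene_id, "gC")
})

test_that("region annotation uses the midpoint and matches per-base majority", {
    gm <- toyGeneModel()
    expect_equal(annotateRegion(gm, "chr1", 900, 1100)$feature, "promoter")
    expect_equal(annotateRegion(gm, "chr1", 15000, 15400)$feature,
                 "distal_intergenic")
    expect_error(annotateRegion(gm, "chr1", 100, 100), "positive length")

    # per-base majority oracle on regions spanning <= 2 features
    regions <- list(c(4400, 4600), c(5900, 6150), c(8850, 8950),
                    c(15000, 15100))
    for (r in regions) {
        mid <- annotateRegion(gm, "chr1", r[1], r[2])$feature
        perBase <- vapply(seq(r[1], r[2] - 1), function(b)
            annotatePosition(gm, "chr1", b + 1)$feature, character(1))
        majority <- names(sort(table(perBase), decreasing = TRUE))[1]
        expect_equal(mid, majority)
    }
})

test_that("overlap fraction satisfies its identities", {
    expect_equal(overlapFraction(0, 100, 50, 150), 0.5)
    expect_equal(overlapFraction(0, 100, 200, 300), 0)
    expect_equal(overlapFraction(10, 20, 0, 100), 1)
    expect_error(overlapFraction(5, 5, 0, 10), "positive length")
    set.seed(40)
    for (i in 1:50) {
        a <- sort(sample.int(1000, 2)); b <- sort(sample.int(1000, 2))
        if (a[1] == a[2] || b[1] == b[2]) next
        expect_equal(overlapFraction(a[1], a[2], b[1], b[2]) * (a[2] - a[1]),
                     overlapFraction(b[1], b[2], a[1], a[2]) * (b[2] - b[1]))
    }
})

test_that("region-set intersection matches the per-base bitmap oracle", {
    g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
    g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
    out <- intersectRegionSets(list(g1, g2))
    expect_equal(GenomicRanges::start(out), 51)
    expect_equal(GenomicRanges::end(out), 100)
    expect_equal(intersectRegionSets(list(g1, g1)), GenomicRanges::reduce(g1))
    expect_error(intersectRegionSets(list(g1)), "at least 2")

    set.seed(41)
    for (i in 1:30) {
        sets <- lapply(1:3, function(j) randomRegionSet(sample(2:6, 1)))
        got <- intersectRegionSets(sets)
        expect_equal(grBases(got), bitmapIntersect(sets))
        # commutativity / associativity
        expect_equal(intersectRegionSets(rev(sets)), got)
        nested <- intersectRegionSets(list(
            intersectRegionSets(sets[1:2]), sets[[3]]))
        expect_equal(nested, got)
    }
})

test_that("probe-in-region lookup respects the coordinate conventions", {
    man <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                      pos = c(101, 100, 150))
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)) # [100,200)
    got <- probesInRegions(man, reg)
    expect_true("a" %in% got)      # 1-based 101 = 0-based 100, inside
    expect_false("b" %in% got)     # 0-based 99, outside
    expect_true("c" %in% got)

    # agreement with a linear scan on random instances
    set.seed(42)
    for (i in 1:20) {
        man2 <- data.frame(probe_id = paste0("p", 1:200), chrom = "chr1",
                           pos = sample.int(10000, 200))
        regs <- randomRegionSet(5)
        got2 <- probesInRegions(man2, regs)
        expected <- man2$probe_id[vapply(man2$pos, function(p) {
            any(p - 1 >= GenomicRanges::start(regs) - 1 &
                    p - 1 < GenomicRanges::end(regs))
        }, logical(1))]
        expect_setequal(got2, expected)
    }
})
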