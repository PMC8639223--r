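#' Load a gene model from GFF3 or BED12
#'
#' Parses a gene model via [rtracklayer::import] and converts it to the
#' internal representation: a `genes` table (0-based half-open span,
#' strand-aware TSS) plus exon and UTR interval tables. For GFF3 (1-based
#' inclusive on disk) `gene`, `exon`, `five_prime_UTR` and `three_prime_UTR`
#' features are used, exons/UTRs tied to their gene via `Parent`/`ID`. For
#' BED12 the blocks are the exons and the thick (CDS) range, when narrower
#' than the transcript, implies the UTRs.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return object of class `"GeneModel"`: list of data.frames `genes`
#'   (`gene_id, name, chrom, strand, start, end, tss` — 0-based half-open,
#'   `tss` a 0-based point), `exons` and `utrs` (`gene_id, chrom, start,
#'   end[, side]`).
#' @export
loadGeneModel <- function(path, format = c("auto", "gff3", "bed12")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE))
            "bed12" else "gff3"
    if (format == "gff3") {
        gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                       error = function(e)
                           stop("malformed GFF3 in ", path, ": ",
                                conditionMessage(e)))
        isGene <- gr$type == "gene"
        if (!any(isGene)) stop("no gene features in ", path)
        g <- gr[isGene]
        ids <- as.character(g$ID)
        genes <- data.frame(
            gene_id = ids,
            name = if (!is.null(g$Name)) as.character(g$Name) else ids,
            chrom = normalizeChrom(as.character(GenomicRanges::seqnames(g))),
            strand = as.character(GenomicRanges::strand(g)),
            start = GenomicRanges::start(g) - 1L,
            end = GenomicRanges::end(g))
        pickChildren <- function(type) {
            x <- gr[gr$type %in% type]
            if (!length(x)) {
                return(data.frame(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer()))
            }
            parent <- vapply(x$Parent, function(p)
                if (length(p)) as.character(p[[1]]) else NA_character_,
                character(1))
            data.frame(
                gene_id = parent,
                chrom = normalizeChrom(as.character(GenomicRanges::seqnames(x))),
                start = GenomicRanges::start(x) - 1L,
                end = GenomicRanges::end(x))
        }
        exons <- pickChildren("exon")
        utr5 <- pickChildren("five_prime_UTR")
        utr3 <- pickChildren("three_prime_UTR")
        utrs <- rbind(
            if (nrow(utr5)) cbind(utr5, side = "five_utr"),
            if (nrow(utr3)) cbind(utr3, side = "three_utr"))
        if (is.null(utrs))
            utrs <- data.frame(gene_id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               side = character())
    } else {
        gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                       error = function(e)
                           stop("malformed BED12 in ", path, ": ",
                                conditionMessage(e)))
        ids <- if (!is.null(gr$name)) as.character(gr$name)
               else paste0("gene", seq_along(gr))
        genes <- data.frame(
            gene_id = ids, name = ids,
            chrom = normalizeChrom(as.character(GenomicRanges::seqnames(gr))),
            strand = as.character(GenomicRanges::strand(gr)),
            start = GenomicRanges::start(gr) - 1L,
            end = GenomicRanges::end(gr))
        exons <- utrs <- NULL
        blocks <- gr$blocks
        for (i in seq_along(gr)) {
            bl <- if (!is.null(blocks)) {
                GenomicRanges::shift(blocks[[i]], GenomicRanges::start(gr)[i] - 1L)
            } else IRanges::IRanges(GenomicRanges::start(gr)[i],
                                    GenomicRanges::end(gr)[i])
            exons <- rbind(exons, data.frame(
                gene_id = ids[i], chrom = genes$chrom[i],
                start = IRanges::start(bl) - 1L, end = IRanges::end(bl)))
            th <- gr$thick[i]
            if (!is.null(th) && IRanges::width(th) > 0 &&
                (IRanges::start(th) > GenomicRanges::start(gr)[i] ||
                 IRanges::end(th) < GenomicRanges::end(gr)[i])) {
                left <- c(genes$start[i], IRanges::start(th) - 1L)
                right <- c(IRanges::end(th), genes$end[i])
                plus <- genes$strand[i] != "-"
                if (left[2] > left[1])
                    utrs <- rbind(utrs, data.frame(
                        gene_id = ids[i], chrom = genes$chrom[i],
                        start = left[1], end = left[2],
                        side = if (plus) "five_utr" else "three_utr"))
                if (right[2] > right[1])
                    utrs <- rbind(utrs, data.frame(
                        gene_id = ids[i], chrom = genes$chrom[i],
                        start = right[1], end = right[2],
                        side = if (plus) "three_utr" else "five_utr"))
            }
        }
        if (is.null(utrs))
            utrs <- data.frame(gene_id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               side = character())
    }
    genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
    structure(list(genes = genes, exons = exons, utrs = utrs),
              class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
    cat("GeneModel:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
        nrow(x$utrs), "UTR intervals\n")
    invisible(x)
}

#' Assign a genomic feature to a position
#'
#' Classifies a single CpG position against the gene model with the fixed
#' priority promoter > 5'UTR > 3'UTR > exon > intron > downstream >
#' distal_intergenic. The promoter is `TSS - promoterUp .. TSS +
#' promoterDown` (strand-aware); `downstream` covers at most
#' `downstreamWindow` bp past the gene's 3' end. Ties across genes are
#' broken by the smallest absolute distance to a TSS.
#'
#' @param model a [loadGeneModel()] object.
#' @param chrom chromosome label (any dialect).
#' @param pos 1-based position of the CpG (as in array manifests).
#' @param promoterUp,promoterDown promoter window around the TSS in bp
#'   (defaults 3000/3000).
#' @param downstreamWindow bp past the gene 3' end still called
#'   "downstream" (default 300).
#' @return `data.frame(feature, gene_id, distance_to_tss)`; the distance is
#'   signed, positive downstream of the TSS in gene orientation.
#' @export
annotatePosition <- function(model, chrom, pos, promoterUp = 3000,
                             promoterDown = 3000, downstreamWindow = 300) {
    stopifnot(inherits(model, "GeneModel"))
    chrom <- normalizeChrom(chrom)
    point <- pos - 1L                      # 0-based point
    g <- model$genes[model$genes$chrom == chrom, , drop = FALSE]
    if (!nrow(g)) {
        return(data.frame(feature = "distal_intergenic",
                          gene_id = NA_character_,
                          distance_to_tss = NA_real_,
                          flagged_unknown_chrom = TRUE))
    }
    minus <- g$strand == "-"
    dist <- ifelse(minus, g$tss - point, point - g$tss)  # + downstream of TSS

    inPromoter <- dist >= -promoterUp & dist <= promoterDown
    within <- function(tab, gid) {
        t2 <- tab[tab$chrom == chrom & tab$gene_id == gid, , drop = FALSE]
        any(point >= t2$start & point < t2$end)
    }
    featureFor <- function(i) {
        gid <- g$gene_id[i]
        if (inPromoter[i]) return("promoter")
        u <- model$utrs[model$utrs$gene_id == gid &
                        model$utrs$chrom == chrom, , drop = FALSE]
        inU <- u[point >= u$start & point < u$end, , drop = FALSE]
        if (nrow(inU)) {
            if (any(inU$side == "five_utr")) return("five_utr")
            return("three_utr")
        }
        inGene <- point >= g$start[i] & point < g$end[i]
        if (inGene) {
            if (within(model$exons, gid)) return("exon")
            return("intron")
        }
        threeEnd <- if (minus[i]) g$start[i] else g$end[i] - 1L
        dDown <- if (minus[i]) threeEnd - point else point - threeEnd
        if (dDown > 0 && dDown < downstreamWindow) return("downstream")
        "distal_intergenic"
    }
    feats <- vapply(seq_len(nrow(g)), featureFor, character(1))
    prio <- c(promoter = 1, five_utr = 2, three_utr = 3, exon = 4,
              intron = 5, downstream = 6, distal_intergenic = 7)
    ord <- order(prio[feats], abs(dist))
    best <- ord[1]
    data.frame(feature = feats[best], gene_id = g$gene_id[best],
               distance_to_tss = dist[best], flagged_unknown_chrom = FALSE)
}

#' Annotate a region by its midpoint
#'
#' Regions (DMRs) are assigned the feature of their midpoint position, the
#' peak-annotation convention; gene assignment comes from the same call.
#'
#' @param model a [loadGeneModel()] object.
#' @param chrom chromosome label.
#' @param start,end 0-based half-open region bounds.
#' @param ... passed to [annotatePosition()].
#' @return as [annotatePosition()].
#' @export
annotateRegion <- function(model, chrom, start, end, ...) {
    if (end <= start) stop("region must have positive length")
    mid <- floor((start + end) / 2)       # 0-based midpoint
    annotatePosition(model, chrom, mid + 1L, ...)
}

#' Annotate a DMR table
#'
#' @param dmrs DMR `data.frame` with `chrom`, `start`, `end`.
#' @param model gene model.
#' @param ... passed to [annotatePosition()].
#' @return input with `feature`, `gene_id`, `distance_to_tss` appended.
#' @export
annotateDmrs <- function(dmrs, model, ...) {
    if (!nrow(dmrs)) {
        dmrs$feature <- character(0)
        dmrs$gene_id <- character(0)
        dmrs$distance_to_tss <- numeric(0)
        return(dmrs)
    }
    ann <- do.call(rbind, lapply(seq_len(nrow(dmrs)), function(i)
        annotateRegion(model, dmrs$chrom[i], dmrs$start[i], dmrs$end[i], ...)))
    dmrs$feature <- ann$feature
    dmrs$gene_id <- ann$gene_id
    dmrs$distance_to_tss <- ann$distance_to_tss
    dmrs
}

#' Fraction of interval a covered by interval b
#'
#' Both intervals are 0-based half-open on the same chromosome.
#'
#' @param aStart,aEnd,bStart,bEnd interval bounds.
#' @return `|a intersect b| / |a|` in `[0, 1]`.
#' @export
overlapFraction <- function(aStart, aEnd, bStart, bEnd) {
    if (aEnd <= aStart) stop("interval a must have positive length")
    ov <- pmax(0, pmin(aEnd, bEnd) - pmax(aStart, bStart))
    ov / (aEnd - aStart)
}

#' Base-pair intersection of region sets
#'
#' @param sets list (length >= 2) of `GRanges`.
#' @return `GRanges` of the base-pair-level intersection across all sets,
#'   adjacent intervals merged.
#' @export
intersectRegionSets <- function(sets) {
    if (length(sets) < 2) stop("need at least 2 region sets")
    out <- Reduce(function(a, b)
        GenomicRanges::intersect(GenomicRanges::reduce(a),
                                 GenomicRanges::reduce(b),
                                 ignore.strand = TRUE), sets)
    GenomicRanges::reduce(out)
}

#' Probes whose CpG lies inside a region set
#'
#' Array manifests give 1-based CpG positions; the position is treated as a
#' 0-based point `pos - 1` against the 0-based half-open intervals, so a
#' probe at 1-based pos 101 is inside `[100, 200)` and a probe at pos 100
#' is not.
#'
#' @param manifest manifest `data.frame` with `probe_id`, `chrom`, `pos`.
#' @param regions `GRanges` region set.
#' @return character vector of probe ids inside any interval.
#' @export
probesInRegions <- function(manifest, regions) {
    pts <- GenomicRanges::GRanges(
        seqnames = normalizeChrom(manifest$chrom),
        ranges = IRanges::IRanges(start = manifest$pos, width = 1L))
    hit <- suppressWarnings(GenomicRanges::countOverlaps(
        pts, regions, ignore.strand = TRUE)) > 0
    manifest$probe_id[hit]
}
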