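#' Normalize chromosome labels
#'
#' Maps the common dialects ("1", "chr1", "X", "chrx") onto a canonical
#' "chr"-prefixed form so that manifests, BED files and gene models from
#' different sources can be joined safely.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of canonical labels ("chr1", ..., "chrX", "chrY").
#' @export
normalizeChrom <- function(chrom) {
    x <- as.character(chrom)
    x <- sub("^[Cc][Hh][Rr]", "", x)
    x[toupper(x) == "X"] <- "X"
    x[toupper(x) == "Y"] <- "Y"
    paste0("chr", x)
}

#' Read a BED file into a GRanges
#'
#' BED intervals are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] uses the usual 1-based closed convention, so a
#' BED record `start=100 end=200` becomes `101..200`. A 4th column, when
#' present, is kept as the `label` metadata column.
#'
#' @param path path to a (plain-text) BED file.
#' @param name optional name stored in `metadata(gr)$name`.
#' @return `GRanges` with optional `label` metadata column.
#' @export
readBedRegions <- function(path, name = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
    gr <- GenomicRanges::GRanges(
        seqnames = normalizeChrom(df[[1]]),
        ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]))
    if (ncol(df) >= 4) S4Vectors::mcols(gr)$label <- as.character(df[[4]])
    S4Vectors::metadata(gr)$name <- if (is.null(name))
        sub("\\.bed$", "", basename(path)) else name
    gr
}

#' Write a GRanges as a BED file (0-based half-open)
#'
#' @param gr `GRanges`; a `label` metadata column becomes the BED name field,
#'   a `score` column the score field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedRegions <- function(gr, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    mc <- S4Vectors::mcols(gr)
    if ("label" %in% names(mc)) {
        df$name <- as.character(mc$label)
        df$score <- if ("score" %in% names(mc)) mc$score else 0
        df$strand <- "."
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# Convert a 0-based half-open data.frame (chrom/start/end) to GRanges.
.df2gr <- function(df) {
    GenomicRanges::GRanges(seqnames = normalizeChrom(df$chrom),
                           ranges = IRanges::IRanges(start = df$start + 1L,
                                                     end = df$end))
}

#' Write a TSV with a provenance header
#'
#' All tabular outputs of the pipeline carry a comment header stating the
#' tool version, the configuration hash and the coordinate convention, so a
#' table can always be traced back to the run that produced it.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param configHash character hash echoed into the header (or `NA`).
#' @param coords text describing the coordinate convention of the table.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, configHash = NA_character_,
                     coords = "0-based half-open") {
    ver <- as.character(utils::packageVersion("methexpand"))
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c(paste0("# methexpand ", ver),
                 paste0("# config_hash: ", configHash),
                 paste0("# coordinates: ", coords)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a TSV written by [writeTsv()]
#' @param path input path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
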