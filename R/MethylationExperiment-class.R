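#' MethylationExperiment: array-style methylation values with sample metadata
#'
#' Container for a probes x samples methylation matrix together with an
#' optional detection p-value matrix and the sample sheet (donor, run, day,
#' cell type, cumulative expansion rate). Extends
#' [SummarizedExperiment::SummarizedExperiment] so the usual subsetting,
#' `colData()` and `assay()` machinery applies. Values live either on the
#' beta scale (methylation fraction in `[0, 1]`) or the M scale (logit2);
#' the current scale is tracked in the object and checked by each operation.
#'
#' @slot ... inherited from `SummarizedExperiment`; the methylation values
#'   are the `"meth"` assay, detection p-values (when present) the `"detP"`
#'   assay. `metadata()` keeps `scale` (`"beta"` or `"M"`), the M-offset
#'   used for conversion, and the probe-filtering report once filtering has
#'   run.
#'
#' @aliases MethylationExperiment-class
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
    msg <- character()
    if (!"meth" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'meth' is required")
    ids <- rownames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "probe ids must be present and unique")
    sid <- colnames(object)
    if (is.null(sid) || anyDuplicated(sid))
        msg <- c(msg, "sample ids must be present and unique")
    sc <- S4Vectors::metadata(object)$scale
    if (is.null(sc) || !sc %in% c("beta", "M"))
        msg <- c(msg, "metadata scale must be 'beta' or 'M'")
    x <- SummarizedExperiment::assay(object, "meth")
    if (identical(sc, "beta") && length(x) &&
        (min(x, na.rm = TRUE) < 0 || max(x, na.rm = TRUE) > 1))
        msg <- c(msg, "beta-scale values must lie in [0, 1]")
    if ("detP" %in% SummarizedExperiment::assayNames(object)) {
        dp <- SummarizedExperiment::assay(object, "detP")
        if (length(dp) && (min(dp, na.rm = TRUE) <= 0 || max(dp, na.rm = TRUE) > 1))
            msg <- c(msg, "detection p-values must lie in (0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param beta numeric matrix (probes x samples) of methylation values on the
#'   scale given by `scale`. Needs row and column names.
#' @param detectionP optional matrix of detection p-values in `(0, 1]` with
#'   the same dimensions as `beta`.
#' @param sampleSheet optional `data.frame` of per-sample metadata; rows are
#'   matched to `colnames(beta)` via a `sample_id` column (or rownames).
#'   Typical columns: `donor`, `run`, `day`, `cell_type`,
#'   `cumulative_expansion_rate`.
#' @param scale `"beta"` (default) or `"M"`.
#' @param mOffset offset used when converting between beta and M values.
#' @return a [MethylationExperiment-class] object.
#' @examples
#' b <- matrix(runif(12), 4, 3,
#'             dimnames = list(paste0("cg", 1:4), paste0("s", 1:3)))
#' me <- MethylationExperiment(b)
#' methScale(me)
#' @export
MethylationExperiment <- function(beta, detectionP = NULL, sampleSheet = NULL,
                                  scale = c("beta", "M"), mOffset = 1e-3) {
    scale <- match.arg(scale)
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("'beta' needs probe rownames and sample colnames")
    assays <- list(meth = beta)
    if (!is.null(detectionP)) {
        detectionP <- as.matrix(detectionP)
        if (!identical(dim(detectionP), dim(beta)))
            stop("'detectionP' must match the dimensions of 'beta'")
        dimnames(detectionP) <- dimnames(beta)
        assays$detP <- detectionP
    }
    if (is.null(sampleSheet)) {
        cd <- S4Vectors::DataFrame(row.names = colnames(beta))
    } else {
        sampleSheet <- as.data.frame(sampleSheet)
        key <- if ("sample_id" %in% names(sampleSheet))
            as.character(sampleSheet$sample_id) else rownames(sampleSheet)
        idx <- match(colnames(beta), key)
        if (anyNA(idx))
            stop("sampleSheet is missing samples: ",
                 paste(colnames(beta)[is.na(idx)], collapse = ", "))
        cd <- S4Vectors::DataFrame(sampleSheet[idx, , drop = FALSE],
                                   row.names = colnames(beta))
    }
    se <- SummarizedExperiment::SummarizedExperiment(assays = assays, colData = cd)
    S4Vectors::metadata(se)$scale <- scale
    S4Vectors::metadata(se)$mOffset <- mOffset
    methods::new("MethylationExperiment", se)
}

#' @rdname MethylationExperiment
#' @param x,object a `MethylationExperiment`.
#' @export
setGeneric("methValues", function(x) standardGeneric("methValues"))

#' @rdname MethylationExperiment
#' @export
setMethod("methValues", "MethylationExperiment", function(x)
    SummarizedExperiment::assay(x, "meth"))

#' @rdname MethylationExperiment
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname MethylationExperiment
#' @export
setMethod("detectionP", "MethylationExperiment", function(x) {
    if (!"detP" %in% SummarizedExperiment::assayNames(x)) NULL
    else SummarizedExperiment::assay(x, "detP")
})

#' @rdname MethylationExperiment
#' @export
setGeneric("methScale", function(x) standardGeneric("methScale"))

#' @rdname MethylationExperiment
#' @export
setMethod("methScale", "MethylationExperiment", function(x)
    S4Vectors::metadata(x)$scale)

#' @rdname MethylationExperiment
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname MethylationExperiment
#' @export
setMethod("sampleSheet", "MethylationExperiment", function(x) {
    df <- as.data.frame(SummarizedExperiment::colData(x))
    df$sample_id <- colnames(x)
    df[, c("sample_id", setdiff(names(df), "sample_id")), drop = FALSE]
})

#' @rdname MethylationExperiment
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname MethylationExperiment
#' @export
setMethod("filterReport", "MethylationExperiment", function(x)
    S4Vectors::metadata(x)$filterReport)

setMethod("show", "MethylationExperiment", function(object) {
    cat("MethylationExperiment:", nrow(object), "probes x",
        ncol(object), "samples\n")
    cat("  scale:", methScale(object),
        if ("detP" %in% SummarizedExperiment::assayNames(object))
            "| detection-p present" else "| no detection-p", "\n")
    rep <- filterReport(object)
    if (!is.null(rep))
        cat("  filtered:", sum(rep$removed), "probes removed (",
            paste0(rep$reason, "=", rep$removed, collapse = ", "), ")\n")
    invisible(NULL)
})

# internal helper: replace the meth assay, optionally switching scale
.replaceMeth <- function(me, values, scale = methScale(me)) {
    SummarizedExperiment::assay(me, "meth") <- values
    S4Vectors::metadata(me)$scale <- scale
    methods::validObject(me)
    me
}
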