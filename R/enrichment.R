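#' Read gene sets from a GMT file
#'
#' @param path GMT path (term, description, then member genes, tab-separated).
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, character(1), 1)
    attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
    sets
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test per term: with a universe of `N` genes of
#' which `K` are in the term and a query of `n` genes with `k` in the term,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`; BH adjustment across
#' terms.
#'
#' @param query character vector of query genes (must be a subset of the
#'   universe; duplicates collapsed).
#' @param universe character vector of background genes.
#' @param sets named list of gene sets (members outside the universe are
#'   ignored; empty sets dropped).
#' @param fdrThreshold threshold on the adjusted p (default 0.05).
#' @return `data.frame(term, overlap, set_size, query_size, universe_size,
#'   p, q, significant)` ordered by p.
#' @export
oraHypergeometric <- function(query, universe, sets, fdrThreshold = 0.05) {
    query <- unique(query)
    universe <- unique(universe)
    if (!length(query)) stop("query gene list is empty")
    if (!all(query %in% universe))
        stop("query genes must be a subset of the universe")
    N <- length(universe)
    n <- length(query)
    sets <- lapply(sets, function(s) intersect(unique(s), universe))
    sets <- sets[lengths(sets) > 0]
    res <- do.call(rbind, lapply(names(sets), function(term) {
        K <- length(sets[[term]])
        k <- length(intersect(query, sets[[term]]))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term = term, overlap = k, set_size = K, query_size = n,
                   universe_size = N, p = p)
    }))
    res$q <- bhAdjust(res$p)
    res$significant <- res$q < fdrThreshold
    res[order(res$p), , drop = FALSE]
}

# weighted running-sum enrichment score for set positions in a ranked list
.gseaES <- function(absScore, inSet, weight) {
    N <- length(absScore)
    K <- sum(inSet)
    w <- if (weight == 0) rep(1, N) else absScore^weight
    hit <- ifelse(inSet, w, 0)
    denomHit <- sum(hit)
    if (denomHit == 0) return(0)
    run <- cumsum(hit / denomHit - (!inSet) / (N - K))
    run[which.max(abs(run))]
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score on a ranked
#' gene list, with a gene-label permutation null: NES is the ES divided by
#' the mean |null ES| of the same sign, and the empirical two-sided p uses
#' the same-sign null tail with a +1 correction (so p is never below
#' `1/(nPermutations + 1)`). BH adjustment across sets.
#'
#' @param scores named numeric vector of ranking scores (unique gene names,
#'   finite values); sorted internally in decreasing order.
#' @param sets named list of gene sets; sets with fewer than 2 ranked
#'   members are skipped with a warning.
#' @param nPermutations permutation count (default 1000).
#' @param seed RNG seed for the permutations.
#' @param weight running-sum weight (default 1; 0 gives the classical
#'   unweighted KS statistic).
#' @return `data.frame(term, size, es, nes, p, q)`.
#' @export
gseaPreranked <- function(scores, sets, nPermutations = 1000, seed = 1,
                          weight = 1) {
    if (anyDuplicated(names(scores))) stop("gene names must be unique")
    if (any(!is.finite(scores))) stop("ranking scores must be finite")
    ord <- order(scores, decreasing = TRUE)
    scores <- scores[ord]
    genes <- names(scores)
    absScore <- abs(scores)
    N <- length(scores)

    keep <- vapply(sets, function(s) sum(genes %in% s) >= 2, logical(1))
    if (any(!keep))
        warning(sum(!keep), " set(s) with < 2 ranked members skipped")
    sets <- sets[keep]
    if (!length(sets))
        return(data.frame(term = character(), size = integer(),
                          es = numeric(), nes = numeric(), p = numeric(),
                          q = numeric()))
    set.seed(seed)
    res <- do.call(rbind, lapply(names(sets), function(term) {
        inSet <- genes %in% sets[[term]]
        K <- sum(inSet)
        es <- .gseaES(absScore, inSet, weight)
        nullES <- vapply(seq_len(nPermutations), function(i) {
            idx <- sample.int(N, K)
            flag <- logical(N)
            flag[idx] <- TRUE
            .gseaES(absScore, flag, weight)
        }, numeric(1))
        same <- nullES[sign(nullES) == sign(es) | nullES == 0]
        p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
        nes <- if (length(same) && mean(abs(same)) > 0)
            es / mean(abs(same)) else NA_real_
        data.frame(term = term, size = K, es = es, nes = nes, p = p)
    }))
    res$q <- bhAdjust(res$p)
    res
}
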