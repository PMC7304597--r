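# Hypergeometric GO-BP over-representation test for a gene window against
# the genome-wide GO-BP universe, with GOstats-compatible output rows.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a
#' window of `n` genes drawn without replacement from a universe of `N`
#' genes, `K` of which carry the term, contains at least `k` carriers.
#' Computed with [stats::phyper()] (stable in log space internally).
#'
#' @param N Universe size (GO-BP-annotated genes genome-wide).
#' @param K Universe genes carrying the term.
#' @param n Window size (after tandem collapse).
#' @param k Window genes carrying the term (after collapse).
#' @return The upper-tail probability, in (0, 1].
#' @export
hypergeom_upper <- function(N, K, n, k) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(n, K)) stop("k must lie in [0, min(n, K)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO-BP enrichment rows for a gene window
#'
#' Tests every GO-BP term carried by at least `min_count` window genes for
#' over-representation against the catalog's GO-BP universe. Universe
#' counts are never tandem-collapsed; collapse applies only to the tested
#' window, so pass the retained genes after [collapse_tandems()]. Output
#' columns follow the GOstats hyperGTest convention; the odds ratio
#' `k (N-K-n+k) / ((n-k)(K-k))` is reported as infinite when `n == k` or
#' `K == k`.
#'
#' @param window_genes Data frame of (collapsed) window genes with list
#'   column `go_bp`; genes with empty GO-BP sets contribute nothing and
#'   should not be in the window.
#' @param catalog The `GeneCatalog` providing `universe_N` and `term_K`.
#' @param min_count Minimum window genes sharing a term for the term to be
#'   reported (default 3: the prerequisite for calling a cluster).
#' @param p_threshold Report only rows with `p_value` at or below this
#'   (default 1: report all tested terms).
#' @return Data frame with columns `go_id`, `p_value`, `odds_ratio`,
#'   `exp_count`, `count`, `size`, `term`, sorted by ascending `p_value`
#'   then `go_id`.
#' @export
enrich_window <- function(window_genes, catalog, min_count = 3L,
                          p_threshold = 1) {
  n <- nrow(window_genes)
  empty <- data.frame(go_id = character(), p_value = double(),
                      odds_ratio = double(), exp_count = double(),
                      count = integer(), size = integer(),
                      term = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  counts <- table(unlist(window_genes$go_bp, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (!length(counts)) return(empty)
  N <- catalog$universe_N
  go_id <- names(counts)
  k <- as.integer(counts)
  K <- unname(catalog$term_K[go_id])
  if (anyNA(K)) stop("window term(s) missing from catalog universe")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  or <- ifelse(n == k | K == k, Inf,
               k * (N - K - n + k) / ((n - k) * (K - k)))
  term <- if (is.null(catalog$term_names)) NA_character_ else
    unname(catalog$term_names[go_id])
  out <- data.frame(go_id = go_id, p_value = p, odds_ratio = or,
                    exp_count = n * K / N, count = k, size = K,
                    term = term, stringsAsFactors = FALSE)
  out <- out[out$p_value <= p_threshold, , drop = FALSE]
  out <- out[order(out$p_value, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
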