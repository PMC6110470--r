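# Gene-set overlap, hypergeometric over-representation against a fixed
# background, and rank-sum comparison of per-gene scores.

#' Overlap between a query gene list and a gene set
#'
#' @param query Character vector of gene symbols.
#' @param target Character vector (a gene set).
#' @return Alphabetically sorted intersection.
#' @export
set_overlap <- function(query, target) {
  sort(intersect(unique(query), unique(target)))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`: the chance of observing at least `k` gene-set
#' members in a query of size `n` drawn from a background universe of size
#' `N` containing `K` set members. `k = 0` returns exactly 1.
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Gene-set size (within the background).
#' @param N Background universe size.
#' @return Tibble of class `exodel_overrep`: k, n, K, N, expected overlap,
#'   fold enrichment and upper-tail `p`.
#' @export
overrep_test <- function(k, n, K, N) {
  if (k > min(n, K) || n > N || K > N || any(c(k, n, K, N) < 0)) {
    abort("inconsistent counts: need k <= min(n, K) and n, K <= N")
  }
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  structure(tibble(k = k, n = n, K = K, N = N, expected = expected,
                   fold_enrichment = if (expected > 0) k / expected else NA_real_,
                   p = p),
            class = c("exodel_overrep", "tbl_df", "tbl", "data.frame"))
}

#' Over-representation of a query against each of several gene sets
#'
#' @param query Character vector of gene symbols (restricted to the
#'   background before testing).
#' @param sets Named list of character vectors.
#' @param background Character vector: the universe (e.g. all
#'   brain-expressed genes). Sets are intersected with it.
#' @return Tibble with one row per set: set, overlap genes, k/n/K/N, p.
#' @export
overrep_gene_sets <- function(query, sets, background) {
  background <- unique(background)
  q <- intersect(unique(query), background)
  purrr::imap(sets, function(s, nm) {
    s_bg <- intersect(unique(s), background)
    ov <- set_overlap(q, s_bg)
    res <- overrep_test(length(ov), length(q), length(s_bg), length(background))
    tibble(set = nm, overlap = list(ov), k = res$k, n = res$n, K = res$K,
           N = res$N, fold_enrichment = res$fold_enrichment, p = res$p)
  }) %>% bind_rows() %>% arrange(.data$p)
}

#' Wilcoxon rank-sum comparison of two score vectors
#'
#' Exact null distribution when both groups have at most `exact_limit`
#' observations and the data contain no ties; otherwise the normal
#' approximation with mid-ranks and tie-corrected variance. Two identical
#' multisets (or all-constant data) return p = 1 by convention.
#'
#' @param scores_a,scores_b Non-empty numeric vectors.
#' @param exact_limit Maximum group size for the exact distribution
#'   (default 20).
#' @return Tibble: n_a, n_b, statistic (Mann-Whitney U of group a), method,
#'   two-sided p.
#' @export
rank_sum_test <- function(scores_a, scores_b, exact_limit = 20) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    abort("both score vectors must be non-empty")
  }
  pooled <- c(scores_a, scores_b)
  u <- sum(rank(pooled)[seq_along(scores_a)]) -
    length(scores_a) * (length(scores_a) + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(tibble(n_a = length(scores_a), n_b = length(scores_b),
                  statistic = u, method = "degenerate", p = 1))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && length(scores_a) <= exact_limit &&
    length(scores_b) <= exact_limit
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b, exact = exact,
                                     correct = !exact))
  tibble(n_a = length(scores_a), n_b = length(scores_b), statistic = u,
         method = if (exact) "exact" else "normal approximation (tie-corrected)",
         p = min(1, wt$p.value))
}
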