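# Large/rare-deletion burden testing by case-control label permutation.

#' Burden-test configuration
#'
#' @param min_length_bp Deletions must be strictly longer than this
#'   (default 400 kb).
#' @param match_overlap_fraction Reciprocal-overlap threshold used to group
#'   calls into loci when computing internal carrier frequency (default 0.7).
#' @param max_internal_freq Deletions carried by at least this fraction of
#'   all samples are excluded (strict `<`, default 0.005).
#' @param n_perm Number of label permutations (default 10,000).
#' @param exhaustive_limit Enumerate all labelings exactly when the number
#'   of distinct case/control assignments is at most this.
#' @param seed Integer seed for the permutation stream.
#' @return List of class `exodel_burden_config`.
#' @export
burden_config <- function(min_length_bp = 400000, match_overlap_fraction = 0.7,
                          max_internal_freq = 0.005, n_perm = 10000,
                          exhaustive_limit = 5000, seed = 1L) {
  stopifnot(n_perm >= 1, max_internal_freq > 0, max_internal_freq < 1,
            match_overlap_fraction > 0, match_overlap_fraction <= 1,
            min_length_bp >= 0)
  structure(list(min_length_bp = min_length_bp,
                 match_overlap_fraction = match_overlap_fraction,
                 max_internal_freq = max_internal_freq,
                 n_perm = as.integer(n_perm),
                 exhaustive_limit = exhaustive_limit,
                 seed = as.integer(seed)),
            class = "exodel_burden_config")
}

#' Select the large, rare deletions entering the burden test
#'
#' Keeps deletions with length strictly above `min_length_bp` whose carrier
#' frequency - the fraction of all samples (cases and controls) carrying a
#' matching call at the configured reciprocal overlap - is strictly below
#' `max_internal_freq`.
#'
#' @param calls Filtered deletion calls with `sample` columns.
#' @param samples Tibble of all samples (sample, phenotype); the denominator
#'   of the internal frequency.
#' @param cfg [burden_config()].
#' @return The retained calls.
#' @export
select_burden_set <- function(calls, samples, cfg = burden_config()) {
  if (nrow(calls) == 0) return(calls)
  large <- calls[call_length(calls) > cfg$min_length_bp, , drop = FALSE]
  if (nrow(large) == 0) return(large)
  carriers <- matching_carriers(large, large, cfg$match_overlap_fraction)
  freq <- carriers / nrow(samples)
  large[freq < cfg$max_internal_freq, , drop = FALSE]
}

# Per-sample aggregates used by the permutation machinery: for each sample
# (in `samples` order) the number of calls and total deleted bp.
sample_aggregates <- function(calls, samples) {
  idx <- match(calls$sample, samples$sample)
  if (anyNA(idx)) abort("call sample missing from the sample table")
  counts <- tabulate(idx, nbins = nrow(samples))
  lengths <- rep(0, nrow(samples))
  if (nrow(calls) > 0) {
    by <- tapply(call_length(calls), idx, sum)
    lengths[as.integer(names(by))] <- by
  }
  list(counts = counts, lengths = lengths)
}

# The four burden statistics for a case index set, given aggregates.
burden_stats_for <- function(agg, case_idx, n_case, n_control) {
  cc <- agg$counts[case_idx]
  cl <- agg$lengths[case_idx]
  kc <- agg$counts[-case_idx]
  kl <- agg$lengths[-case_idx]
  stat <- function(counts, lens, n) {
    ncalls <- sum(counts)
    c(rate_per_person = ncalls / n,
      proportion_with_deletion = sum(counts > 0) / n,
      total_length = sum(lens) / n,
      average_length = if (ncalls > 0) sum(lens) / ncalls else 0)
  }
  stat(cc, cl, n_case) - stat(kc, kl, n_control)
}

#' Per-group burden statistics
#'
#' Deletion rate per person, proportion of samples with at least one
#' deletion, total deleted length per person, and average deletion length
#' (0 by convention for a group without calls).
#'
#' @param calls Deletion calls with a `sample` column.
#' @param samples Tibble (sample, phenotype); `phenotype` defines the groups.
#' @return Tibble with one row per phenotype and one column per statistic.
#' @export
burden_statistics <- function(calls, samples) {
  if (nrow(samples) == 0) abort("empty sample table")
  groups <- split(seq_len(nrow(samples)), samples$phenotype)
  if (any(lengths(groups) == 0)) abort("empty phenotype group")
  agg <- sample_aggregates(calls, samples)
  purrr::imap(groups, function(idx, ph) {
    counts <- agg$counts[idx]
    lens <- agg$lengths[idx]
    ncalls <- sum(counts)
    tibble(phenotype = ph,
           n_samples = length(idx),
           n_deletions = ncalls,
           rate_per_person = ncalls / length(idx),
           proportion_with_deletion = sum(counts > 0) / length(idx),
           total_length = sum(lens) / length(idx),
           average_length = if (ncalls > 0) sum(lens) / ncalls else 0)
  }) %>% bind_rows()
}

#' Empirical burden p-values by case-control label permutation
#'
#' For each statistic the observed case-minus-control difference is compared
#' with its permutation distribution under random relabeling (one-sided,
#' cases higher). When the number of distinct labelings is at most
#' `exhaustive_limit` all of them are enumerated and
#' `p = #\{delta* >= delta\} / n_labelings` exactly; otherwise `n_perm`
#' random relabelings are drawn and the add-one-corrected estimator
#' `p = (1 + #\{delta* >= delta\}) / (1 + n_perm)` is used, which is never
#' zero.
#'
#' @param calls Deletion calls (typically [select_burden_set()] output).
#' @param samples Tibble (sample, phenotype) with phenotype either
#'   `"case"`/`"control"` or anything else mapped via `case_levels`.
#' @param cfg [burden_config()].
#' @param case_levels Phenotype labels counted as cases; all others are
#'   controls.
#' @return Object of class `exodel_burden`: tibble `result` (statistic,
#'   case, control, delta, p) plus metadata (n_perm or exact enumeration).
#' @export
permutation_pvalue <- function(calls, samples, cfg = burden_config(),
                               case_levels = c("case", "GGE", "RE")) {
  is_case <- samples$phenotype %in% case_levels
  n_case <- sum(is_case)
  n_control <- sum(!is_case)
  if (n_case == 0 || n_control == 0) abort("need at least one case and one control")
  agg <- sample_aggregates(calls, samples)
  n <- nrow(samples)
  observed <- burden_stats_for(agg, which(is_case), n_case, n_control)

  n_labelings <- suppressWarnings(choose(n, n_case))
  exact <- is.finite(n_labelings) && n_labelings <= cfg$exhaustive_limit
  if (exact) {
    combos <- combn(n, n_case)
    deltas <- apply(combos, 2, function(idx)
      burden_stats_for(agg, idx, n_case, n_control))
    exceed <- rowSums(deltas >= observed - 1e-12)
    p <- exceed / ncol(combos)
    n_used <- ncol(combos)
  } else {
    set.seed(cfg$seed)
    exceed <- numeric(4)
    for (b in seq_len(cfg$n_perm)) {
      idx <- sample.int(n, n_case)
      exceed <- exceed + (burden_stats_for(agg, idx, n_case, n_control) >=
                            observed - 1e-12)
    }
    p <- (1 + exceed) / (1 + cfg$n_perm)
    n_used <- cfg$n_perm
  }
  group_stats <- burden_statistics(
    calls, mutate(samples, phenotype = if_else(is_case, "case", "control")))
  stat_names <- c("rate_per_person", "proportion_with_deletion",
                  "total_length", "average_length")
  result <- tibble(
    statistic = stat_names,
    case = unlist(group_stats[group_stats$phenotype == "case", stat_names],
                  use.names = FALSE),
    control = unlist(group_stats[group_stats$phenotype == "control", stat_names],
                     use.names = FALSE),
    delta = unname(observed),
    p = unname(p)
  )
  structure(list(result = result, exact = exact, n_permutations = n_used,
                 n_case = n_case, n_control = n_control,
                 n_calls = nrow(calls), seed = cfg$seed),
            class = "exodel_burden")
}

#' @export
print.exodel_burden <- function(x, ...) {
  cat(sprintf("<exodel_burden> %d cases vs %d controls, %d deletions, %s (%d labelings)\n",
              x$n_case, x$n_control, x$n_calls,
              if (x$exact) "exact enumeration" else "sampled permutations",
              x$n_permutations))
  print(x$result)
  invisible(x)
}

#' @method tidy exodel_burden
#' @export
tidy.exodel_burden <- function(x, ...) {
  x$result
}

#' @method glance exodel_burden
#' @export
glance.exodel_burden <- function(x, ...) {
  tibble(n_case = x$n_case, n_control = x$n_control, n_calls = x$n_calls,
         exact = x$exact, n_permutations = x$n_permutations,
         min_p = min(x$result$p))
}

#' Plot observed burden differences against their permutation scale
#'
#' @param object An `exodel_burden` fit.
#' @param ... Ignored.
#' @return A ggplot: one bar per statistic showing the empirical p-value on
#'   a -log10 scale.
#' @method autoplot exodel_burden
#' @export
autoplot.exodel_burden <- function(object, ...) {
  df <- object$result
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = -log10(.data$p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Deletion burden: empirical permutation p-values") +
    ggplot2::theme_minimal()
}
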