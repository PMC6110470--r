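# Sample-level coverage QC and PCA-based depth normalization.

#' Exclude samples with inadequate exome coverage
#'
#' A sample is excluded iff its mean target depth is below `min_mean_depth`
#' or the fraction of targets covered at >= `cover_threshold` reads falls
#' below `min_frac_covered`.
#'
#' @param cohort An `exodel_cohort` (or any list with `depth`, `samples`,
#'   `targets`).
#' @param min_mean_depth Minimum mean depth (default 30x).
#' @param min_frac_covered Minimum fraction of targets covered (default 0.70).
#' @param cover_threshold Depth defining "covered" (default 20x).
#' @return List with `cohort` (survivors, same structure) and `excluded`
#'   (tibble: sample, mean_depth, frac_covered, reason).
#' @export
sample_coverage_qc <- function(cohort, min_mean_depth = 30,
                               min_frac_covered = 0.70, cover_threshold = 20) {
  depth <- cohort$depth
  if (is.null(depth) || nrow(depth) == 0) abort("empty depth matrix")
  mean_depth <- rowMeans(depth)
  frac_cov <- rowMeans(depth >= cover_threshold)
  bad_depth <- mean_depth < min_mean_depth
  bad_cov <- frac_cov < min_frac_covered
  drop <- bad_depth | bad_cov
  if (all(drop)) abort("all samples fail coverage QC")
  excluded <- tibble(
    sample = rownames(depth)[drop],
    mean_depth = mean_depth[drop],
    frac_covered = frac_cov[drop],
    reason = dplyr::case_when(
      bad_depth[drop] & bad_cov[drop] ~ "mean_depth;frac_covered",
      bad_depth[drop] ~ "mean_depth",
      TRUE ~ "frac_covered"
    )
  )
  out <- cohort
  out$depth <- depth[!drop, , drop = FALSE]
  out$samples <- cohort$samples[!drop, , drop = FALSE]
  if (!is.null(out$truth)) {
    out$truth <- filter(out$truth, !.data$sample %in% excluded$sample)
  }
  list(cohort = out, excluded = excluded)
}

#' PCA-normalize a depth matrix into per-sample z-scores
#'
#' Columns (targets) are mean-centred; principal components whose variance
#' exceeds `rel_var_threshold` times the mean component variance are
#' subtracted (removing latent batch, capture-efficiency and sample-loading
#' structure); each residual row is then divided by its own standard
#' deviation, giving per-sample, per-target z-scores with unit row sd.
#'
#' @param cohort An `exodel_cohort` after coverage QC (>= 2 samples and
#'   >= 2 targets).
#' @param rel_var_threshold Relative-variance removal criterion (default
#'   0.7: remove components with variance > 0.7 x mean component variance).
#' @return Object of class `exodel_norm`: `z` (matrix), `samples`,
#'   `targets`, `n_components_removed`, `dropped_samples`.
#' @export
pca_normalize <- function(cohort, rel_var_threshold = 0.7) {
  depth <- cohort$depth
  if (nrow(depth) < 2 || ncol(depth) < 2) {
    abort("need at least 2 samples and 2 targets to normalize")
  }
  x <- sweep(depth, 2, colMeans(depth))
  sv <- svd(x)
  d2 <- sv$d^2
  remove <- which(d2 > rel_var_threshold * mean(d2))
  if (length(remove) > 0) {
    x <- x - sv$u[, remove, drop = FALSE] %*%
      (sv$d[remove] * t(sv$v[, remove, drop = FALSE]))
  }
  row_sd <- apply(x, 1, sd)
  degenerate <- row_sd < .Machine$double.eps^0.5
  if (any(degenerate)) {
    warn(sprintf("dropping %d sample(s) with zero residual variance: %s",
                 sum(degenerate),
                 paste(rownames(depth)[degenerate], collapse = ", ")))
  }
  z <- x[!degenerate, , drop = FALSE] / row_sd[!degenerate]
  structure(list(
    z = z,
    samples = cohort$samples[!degenerate, , drop = FALSE],
    targets = cohort$targets,
    n_components_removed = length(remove),
    dropped_samples = rownames(depth)[degenerate]
  ), class = "exodel_norm")
}

#' @export
print.exodel_norm <- function(x, ...) {
  cat(sprintf("<exodel_norm> %d samples x %d targets, %d component(s) removed\n",
              nrow(x$z), ncol(x$z), x$n_components_removed))
  invisible(x)
}
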