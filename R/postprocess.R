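# Deletion filtering, cross-sample and reference-map matching, and gene
# annotation. All coordinates follow the package convention: 1-based
# inclusive start, exclusive end, length = end - start.

#' Filter scored CNV calls down to confident deletions
#'
#' Retains deletion calls with mean segment z strictly below `z_max`
#' (default -3) and segment quality `q_some` at or above `q_some_min`
#' (default 60). Duplication calls are always dropped: read-depth
#' duplication calls carry too high a false-positive rate for downstream
#' interpretation.
#'
#' @param calls Tibble of scored calls ([call_cnvs()]).
#' @param z_max Deletions must satisfy `z_mean < z_max` (strict).
#' @param q_some_min Minimum segment quality (inclusive).
#' @return Filtered tibble of DEL calls.
#' @export
filter_deletions <- function(calls, z_max = -3, q_some_min = 60) {
  calls %>%
    filter(.data$type == "DEL", .data$z_mean < z_max,
           .data$q_some >= q_some_min)
}

#' Reciprocal overlap of two genomic intervals
#'
#' `min(|a intersect b| / |a|, |a intersect b| / |b|)`; 0 for intervals on
#' different chromosomes. Vectorized with recycling; symmetric in its two
#' interval arguments.
#'
#' @param chrom_a,start_a,end_a First interval(s), end exclusive.
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Numeric fraction(s) in \[0, 1\].
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a,
                               chrom_b, start_b, end_b) {
  if (any(start_a >= end_a) || any(start_b >= end_b)) {
    abort("invalid interval: start must be < end")
  }
  inter <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  out <- pmin(inter / (end_a - start_a), inter / (end_b - start_b))
  out[chrom_a != chrom_b] <- 0
  out
}

# For each row of `calls`, the number of distinct samples in `others` with a
# call matching at >= frac reciprocal overlap.
matching_carriers <- function(calls, others, frac) {
  if (nrow(others) == 0) return(rep(0L, nrow(calls)))
  vapply(seq_len(nrow(calls)), function(i) {
    same <- others[others$chrom == calls$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(0L)
    ro <- reciprocal_overlap(calls$chrom[i], calls$start[i], calls$end[i],
                             same$chrom, same$start, same$end)
    length(unique(same$sample[ro >= frac]))
  }, integer(1))
}

#' Select case-only, low-frequency deletions
#'
#' A case call is retained iff (i) no control call matches it at
#' `match_overlap_fraction` reciprocal overlap, (ii) at most
#' `max_case_carriers` distinct case samples carry a matching call, and
#' (iii) no reference-map interval with frequency above `max_ref_freq`
#' matches it.
#'
#' @param case_calls,control_calls Filtered deletion tibbles with `sample`
#'   columns.
#' @param maps Named list of reference CNV maps (tibbles: chrom, start, end,
#'   frequency).
#' @param max_case_carriers Maximum number of independent case carriers.
#' @param max_ref_freq Maximum tolerated reference-map frequency.
#' @param match_overlap_fraction Reciprocal-overlap threshold for matching.
#' @return The retained case calls.
#' @export
case_only_filter <- function(case_calls, control_calls, maps = list(),
                             max_case_carriers = 2, max_ref_freq = 0.01,
                             match_overlap_fraction = 0.7) {
  if (nrow(case_calls) == 0) return(case_calls)
  in_controls <- matching_carriers(case_calls, control_calls,
                                   match_overlap_fraction) > 0
  n_case_carriers <- matching_carriers(case_calls, case_calls,
                                       match_overlap_fraction)
  common_in_map <- rep(FALSE, nrow(case_calls))
  for (m in maps) {
    freq_ok <- m[m$frequency > max_ref_freq, , drop = FALSE]
    if (nrow(freq_ok) == 0) next
    hit <- vapply(seq_len(nrow(case_calls)), function(i) {
      same <- freq_ok[freq_ok$chrom == case_calls$chrom[i], , drop = FALSE]
      if (nrow(same) == 0) return(FALSE)
      any(reciprocal_overlap(case_calls$chrom[i], case_calls$start[i],
                             case_calls$end[i], same$chrom, same$start,
                             same$end) >= match_overlap_fraction)
    }, logical(1))
    common_in_map <- common_in_map | hit
  }
  case_calls[!in_controls & n_case_carriers <= max_case_carriers &
               !common_in_map, , drop = FALSE]
}

#' Annotate calls with overlapping gene symbols
#'
#' A gene is reported when its span shares at least one base with the call
#' interval (end-exclusive semantics on both sides); symbols are sorted
#' alphabetically.
#'
#' @param calls Tibble of calls (chrom, start, end).
#' @param genes Gene models (symbol, chrom, start, end).
#' @return `calls` with a `genes` list-column and an `n_genes` count.
#' @export
annotate_genes <- function(calls, genes) {
  hits <- purrr::pmap(calls[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      same <- genes[genes$chrom == chrom, , drop = FALSE]
      if (nrow(same) == 0) return(character(0))
      ov <- pmin(same$end, end) - pmax(same$start, start)
      sort(same$symbol[ov > 0])
    })
  calls$genes <- hits
  calls$n_genes <- lengths(hits)
  calls
}

#' Deletion length in base pairs
#'
#' Defined as `end - start`, matching end-exclusive interval arithmetic.
#'
#' @param calls Tibble with start/end columns (or a one-row call).
#' @return Numeric vector of lengths.
#' @export
call_length <- function(calls) {
  if (any(calls$start >= calls$end)) abort("invalid interval: start must be < end")
  calls$end - calls$start
}
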