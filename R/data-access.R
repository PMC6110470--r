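# Bundled reference data.

#' Published epilepsy-cohort microdeletions
#'
#' The 104 case-only exome deletions reported in a GGE/RE epilepsy cohort
#' study (two phenotypes, read-depth calling, z < -3 and segment quality
#' >= 60 filtering), bundled as a plain-text table. Coordinates follow the
#' package convention: length = end - start for every row.
#'
#' @return Tibble: phenotype (GGE/RE), chrom, start, end, z_score, length,
#'   genes (comma-separated symbols).
#' @export
cohort_microdeletions <- function() {
  path <- system.file("extdata", "cohort_microdeletions.tsv",
                      package = "exodel", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}
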