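# Genotype/site quality control, multi-allelic decomposition with left
# normalization, rarity filtering, and the composite deleterious-variant
# classifier.

PREDICTOR_PANEL <- c("sift", "pp2_hdiv", "pp2_hvar", "lrt", "mutation_taster",
                     "mutation_assessor", "fathmm", "metasvm", "metalr")

#' Genotype-level QC: mask low-confidence genotypes
#'
#' Genotypes with read depth below `dp_min` or genotype quality below
#' `gq_min` are set to missing; per-site missingness is recomputed over the
#' cohort. Allele fields are never altered.
#'
#' @param variants An `exodel_variants` object (or list with `sites` and
#'   `genotypes`).
#' @param n_samples Cohort size used as the missingness denominator
#'   (defaults to the number of distinct samples seen in the genotypes).
#' @param dp_min,gq_min Masking thresholds (strict `<`, defaults 10 / 20).
#' @return The object with masked genotypes and updated `sites$missingness`.
#' @export
apply_genotype_qc <- function(variants, n_samples = NULL, dp_min = 10,
                              gq_min = 20) {
  geno <- variants$genotypes
  if (is.null(n_samples)) n_samples <- max(1L, dplyr::n_distinct(geno$sample))
  mask <- geno$dp < dp_min | geno$gq < gq_min
  geno$gt[mask] <- NA_character_
  miss <- geno %>% group_by(.data$variant_id) %>%
    summarise(n_missing = sum(is.na(.data$gt)), .groups = "drop")
  sites <- variants$sites %>%
    left_join(miss, by = "variant_id") %>%
    mutate(missingness = dplyr::coalesce(.data$n_missing, 0L) / n_samples) %>%
    select(-"n_missing")
  out <- variants
  out$sites <- sites
  out$genotypes <- geno
  out
}

#' Site-filter configuration
#'
#' Default SNV thresholds: fail on QD < 2.0, FS > 60.0, MQ < 40.0,
#' MQRankSum < -12.5, ReadPosRankSum < -8.0, site DP < 10.0,
#' GQ_MEAN < 20.0, VQSLOD < 0, missingness > 0.05, ABHet outside
#' \[0.25, 0.75\], Hardy-Weinberg phred-scale p > 20 (i.e. HWE p < 0.01).
#' INDEL mode relaxes FS to > 200.0 and ReadPosRankSum to < -20.0 and drops
#' the MQ/MQRankSum/ABHet predicates. The direction of the INDEL VQSLOD
#' predicate is ambiguous in common practice and is therefore an explicit
#' choice: `"fail_negative"` (like SNVs) or `"fail_positive"`.
#'
#' @param mode `"SNV"` or `"INDEL"`.
#' @param strict_missing If `TRUE`, a missing annotation fails its
#'   predicate; by default missing annotations pass (filter on evidence
#'   present).
#' @param indel_vqslod_rule `"fail_negative"` or `"fail_positive"`.
#' @return List of class `exodel_site_filter_config`.
#' @export
site_filter_config <- function(mode = c("SNV", "INDEL"),
                               strict_missing = FALSE,
                               indel_vqslod_rule = c("fail_negative",
                                                     "fail_positive")) {
  mode <- match.arg(mode)
  indel_vqslod_rule <- match.arg(indel_vqslod_rule)
  structure(list(mode = mode, strict_missing = strict_missing,
                 indel_vqslod_rule = indel_vqslod_rule),
            class = "exodel_site_filter_config")
}

#' Apply site-level QC predicates
#'
#' @param sites Sites tibble with annotation columns (qd, fs, mq,
#'   mq_rank_sum, read_pos_rank_sum, dp_site, gq_mean, vqslod, missingness,
#'   abhet, hwe_phred).
#' @param cfg [site_filter_config()].
#' @return `sites` with `site_pass` (logical) and `fail_reasons`
#'   (list-column naming every tripped predicate).
#' @export
apply_site_filters <- function(sites, cfg = site_filter_config()) {
  n <- nrow(sites)
  miss_default <- cfg$strict_missing  # value a predicate takes on NA input
  trip <- function(col, f) {
    if (!col %in% names(sites)) return(rep(miss_default, n))
    v <- sites[[col]]
    out <- f(v)
    out[is.na(out)] <- miss_default
    out
  }
  reasons <- list(
    QD = trip("qd", function(v) v < 2.0),
    DP = trip("dp_site", function(v) v < 10.0),
    GQ_MEAN = trip("gq_mean", function(v) v < 20.0),
    missingness = trip("missingness", function(v) v > 0.05),
    HWE = trip("hwe_phred", function(v) v > 20)
  )
  if (cfg$mode == "SNV") {
    reasons$FS <- trip("fs", function(v) v > 60.0)
    reasons$MQ <- trip("mq", function(v) v < 40.0)
    reasons$MQRankSum <- trip("mq_rank_sum", function(v) v < -12.5)
    reasons$ReadPosRankSum <- trip("read_pos_rank_sum", function(v) v < -8.0)
    reasons$ABHet <- trip("abhet", function(v) v > 0.75 | v < 0.25)
    reasons$VQSLOD <- trip("vqslod", function(v) v < 0)
  } else {
    reasons$FS <- trip("fs", function(v) v > 200.0)
    reasons$ReadPosRankSum <- trip("read_pos_rank_sum", function(v) v < -20.0)
    reasons$VQSLOD <- if (cfg$indel_vqslod_rule == "fail_negative") {
      trip("vqslod", function(v) v < 0)
    } else {
      trip("vqslod", function(v) v > 0)
    }
  }
  mat <- do.call(cbind, reasons)
  sites$fail_reasons <- purrr::map(seq_len(n), function(i)
    colnames(mat)[mat[i, ]])
  sites$site_pass <- !apply(mat, 1, any)
  sites
}

#' Decompose multi-allelic records and left-normalize alleles
#'
#' Each alternate allele becomes its own biallelic record; shared trailing
#' then leading bases are trimmed, and indels are shifted left while an
#' identical representation against the reference exists. Idempotent.
#'
#' @param sites Tibble with chrom, pos (1-based), ref, alt
#'   (comma-separated for multi-allelic records).
#' @param reference Named list per chromosome: list(seq = <string>,
#'   offset = <1-based position of the first base of seq>). Must cover each
#'   variant plus its left flank.
#' @return Decomposed, normalized sites tibble (other columns duplicated
#'   per alt allele).
#' @export
decompose_and_normalize <- function(sites, reference) {
  if (nrow(sites) == 0) return(sites)
  long <- sites %>%
    mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) %>%
    tidyr::unnest("alt")
  for (i in seq_len(nrow(long))) {
    ctx <- reference[[long$chrom[i]]]
    if (is.null(ctx)) abort(sprintf("no reference context for %s", long$chrom[i]))
    norm <- normalize_allele(long$pos[i], long$ref[i], long$alt[i],
                             ctx$seq, ctx$offset)
    long$pos[i] <- norm$pos
    long$ref[i] <- norm$ref
    long$alt[i] <- norm$alt
  }
  long
}

ref_base <- function(seq, offset, pos) {
  if (pos < offset || pos > offset + nchar(seq) - 1) {
    abort("reference context does not cover the required position")
  }
  substr(seq, pos - offset + 1, pos - offset + 1)
}

# vt-style normalization of one biallelic record
normalize_allele <- function(pos, ref, alt, seq, offset) {
  ref_in_ctx <- substr(seq, pos - offset + 1, pos - offset + nchar(ref))
  if (!identical(ref_in_ctx, ref)) {
    abort(sprintf("ref allele %s at %d inconsistent with reference context (%s)",
                  ref, pos, ref_in_ctx))
  }
  repeat {
    # trim shared trailing base, extending left if an allele would empty
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      if (nchar(ref) == 1 || nchar(alt) == 1) {
        if (pos == offset) break  # cannot extend further left
        pos <- pos - 1
        b <- ref_base(seq, offset, pos)
        ref <- paste0(b, substr(ref, 1, nchar(ref) - 1))
        alt <- paste0(b, substr(alt, 1, nchar(alt) - 1))
      } else {
        ref <- substr(ref, 1, nchar(ref) - 1)
        alt <- substr(alt, 1, nchar(alt) - 1)
      }
    }
    break
  }
  # trim shared leading bases while both alleles keep >= 1 base
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Flag variants rare in every population database
#'
#' A variant is rare iff its minor allele frequency is strictly below
#' `maf_max` in every allele-frequency column (columns matching `af_`);
#' a missing database entry counts as frequency 0.
#'
#' @param sites Sites tibble.
#' @param maf_max MAF threshold (strict `<`, default 0.005).
#' @param af_cols Allele-frequency columns (default: all starting `af_`).
#' @return `sites` with a logical `rare` column.
#' @export
is_rare <- function(sites, maf_max = 0.005,
                    af_cols = grep("^af_", names(sites), value = TRUE)) {
  if (length(af_cols) == 0) {
    sites$rare <- rep(TRUE, nrow(sites))
    return(sites)
  }
  af <- as.matrix(sites[, af_cols, drop = FALSE])
  af[is.na(af)] <- 0
  maf <- pmin(af, 1 - af)
  sites$rare <- apply(maf < maf_max, 1, all)
  sites
}

#' Classifier configuration for composite deleteriousness
#'
#' @param min_predictor_hits Minimum "deleterious" calls among the missense
#'   predictor panel (default 5).
#' @param predictor_panel Panel column names (default: the nine dbNSFP-style
#'   missense predictors).
#' @param cadd_min CADD threshold (strict `>`, default 4.5).
#' @param gerp_min,phylop_min,siphy_min Conservation predicates
#'   (GERP > 3, PhyloP > 0.95, SiPhy > 10); at least `min_conservation`
#'   of the three must hold.
#' @param min_conservation Default 2.
#' @param maf_max Rarity threshold carried alongside (default 0.005).
#' @return List of class `exodel_classifier_config`.
#' @export
classifier_config <- function(min_predictor_hits = 5,
                              predictor_panel = PREDICTOR_PANEL,
                              cadd_min = 4.5, gerp_min = 3,
                              phylop_min = 0.95, siphy_min = 10,
                              min_conservation = 2, maf_max = 0.005) {
  stopifnot(min_predictor_hits <= length(predictor_panel),
            min_conservation <= 3)
  structure(list(min_predictor_hits = min_predictor_hits,
                 predictor_panel = predictor_panel, cadd_min = cadd_min,
                 gerp_min = gerp_min, phylop_min = phylop_min,
                 siphy_min = siphy_min, min_conservation = min_conservation,
                 maf_max = maf_max),
            class = "exodel_classifier_config")
}

#' Composite deleterious-variant classification
#'
#' A variant is deleterious iff any criterion fires:
#' \describe{
#'   \item{lof}{effect is splicing, stop-gain or stop-loss;}
#'   \item{indel}{effect is insertion or deletion;}
#'   \item{predicted}{effect is not synonymous AND (at least
#'     `min_predictor_hits` panel predictors call it deleterious, OR
#'     CADD > `cadd_min`, OR at least `min_conservation` of the three
#'     conservation predicates hold).}
#' }
#' Synonymous variants never qualify through the `predicted` route, no
#' matter how extreme their scores. Missing predictor calls never count
#' toward the hit quorum.
#'
#' @param sites Sites tibble with effect, predictor, cadd and conservation
#'   columns.
#' @param cfg [classifier_config()].
#' @return `sites` with `deleterious` (logical) and `criteria` (list-column
#'   of fired criterion names).
#' @export
classify_deleterious <- function(sites, cfg = classifier_config()) {
  n <- nrow(sites)
  effect <- sites$effect
  lof <- effect %in% c("splicing", "stopgain", "stoploss")
  indel <- effect %in% c("insertion", "deletion")
  panel_cols <- intersect(cfg$predictor_panel, names(sites))
  hits <- if (length(panel_cols) > 0) {
    rowSums(as.matrix(sites[, panel_cols, drop = FALSE]) == "D", na.rm = TRUE)
  } else rep(0L, n)
  cadd_hit <- !is.na(sites$cadd) & sites$cadd > cfg$cadd_min
  cons_count <- (!is.na(sites$gerp) & sites$gerp > cfg$gerp_min) +
    (!is.na(sites$phylop) & sites$phylop > cfg$phylop_min) +
    (!is.na(sites$siphy) & sites$siphy > cfg$siphy_min)
  predicted <- effect != "synonymous" &
    (hits >= cfg$min_predictor_hits | cadd_hit |
       cons_count >= cfg$min_conservation)
  sites$deleterious <- lof | indel | predicted
  sites$criteria <- purrr::pmap(list(lof, indel, predicted),
    function(l, i, p) c("lof", "indel", "predicted")[c(l, i, p)])
  sites
}
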