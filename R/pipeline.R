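# End-to-end orchestration: simulate -> coverage QC -> normalize -> call ->
# filter -> case-only -> burden, plus classify -> comphet and enrichment,
# with per-stage record counts collected into a run report.

#' Pipeline configuration
#'
#' Bundles the stage configurations. All stage seeds derive from the
#' simulation config's global seed via named child streams, so a pipeline
#' run is reproducible end to end and any stage is replayable in isolation.
#'
#' @param sim [sim_config()].
#' @param hmm [hmm_params()].
#' @param z_max,q_some_min Deletion filter thresholds.
#' @param max_case_carriers,max_ref_freq,match_overlap_fraction Case-only
#'   filter parameters.
#' @param burden [burden_config()] or `NULL` to skip the burden stage; the
#'   permutation seed is derived from the global seed when left at its
#'   default.
#' @param run_variants,run_enrichment Stage toggles.
#' @param out_dir Optional directory for stage outputs (TSV/VCF).
#' @return List of class `exodel_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), hmm = hmm_params(),
                            z_max = -3, q_some_min = 60,
                            max_case_carriers = 2, max_ref_freq = 0.01,
                            match_overlap_fraction = 0.7,
                            burden = burden_config(n_perm = 1000),
                            run_variants = TRUE, run_enrichment = TRUE,
                            out_dir = NULL) {
  if (!is.null(burden)) burden$seed <- child_seed(sim$seed, "burden")
  structure(list(sim = sim, hmm = hmm, z_max = z_max,
                 q_some_min = q_some_min,
                 max_case_carriers = max_case_carriers,
                 max_ref_freq = max_ref_freq,
                 match_overlap_fraction = match_overlap_fraction,
                 burden = burden, run_variants = run_variants,
                 run_enrichment = run_enrichment, out_dir = out_dir),
            class = "exodel_pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full deletion-discovery and interpretation pipeline
#'
#' @param config [pipeline_config()].
#' @return Object of class `exodel_report`: stage outputs (`calls`,
#'   `case_only`, `burden`, `variants`, `comphet`, `enrichment`, ...), a
#'   `counts` tibble tracking records through every stage, and the seed.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "exodel_pipeline_config"))
  counts <- list()
  note <- function(stage, n) counts[[length(counts) + 1]] <<- tibble(
    stage = stage, n = as.integer(n))

  cohort <- run_stage("simulate", simulate_depth_cohort(config$sim))
  note("samples_simulated", nrow(cohort$depth))
  note("targets_simulated", ncol(cohort$depth))
  note("truth_deletions", nrow(cohort$truth))

  qc <- run_stage("coverage_qc", sample_coverage_qc(cohort))
  note("samples_pass_qc", nrow(qc$cohort$depth))

  norm <- run_stage("normalize", pca_normalize(qc$cohort))
  calls <- run_stage("call", call_cnvs(norm, config$hmm))
  note("raw_calls", nrow(calls))

  dels <- run_stage("filter", filter_deletions(calls, config$z_max,
                                               config$q_some_min))
  note("filtered_deletions", nrow(dels))

  maps <- run_stage("reference_maps", simulate_reference_maps(config$sim))
  is_case <- dels$phenotype != "control"
  case_only <- run_stage("case_only", case_only_filter(
    dels[is_case, , drop = FALSE], dels[!is_case, , drop = FALSE], maps,
    config$max_case_carriers, config$max_ref_freq,
    config$match_overlap_fraction))
  note("case_only_deletions", nrow(case_only))

  genes <- run_stage("gene_models", simulate_gene_models(config$sim))
  case_only <- run_stage("annotate", annotate_genes(case_only, genes))
  deleted_genes <- case_only %>%
    select("sample", "genes") %>% tidyr::unnest("genes") %>%
    rename(gene = "genes") %>% distinct()
  note("deleted_genes", dplyr::n_distinct(deleted_genes$gene))

  burden <- NULL
  if (!is.null(config$burden)) {
    burden_set <- run_stage("burden_select", select_burden_set(
      dels, norm$samples, config$burden))
    note("burden_deletions", nrow(burden_set))
    burden <- if (nrow(burden_set) > 0) {
      run_stage("burden_test", permutation_pvalue(
        burden_set, norm$samples, config$burden))
    }
  }

  variants <- comphet <- NULL
  if (config$run_variants) {
    variants <- run_stage("simulate_variants",
                          simulate_variant_table(config$sim, genes))
    note("variant_sites", nrow(variants$sites))
    variants <- run_stage("genotype_qc", apply_genotype_qc(
      variants, n_samples = nrow(cohort$depth)))
    is_indel <- variants$sites$effect %in% c("insertion", "deletion")
    snv <- apply_site_filters(variants$sites[!is_indel, , drop = FALSE],
                              site_filter_config("SNV"))
    ind <- apply_site_filters(variants$sites[is_indel, , drop = FALSE],
                              site_filter_config("INDEL"))
    variants$sites <- bind_rows(snv, ind) %>% arrange(.data$variant_id)
    note("sites_pass_qc", sum(variants$sites$site_pass))
    variants$sites <- is_rare(variants$sites)
    variants$sites <- classify_deleterious(variants$sites)
    note("rare_deleterious_sites",
         sum(variants$sites$site_pass & variants$sites$rare &
               variants$sites$deleterious))

    network <- run_stage("network", simulate_network(config$sim, genes$symbol))
    brain <- run_stage("brain_network", build_brain_network(
      network, valid_symbols = genes$symbol,
      brain_genes = genes$symbol[genes$brain_expressed]))
    note("brain_network_genes", nrow(brain$nodes))
    note("brain_network_edges", nrow(brain$edges))

    carried <- variants$genotypes %>% filter(!is.na(.data$gt))
    del_vars <- variants$sites %>%
      filter(.data$site_pass, .data$rare, .data$deleterious) %>%
      select("variant_id", "gene", "chrom", "pos", "ref", "alt", "effect") %>%
      left_join(carried, by = "variant_id", relationship = "many-to-many") %>%
      filter(!is.na(.data$sample))
    comphet <- run_stage("comphet", find_comphet_hits(
      deleted_genes, del_vars, brain))
    note("comphet_hits", nrow(comphet))
  }

  enrichment <- NULL
  if (config$run_enrichment) {
    brain_universe <- genes$symbol[genes$brain_expressed]
    query <- intersect(deleted_genes$gene, brain_universe)
    sets <- run_stage("gene_sets", simulate_gene_sets(
      config$sim, brain_universe, favoured = query))
    enrichment <- run_stage("enrichment", overrep_gene_sets(
      query, sets, brain_universe))
    note("enrichment_sets", nrow(enrichment))
  }

  report <- structure(list(
    counts = bind_rows(counts),
    excluded_samples = qc$excluded,
    calls = calls, filtered = dels, case_only = case_only,
    burden = burden, variants = variants, comphet = comphet,
    enrichment = enrichment, truth = cohort$truth,
    seed = config$sim$seed
  ), class = "exodel_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_calls_tsv(calls, p("calls.tsv"))
    write_calls_tsv(case_only, p("deletions_case_only.tsv"))
    if (!is.null(burden)) readr::write_tsv(burden$result, p("burden.tsv"))
    if (!is.null(variants)) {
      write_variants_vcf(variants, p("variants.vcf"))
    }
    if (!is.null(comphet)) readr::write_tsv(comphet, p("comphet_hits.tsv"))
    if (!is.null(enrichment)) {
      readr::write_tsv(select(enrichment, -"overlap"), p("enrichment.tsv"))
    }
    readr::write_tsv(report$counts, p("stage_counts.tsv"))
  }
  report
}

#' @export
print.exodel_report <- function(x, ...) {
  cat("<exodel_report> seed", x$seed, "\n")
  print(x$counts, n = Inf)
  invisible(x)
}

#' @method glance exodel_report
#' @export
glance.exodel_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$counts, names_from = "stage", values_from = "n")
  wide$seed <- x$seed
  wide
}

#' Histogram of normalized depth z-scores
#'
#' Shows the pooled z distribution with the emission means of the three HMM
#' states; a shoulder near -3 indicates heterozygous-deletion signal.
#'
#' @param object An `exodel_norm` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot exodel_norm
#' @export
autoplot.exodel_norm <- function(object, ...) {
  df <- tibble(z = as.vector(object$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 100, fill = "grey60") +
    ggplot2::geom_vline(xintercept = c(-3, 0, 3), linetype = "dashed",
                        colour = c("firebrick", "black", "steelblue")) +
    ggplot2::labs(x = "normalized depth z", y = "targets",
                  title = "PCA-normalized read depth") +
    ggplot2::theme_minimal()
}

#' Deletion size distribution by phenotype
#'
#' @param calls Deletion calls tibble (needs length_bp and phenotype).
#' @return A ggplot.
#' @export
plot_deletion_sizes <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$length_bp,
                                      fill = .data$phenotype)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "deletion length (bp)", y = "calls",
                  title = "Filtered deletion sizes") +
    ggplot2::theme_minimal()
}
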