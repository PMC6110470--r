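# Synthetic cohort generator: depth matrices with low-rank batch structure
# and embedded heterozygous deletions, annotated variant tables, interaction
# networks, gene models/sets and reference CNV frequency maps. Every
# generator draws from a named child stream of one global seed.

#' Deletion injection specification
#'
#' One row per deletion locus. Carriers are drawn from the union of the
#' listed phenotype groups; heterozygous deletions use copy ratio 0.5.
#'
#' @param phenotypes Character vector; each element a `;`-separated list of
#'   phenotype labels eligible to carry the locus.
#' @param n_carriers Integer vector, carriers per locus.
#' @param n_targets Integer vector, consecutive exome targets spanned.
#' @param copy_ratio Numeric in (0, 1]; 0.5 for a heterozygous deletion.
#' @param common_in_reference Logical; if `TRUE` the locus is planted in the
#'   simulated reference CNV maps at >1% frequency (so that case-only
#'   filtering removes it).
#' @return A tibble with one row per locus.
#' @export
deletion_spec <- function(phenotypes = character(),
                          n_carriers = integer(),
                          n_targets = integer(),
                          copy_ratio = 0.5,
                          common_in_reference = FALSE) {
  tibble(
    phenotypes = as.character(phenotypes),
    n_carriers = as.integer(n_carriers),
    n_targets = as.integer(n_targets),
    copy_ratio = as.numeric(copy_ratio),
    common_in_reference = as.logical(common_in_reference)
  )
}

default_deletion_spec <- function() {
  deletion_spec(
    phenotypes = c(rep("GGE", 4), rep("RE", 4), "GGE;RE",
                   "GGE;RE;control", "control", "GGE;RE;control",
                   "GGE;RE", "control"),
    n_carriers = c(1L, 1L, 2L, 1L, 1L, 1L, 2L, 1L, 2L, 30L, 1L, 25L, 3L, 1L),
    n_targets = c(10L, 12L, 15L, 20L, 10L, 12L, 15L, 20L, 12L, 10L, 15L, 12L,
                  45L, 50L),
    copy_ratio = 0.5,
    common_in_reference = c(rep(FALSE, 9), TRUE, FALSE, TRUE, FALSE, FALSE)
  )
}

#' Variant generation specification
#'
#' @param per_gene_rate Mean number of variant sites per gene (Poisson).
#' @param effect_probs Named probabilities over functional effect classes.
#' @param missense_deleterious_frac Fraction of missense sites generated as
#'   deleterious (predictor consensus, high CADD, high conservation).
#' @param predictor_missing_prob Probability an individual predictor call is
#'   missing.
#' @param rare_fraction Fraction of sites drawn from the rare part of the
#'   allele-frequency mixture (all database AFs < 0.005).
#' @param mean_carriers Mean number of heterozygous carriers per site.
#' @param low_quality_site_frac Fraction of sites that trip one random site
#'   QC predicate.
#' @param low_quality_gt_frac Fraction of genotypes with DP or GQ below the
#'   genotype-QC thresholds.
#' @return A list of class `exodel_variant_spec`.
#' @export
variant_spec <- function(per_gene_rate = 2,
                         effect_probs = c(synonymous = 0.30, missense = 0.40,
                                          splicing = 0.05, stopgain = 0.05,
                                          stoploss = 0.02, insertion = 0.09,
                                          deletion = 0.09),
                         missense_deleterious_frac = 0.35,
                         predictor_missing_prob = 0.05,
                         rare_fraction = 0.8,
                         mean_carriers = 1.5,
                         low_quality_site_frac = 0.05,
                         low_quality_gt_frac = 0.03) {
  stopifnot(abs(sum(effect_probs) - 1) < 1e-8, per_gene_rate >= 0)
  structure(list(per_gene_rate = per_gene_rate, effect_probs = effect_probs,
                 missense_deleterious_frac = missense_deleterious_frac,
                 predictor_missing_prob = predictor_missing_prob,
                 rare_fraction = rare_fraction, mean_carriers = mean_carriers,
                 low_quality_site_frac = low_quality_site_frac,
                 low_quality_gt_frac = low_quality_gt_frac),
            class = "exodel_variant_spec")
}

#' Interaction-network generation specification
#'
#' Defaults emulate a curated protein-interaction network restricted to
#' nomenclature-valid symbols (mean degree ~21 at full scale is typical of
#' such networks; scaled-down simulations use the configured value).
#'
#' @param mean_degree Target mean degree of the random graph.
#' @param brain_expressed_fraction Fraction of nodes flagged brain-expressed.
#' @export
network_spec <- function(mean_degree = 8, brain_expressed_fraction = 0.78) {
  stopifnot(mean_degree > 0, brain_expressed_fraction >= 0,
            brain_expressed_fraction <= 1)
  list(mean_degree = mean_degree,
       brain_expressed_fraction = brain_expressed_fraction)
}

#' Gene-set generation specification
#'
#' @param n_sets Number of background gene sets.
#' @param set_size Symbols per set.
#' @param enriched_fraction Fraction of the first ("disease") set drawn from
#'   a favoured gene list when one is supplied, creating true enrichment.
#' @export
geneset_spec <- function(n_sets = 3, set_size = 50, enriched_fraction = 0.3) {
  list(n_sets = n_sets, set_size = set_size,
       enriched_fraction = enriched_fraction)
}

#' Simulation configuration for a two-phenotype case cohort plus controls
#'
#' Defaults mirror a post-QC exome cohort of 196 GGE-like and 194 RE-like
#' cases with 572 population controls, sequenced to ~100x mean target depth.
#' Depth is negative-binomial with log-normal per-sample size factors and
#' multiplicative low-rank batch structure, so PCA normalization has a true
#' signal to remove.
#'
#' @param n_cases_a,n_cases_b,n_controls Group sizes (GGE-like, RE-like,
#'   controls).
#' @param n_targets Number of exome targets across all synthetic chromosomes.
#' @param n_chrom Number of synthetic chromosomes the targets tile.
#' @param target_length_mean,target_length_sd Target length distribution (bp).
#' @param target_gap_mean Mean inter-target gap (bp, exponential).
#' @param depth_mean Expected mean read depth per diploid target.
#' @param depth_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi mu^2).
#' @param sample_sd Log-scale sd of per-sample size factors.
#' @param batch_rank Number of latent low-rank batch components.
#' @param batch_sd Per-component log-scale batch amplitude.
#' @param deletion_spec Tibble from [deletion_spec()].
#' @param variant_spec List from [variant_spec()].
#' @param network_spec List from [network_spec()].
#' @param geneset_spec List from [geneset_spec()].
#' @param n_genes Number of synthetic gene models.
#' @param brain_expressed_fraction Fraction of gene models flagged
#'   brain-expressed.
#' @param seed Global integer seed; all generators derive named child seeds
#'   from it.
#' @return A validated list of class `exodel_sim_config`.
#' @export
sim_config <- function(n_cases_a = 196, n_cases_b = 194, n_controls = 572,
                       n_targets = 2000, n_chrom = 4,
                       target_length_mean = 150, target_length_sd = 30,
                       target_gap_mean = 12000,
                       depth_mean = 100, depth_dispersion = 0.005,
                       sample_sd = 0.1, batch_rank = 3, batch_sd = 0.15,
                       deletion_spec = default_deletion_spec(),
                       variant_spec = exodel::variant_spec(),
                       network_spec = exodel::network_spec(),
                       geneset_spec = exodel::geneset_spec(),
                       n_genes = 400, brain_expressed_fraction = 0.7,
                       seed = 1L) {
  assert_count(n_cases_a, "n_cases_a")
  assert_count(n_cases_b, "n_cases_b")
  assert_count(n_controls, "n_controls")
  assert_count(n_targets, "n_targets")
  assert_count(n_chrom, "n_chrom")
  stopifnot(depth_mean > 0, depth_dispersion >= 0, batch_rank >= 0,
            batch_sd >= 0, sample_sd >= 0, n_genes >= 1)
  assert_fraction(brain_expressed_fraction, "brain_expressed_fraction")
  if (nrow(deletion_spec) > 0) {
    if (any(deletion_spec$copy_ratio <= 0 | deletion_spec$copy_ratio > 1)) {
      abort("deletion copy_ratio must lie in (0, 1]")
    }
    if (any(deletion_spec$n_carriers < 0) || any(deletion_spec$n_targets < 1)) {
      abort("deletion_spec n_carriers must be >= 0 and n_targets >= 1")
    }
  }
  structure(list(
    n_cases_a = as.integer(n_cases_a), n_cases_b = as.integer(n_cases_b),
    n_controls = as.integer(n_controls), n_targets = as.integer(n_targets),
    n_chrom = as.integer(n_chrom), target_length_mean = target_length_mean,
    target_length_sd = target_length_sd, target_gap_mean = target_gap_mean,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    sample_sd = sample_sd, batch_rank = as.integer(batch_rank),
    batch_sd = batch_sd, deletion_spec = deletion_spec,
    variant_spec = variant_spec, network_spec = network_spec,
    geneset_spec = geneset_spec, n_genes = as.integer(n_genes),
    brain_expressed_fraction = brain_expressed_fraction,
    seed = as.integer(seed)
  ), class = "exodel_sim_config")
}

sim_samples <- function(config) {
  tibble(
    sample = c(sprintf("GGE_%04d", seq_len(config$n_cases_a)),
               sprintf("RE_%04d", seq_len(config$n_cases_b)),
               sprintf("CTRL_%04d", seq_len(config$n_controls))),
    phenotype = c(rep("GGE", config$n_cases_a), rep("RE", config$n_cases_b),
                  rep("control", config$n_controls))
  )
}

# Deterministic layout shared by the depth, reference-map and gene-model
# generators: target coordinates, deletion locus placement and carrier
# assignment, all under the "layout" child stream.
cohort_layout <- function(config) {
  set.seed(child_seed(config$seed, "layout"))
  m <- config$n_targets
  per_chrom <- diff(round(seq(0, m, length.out = config$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per_chrom)
  len <- pmax(50, round(rnorm(m, config$target_length_mean,
                              config$target_length_sd)))
  gap <- pmax(100, round(-config$target_gap_mean * log(runif(m))))
  start <- numeric(m)
  end <- numeric(m)
  pos <- 10001
  for (i in seq_len(m)) {
    if (i > 1 && chrom[i] != chrom[i - 1]) pos <- 10001
    start[i] <- pos
    end[i] <- pos + len[i]
    pos <- end[i] + gap[i]
  }
  targets <- tibble(chrom = chrom, start = start, end = end)
  targets$target <- format_target_ids(targets)
  targets <- targets[, c("target", "chrom", "start", "end")]

  samples <- sim_samples(config)
  spec <- config$deletion_spec
  loci <- tibble(locus_id = character(), chrom = character(),
                 start = numeric(), end = numeric(),
                 t_first = integer(), t_last = integer(),
                 copy_ratio = numeric(), common_in_reference = logical())
  carriers <- tibble(locus_id = character(), sample = character())
  if (nrow(spec) > 0) {
    chrom_rle <- rle(chrom)
    chrom_first <- cumsum(c(1L, head(chrom_rle$lengths, -1)))
    taken <- rep(FALSE, m)
    for (k in order(spec$n_targets, decreasing = TRUE)) {  # big loci first
      span <- spec$n_targets[k]
      if (span > max(chrom_rle$lengths)) {
        abort(sprintf(
          "deletion locus %d spans %d targets but the largest chromosome has only %d",
          k, span, max(chrom_rle$lengths)))
      }
      # enumerate every feasible non-overlapping start, then sample one
      feasible <- integer(0)
      for (ci in which(chrom_rle$lengths >= span)) {
        lo <- chrom_first[ci]
        hi <- lo + chrom_rle$lengths[ci] - span
        cand <- lo:hi
        ok <- vapply(cand, function(i) !any(taken[i:(i + span - 1L)]),
                     logical(1))
        feasible <- c(feasible, cand[ok])
      }
      if (length(feasible) == 0) {
        abort("could not place deletion loci without overlap; reduce spec")
      }
      first <- feasible[sample.int(length(feasible), 1L)]
      taken[first:(first + span - 1L)] <- TRUE
      loci <- bind_rows(loci, tibble(
        locus_id = sprintf("locus_%02d", k), chrom = chrom[first],
        start = start[first], end = end[first + span - 1L],
        t_first = as.integer(first), t_last = as.integer(first + span - 1L),
        copy_ratio = spec$copy_ratio[k],
        common_in_reference = spec$common_in_reference[k]))
      pheno <- strsplit(spec$phenotypes[k], ";")[[1]]
      pool <- samples$sample[samples$phenotype %in% pheno]
      if (spec$n_carriers[k] > length(pool)) {
        abort(sprintf("locus %d requests %d carriers but only %d samples match '%s'",
                      k, spec$n_carriers[k], length(pool), spec$phenotypes[k]))
      }
      who <- sample(pool, spec$n_carriers[k])
      if (length(who) > 0) {
        carriers <- bind_rows(carriers, tibble(
          locus_id = sprintf("locus_%02d", k), sample = who))
      }
    }
  }
  list(targets = targets, samples = samples, loci = loci, carriers = carriers)
}

#' Simulate a sample-by-target exome read-depth cohort
#'
#' Depth is drawn per cell from a negative binomial with mean
#' `depth_mean * s_i * t_j * b_ij` (sample size factor, target effect,
#' low-rank batch factor) and dispersion `depth_dispersion`; targets spanned
#' by an injected deletion have their expected depth multiplied by the locus
#' copy ratio in carrier samples.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `exodel_cohort`: list with `depth` (numeric
#'   matrix, samples x targets), `samples`, `targets`, and `truth` (injected
#'   deletions: sample, chrom, start, end, copy_ratio, locus_id).
#' @export
simulate_depth_cohort <- function(config) {
  stopifnot(inherits(config, "exodel_sim_config"))
  layout <- cohort_layout(config)
  set.seed(child_seed(config$seed, "depth"))
  n <- nrow(layout$samples)
  m <- nrow(layout$targets)
  target_effect <- rlnorm(m, 0, 0.3)
  sample_factor <- rlnorm(n, 0, config$sample_sd)
  log_mu <- log(config$depth_mean) + outer(log(sample_factor),
                                           log(target_effect), `+`)
  if (config$batch_rank > 0) {
    A <- matrix(rnorm(n * config$batch_rank), n, config$batch_rank)
    B <- matrix(rnorm(m * config$batch_rank), m, config$batch_rank)
    log_mu <- log_mu + config$batch_sd * tcrossprod(A, B)
  }
  mu <- exp(log_mu)
  truth <- tibble(sample = character(), chrom = character(),
                  start = numeric(), end = numeric(), copy_ratio = numeric(),
                  locus_id = character())
  if (nrow(layout$carriers) > 0) {
    joined <- left_join(layout$carriers, layout$loci, by = "locus_id")
    for (i in seq_len(nrow(joined))) {
      r <- match(joined$sample[i], layout$samples$sample)
      idx <- joined$t_first[i]:joined$t_last[i]
      mu[r, idx] <- mu[r, idx] * joined$copy_ratio[i]
    }
    truth <- joined %>%
      select("sample", "chrom", "start", "end", "copy_ratio", "locus_id") %>%
      arrange(.data$sample, .data$chrom, .data$start)
  }
  size <- if (config$depth_dispersion > 0) 1 / config$depth_dispersion else Inf
  depth <- if (is.finite(size)) {
    matrix(rnbinom(n * m, mu = mu, size = size), n, m)
  } else {
    matrix(rpois(n * m, mu), n, m)
  }
  dimnames(depth) <- list(layout$samples$sample, layout$targets$target)
  structure(list(depth = depth, samples = layout$samples,
                 targets = layout$targets, truth = truth, config = config),
            class = "exodel_cohort")
}

#' @export
print.exodel_cohort <- function(x, ...) {
  cat(sprintf("<exodel_cohort> %d samples x %d targets, %d injected deletion records\n",
              nrow(x$depth), ncol(x$depth), nrow(x$truth)))
  invisible(x)
}

#' Simulate gene models over the synthetic target space
#'
#' Genes are non-overlapping runs of consecutive targets (their "exons"),
#' so deletions spanning targets also span genes.
#'
#' @param config An [sim_config()] object.
#' @return Tibble: symbol, chrom, start, end, brain_expressed, exons
#'   (list-column of exon interval tibbles).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "exodel_sim_config"))
  layout <- cohort_layout(config)
  set.seed(child_seed(config$seed, "genes"))
  targets <- layout$targets
  m <- nrow(targets)
  sizes <- pmin(8L, 1L + rpois(config$n_genes, 2))
  genes <- vector("list", config$n_genes)
  i <- 1L
  g <- 0L
  while (g < config$n_genes && i <= m) {
    g <- g + 1L
    last <- min(m, i + sizes[g] - 1L)
    block <- targets[i:last, ]
    if (length(unique(block$chrom)) > 1L) {  # genes never straddle chromosomes
      block <- block[block$chrom == block$chrom[1], ]
      last <- i + nrow(block) - 1L
    }
    genes[[g]] <- tibble(
      symbol = sprintf("GENE%04d", g), chrom = block$chrom[1],
      start = min(block$start), end = max(block$end),
      exons = list(block[, c("chrom", "start", "end")])
    )
    i <- last + 1L + rpois(1, 1)
  }
  out <- bind_rows(genes[seq_len(g)])
  out$brain_expressed <- runif(nrow(out)) < config$brain_expressed_fraction
  out[, c("symbol", "chrom", "start", "end", "brain_expressed", "exons")]
}

#' Simulate an annotated variant table
#'
#' Emulates a jointly genotyped, annotated exome call set: per-site
#' functional class, nine missense predictor calls, CADD, three conservation
#' scores, four database allele frequencies, GATK-style site annotations,
#' and per-sample heterozygous genotypes with DP/GQ.
#'
#' @param config An [sim_config()] object.
#' @param genes Gene models from [simulate_gene_models()] (or any tibble
#'   with symbol/chrom/start/end).
#' @return Object of class `exodel_variants`: list with `sites` and
#'   `genotypes` tibbles and a `truth` tibble of sites generated deleterious
#'   (sample-free; join on variant_id).
#' @export
simulate_variant_table <- function(config, genes) {
  stopifnot(inherits(config, "exodel_sim_config"), nrow(genes) > 0)
  vs <- config$variant_spec
  samples <- sim_samples(config)
  set.seed(child_seed(config$seed, "variants"))
  n_var_gene <- rpois(nrow(genes), vs$per_gene_rate)
  total <- sum(n_var_gene)
  if (total == 0) {
    return(structure(list(
      sites = empty_sites_tbl(), genotypes = tibble(
        variant_id = character(), sample = character(), gt = character(),
        dp = integer(), gq = integer()),
      truth = tibble(variant_id = character(), gene = character(),
                     criterion = character())),
      class = "exodel_variants"))
  }
  gi <- rep(seq_len(nrow(genes)), n_var_gene)
  bases <- c("A", "C", "G", "T")
  effect <- sample(names(vs$effect_probs), total, replace = TRUE,
                   prob = vs$effect_probs)
  pos <- floor(runif(total, genes$start[gi], genes$end[gi] - 1))
  ref <- sample(bases, total, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  ins <- effect == "insertion"
  del <- effect == "deletion"
  alt[ins] <- paste0(ref[ins], replicate(sum(ins),
    paste(sample(bases, 1 + rpois(1, 1), replace = TRUE), collapse = "")))
  ref[del] <- vapply(ref[del], function(b) paste0(
    b, paste(sample(bases, 1 + rpois(1, 1), replace = TRUE), collapse = "")),
    character(1))
  alt[del] <- substr(ref[del], 1, 1)

  predictors <- c("sift", "pp2_hdiv", "pp2_hvar", "lrt", "mutation_taster",
                  "mutation_assessor", "fathmm", "metasvm", "metalr")
  is_missense <- effect == "missense"
  latent_del <- is_missense & runif(total) < vs$missense_deleterious_frac
  pred_mat <- matrix(NA_character_, total, length(predictors),
                     dimnames = list(NULL, predictors))
  p_del <- ifelse(latent_del, 0.85, 0.08)
  for (j in seq_along(predictors)) {
    call <- ifelse(runif(total) < p_del, "D", "T")
    call[runif(total) < vs$predictor_missing_prob] <- NA_character_
    call[!is_missense] <- NA_character_
    pred_mat[, j] <- call
  }
  cadd <- ifelse(latent_del, rlnorm(total, log(20), 0.4),
                 rlnorm(total, log(2), 0.6))
  gerp <- ifelse(latent_del, runif(total, 3.5, 6), runif(total, -2, 2.5))
  phylop <- ifelse(latent_del, runif(total, 0.96, 1), runif(total, 0, 0.9))
  siphy <- ifelse(latent_del, runif(total, 11, 20), runif(total, 0, 9))

  rare <- runif(total) < vs$rare_fraction
  draw_af <- function() ifelse(rare, runif(total, 0, 0.004),
                               runif(total, 0.01, 0.4))
  sites <- tibble(
    variant_id = sprintf("var_%05d", seq_len(total)),
    chrom = genes$chrom[gi], pos = pos, ref = ref, alt = alt,
    gene = genes$symbol[gi], effect = effect
  )
  sites <- bind_cols(sites, as_tibble(pred_mat))
  sites$cadd <- cadd
  sites$gerp <- gerp
  sites$phylop <- phylop
  sites$siphy <- siphy
  sites$af_kg <- draw_af()
  sites$af_exac <- draw_af()
  sites$af_evs <- draw_af()
  sites$af_dbsnp <- draw_af()
  # site-level QC annotations; a configured fraction trips one predicate
  sites$qd <- runif(total, 5, 30)
  sites$fs <- runif(total, 0, 30)
  sites$mq <- runif(total, 50, 60)
  sites$mq_rank_sum <- rnorm(total, 0, 2)
  sites$read_pos_rank_sum <- rnorm(total, 0, 2)
  sites$dp_site <- runif(total, 20, 200)
  sites$gq_mean <- runif(total, 40, 90)
  sites$vqslod <- runif(total, 1, 15)
  sites$abhet <- runif(total, 0.35, 0.65)
  sites$hwe_phred <- runif(total, 0, 10)
  bad <- which(runif(total) < vs$low_quality_site_frac)
  if (length(bad) > 0) {
    which_pred <- sample(c("qd", "fs", "vqslod", "abhet"), length(bad),
                         replace = TRUE)
    sites$qd[bad[which_pred == "qd"]] <- runif(sum(which_pred == "qd"), 0, 1.9)
    sites$fs[bad[which_pred == "fs"]] <- runif(sum(which_pred == "fs"), 61, 300)
    sites$vqslod[bad[which_pred == "vqslod"]] <-
      runif(sum(which_pred == "vqslod"), -10, -0.1)
    sites$abhet[bad[which_pred == "abhet"]] <-
      sample(c(runif(sum(which_pred == "abhet"), 0, 0.2),
               runif(sum(which_pred == "abhet"), 0.8, 1)),
             sum(which_pred == "abhet"))
  }

  n_carr <- pmin(nrow(samples), 1L + rpois(total, vs$mean_carriers - 1))
  geno <- purrr::map2(sites$variant_id, n_carr, function(id, k) {
    tibble(variant_id = id, sample = sample(samples$sample, k))
  }) %>% bind_rows()
  ng <- nrow(geno)
  geno$gt <- "0/1"
  geno$dp <- 1L + rnbinom(ng, mu = 60, size = 10)
  geno$gq <- sample(30:99, ng, replace = TRUE)
  lowq <- runif(ng) < vs$low_quality_gt_frac
  geno$dp[lowq] <- sample(0:9, sum(lowq), replace = TRUE)
  sites$missingness <- 0

  crit <- dplyr::case_when(
    effect %in% c("splicing", "stopgain", "stoploss") ~ "lof",
    effect %in% c("insertion", "deletion") ~ "indel",
    latent_del ~ "missense_consensus",
    TRUE ~ NA_character_
  )
  truth <- tibble(variant_id = sites$variant_id, gene = sites$gene,
                  criterion = crit) %>% filter(!is.na(.data$criterion))
  structure(list(sites = sites, genotypes = geno, truth = truth),
            class = "exodel_variants")
}

empty_sites_tbl <- function() {
  tibble(variant_id = character(), chrom = character(), pos = numeric(),
         ref = character(), alt = character(), gene = character(),
         effect = character())
}

#' @export
print.exodel_variants <- function(x, ...) {
  cat(sprintf("<exodel_variants> %d sites, %d genotype records\n",
              nrow(x$sites), nrow(x$genotypes)))
  invisible(x)
}

#' Simulate an undirected gene-interaction network
#'
#' Erdos-Renyi G(n, m) with m = round(n * mean_degree / 2) edges: a simple
#' graph without self-loops, each node carrying a brain-expression flag.
#'
#' @param config An [sim_config()] object (uses `network_spec` and the seed).
#' @param genes Character vector of gene symbols (>= 2).
#' @return Object of class `exodel_network`: list with `nodes`
#'   (gene, brain_expressed) and `edges` (from, to) tibbles.
#' @export
simulate_network <- function(config, genes) {
  stopifnot(inherits(config, "exodel_sim_config"))
  genes <- unique(as.character(genes))
  if (length(genes) < 2) abort("need at least 2 gene symbols")
  ns <- config$network_spec
  if (ns$mean_degree >= length(genes)) {
    abort("mean degree must be smaller than the number of genes")
  }
  set.seed(child_seed(config$seed, "network"))
  n <- length(genes)
  n_edges <- min(round(n * ns$mean_degree / 2), choose(n, 2))
  g <- igraph::sample_gnm(n, n_edges, directed = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- tibble(from = genes[el[, 1]], to = genes[el[, 2]])
  nodes <- tibble(gene = genes,
                  brain_expressed = runif(n) < ns$brain_expressed_fraction)
  new_network(nodes, edges)
}

new_network <- function(nodes, edges) {
  # canonicalize: undirected simple graph, lexicographic edge endpoints
  if (nrow(edges) > 0) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges %>% filter(.data$from != .data$to) %>%
      distinct() %>% arrange(.data$from, .data$to)
  }
  structure(list(nodes = arrange(nodes, .data$gene), edges = edges),
            class = "exodel_network")
}

#' @export
print.exodel_network <- function(x, ...) {
  cat(sprintf("<exodel_network> %d genes, %d interactions (%d brain-expressed genes)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$brain_expressed)))
  invisible(x)
}

#' Simulate reference CNV frequency maps
#'
#' Emulates population structural-variant frequency resources: BED-like
#' interval sets with a frequency column. Deletion loci flagged
#' `common_in_reference` in the config are planted at >1% frequency with at
#' least 70% reciprocal overlap, so case-only filtering removes them;
#' background intervals overlapping other truth loci are kept rare.
#'
#' @param config An [sim_config()] object.
#' @param map_names Names of the maps to generate.
#' @param n_background Random background intervals per map.
#' @return Named list of tibbles (chrom, start, end, frequency).
#' @export
simulate_reference_maps <- function(config,
                                    map_names = c("cnvmap_synthetic",
                                                  "sv_background_synthetic"),
                                    n_background = 100) {
  stopifnot(inherits(config, "exodel_sim_config"))
  layout <- cohort_layout(config)
  set.seed(child_seed(config$seed, "maps"))
  targets <- layout$targets
  loci <- layout$loci
  span_by_chrom <- targets %>% group_by(.data$chrom) %>%
    summarise(lo = min(.data$start), hi = max(.data$end), .groups = "drop")
  out <- purrr::map(map_names, function(nm) {
    ci <- sample.int(nrow(span_by_chrom), n_background, replace = TRUE)
    len <- pmax(500, round(rlnorm(n_background, log(20000), 1)))
    lo <- span_by_chrom$lo[ci]
    hi <- pmax(lo + 1, span_by_chrom$hi[ci] - len)
    start <- floor(runif(n_background, lo, hi))
    m <- tibble(chrom = span_by_chrom$chrom[ci], start = start,
                end = start + len,
                frequency = stats::rbeta(n_background, 0.3, 8))
    # never let a random common interval shadow a truth locus meant to
    # survive case-only filtering
    if (nrow(loci) > 0) {
      protect <- loci %>% filter(!.data$common_in_reference)
      if (nrow(protect) > 0) {
        ro <- purrr::pmap_dbl(m[, c("chrom", "start", "end")], function(chrom, start, end) {
          same <- protect[protect$chrom == chrom, ]
          if (nrow(same) == 0) return(0)
          max(reciprocal_overlap(chrom, start, end, same$chrom, same$start, same$end))
        })
        m$frequency[ro >= 0.5 & m$frequency > 0.01] <- 0.001
      }
      common <- loci %>% filter(.data$common_in_reference)
      if (nrow(common) > 0) {
        m <- bind_rows(m, tibble(
          chrom = common$chrom, start = common$start, end = common$end,
          frequency = runif(nrow(common), 0.02, 0.2)))
      }
    }
    arrange(m, .data$chrom, .data$start)
  })
  setNames(out, map_names)
}

#' Simulate named gene sets
#'
#' The first set ("DISEASE_PANEL") is enriched for symbols from `favoured`
#' (when supplied) at the configured fraction; remaining sets are uniform
#' draws from the universe.
#'
#' @param config An [sim_config()] object.
#' @param universe Character vector of all gene symbols.
#' @param favoured Optional character vector of symbols to enrich for.
#' @return Named list of character vectors (GMT-ready).
#' @export
simulate_gene_sets <- function(config, universe, favoured = NULL) {
  stopifnot(inherits(config, "exodel_sim_config"), length(universe) >= 2)
  gs <- config$geneset_spec
  set.seed(child_seed(config$seed, "genesets"))
  size <- min(gs$set_size, length(universe))
  sets <- purrr::map(seq_len(gs$n_sets), function(i) {
    if (i == 1 && length(favoured) > 0) {
      k <- min(length(favoured), round(gs$enriched_fraction * size))
      picked <- sample(favoured, k)
      rest <- sample(setdiff(universe, picked), size - k)
      sort(c(picked, rest))
    } else {
      sort(sample(universe, size))
    }
  })
  setNames(sets, c("DISEASE_PANEL",
                   sprintf("RANDOM_SET_%02d", seq_len(gs$n_sets))[-1]))
}
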