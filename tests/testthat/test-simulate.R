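# Synthetic cohort generator: determinism, injection calibration, and the
# statistical contracts downstream stages rely on.

small_cfg <- function(seed = 1, n_targets = 600, n_genes = 60, ...) {
  sim_config(n_cases_a = 10, n_cases_b = 10, n_controls = 20,
             n_targets = n_targets, n_genes = n_genes, seed = seed, ...)
}

test_that("identical seeds reproduce identical cohorts, different seeds differ", {
  cfg <- small_cfg(seed = 42)
  a <- simulate_depth_cohort(cfg)
  b <- simulate_depth_cohort(cfg)
  expect_identical(a$depth, b$depth)
  expect_identical(a$truth, b$truth)
  c <- simulate_depth_cohort(small_cfg(seed = 43))
  expect_false(identical(a$depth, c$depth))
})

test_that("empty deletion spec injects nothing", {
  cfg <- small_cfg(deletion_spec = deletion_spec())
  co <- simulate_depth_cohort(cfg)
  expect_equal(nrow(co$truth), 0)
})

test_that("truth intervals lie within the simulated target space", {
  co <- simulate_depth_cohort(small_cfg(seed = 7))
  for (i in seq_len(nrow(co$truth))) {
    tg <- co$targets[co$targets$chrom == co$truth$chrom[i], ]
    expect_gte(co$truth$start[i], min(tg$start))
    expect_lte(co$truth$end[i], max(tg$end))
  }
})

test_that("deletion spec exceeding the target space is rejected", {
  cfg <- small_cfg(deletion_spec = deletion_spec(
    phenotypes = "GGE", n_carriers = 1, n_targets = 500, copy_ratio = 0.5))
  expect_error(simulate_depth_cohort(cfg), "targets")
})

test_that("injected deletions halve expected depth (copy ratio 0.5)", {
  cfg <- sim_config(n_cases_a = 60, n_cases_b = 10, n_controls = 50,
                    n_targets = 600, seed = 3,
                    deletion_spec = deletion_spec(
                      phenotypes = "GGE", n_carriers = 50, n_targets = 20,
                      copy_ratio = 0.5))
  expect_error(sim_config(n_cases_a = 0), "n_cases_a")
  co <- simulate_depth_cohort(cfg)
  tr <- co$truth
  jj <- which(co$targets$chrom == tr$chrom[1] &
                co$targets$start >= min(tr$start) &
                co$targets$end <= max(tr$end))
  carriers <- match(unique(tr$sample), rownames(co$depth))
  ratio <- mean(co$depth[carriers, jj]) / mean(co$depth[-carriers, jj])
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.55)
})

test_that("depth follows the configured negative-binomial model", {
  cfg <- sim_config(n_cases_a = 250, n_cases_b = 250, n_controls = 100,
                    n_targets = 150, seed = 9, batch_rank = 0, sample_sd = 0,
                    depth_mean = 100, depth_dispersion = 0.005,
                    deletion_spec = deletion_spec())
  co <- simulate_depth_cohort(cfg)
  mu_hat <- colMeans(co$depth)
  var_hat <- apply(co$depth, 2, var)
  var_expected <- mu_hat + 0.005 * mu_hat^2
  # per-target variance matches mu + phi*mu^2 within Monte-Carlo tolerance
  expect_lt(abs(median(var_hat / var_expected) - 1), 0.15)
  expect_gt(cor(mu_hat, var_hat), 0.5)
})

test_that("variant generator respects effect-class fractions and determinism", {
  cfg <- small_cfg(seed = 5, n_targets = 2500, n_genes = 400,
                   variant_spec = variant_spec(
    per_gene_rate = 2.5,
    effect_probs = c(synonymous = 0.2, missense = 0.3, splicing = 0.05,
                     stopgain = 0.3, stoploss = 0.05, insertion = 0.05,
                     deletion = 0.05)))
  genes <- simulate_gene_models(cfg)
  v1 <- simulate_variant_table(cfg, genes)
  v2 <- simulate_variant_table(cfg, genes)
  expect_identical(v1$sites, v2$sites)
  expect_gt(nrow(v1$sites), 500)
  frac_stop <- mean(v1$sites$effect == "stopgain")
  expect_gt(frac_stop, 0.27)  # binomial interval around the configured 0.30
  expect_lt(frac_stop, 0.33)
  # zero rate gives an empty table
  v0 <- simulate_variant_table(
    small_cfg(variant_spec = variant_spec(per_gene_rate = 0)), genes)
  expect_equal(nrow(v0$sites), 0)
})

test_that("network generator hits configured size, degree and flags", {
  genes <- sprintf("G%04d", 1:2000)
  cfg <- small_cfg(network_spec = network_spec(mean_degree = 10))
  net <- simulate_network(cfg, genes)
  expect_equal(nrow(net$nodes), 2000)
  expect_gte(nrow(net$edges), 9000)
  expect_lte(nrow(net$edges), 11000)
  expect_false(any(net$edges$from == net$edges$to))
  expect_equal(anyDuplicated(net$edges), 0)

  two <- simulate_network(small_cfg(network_spec = network_spec(mean_degree = 1)),
                          c("A", "B"))
  expect_equal(nrow(two$edges), 1)
  all_brain <- simulate_network(
    small_cfg(network_spec = network_spec(mean_degree = 2,
                                          brain_expressed_fraction = 1)),
    sprintf("G%02d", 1:50))
  expect_true(all(all_brain$nodes$brain_expressed))
  expect_error(simulate_network(
    small_cfg(network_spec = network_spec(mean_degree = 5)), c("A", "B")),
    "mean degree")
})

test_that("reference maps plant exactly the configured common loci", {
  spec <- deletion_spec(
    phenotypes = rep("GGE", 8), n_carriers = 1,
    n_targets = rep(10, 8), copy_ratio = 0.5,
    common_in_reference = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  cfg <- small_cfg(seed = 21, n_targets = 800, deletion_spec = spec)
  maps <- simulate_reference_maps(cfg)
  expect_identical(maps, simulate_reference_maps(cfg))
  co <- simulate_depth_cohort(cfg)
  loci <- unique(co$truth[, c("chrom", "start", "end", "locus_id")])
  common_hit <- vapply(seq_len(nrow(loci)), function(i) {
    any(vapply(maps, function(m) {
      cand <- m[m$frequency > 0.01 & m$chrom == loci$chrom[i], , drop = FALSE]
      nrow(cand) > 0 &&
        any(reciprocal_overlap(loci$chrom[i], loci$start[i], loci$end[i],
                               cand$chrom, cand$start, cand$end) >= 0.7)
    }, logical(1)))
  }, logical(1))
  expect_equal(sum(common_hit), 5)
})
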