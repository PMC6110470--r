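# Genotype/site QC, decomposition + left-normalization, rarity, and the
# composite deleteriousness classifier.

base_site <- function(...) {
  defaults <- list(variant_id = "v1", chrom = "chr1", pos = 100, ref = "A",
                   alt = "G", gene = "GENE1", effect = "missense",
                   sift = "T", pp2_hdiv = "T", pp2_hvar = "T", lrt = "T",
                   mutation_taster = "T", mutation_assessor = "T",
                   fathmm = "T", metasvm = "T", metalr = "T",
                   cadd = 1, gerp = 0, phylop = 0.1, siphy = 1,
                   af_kg = 0.001, af_exac = 0.001, af_evs = 0.001,
                   af_dbsnp = 0.001,
                   qd = 20, fs = 5, mq = 55, mq_rank_sum = 0,
                   read_pos_rank_sum = 0, dp_site = 50, gq_mean = 60,
                   vqslod = 5, abhet = 0.5, hwe_phred = 2, missingness = 0)
  mods <- list(...)
  defaults[names(mods)] <- mods
  tibble::as_tibble(defaults)
}

test_that("genotype QC masks DP<10 or GQ<20 and recomputes missingness", {
  v <- list(
    sites = base_site(),
    genotypes = tibble::tibble(
      variant_id = "v1", sample = c("s1", "s2", "s3", "s4"),
      gt = "0/1", dp = c(9L, 10L, 50L, 50L), gq = c(99L, 20L, 19L, 60L)))
  out <- apply_genotype_qc(v, n_samples = 4)
  expect_equal(is.na(out$genotypes$gt), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$sites$missingness, 0.5)
  # allele fields untouched
  expect_identical(out$sites$ref, v$sites$ref)
  expect_identical(out$sites$alt, v$sites$alt)
  clean <- list(sites = base_site(), genotypes = tibble::tibble(
    variant_id = "v1", sample = c("s1", "s2"), gt = "0/1",
    dp = c(50L, 50L), gq = c(60L, 60L)))
  out2 <- apply_genotype_qc(clean, n_samples = 2)
  expect_identical(out2$genotypes$gt, clean$genotypes$gt)
})

test_that("SNV site filters trip the configured predicates with reasons", {
  s <- dplyr::bind_rows(
    base_site(variant_id = "clean"),
    base_site(variant_id = "qd", qd = 1.9),
    base_site(variant_id = "abhet", abhet = 0.80),
    base_site(variant_id = "multi", qd = 1.0, fs = 100, vqslod = -1))
  out <- apply_site_filters(s, site_filter_config("SNV"))
  expect_true(out$site_pass[out$variant_id == "clean"])
  expect_equal(out$fail_reasons[out$variant_id == "clean"][[1]], character(0))
  expect_equal(out$fail_reasons[out$variant_id == "qd"][[1]], "QD")
  expect_equal(out$fail_reasons[out$variant_id == "abhet"][[1]], "ABHet")
  expect_setequal(out$fail_reasons[out$variant_id == "multi"][[1]],
                  c("QD", "FS", "VQSLOD"))
})

test_that("INDEL mode relaxes FS/ReadPosRankSum and VQSLOD rule is a choice", {
  s <- base_site(variant_id = "i1", effect = "insertion", fs = 100,
                 read_pos_rank_sum = -15, vqslod = 3)
  # FS 100 passes the 200 INDEL threshold, fails the 60 SNV one
  expect_true(apply_site_filters(s, site_filter_config("INDEL"))$site_pass)
  expect_false(apply_site_filters(s, site_filter_config("SNV"))$site_pass)
  s2 <- base_site(vqslod = 3)
  expect_true(apply_site_filters(
    s2, site_filter_config("INDEL", indel_vqslod_rule = "fail_negative"))$site_pass)
  expect_false(apply_site_filters(
    s2, site_filter_config("INDEL", indel_vqslod_rule = "fail_positive"))$site_pass)
})

test_that("missing annotations pass by default and fail in strict mode", {
  s <- base_site(qd = NA_real_)
  expect_true(apply_site_filters(s, site_filter_config("SNV"))$site_pass)
  expect_false(apply_site_filters(
    s, site_filter_config("SNV", strict_missing = TRUE))$site_pass)
})

test_that("multi-allelic records decompose and alleles left-normalize", {
  ref_ctx <- list(chr1 = list(seq = paste(rep("GATTACAGATTACA", 10),
                                          collapse = ""), offset = 1))
  s <- base_site(pos = 8, ref = "G", alt = "A,T")
  out <- decompose_and_normalize(s, ref_ctx)
  expect_equal(nrow(out), 2)
  expect_equal(out$alt, c("A", "T"))
  expect_equal(out$pos, c(8, 8))

  # shared leading/trailing trimming: TCG>TAG at 15 becomes C>A at 16
  ctx2 <- list(chr1 = list(seq = "AAAAAAAAAAAAAATCGAAA", offset = 1))
  s2 <- base_site(pos = 15, ref = "TCG", alt = "TAG")
  out2 <- decompose_and_normalize(s2, ctx2)
  expect_equal(out2$pos, 16)
  expect_equal(out2$ref, "C")
  expect_equal(out2$alt, "A")

  # left-shift through a TA repeat: deletion given at the right edge moves left
  ctx3 <- list(chr1 = list(seq = "GGGGTATATATAGGG", offset = 1))
  s3 <- base_site(pos = 8, ref = "ATA", alt = "A")
  out3 <- decompose_and_normalize(s3, ctx3)
  expect_equal(out3$pos, 4)   # leftmost equivalent 2-bp deletion: GTA > G
  expect_equal(out3$ref, "GTA")
  expect_equal(out3$alt, "G")
  again <- decompose_and_normalize(out3, ctx3)
  expect_equal(again$pos, out3$pos)   # idempotent
  expect_equal(again$ref, out3$ref)
  expect_equal(again$alt, out3$alt)

  expect_error(decompose_and_normalize(base_site(pos = 8, ref = "T", alt = "C"),
                                       ref_ctx), "inconsistent")
})

test_that("left-normalization is idempotent on random indels", {
  set.seed(20)
  bases <- c("A", "C", "G", "T")
  seq <- paste(sample(bases, 400, replace = TRUE), collapse = "")
  ctx <- list(chr1 = list(seq = seq, offset = 1))
  for (i in 1:40) {
    pos <- sample(50:350, 1)
    len <- sample(1:4, 1)
    ref <- substr(seq, pos, pos + len)
    alt <- substr(seq, pos, pos)   # deletion of `len` bases
    if (sample(c(TRUE, FALSE), 1)) {   # or an insertion
      ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
      alt <- paste0(ref, ins)
    }
    s <- base_site(pos = pos, ref = ref, alt = alt)
    once <- decompose_and_normalize(s, ctx)
    twice <- decompose_and_normalize(once, ctx)
    expect_equal(once$pos, twice$pos)
    expect_equal(once$ref, twice$ref)
    expect_equal(once$alt, twice$alt)
    # the normalized record still differs ref vs alt
    expect_false(identical(once$ref, once$alt))
  }
})

test_that("rarity requires MAF < 0.005 in every database, absent counts as 0", {
  s <- dplyr::bind_rows(
    base_site(variant_id = "rare", af_kg = 0.001, af_exac = 0.004,
              af_evs = 0, af_dbsnp = 0.0049),
    base_site(variant_id = "boundary", af_kg = 0.001, af_exac = 0.005),
    base_site(variant_id = "na", af_kg = NA_real_, af_exac = NA_real_,
              af_evs = NA_real_, af_dbsnp = NA_real_),
    base_site(variant_id = "major", af_kg = 0.999))  # MAF 0.001: rare
  out <- is_rare(s)
  expect_equal(out$rare, c(TRUE, FALSE, TRUE, TRUE))
  no_af <- base_site()[, setdiff(names(base_site()),
                                 c("af_kg", "af_exac", "af_evs", "af_dbsnp"))]
  expect_true(is_rare(no_af)$rare)
})

test_that("classifier matches the composite rule on hand-picked cases", {
  cases <- dplyr::bind_rows(
    base_site(variant_id = "stopgain", effect = "stopgain",
              sift = NA_character_, cadd = NA_real_, gerp = NA_real_,
              phylop = NA_real_, siphy = NA_real_),
    base_site(variant_id = "ins", effect = "insertion"),
    base_site(variant_id = "syn", effect = "synonymous", cadd = 30,
              gerp = 6, phylop = 0.99, siphy = 15),
    base_site(variant_id = "weak_mis", effect = "missense",
              sift = "D", pp2_hdiv = "D", pp2_hvar = "D", lrt = "D",
              cadd = 4.0, gerp = 4, phylop = 0.5, siphy = 5),
    base_site(variant_id = "quorum", effect = "missense",
              sift = "D", pp2_hdiv = "D", pp2_hvar = "D", lrt = "D",
              mutation_taster = "D"),
    base_site(variant_id = "cadd_only", effect = "missense", cadd = 4.6),
    base_site(variant_id = "cons", effect = "missense", gerp = 3.1,
              siphy = 10.5))
  out <- classify_deleterious(cases)
  verdicts <- setNames(out$deleterious, out$variant_id)
  expect_true(verdicts[["stopgain"]])
  expect_true(verdicts[["ins"]])
  expect_false(verdicts[["syn"]])       # synonymous never via scores
  expect_false(verdicts[["weak_mis"]])  # 4 hits, CADD 4.0, 1 conservation
  expect_true(verdicts[["quorum"]])     # 5 predictor hits
  expect_true(verdicts[["cadd_only"]])
  expect_true(verdicts[["cons"]])       # 2 of 3 conservation predicates
  expect_equal(out$criteria[out$variant_id == "stopgain"][[1]], "lof")
  expect_equal(out$criteria[out$variant_id == "ins"][[1]], "indel")
})

test_that("missing predictor calls never count toward the quorum", {
  s <- base_site(effect = "missense", sift = "D", pp2_hdiv = "D",
                 pp2_hvar = "D", lrt = "D", mutation_taster = NA_character_,
                 mutation_assessor = NA_character_, fathmm = NA_character_,
                 metasvm = NA_character_, metalr = NA_character_)
  expect_false(classify_deleterious(s)$deleterious)
})
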