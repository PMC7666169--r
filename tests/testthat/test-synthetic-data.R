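test_that("simulate_variants places increasing positions at the right density", {
  cfg <- sim_config(10, chromosome_lengths = 3e6, snp_spacing_bp = 1e4,
                    seed = 11)
  v <- simulate_variants(cfg)
  expect_gt(nrow(v), 200)
  expect_lt(nrow(v), 400)
  expect_true(all(diff(v$pos) > 0))
  expect_true(all(v$pos >= 1 & v$pos <= 3e6))

  cfg2 <- sim_config(10, chromosome_lengths = c(1e6, 2e6),
                     allele_freq_law = function(n) rep(0.5, n), seed = 11)
  v2 <- simulate_variants(cfg2)
  expect_true(all(v2$freq_B == 0.5))
  expect_setequal(unique(v2$chrom), c("1", "2"))

  expect_identical(simulate_variants(cfg), simulate_variants(cfg))
  expect_error(sim_config(10, chromosome_lengths = numeric(0)),
               "chromosome")
})

test_that("simulate_hbd hits target coverage and merges intervals", {
  cfg0 <- sim_config(20, chromosome_lengths = 1e8,
                     f_target_law = function(n) rep(0, n), seed = 5)
  v <- simulate_variants(cfg0)
  h0 <- simulate_hbd(cfg0, v)
  expect_equal(nrow(h0$segments), 0)
  expect_true(all(h0$f_true == 0))

  # single fixed 2 Mb segment on a 100 Mb genome
  cfg1 <- sim_config(10, chromosome_lengths = 1e8,
                     f_target_law = function(n) rep(0.02, n),
                     hbd_length_law = function(n) rep(2e6, n), seed = 5)
  h1 <- simulate_hbd(cfg1, v)
  expect_equal(unname(h1$f_true), rep(0.02, 10), tolerance = 1e-6)
  expect_equal(nrow(h1$segments), 10)  # one segment per sample

  # segments within a sample are non-overlapping after merging
  cfgm <- sim_config(30, chromosome_lengths = 5e7,
                     f_target_law = function(n) rep(0.3, n),
                     hbd_length_law = function(n) rexp(n, 1 / 2e6), seed = 6)
  hm <- simulate_hbd(cfgm, simulate_variants(cfgm))
  for (sid in unique(hm$segments$sample_id)) {
    s <- hm$segments[hm$segments$sample_id == sid, ]
    s <- s[order(s$chrom, s$start), ]
    for (ch in unique(s$chrom)) {
      sc <- s[s$chrom == ch, ]
      if (nrow(sc) > 1)
        expect_true(all(sc$start[-1] > sc$end[-nrow(sc)] + 1))
    }
  }
  expect_error(simulate_hbd(
    sim_config(2, f_target_law = function(n) rep(1, n), seed = 1), v),
    "\\[0, 1\\)")
})

test_that("generator is self-consistent: mean F_true matches the target law", {
  cfg <- sim_config(500, chromosome_lengths = 3e9, snp_spacing_bp = 1e6,
                    f_target_law = function(n) rep(1 / 16, n), seed = 21)
  h <- simulate_hbd(cfg, simulate_variants(cfg))
  se <- stats::sd(h$f_true) / sqrt(length(h$f_true)) + 1e-9
  expect_lt(abs(mean(h$f_true) - 1 / 16), 3 * se + 1e-6)
})

test_that("simulate_genotypes: HBD intervals are homozygous, HWE elsewhere", {
  cfg <- sim_config(40, chromosome_lengths = 2e7, snp_spacing_bp = 2e4,
                    allele_freq_law = function(n) rep(0.5, n),
                    f_target_law = function(n) rep(0, n), seed = 31)
  v <- simulate_variants(cfg)
  h <- simulate_hbd(cfg, v)
  d <- simulate_genotypes(v, h, cfg)
  het <- colMeans(d$genotypes == 1L)
  expect_equal(mean(het), 0.5, tolerance = 0.02)  # HWE at p = 0.5

  # whole-genome HBD -> zero heterozygous calls
  cfg2 <- sim_config(5, chromosome_lengths = 2e7, snp_spacing_bp = 2e4,
                     f_target_law = function(n) rep(0.999, n),
                     hbd_length_law = function(n) rep(2e7, n), seed = 31)
  h2 <- simulate_hbd(cfg2, v)
  d2 <- simulate_genotypes(v, h2, cfg2)
  expect_equal(sum(d2$genotypes == 1L, na.rm = TRUE), 0)

  # heterozygosity inside any true HBD segment is exactly zero
  cfg3 <- sim_config(25, chromosome_lengths = 2e7, snp_spacing_bp = 2e4,
                     f_target_law = function(n) rep(0.2, n), seed = 32)
  h3 <- simulate_hbd(cfg3, v)
  d3 <- simulate_genotypes(v, h3, cfg3)
  for (k in seq_len(nrow(h3$segments))) {
    seg <- h3$segments[k, ]
    i <- match(seg$sample_id, d3$samples$sample_id)
    inside <- v$chrom == seg$chrom & v$pos >= seg$start & v$pos <= seg$end
    if (any(inside))
      expect_equal(sum(d3$genotypes[i, inside] == 1L), 0)
  }
})

test_that("expected_depression closed form", {
  expect_equal(expected_depression(0, rep(0.5, 100), rep(0.5, 100)), 0)
  expect_equal(expected_depression(1 / 16, rep(0.5, 100), rep(0.5, 100)),
               -1.5625)
  expect_equal(expected_depression(1 / 64, 1, 0.5), -0.0078125)
})

test_that("simulate_trait: no dominance implies no inbreeding depression", {
  cfg <- sim_config(800, chromosome_lengths = 5e7, snp_spacing_bp = 1e5,
                    n_causal_loci = 50, dominance_mean_d = 0,
                    additive_effect_a = 0,
                    f_target_law = function(n) runif(n, 0, 0.2), seed = 41)
  co <- simulate_cohort(cfg)
  fit <- summary(lm(co$data$samples$trait ~ co$data$samples$F_true))
  ci <- fit$coefficients[2, 1] +
    c(-1, 1) * 1.96 * fit$coefficients[2, 2]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("sex-specific betas flip the trait-on-F slope between sexes", {
  cfg <- sim_config(1500, chromosome_lengths = 5e7, snp_spacing_bp = 1e5,
                    n_causal_loci = 10,
                    sex_specific_beta = c(male = -10, female = 10),
                    f_target_law = function(n) runif(n, 0, 0.2),
                    polygenic_variance = 0.2, residual_variance = 0.2,
                    seed = 42)
  co <- simulate_cohort(cfg)
  s <- co$data$samples
  bm <- coef(lm(trait ~ F_true, data = s[s$sex == "male", ]))[2]
  bf <- coef(lm(trait ~ F_true, data = s[s$sex == "female", ]))[2]
  expect_lt(bm, 0)
  expect_gt(bf, 0)
})

test_that("identical seed gives bit-identical cohorts; causal loci respect MAF range", {
  cfg <- sim_config(30, chromosome_lengths = 1e7, snp_spacing_bp = 5e4,
                    n_causal_loci = 20, causal_maf_range = c(0.2, 0.4),
                    seed = 51)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$data$genotypes, b$data$genotypes)
  expect_identical(a$data$samples$trait, b$data$samples$trait)
  expect_true(all(a$causal$p >= 0.2 & a$causal$p <= 0.4))
  cfg_bad <- sim_config(30, chromosome_lengths = 1e7, snp_spacing_bp = 5e4,
                        n_causal_loci = 20, causal_maf_range = c(0.9, 0.95),
                        seed = 51)
  v <- simulate_variants(cfg_bad)
  h <- simulate_hbd(cfg_bad, v)
  d <- simulate_genotypes(v, h, cfg_bad)
  expect_error(simulate_trait(d, cfg_bad), "causal_maf_range")
})
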