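test_that("compute_f_roh arithmetic and bounds", {
  ids <- c("S1", "S2", "S3")
  # segments totaling 27.9 Mb of qualifying ROH over 3 Gb -> 0.0093
  seg <- data.frame(sample_id = "S1", chrom = c("1", "2"),
                    start_bp = c(1, 1), end_bp = c(12.9e6, 15e6),
                    n_snps = 1000L)
  seg$length_kb <- (seg$end_bp - seg$start_bp + 1) / 1000
  fr <- compute_f_roh(seg, ids)
  expect_equal(fr$F_ROH[1], 27.9e6 / 3e9, tolerance = 1e-6)
  expect_equal(fr$F_ROH[2:3], c(0, 0))   # no segments -> 0
  expect_equal(fr$n_roh, c(2L, 0L, 0L))

  whole <- data.frame(sample_id = "S1", chrom = "1", start_bp = 1,
                      end_bp = 3e9, n_snps = 1L, length_kb = 3e6)
  expect_equal(compute_f_roh(whole, "S1")$F_ROH, 1.0)

  # sub-threshold segments do not count
  short <- data.frame(sample_id = "S1", chrom = "1", start_bp = 1,
                      end_bp = 1e6, n_snps = 1L, length_kb = 1000)
  expect_equal(compute_f_roh(short, "S1")$F_ROH, 0)
  bad <- data.frame(sample_id = "S1", chrom = "1", start_bp = 10,
                    end_bp = 5, n_snps = 1L, length_kb = -0.005)
  expect_error(compute_f_roh(bad, "S1"), "negative")
})

test_that("F_ROH is monotone in the segment set", {
  set.seed(3)
  seg <- data.frame(sample_id = "S1", chrom = "1",
                    start_bp = c(1e6, 10e6), end_bp = c(3e6, 13e6),
                    n_snps = 100L)
  seg$length_kb <- (seg$end_bp - seg$start_bp + 1) / 1000
  f1 <- compute_f_roh(seg, "S1")$F_ROH
  extra <- rbind(seg, data.frame(sample_id = "S1", chrom = "2",
                                 start_bp = 1, end_bp = 2e6, n_snps = 100L,
                                 length_kb = 2000))
  expect_gte(compute_f_roh(extra, "S1")$F_ROH, f1)
})

test_that("F_GRM identities: +1 fully homozygous at p = 0.5, -1 fully het", {
  m <- 40
  hom <- matrix(rep(c(0L, 2L), m / 2), 1, m)
  d <- toy_dataset(rbind(hom, hom), freq = rep(0.5, m))
  expect_equal(unname(compute_f_grm(d, freqs = rep(0.5, m))), c(1, 1))

  set.seed(4)
  p <- runif(m, 0.1, 0.9)
  het <- toy_dataset(matrix(1L, 2, m), freq = p)
  expect_equal(unname(compute_f_grm(het, freqs = p, maf_min = 0.05)), c(-1, -1))
  expect_error(compute_f_grm(het, freqs = rep(0.01, m)), "no usable loci")
})

test_that("mean F_GRM is near zero under HWE", {
  set.seed(5)
  n <- 800; m <- 500
  p <- runif(m, 0.1, 0.5)
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  d <- toy_dataset(g)
  f <- compute_f_grm(d, freqs = p)
  se <- sd(f) / sqrt(n)
  expect_lt(abs(mean(f)), 3 * se + 1e-3)
})

test_that("F_outsideROH matches hand-worked arithmetic", {
  # 10 SNPs, 3 inside a called ROH; worked by hand below
  g <- c(2L, 0L, 1L, 2L, 2L, 0L, 1L, 1L, 2L, 0L)
  p <- c(0.5, 0.4, 0.3, 0.5, 0.2, 0.5, 0.4, 0.3, 0.2, 0.5)
  pos <- seq(1e6, by = 1e6, length.out = 10)
  d <- toy_dataset(matrix(g, 1), pos = pos, freq = p)
  seg <- data.frame(sample_id = "S001", chrom = "1", start_bp = 3.5e6,
                    end_bp = 6.5e6, n_snps = 3L, length_kb = 3000)
  # inside ROH: SNPs at 4,5,6 Mb with genotypes 2,2,0 -> N_ROH = 3, all hom
  # N = 10, O = 7, E = sum(1 - 2 p q) = 10 - 2*sum(p*(1-p))
  E <- 10 - 2 * sum(p * (1 - p))
  O2 <- 7 - 3
  E2 <- (10 - 3) / 10 * E
  N2 <- 10 - 3
  expect_equal(unname(compute_f_outside_roh(d, seg, freqs = p)),
               (O2 - E2) / (N2 - E2))
})

test_that("F_outsideROH reduces to classic excess homozygosity with no ROH", {
  set.seed(6)
  n <- 50; m <- 200
  p <- runif(m, 0.2, 0.5)
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  d <- toy_dataset(g, freq = p)
  empty <- roh_empty_for_test()
  f <- compute_f_outside_roh(d, empty, freqs = p)
  classic <- apply(g, 1, function(x) {
    O <- sum(x != 1); E <- sum(1 - 2 * p * (1 - p)); N <- m
    (O - E) / (N - E)
  })
  expect_equal(unname(f), classic)
  expect_lt(abs(mean(f)), 3 * sd(f) / sqrt(n) + 0.01)

  # all SNPs homozygous, no ROH called -> exactly 1
  dall <- toy_dataset(matrix(rep(c(0L, 2L), 100), 1), freq = p)
  expect_equal(unname(compute_f_outside_roh(dall, empty, freqs = p)), 1.0)

  # degenerate denominator flagged, not silently zero
  seg_all <- data.frame(sample_id = "S001", chrom = "1", start_bp = 1,
                        end_bp = 1e9, n_snps = m, length_kb = 1e6)
  expect_warning(res <- compute_f_outside_roh(d[["genotypes"]][1, , drop = FALSE] |>
    toy_dataset(freq = p), seg_all, freqs = p), "degenerate")
  expect_true(is.na(res[1]))
})

test_that("GRM matches hand arithmetic and behaves under HWE", {
  # 3 samples, 4 loci, fixed frequencies
  g <- rbind(c(0L, 1L, 2L, 1L),
             c(1L, 1L, 2L, 0L),
             c(2L, 0L, 1L, 1L))
  p <- c(0.3, 0.5, 0.4, 0.25)
  d <- toy_dataset(g, freq = p)
  W <- sweep(g, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  A_hand <- tcrossprod(W) / 4
  expect_equal(unname(compute_grm(d, freqs = p)), unname(A_hand))

  # duplicate samples: off-diagonal approximately equals the diagonal
  dup <- toy_dataset(rbind(g, g[1, ]), freq = p)
  A <- compute_grm(dup, freqs = p)
  expect_equal(A[1, 4], A[1, 1])

  set.seed(8)
  n <- 200; m <- 600
  ph <- runif(m, 0.1, 0.5)
  gh <- sapply(ph, function(pp) rbinom(n, 2, pp))
  Ah <- compute_grm(toy_dataset(gh), freqs = ph)
  off <- Ah[upper.tri(Ah)]
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)) + 1e-3)
  expect_error(compute_grm(toy_dataset(gh[1, , drop = FALSE])), "2 samples")
})

test_that("PCs separate two simulated populations deterministically", {
  set.seed(9)
  n <- 60; m <- 300
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(pmax(p1 + sample(c(-0.25, 0.25), m, TRUE), 0.05), 0.95)
  g <- rbind(sapply(p1, function(pp) rbinom(n / 2, 2, pp)),
             sapply(p2, function(pp) rbinom(n / 2, 2, pp)))
  d <- toy_dataset(g)
  pcs <- compute_pcs(d, k = 2, prune = FALSE)
  grp <- rep(c(1, 2), each = n / 2)
  expect_lt(t.test(pcs[grp == 1, 1], pcs[grp == 2, 1])$p.value, 1e-6)
  expect_identical(pcs, compute_pcs(d, k = 2, prune = FALSE))
  expect_equal(ncol(compute_pcs(d, k = 0)), 0)
  expect_error(compute_pcs(d, k = n + 1), "exceeds")
})

test_that("F_ROH from called segments tracks true autozygosity", {
  cfg <- sim_config(40, chromosome_lengths = 5e7, snp_spacing_bp = 9000,
                    f_target_law = function(n) runif(n, 0, 0.25),
                    hbd_length_law = function(n) rep(2.5e6, n), seed = 99)
  co <- simulate_cohort(cfg)
  seg <- call_roh(co$data)
  fr <- compute_f_roh(seg, co$data$samples$sample_id,
                      genome_length_bp = 5e7)
  expect_gte(cor(fr$F_ROH, co$hbd$f_true), 0.95)
})

test_that("inbreeding_profile assembles all three coefficients", {
  cfg <- sim_config(25, chromosome_lengths = 4e7, snp_spacing_bp = 1e4,
                    f_target_law = function(n) runif(n, 0, 0.2), seed = 13)
  co <- simulate_cohort(cfg)
  seg <- call_roh(co$data)
  prof <- inbreeding_profile(co$data, seg, genome_length_bp = 4e7)
  expect_equal(names(prof), c("sample_id", "F_ROH", "F_GRM", "F_outsideROH",
                              "sum_roh_kb", "n_roh"))
  expect_true(all(prof$F_ROH >= 0 & prof$F_ROH <= 1))
  expect_true(all((prof$F_ROH == 0) == (prof$n_roh == 0)))
})
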