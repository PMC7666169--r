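# A covariate table with PCs, built in code.
make_samples <- function(n, seed = 1, n_pcs = 15) {
  set.seed(seed)
  s <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, TRUE),
    age = runif(n, 40, 60),
    site = sample(paste0("site", 1:4), n, TRUE),
    SES.Q = sample(1:5, n, TRUE),
    night_light = sample(0:40, n, TRUE),
    edu = sample(1:4, n, TRUE),
    occu = sample(1:5, n, TRUE),
    height = rnorm(n, 1.65, 0.08),
    BMI = rnorm(n, 26, 4),
    stringsAsFactors = FALSE)
  for (j in seq_len(n_pcs)) s[[paste0("pc", j)]] <- rnorm(n)
  s
}

test_that("build_design expands the documented covariate sets", {
  s <- make_samples(200)
  s$weight <- rnorm(200, 70, 10)
  s$pulse <- rnorm(200, 70, 8)
  specs <- default_model_specs()
  d <- build_design("weight", s, specs$weight)
  cn <- colnames(d$X)
  expect_true("(Intercept)" %in% cn)
  expect_true(any(grepl("^sex", cn)))
  expect_true(all(c("age", "age2", "night_light", "pc1", "pc15") %in% cn))
  expect_equal(sum(grepl("^SES.Q", cn)), 4)  # 5 quintiles -> 4 contrasts
  expect_false("BMI" %in% cn)
  dp <- build_design("pulse", s, specs$pulse)
  expect_true("BMI" %in% colnames(dp$X))
  expect_error(build_design("weight", s, c("age", "bogus")), "bogus")
  s2 <- s; s2$age[1:5] <- NA
  d2 <- build_design("weight", s2, specs$weight)
  expect_equal(d2$n_dropped, 5)
})

test_that("fit_polygenic with identity GRM returns OLS residuals, flagged", {
  set.seed(21)
  n <- 150
  X <- cbind(1, rnorm(n))
  y <- X %*% c(2, -1) + rnorm(n)
  fit <- fit_polygenic(y, X, diag(n))
  ols <- lm.fit(X, y)
  expect_false(fit$identifiable)
  expect_equal(fit$sigma_g2, 0)
  expect_equal(fit$residuals, as.numeric(ols$residuals), tolerance = 1e-10)

  # exact linear response -> residuals vanish
  y0 <- X %*% c(3, 0.5)
  A <- crossprod(matrix(rnorm(n * n), n)) / n + diag(n) * 0.1
  fit0 <- fit_polygenic(as.numeric(y0), X, A)
  expect_lt(sqrt(sum(fit0$residuals^2)), 1e-8 * sqrt(sum(y0^2)))
  expect_error(fit_polygenic(y, X, matrix(rnorm(n * n), n)), "symmetric")
})

test_that("fit_polygenic recovers planted variance components", {
  set.seed(22)
  n <- 400
  reps <- 4
  sg <- numeric(reps)
  for (r in seq_len(reps)) {
    Z <- matrix(rnorm(n * 80), n, 80)
    A <- tcrossprod(Z) / 80          # genuine relatedness structure
    A <- A / mean(diag(A))
    X <- cbind(1, rnorm(n))
    u <- t(chol(2 * A + diag(n) * 1e-8)) %*% rnorm(n)
    y <- as.numeric(X %*% c(1, 0.5) + u + rnorm(n, 0, 1))
    f <- fit_polygenic(y, X, A)
    expect_true(f$identifiable)
    sg[r] <- f$sigma_g2
  }
  expect_lt(abs(mean(sg) - 2), 3 * sd(sg) / sqrt(reps) + 0.3)
})

test_that("two-step equals one-step OLS when F is orthogonal to X", {
  set.seed(23)
  n <- 500
  X <- cbind(1, rnorm(n), rnorm(n))
  F_raw <- rexp(n, 50)
  F_orth <- as.numeric(lm.fit(X, F_raw)$residuals)  # orthogonalized exposure
  y <- as.numeric(X %*% c(1, 2, -1) - 30 * F_orth + rnorm(n))
  one_step <- coef(lm(y ~ X[, -1] + F_orth))[["F_orth"]]
  step1 <- fit_polygenic(y, X, A = NULL)
  prof <- data.frame(F_ROH = F_orth)
  two_step <- fit_id(step1$residuals, prof, include_f_outside = FALSE)
  expect_equal(two_step$beta, one_step, tolerance = 1e-6)
})

test_that("fit_id recovers a planted effect and standardizes sanely", {
  set.seed(24)
  n <- 4000
  F <- rexp(n, 1 / 0.01)
  e <- -30 * F + rnorm(n, 0, 1)
  prof <- data.frame(F_ROH = F)
  est <- fit_id(e, prof, include_f_outside = FALSE)
  expect_lt(abs(est$beta + 30), 3 * est$se)
  expect_true(est$ci_lo < est$beta && est$beta < est$ci_hi)
  expect_lt(est$p, 1e-6)
  # affine trait rescaling: beta scales, standardized beta does not
  est10 <- fit_id(10 * e, prof, include_f_outside = FALSE)
  expect_equal(est10$beta, 10 * est$beta, tolerance = 1e-8)
  expect_equal(est10$beta_std, est$beta_std, tolerance = 1e-8)
  expect_error(fit_id(e, data.frame(F_ROH = rep(0, n))), "zero variance")
})

test_that("fit_id includes F_outsideROH when asked", {
  set.seed(25)
  n <- 1000
  prof <- data.frame(F_ROH = rexp(n, 100), F_outsideROH = rnorm(n, 0, 0.02))
  e <- -20 * prof$F_ROH + 5 * prof$F_outsideROH + rnorm(n, 0, 0.5)
  est <- fit_id(e, prof)
  fo <- attr(est, "f_outside")
  expect_false(is.null(fo))
  expect_lt(abs(fo$beta - 5), 3 * fo$se)
})

test_that("bivariate conditioning distinguishes F_ROH from noise F_GRM", {
  set.seed(26)
  n <- 2000
  F <- rexp(n, 1 / 0.02)
  prof <- data.frame(F_ROH = F, F_GRM = F + rnorm(n, 0, 0.03))
  e <- -25 * F + rnorm(n)
  biv <- fit_bivariate(e, prof)
  expect_equal(biv$term, c("F_ROH", "F_GRM"))
  # pure-noise F_GRM: its conditional CI covers zero
  prof2 <- data.frame(F_ROH = F, F_GRM = rnorm(n, 0, 0.02))
  biv2 <- fit_bivariate(e, prof2)
  g <- biv2[biv2$term == "F_GRM", ]
  expect_true(g$ci_lo < 0 && g$ci_hi > 0)
  expect_error(fit_bivariate(e, data.frame(F_ROH = F, F_GRM = F)),
               "collinear")
})

test_that("fit_stratified: identical strata agree; small strata skipped", {
  set.seed(27)
  n <- 600
  s <- make_samples(n, seed = 27, n_pcs = 2)
  F <- rexp(n, 1 / 0.02)
  s$trait <- -15 * F + 0.1 * s$age + rnorm(n)
  prof <- data.frame(F_ROH = F)
  est <- fit_stratified("trait", s, prof, c("age", "SES.Q", "night_light"),
                        strata = "sex", include_f_outside = FALSE)
  expect_equal(nrow(est), 2)
  expect_lt(abs(est$beta[1] - est$beta[2]),
            3 * sqrt(sum(est$se^2)))
  s$sex[1:10] <- "other"
  expect_warning(
    fit_stratified("trait", s, prof, c("age"), strata = "sex",
                   include_f_outside = FALSE, min_n = 50), "skipped")
})

test_that("fit_stratified luminosity split swaps night_light for site", {
  set.seed(28)
  n <- 700
  s <- make_samples(n, seed = 28, n_pcs = 2)
  s$night_light <- ifelse(s$site %in% c("site1", "site2"),
                          sample(0:4, n, TRUE), sample(6:40, n, TRUE))
  F <- rexp(n, 1 / 0.02)
  s$trait <- -10 * F + rnorm(n)
  prof <- data.frame(F_ROH = F)
  est <- fit_stratified("trait", s, prof,
                        c("age", "night_light"), strata = "luminosity",
                        include_f_outside = FALSE)
  expect_setequal(est$stratum, c("luminosity<5", "luminosity>=5"))
})

test_that("compare_strata detects equal and unequal slopes correctly", {
  set.seed(29)
  n <- 1200
  F <- rexp(n, 1 / 0.02)
  grp <- rep(c("a", "b"), each = n / 2)
  e_same <- -10 * F + rnorm(n)
  res <- compare_strata(e_same, data.frame(F_ROH = F), grp)
  expect_gt(res$p, 0.001)
  expect_error(compare_strata(e_same, data.frame(F_ROH = F),
                              rep("a", n)), "two levels")
})

test_that("compare_beta_sets: exact Mann-Whitney behavior", {
  x <- c(1, 2, 3, 4)
  res <- compare_beta_sets(x, x)
  expect_equal(res$p, 1)
  # fully separated 9 vs 9: U = 0, exact two-sided p = 2 / choose(18, 9)
  a <- 1:9; b <- 101:109
  res2 <- compare_beta_sets(a, b)
  expect_equal(res2$U, 0)
  expect_equal(res2$p, 2 / choose(18, 9))
  expect_equal(res2$method, "exact enumeration")
  # large nearly-identical sets -> p near 1, normal approximation
  set.seed(30)
  big <- rnorm(30)
  res3 <- compare_beta_sets(big, big + 1e-4)
  expect_gt(res3$p, 0.8)
  expect_equal(res3$method, "normal approximation")
  expect_error(compare_beta_sets(1, c(1, 2)), "at least 2")
})

test_that("compare_beta_sets matches wilcox.test where both are exact", {
  set.seed(31)
  a <- rnorm(7); b <- rnorm(7, 1)
  mine <- compare_beta_sets(a, b)
  ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("predicted_change applies the reporting convention", {
  expect_equal(predicted_change(-64, 1 / 64), -1)
  expect_equal(predicted_change(0, 0.3), 0)
  est <- data.frame(beta = -30)
  expect_equal(predicted_change(est), -30 / 64)
})

test_that("type-I error of the step-2 test is calibrated", {
  set.seed(32)
  reps <- 200
  n <- 800
  hits <- 0
  for (r in seq_len(reps)) {
    F <- rexp(n, 1 / 0.01)
    e <- rnorm(n)
    est <- fit_id(e, data.frame(F_ROH = F), include_f_outside = FALSE)
    if (est$p < 0.05) hits <- hits + 1
  }
  band <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})
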