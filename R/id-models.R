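#' Pedigree inbreeding coefficient of second-cousin offspring
#'
#' The conventional reporting unit for inbreeding-depression effect sizes
#' (`beta * 1/64`).
#' @export
SECOND_COUSIN_F <- 1 / 64

#' Default per-trait covariate model specifications
#'
#' The covariate sets conventionally used for cardiometabolic traits in
#' multi-site cohort analyses: all traits adjust for sex, age, age-squared,
#' SES quintile, night-light intensity and 15 genotype PCs; body-shape
#' traits (WHR, VAT, SCAT) additionally adjust for height; circulatory
#' traits (pulse, systolic/diastolic BP) for BMI; and the SES.Q model
#' swaps SES.Q out for education and occupation (and drops age-squared).
#'
#' @param n_pcs number of principal components (default 15).
#' @return named list mapping trait name to a character vector of
#'   covariate names (`"age2"` denotes centered age squared).
#' @export
default_model_specs <- function(n_pcs = 15) {
  pcs <- paste0("pc", seq_len(n_pcs))
  base <- c("sex", "age", "age2", "SES.Q", "night_light", pcs)
  specs <- list(
    SES.Q = c("sex", "age", "edu", "occu", "night_light", pcs),
    height = base, weight = base, BMI = base,
    WHR = c(base, "height"), VAT = c(base, "height"), SCAT = c(base, "height"),
    HDL = base, LDL = base, TC = base, TG = base,
    pulse = c(base, "BMI"),
    systolic_bp = c(base, "BMI"), diastolic_bp = c(base, "BMI"))
  specs
}

#' Build a regression design matrix for a trait model
#'
#' Expands categorical covariates (sex, site, edu, occu, SES.Q) to
#' indicator contrasts, computes `age2` as centered-age squared (centering
#' improves conditioning and does not change the fit), includes an
#' intercept, and drops rows with missing values in any used column (the
#' count is reported).
#'
#' @param trait trait column name in `samples`.
#' @param samples sample table (data.frame).
#' @param covariates character vector of covariate names.
#' @return list: `y` (response), `X` (design matrix), `rows` (logical
#'   vector of retained rows), `n_dropped`.
#' @export
build_design <- function(trait, samples, covariates) {
  if (!trait %in% names(samples)) stop("trait '", trait, "' not in samples")
  needs_age <- "age2" %in% covariates
  cols <- setdiff(covariates, "age2")
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols))
    stop("unknown covariate(s): ", paste(missing_cols, collapse = ", "))
  if (needs_age && !"age" %in% names(samples))
    stop("age2 requested but no 'age' column")
  df <- samples[, unique(c(trait, cols, if (needs_age) "age")), drop = FALSE]
  rows <- stats::complete.cases(df)
  n_dropped <- sum(!rows)
  df <- df[rows, , drop = FALSE]
  if (nrow(df) == 0) stop("no complete rows for trait '", trait, "'")
  categorical <- intersect(c("sex", "site", "edu", "occu", "SES.Q"), cols)
  for (cc in categorical) df[[cc]] <- factor(df[[cc]])
  # single-level factors carry no information; drop to keep X full rank
  keep <- vapply(cols, function(cc)
    !is.factor(df[[cc]]) || nlevels(df[[cc]]) > 1, TRUE)
  cols <- cols[keep]
  if (needs_age) df$age2 <- (df$age - mean(df$age))^2
  rhs <- c(cols, if (needs_age) "age2")
  form <- stats::as.formula(paste("~", paste(c("1", rhs), collapse = " + ")))
  X <- stats::model.matrix(form, df)
  list(y = df[[trait]], X = X, rows = rows, n_dropped = n_dropped)
}

#' Fit the polygenic covariate model (step 1)
#'
#' Mixed model `y = Xb + u + e` with `u ~ N(0, sg2 * A)` and
#' `e ~ N(0, se2 * I)`, fitted by REML through a single spectral
#' decomposition of the GRM `A`: with `A = U D U'`, the rotated data
#' `U'y`, `U'X` have diagonal covariance `sg2 D + se2 I`, so the
#' heritability ratio is profiled by one-dimensional optimization
#' (tolerance 1e-6 on the ratio). The returned residual removes both the
#' fixed effects and the BLUP of `u`: `e' = y - X bhat - uhat` (a flag
#' keeps `uhat` in the residual for sensitivity analysis). When `A` is
#' (numerically) the identity the split of variance is unidentifiable;
#' the fit is flagged, the boundary `sg2 = 0` is reported and the
#' residuals equal the OLS residuals.
#'
#' @param y response vector.
#' @param X design matrix (with intercept).
#' @param A GRM (symmetric, same order as `y`); `NULL` for a plain OLS fit.
#' @param keep_blup_in_residuals if TRUE, return `y - X bhat` instead.
#' @return object of class `polygenic_fit`: `b`, `sigma_g2`, `sigma_e2`,
#'   `h2`, `residuals`, `loglik`, `identifiable`.
#' @export
fit_polygenic <- function(y, X, A = NULL, keep_blup_in_residuals = FALSE) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(A)) {
    fit <- stats::lm.fit(X, y)
    return(structure(list(b = fit$coefficients, sigma_g2 = 0,
                          sigma_e2 = sum(fit$residuals^2) / (n - ncol(X)),
                          h2 = 0, residuals = fit$residuals,
                          loglik = NA_real_, identifiable = FALSE),
                     class = "polygenic_fit"))
  }
  stopifnot(nrow(A) == n, ncol(A) == n)
  if (max(abs(A - t(A))) > 1e-8) stop("GRM 'A' is not symmetric")
  ev <- eigen(A, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) < -1e-6 * max(abs(lam))) {
    lam <- lam + abs(min(lam)) + 1e-8  # ridge regularization attempt
    if (min(lam) <= 0) stop("GRM 'A' is not positive definite")
  } else lam <- pmax(lam, 1e-10)
  if (stats::sd(lam) < 1e-8 * mean(lam)) {
    # A ~ identity: variance split unidentifiable, report the boundary
    fit <- stats::lm.fit(X, y)
    return(structure(list(b = fit$coefficients, sigma_g2 = 0,
                          sigma_e2 = sum(fit$residuals^2) / (n - ncol(X)),
                          h2 = 0, residuals = fit$residuals,
                          loglik = NA_real_, identifiable = FALSE),
                     class = "polygenic_fit"))
  }
  U <- ev$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  p <- qr(X)$rank
  reml_neg <- function(h2) {
    v <- h2 * lam + (1 - h2)
    wy <- yr / sqrt(v); wX <- Xr / sqrt(v)
    fit <- stats::lm.fit(wX, wy)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    XtVX <- crossprod(wX)
    0.5 * ((n - p) * log(s2) + sum(log(v)) +
             determinant(XtVX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(reml_neg, c(1e-8, 1 - 1e-8), tol = 1e-6)
  h2 <- opt$minimum
  v <- h2 * lam + (1 - h2)
  wy <- yr / sqrt(v); wX <- Xr / sqrt(v)
  gls <- stats::lm.fit(wX, wy)
  b <- gls$coefficients
  s2 <- sum(gls$residuals^2) / (n - p)
  sigma_g2 <- h2 * s2
  sigma_e2 <- (1 - h2) * s2
  r_rot <- yr - Xr %*% ifelse(is.na(b), 0, b)
  u_rot <- (h2 * lam / v) * r_rot           # BLUP of u in rotated space
  uhat <- U %*% u_rot
  fixed_resid <- y - X %*% ifelse(is.na(b), 0, b)
  resid <- if (keep_blup_in_residuals) fixed_resid else fixed_resid - uhat
  structure(list(b = b, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2,
                 residuals = as.numeric(resid), loglik = -opt$objective,
                 identifiable = TRUE),
            class = "polygenic_fit")
}

id_estimate_row <- function(fit, term, trait, stratum, trait_sd, n) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) stop("term '", term, "' not estimable")
  b <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
  p <- sm[term, "Pr(>|t|)"]
  dfree <- fit$df.residual
  ci <- b + c(-1, 1) * stats::qt(0.975, dfree) * se
  data.frame(trait = trait, stratum = stratum, term = term,
             beta = b, se = se, ci_lo = ci[1], ci_hi = ci[2], p = p,
             beta_std = b / trait_sd, n = n, stringsAsFactors = FALSE)
}

#' Regress trait residuals on F_ROH (step 2)
#'
#' Ordinary least squares of the step-1 residuals on F_ROH (and, by
#' default, F_outsideROH): `e' = mu + b_FROH * F_ROH
#' [+ b_FoutsideROH * F_outsideROH] + e`. The standardized effect divides
#' `b_FROH` by the trait standard deviation of the analyzed stratum so
#' effects are comparable across traits and strata.
#'
#' @param residuals step-1 residual vector.
#' @param profile inbreeding profile data.frame aligned with `residuals`
#'   (columns `F_ROH`, optionally `F_outsideROH`).
#' @param include_f_outside include F_outsideROH in the model (default TRUE
#'   when the column is present).
#' @param trait_sd standard deviation used for standardization; default the
#'   SD of the supplied residual vector (scales with the trait, so the
#'   standardized effect is invariant to affine trait rescaling).
#' @param trait,stratum labels carried into the output.
#' @return one-row data.frame (`id_estimate`): trait, stratum, term, beta,
#'   se, ci_lo, ci_hi, p, beta_std, n; the F_outsideROH row (when fitted)
#'   is attached as attribute `"f_outside"`.
#' @export
fit_id <- function(residuals, profile,
                   include_f_outside = "F_outsideROH" %in% names(profile),
                   trait_sd = stats::sd(residuals),
                   trait = "trait", stratum = "all") {
  stopifnot(length(residuals) == nrow(profile))
  if (stats::var(profile$F_ROH) == 0) stop("F_ROH has zero variance")
  df <- data.frame(e = residuals, F_ROH = profile$F_ROH)
  if (include_f_outside) {
    df$F_outsideROH <- profile$F_outsideROH
    df <- df[stats::complete.cases(df), , drop = FALSE]
    fit <- stats::lm(e ~ F_ROH + F_outsideROH, data = df)
  } else {
    fit <- stats::lm(e ~ F_ROH, data = df)
  }
  out <- id_estimate_row(fit, "F_ROH", trait, stratum, trait_sd, nrow(df))
  if (include_f_outside)
    attr(out, "f_outside") <-
      id_estimate_row(fit, "F_outsideROH", trait, stratum, trait_sd, nrow(df))
  out
}

#' Bivariate conditioning of F_ROH on F_GRM
#'
#' Joint least squares `e' ~ F_ROH + F_GRM`, reporting both conditional
#' coefficients. If autozygous rare recessive variants inside ROH drive the
#' depression, `|beta_FROH|FGRM|` exceeds `|beta_FGRM|FROH|`; homozygosity
#' of common variants would show the reverse. Errors out when the two
#' exposures are numerically collinear.
#'
#' @param residuals step-1 residual vector.
#' @param profile data.frame with `F_ROH` and `F_GRM` aligned to residuals.
#' @param trait label carried into the output.
#' @return two-row data.frame with terms `F_ROH` and `F_GRM`.
#' @export
fit_bivariate <- function(residuals, profile, trait = "trait") {
  stopifnot(all(c("F_ROH", "F_GRM") %in% names(profile)))
  r <- stats::cor(profile$F_ROH, profile$F_GRM)
  if (!is.finite(r) || abs(r) > 0.999)
    stop("F_ROH and F_GRM are collinear (|r| = ",
         formatC(abs(r), digits = 4), "); fit univariate models instead")
  df <- data.frame(e = residuals, F_ROH = profile$F_ROH,
                   F_GRM = profile$F_GRM)
  fit <- stats::lm(e ~ F_ROH + F_GRM, data = df)
  sdr <- stats::sd(residuals)
  rbind(id_estimate_row(fit, "F_ROH", trait, "bivariate", sdr, nrow(df)),
        id_estimate_row(fit, "F_GRM", trait, "bivariate", sdr, nrow(df)))
}

#' Stratified two-step inbreeding-depression fit
#'
#' Runs the full two-step pipeline within each stratum: sex strata use the
#' trait's usual covariate spec; luminosity strata (site night-light below
#' vs at/above the cutoff) drop `night_light` from the covariates and add
#' `site` to absorb site confounding. Standardization uses the
#' within-stratum trait SD. Strata smaller than `min_n` are skipped with a
#' warning.
#'
#' @param trait trait column name.
#' @param samples sample table including the trait and covariates.
#' @param profile inbreeding profile aligned with `samples`.
#' @param covariates covariate spec for the trait (character vector).
#' @param strata `"sex"` or `"luminosity"`.
#' @param luminosity_cutoff night-light cutoff (default 5).
#' @param A optional GRM for step 1 (NULL = OLS step 1).
#' @param min_n minimum stratum size (default 50).
#' @param include_f_outside passed to [fit_id()].
#' @return data.frame of `id_estimate` rows, one per stratum.
#' @export
fit_stratified <- function(trait, samples, profile, covariates,
                           strata = c("sex", "luminosity"),
                           luminosity_cutoff = 5, A = NULL, min_n = 50,
                           include_f_outside = "F_outsideROH" %in% names(profile)) {
  strata <- match.arg(strata)
  if (strata == "sex") {
    groups <- split(seq_len(nrow(samples)), samples$sex)
    covs <- setdiff(covariates, "sex")
  } else {
    lab <- ifelse(samples$night_light < luminosity_cutoff,
                  sprintf("luminosity<%g", luminosity_cutoff),
                  sprintf("luminosity>=%g", luminosity_cutoff))
    groups <- split(seq_len(nrow(samples)), lab)
    covs <- union(setdiff(covariates, "night_light"), "site")
  }
  if (length(groups) == 0) stop("no strata found")
  out <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) < min_n) {
      warning("stratum '", g, "' has ", length(idx), " samples (< ", min_n,
              "); skipped")
      next
    }
    s <- samples[idx, , drop = FALSE]
    d <- build_design(trait, s, covs)
    Ai <- if (is.null(A)) NULL else A[idx, idx, drop = FALSE][d$rows, d$rows]
    step1 <- fit_polygenic(d$y, d$X, Ai)
    prof <- profile[idx, , drop = FALSE][d$rows, , drop = FALSE]
    out[[g]] <- fit_id(step1$residuals, prof,
                       include_f_outside = include_f_outside,
                       trait_sd = stats::sd(d$y), trait = trait, stratum = g)
  }
  do.call(rbind, out)
}

#' Test whether the F_ROH effect differs between two strata
#'
#' ANCOVA-style interaction test on the pooled residuals:
#' `e' = mu + b F_ROH + g group + delta (F_ROH x group) + e`; `delta` is
#' the between-group difference in the inbreeding-depression slope.
#'
#' @param residuals pooled step-1 residuals.
#' @param profile inbreeding profile aligned to `residuals`.
#' @param group two-level factor/vector aligned to `residuals`.
#' @return one-row data.frame: delta, se, p, plus the group labels.
#' @export
compare_strata <- function(residuals, profile, group) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("group indicator must have two levels")
  if (nlevels(g) > 2) stop("exactly two groups are supported")
  df <- data.frame(e = residuals, F_ROH = profile$F_ROH, g = g)
  fit <- stats::lm(e ~ F_ROH * g, data = df)
  sm <- summary(fit)$coefficients
  term <- grep("^F_ROH:", rownames(sm), value = TRUE)
  data.frame(group_a = levels(g)[1], group_b = levels(g)[2],
             delta = sm[term, "Estimate"], se = sm[term, "Std. Error"],
             p = sm[term, "Pr(>|t|)"], n = nrow(df),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U comparison of two sets of standardized effects
#'
#' Treats each trait's standardized effect as one observation per set.
#' Uses the exact permutation distribution of U (mid-ranks for ties) when
#' full enumeration is tractable, otherwise the normal approximation with
#' tie correction. Two-sided.
#'
#' @param betas_a,betas_b numeric vectors (each of length >= 2).
#' @param max_enum enumeration budget: exact when `choose(na+nb, na)` is at
#'   most this (default 2e5, covering sets up to about 9+9).
#' @return list: `U` (statistic for the first set), `p`, `method`.
#' @export
compare_beta_sets <- function(betas_a, betas_b, max_enum = 2e5) {
  if (length(betas_a) < 2 || length(betas_b) < 2)
    stop("each set needs at least 2 values")
  na <- length(betas_a); nb <- length(betas_b)
  pooled <- c(betas_a, betas_b)
  rk <- rank(pooled)  # mid-ranks for ties
  U_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (choose(na + nb, na) <= max_enum) {
    combs <- utils::combn(na + nb, na)
    Us <- colSums(matrix(rk[combs], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    n <- na + nb
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U_obs - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = U_obs, p = min(1, p), method = method)
}

#' Predicted trait change at a given inbreeding coefficient
#'
#' The conventional reporting scale: `beta_FROH * F`, e.g. the expected
#' change in the offspring of second cousins at `F = 1/64`
#' ([SECOND_COUSIN_F]).
#'
#' @param estimate an `id_estimate` row from [fit_id()] (or a bare beta).
#' @param F inbreeding coefficient (default 1/64).
#' @return trait-unit change.
#' @export
predicted_change <- function(estimate, F = SECOND_COUSIN_F) {
  beta <- if (is.data.frame(estimate)) estimate$beta else as.numeric(estimate)
  beta * F
}
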