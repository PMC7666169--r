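#' Configuration of a synthetic inbred cohort
#'
#' Describes every knob of the simulated world: marker map, per-individual
#' autozygosity (homozygous-by-descent, HBD, segments), and a trait built
#' from a locus-level additive + directional-dominance model with covariate
#' effects, a polygenic term and residual noise. Under directional dominance
#' the expected change of the trait mean with inbreeding coefficient F is
#' `-2 F sum(d_i p_i q_i)` — the closed form used as a ground-truth oracle
#' (see [expected_depression()]).
#'
#' @param n_individuals number of samples.
#' @param chromosome_lengths bp length of each (autosomal) chromosome.
#' @param snp_spacing_bp mean inter-SNP spacing; markers are placed as a
#'   Poisson process with this mean gap.
#' @param allele_freq_law function(n) drawing B-allele frequencies in (0,1);
#'   default uniform on \[0.05, 0.5\].
#' @param f_target_law function(n) drawing per-individual target inbreeding
#'   coefficients in \[0, 1); default exponential with mean 0.01 capped at
#'   0.5, mimicking a cohort where most people carry little recent
#'   autozygosity and a minority carry a lot.
#' @param hbd_length_law function(n) drawing HBD segment lengths in bp;
#'   default exponential with mean 3 Mb, long enough that most segments
#'   clear the conventional 1.5 Mb F_ROH threshold.
#' @param n_causal_loci number of trait loci.
#' @param additive_effect_a additive effect a: genotypic values are
#'   (-a, d_i, +a) for B-allele counts (0, 1, 2).
#' @param dominance_mean_d mean of the per-locus dominance deviation d_i.
#' @param dominance_sd_d SD of d_i around its mean (0 = all loci identical).
#' @param causal_maf_range interval of allele frequencies from which causal
#'   loci are sampled.
#' @param covariate_effects named numeric vector of per-unit covariate
#'   effects added to the trait (names must match covariate columns).
#' @param sex_specific_beta optional `c(male = , female = )` effect applied
#'   directly on the true inbreeding coefficient; when set it replaces the
#'   locus-level dominance term so the planted sex-specific effect is exact.
#' @param polygenic_variance,residual_variance variance components
#'   (trait units squared).
#' @param missing_rate genotype missingness rate (default 0).
#' @param n_sites number of recruitment sites for the covariate generator.
#' @param trait_mean baseline mean M0 of the trait.
#' @param seed integer seed; all `simulate_*` stages derive their own
#'   stream from it, so a config is fully reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals,
                       chromosome_lengths = rep(136363636, 22),
                       snp_spacing_bp = 10000,
                       allele_freq_law = function(n) stats::runif(n, 0.05, 0.5),
                       f_target_law = function(n) pmin(stats::rexp(n, 1 / 0.01), 0.5),
                       hbd_length_law = function(n) stats::rexp(n, 1 / 3e6),
                       n_causal_loci = 100,
                       additive_effect_a = 0,
                       dominance_mean_d = 0.5,
                       dominance_sd_d = 0,
                       causal_maf_range = c(0.05, 0.5),
                       covariate_effects = c(sex = 0, age = 0),
                       sex_specific_beta = NULL,
                       polygenic_variance = 1,
                       residual_variance = 1,
                       missing_rate = 0,
                       n_sites = 6,
                       trait_mean = 0,
                       seed = 1) {
  if (length(chromosome_lengths) == 0) stop("at least one chromosome required")
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  if (polygenic_variance < 0 || residual_variance < 0)
    stop("variance components must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  if (!is.null(sex_specific_beta)) {
    sex_specific_beta <- unlist(sex_specific_beta)
    if (length(sex_specific_beta) != 2)
      stop("sex_specific_beta must be length 2 (male, female)")
    if (is.null(names(sex_specific_beta)))
      names(sex_specific_beta) <- c("male", "female")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    chromosome_lengths = as.numeric(chromosome_lengths),
    snp_spacing_bp = snp_spacing_bp,
    allele_freq_law = allele_freq_law,
    f_target_law = f_target_law,
    hbd_length_law = hbd_length_law,
    n_causal_loci = as.integer(n_causal_loci),
    additive_effect_a = additive_effect_a,
    dominance_mean_d = dominance_mean_d,
    dominance_sd_d = dominance_sd_d,
    causal_maf_range = causal_maf_range,
    covariate_effects = covariate_effects,
    sex_specific_beta = sex_specific_beta,
    polygenic_variance = polygenic_variance,
    residual_variance = residual_variance,
    missing_rate = missing_rate,
    n_sites = as.integer(n_sites),
    trait_mean = trait_mean,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Fan a global seed out to a fixed per-stage stream (kept < 2^31).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Simulate a marker map
#'
#' Markers are dropped along each chromosome as a Poisson process with mean
#' gap `snp_spacing_bp`; positions are 1-based and strictly increasing.
#' B-allele frequencies come from `allele_freq_law`.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `allele_A`, `allele_B`, `freq_B`.
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "variants"))
  out <- vector("list", length(config$chromosome_lengths))
  for (ch in seq_along(config$chromosome_lengths)) {
    L <- config$chromosome_lengths[ch]
    n_exp <- ceiling(L / config$snp_spacing_bp * 1.3) + 10
    gaps <- stats::rexp(n_exp, 1 / config$snp_spacing_bp)
    pos <- floor(cumsum(gaps)) + 1
    pos <- unique(pos[pos <= L])
    out[[ch]] <- data.frame(chrom = as.character(ch), pos = pos)
  }
  v <- do.call(rbind, out)
  v$variant_id <- paste0("snp", seq_len(nrow(v)))
  v$allele_A <- "A"
  v$allele_B <- "B"
  v$freq_B <- config$allele_freq_law(nrow(v))
  if (any(v$freq_B <= 0 | v$freq_B >= 1))
    stop("allele_freq_law must draw frequencies strictly inside (0,1)")
  v[, c("variant_id", "chrom", "pos", "allele_A", "allele_B", "freq_B")]
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me + 1) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Simulate true homozygous-by-descent segments
#'
#' For each sample a target inbreeding coefficient is drawn from
#' `f_target_law`; HBD segments (length from `hbd_length_law`, uniform
#' placement, chromosome chosen proportional to length) are accumulated and
#' merged greedily until the covered genome fraction reaches the target;
#' the final draw is truncated to the remaining coverage needed, so the
#' realized coverage matches the target within 1 bp. The realized coverage
#' `f_true` — not the target — is the recorded ground truth.
#'
#' @param config a [sim_config()].
#' @param variants marker map from [simulate_variants()] (used only to check
#'   a map exists; segments live on the bp coordinate system).
#' @return object of class `true_hbd`: `$segments` (sample_id, chrom,
#'   start, end; 1-based inclusive) and `$f_true` (named numeric).
#' @export
simulate_hbd <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(variants) || is.null(variants) || nrow(variants) == 0)
    stop("a variant map is required")
  set.seed(stage_seed(config$seed, "hbd"))
  n <- config$n_individuals
  lens <- config$chromosome_lengths
  total <- sum(lens)
  targets <- config$f_target_law(n)
  if (any(targets >= 1) || any(targets < 0))
    stop("f_target_law must draw values in [0, 1)")
  ids <- sprintf("S%04d", seq_len(n))
  segs <- vector("list", n)
  f_true <- numeric(n)
  for (i in seq_len(n)) {
    if (targets[i] <= 0) next
    cur <- vector("list", length(lens))
    covered <- 0
    guard <- 0
    while (covered / total < targets[i]) {
      guard <- guard + 1
      if (guard > 10000) stop("HBD placement failed to reach target F")
      len <- max(1, round(config$hbd_length_law(1)))
      ch <- sample.int(length(lens), 1, prob = lens)
      # truncate the final draw to the remaining coverage needed, so the
      # realized F_true lands on the target within 1 bp (overlap with an
      # existing segment can only undershoot, and the loop then continues)
      needed <- ceiling(targets[i] * total - covered)
      len <- min(len, needed, lens[ch])
      start <- floor(stats::runif(1, 1, lens[ch] - len + 1 + 1))
      start <- min(start, lens[ch] - len + 1)
      m <- rbind(cur[[ch]], c(start, start + len - 1))
      cur[[ch]] <- merge_intervals(m[, 1], m[, 2])
      covered <- sum(vapply(cur, function(x)
        if (is.null(x)) 0 else sum(x[, 2] - x[, 1] + 1), 0))
    }
    keep <- which(!vapply(cur, is.null, TRUE))
    segs[[i]] <- do.call(rbind, lapply(keep, function(ch)
      data.frame(sample_id = ids[i], chrom = as.character(ch),
                 start = cur[[ch]][, 1], end = cur[[ch]][, 2])))
    f_true[i] <- covered / total
  }
  segments <- do.call(rbind, segs)
  if (is.null(segments))
    segments <- data.frame(sample_id = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0))
  names(f_true) <- ids
  structure(list(segments = segments, f_true = f_true,
                 genome_length = total, sample_ids = ids),
            class = "true_hbd")
}

#' Simulate genotypes given true HBD segments
#'
#' Inside a sample's HBD intervals every marker is homozygous, for the B
#' allele with probability `freq_B` (code 2) and otherwise for A (code 0) —
#' the two alleles are identical by descent, so a single founder allele is
#' drawn by frequency. Outside HBD, genotypes follow Hardy-Weinberg
#' proportions. Heterozygosity inside true HBD is therefore exactly zero
#' when the missing rate is zero.
#'
#' @param variants marker map from [simulate_variants()].
#' @param hbd a `true_hbd` from [simulate_hbd()].
#' @param config a [sim_config()].
#' @return a [genotype_dataset()] whose samples table holds simulated
#'   covariates (sex, age, site, SES.Q, night_light, edu, occu).
#' @export
simulate_genotypes <- function(variants, hbd, config) {
  stopifnot(inherits(config, "sim_config"), inherits(hbd, "true_hbd"))
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- length(hbd$sample_ids)
  m <- nrow(variants)
  p <- variants$freq_B
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) g[, j] <- stats::rbinom(n, 2L, p[j])
  if (nrow(hbd$segments) > 0) {
    idx <- split(seq_len(nrow(hbd$segments)), hbd$segments$sample_id)
    for (sid in names(idx)) {
      i <- match(sid, hbd$sample_ids)
      sg <- hbd$segments[idx[[sid]], , drop = FALSE]
      inroh <- rep(FALSE, m)
      for (k in seq_len(nrow(sg))) {
        inroh <- inroh | (variants$chrom == sg$chrom[k] &
                          variants$pos >= sg$start[k] &
                          variants$pos <= sg$end[k])
      }
      w <- which(inroh)
      if (length(w))
        g[i, w] <- 2L * stats::rbinom(length(w), 1L, p[w])
    }
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(g)) < config$missing_rate
    g[drop] <- NA_integer_
  }
  samples <- simulate_covariates(config, hbd$sample_ids)
  genotype_dataset(g, variants, samples)
}

#' Simulate sample covariates
#'
#' Mirrors a multi-site epidemiological cohort: sex (Bernoulli 0.5), age
#' (uniform 40-60 y), recruitment site with a per-site night-light
#' intensity scalar (half the sites below 5 units, half above, so
#' urbanization strata are non-empty), SES quintile, education (1-4) and
#' occupation (1-5) categories.
#'
#' @param config a [sim_config()].
#' @param sample_ids character vector of ids.
#' @return data.frame of covariates.
#' @export
simulate_covariates <- function(config, sample_ids) {
  set.seed(stage_seed(config$seed, "covariates"))
  n <- length(sample_ids)
  ns <- config$n_sites
  site_light <- ifelse(seq_len(ns) %% 2 == 1,
                       stats::runif(ns, 0, 4.5),
                       stats::runif(ns, 5.5, 40))
  site <- sample.int(ns, n, replace = TRUE)
  data.frame(
    sample_id = sample_ids,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = stats::runif(n, 40, 60),
    site = paste0("site", site),
    SES.Q = sample.int(5, n, replace = TRUE),
    night_light = round(site_light[site], 2),
    edu = sample.int(4, n, replace = TRUE),
    occu = sample.int(5, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a quantitative trait with directional dominance
#'
#' Causal loci are sampled within `causal_maf_range`; each contributes the
#' genotypic value (-a, d_i, +a) for B-allele counts (0, 1, 2). With
#' directional dominance (mean d != 0) autozygosity removes heterozygotes
#' and shifts the trait mean by `-2 F sum(d_i p_i q_i)`. Covariate effects,
#' a polygenic term and residual noise are added on top. When
#' `sex_specific_beta` is set, the dominance term is replaced by a direct
#' `beta_sex * F_true` effect (additive locus effects are kept).
#'
#' @param genotypes a [genotype_dataset()].
#' @param config a [sim_config()].
#' @param covariates sample table; defaults to `genotypes$samples`.
#' @param f_true named per-sample true inbreeding coefficients (required
#'   when `sex_specific_beta` is set).
#' @param A optional GRM for a correlated polygenic term; default
#'   independent normal per sample.
#' @return numeric trait vector (one per sample) with attribute `"causal"`,
#'   a data.frame (variant_id, p, d, a) of the realized architecture.
#' @export
simulate_trait <- function(genotypes, config, covariates = NULL,
                           f_true = NULL, A = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "trait"))
  if (is.null(covariates)) covariates <- genotypes$samples
  g <- genotypes$genotypes
  n <- nrow(g)
  p <- genotypes$variants$freq_B
  eligible <- which(p >= config$causal_maf_range[1] &
                    p <= config$causal_maf_range[2])
  if (length(eligible) < config$n_causal_loci)
    stop("only ", length(eligible), " loci inside causal_maf_range (need ",
         config$n_causal_loci, ")")
  causal <- sort(sample(eligible, config$n_causal_loci))
  d <- stats::rnorm(length(causal), config$dominance_mean_d, config$dominance_sd_d)
  a <- config$additive_effect_a
  gc <- g[, causal, drop = FALSE]
  gc[is.na(gc)] <- 1L  # missing causal genotypes contribute the mid value
  add <- (gc - 1L) %*% rep(a, length(causal))  # a * (x - 1) per locus
  y <- config$trait_mean + as.numeric(add)
  if (is.null(config$sex_specific_beta)) {
    y <- y + as.numeric((gc == 1L) %*% d)
  } else {
    if (is.null(f_true)) stop("f_true required when sex_specific_beta is set")
    b <- config$sex_specific_beta
    sex <- as.character(covariates$sex)
    y <- y + ifelse(sex == "male", b[["male"]], b[["female"]]) *
      as.numeric(f_true[covariates$sample_id])
  }
  for (nm in names(config$covariate_effects)) {
    if (config$covariate_effects[[nm]] == 0) next
    if (!nm %in% names(covariates)) stop("covariate '", nm, "' not found")
    x <- covariates[[nm]]
    if (!is.numeric(x)) x <- as.numeric(factor(x)) - 1
    y <- y + config$covariate_effects[[nm]] * x
  }
  if (config$polygenic_variance > 0) {
    z <- stats::rnorm(n, 0, sqrt(config$polygenic_variance))
    if (!is.null(A)) {
      ev <- eigen(A, symmetric = TRUE)
      lam <- pmax(ev$values, 0)
      z <- as.numeric(ev$vectors %*% (sqrt(lam) * stats::rnorm(n))) *
        sqrt(config$polygenic_variance / max(mean(lam), 1e-12))
    }
    y <- y + z
  }
  y <- y + stats::rnorm(n, 0, sqrt(config$residual_variance))
  attr(y, "causal") <- data.frame(
    variant_id = genotypes$variants$variant_id[causal],
    p = p[causal], d = d, a = a)
  y
}

#' Expected inbreeding depression under directional dominance
#'
#' Closed form for the change of a trait mean in a population with
#' inbreeding coefficient F when loci combine additively:
#' `-2 F sum(d_i p_i q_i)` with `q_i = 1 - p_i`. Used as the analytic
#' oracle against which simulated cohorts are checked.
#'
#' @param F inbreeding coefficient (scalar or vector).
#' @param d per-locus dominance deviations.
#' @param p per-locus B-allele frequencies.
#' @return expected trait change in trait units.
#' @export
expected_depression <- function(F, d, p) {
  stopifnot(length(d) == length(p), all(p >= 0 & p <= 1))
  -2 * F * sum(d * p * (1 - p))
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_variants()], [simulate_hbd()],
#' [simulate_genotypes()] and [simulate_trait()]; the trait is appended to
#' the samples table as column `trait`.
#'
#' @param config a [sim_config()].
#' @return list with `data` (a [genotype_dataset()]), `hbd` (`true_hbd`),
#'   and `causal` (realized causal-locus table).
#' @export
simulate_cohort <- function(config) {
  variants <- simulate_variants(config)
  hbd <- simulate_hbd(config, variants)
  data <- simulate_genotypes(variants, hbd, config)
  y <- simulate_trait(data, config, f_true = hbd$f_true)
  data$samples$trait <- as.numeric(y)
  data$samples$F_true <- as.numeric(hbd$f_true[data$samples$sample_id])
  list(data = data, hbd = hbd, causal = attr(y, "causal"))
}
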