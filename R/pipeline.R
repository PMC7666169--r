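#' Pipeline configuration
#'
#' One object describing an end-to-end run: either a simulated cohort
#' (`sim` = arguments to [sim_config()]) or file inputs (`plink_prefix` or
#' `vcf` plus `phenotypes` TSV), the ROH-calling parameters, the F_ROH
#' length threshold and denominator, the traits and their covariate specs,
#' stratification settings, multiple-testing levels, and the output
#' directory. The single `seed` fans out to per-stage streams.
#'
#' @param sim named list of [sim_config()] arguments (or NULL).
#' @param plink_prefix,vcf,phenotypes input paths (used when `sim` is NULL).
#' @param roh a [roh_params()].
#' @param froh_threshold_mb qualifying ROH length for F_ROH (default 1.5).
#' @param genome_length_bp F_ROH denominator; default 3e9, or the summed
#'   simulated genome when `sim` is given and `genome_length_bp` is NA.
#' @param traits character vector of trait column names.
#' @param model_specs named list of covariate vectors per trait; defaults
#'   to sex + age + age2 + SES.Q + night_light + PCs for every trait.
#' @param n_pcs number of genotype PCs appended as covariates (default 0
#'   for small simulated cohorts; set 15 for the conventional analysis).
#' @param use_grm use the GRM polygenic model in step 1 (default FALSE =
#'   OLS; the GRM route is exact but O(n^3) in samples).
#' @param luminosity_cutoff night-light cutoff for urbanization strata.
#' @param n_traits_bonferroni trait count for the per-trait Bonferroni
#'   level (default 14).
#' @param alpha family-wise error level (default 0.05).
#' @param window_bp regional-scan window width (default 3e6).
#' @param do_qc apply [qc_filter()] (default TRUE).
#' @param outdir output directory.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, plink_prefix = NULL, vcf = NULL,
                            phenotypes = NULL, roh = roh_params(),
                            froh_threshold_mb = 1.5,
                            genome_length_bp = NA, traits = "trait",
                            model_specs = NULL, n_pcs = 0, use_grm = FALSE,
                            luminosity_cutoff = 5, n_traits_bonferroni = 14,
                            alpha = 0.05, window_bp = 3e6, do_qc = TRUE,
                            outdir = tempfile("rohid_run_"), seed = 1) {
  if (luminosity_cutoff < 0 || luminosity_cutoff > 63)
    stop("luminosity_cutoff must be in [0, 63]")
  if (is.null(model_specs)) {
    pcs <- if (n_pcs > 0) paste0("pc", seq_len(n_pcs)) else character(0)
    model_specs <- stats::setNames(
      rep(list(c("sex", "age", "age2", "SES.Q", "night_light", pcs)),
          length(traits)), traits)
  }
  missing_spec <- setdiff(traits, names(model_specs))
  if (length(missing_spec))
    stop("no covariate spec for trait(s): ", paste(missing_spec, collapse = ", "))
  structure(list(sim = sim, plink_prefix = plink_prefix, vcf = vcf,
                 phenotypes = phenotypes, roh = roh,
                 froh_threshold_mb = froh_threshold_mb,
                 genome_length_bp = genome_length_bp, traits = traits,
                 model_specs = model_specs, n_pcs = n_pcs, use_grm = use_grm,
                 luminosity_cutoff = luminosity_cutoff,
                 n_traits_bonferroni = n_traits_bonferroni, alpha = alpha,
                 window_bp = window_bp, do_qc = do_qc, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' simulate/load -> QC -> ROH calling -> inbreeding profile (+PCs) ->
#' per-trait two-step inbreeding-depression fits (overall, bivariate,
#' sex- and luminosity-stratified) -> regional 3-Mb window scan on the
#' first trait's residuals. All result tables are written as TSV under
#' `config$outdir` together with a JSON run manifest sufficient to
#' reproduce the run.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list: `id_results`, `bivariate`, `scan`,
#'   `profile`, `qc_report`, `manifest`, `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "rohid",
                   version = as.character(utils::packageVersion("rohid")),
                   seed = config$seed, alpha = config$alpha,
                   froh_threshold_mb = config$froh_threshold_mb,
                   roh_params = unclass(config$roh), stages = list())
  note <- function(.stage, ...) {
    manifest$stages[[.stage]] <<- list(...)
    message("[", .stage, "] ", paste(names(list(...)), unlist(list(...)),
                                     sep = "=", collapse = " "))
  }

  hbd <- NULL
  if (!is.null(config$sim)) {
    cohort <- stage("simulate", {
      args <- config$sim
      args$seed <- config$seed
      simulate_cohort(do.call(sim_config, args))
    })
    data <- cohort$data
    hbd <- cohort$hbd
    chrom_lengths <- do.call(sim_config, c(config$sim, list(seed = 1)))$chromosome_lengths
    write_truth(hbd, file.path(config$outdir, "cohort"))
    note("simulate", n = nrow(data$genotypes), m = ncol(data$genotypes))
  } else {
    data <- stage("load", {
      d <- if (!is.null(config$plink_prefix)) read_plink(config$plink_prefix)
           else if (!is.null(config$vcf)) read_vcf(config$vcf)
           else stop("no input: give sim, plink_prefix or vcf")
      if (!is.null(config$phenotypes)) {
        ph <- read_phenotypes(config$phenotypes)
        i <- match(d$samples$sample_id, ph$sample_id)
        if (all(is.na(i))) stop("no sample ids shared with ", config$phenotypes)
        d$samples <- cbind(d$samples,
                           ph[i, setdiff(names(ph), names(d$samples)),
                              drop = FALSE])
      }
      d
    })
    chrom_lengths <- tapply(data$variants$pos, data$variants$chrom, max)
    note("load", n = nrow(data$genotypes), m = ncol(data$genotypes))
  }

  qc_report <- NULL
  if (config$do_qc) {
    qc <- stage("qc", qc_filter(data))
    data <- qc$data
    qc_report <- qc$report
    utils::write.table(qc_report, file.path(config$outdir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("qc", n = nrow(data$genotypes), m = ncol(data$genotypes))
  }

  segments <- stage("call-roh", call_roh(data, config$roh))
  write_roh(segments, file.path(config$outdir, "roh.tsv"))
  note("call-roh", segments = nrow(segments))

  gl <- if (is.na(config$genome_length_bp)) {
    if (!is.null(config$sim)) sum(chrom_lengths) else 3e9
  } else config$genome_length_bp
  profile <- stage("inbreeding", {
    pr <- inbreeding_profile(data, segments, genome_length_bp = gl,
                             threshold_mb = config$froh_threshold_mb)
    if (config$n_pcs > 0) {
      pcs <- compute_pcs(data, k = config$n_pcs)
      data$samples <- cbind(data$samples, as.data.frame(pcs))
    }
    pr
  })
  utils::write.table(profile, file.path(config$outdir, "inbreeding_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("inbreeding", mean_F_ROH = signif(mean(profile$F_ROH), 4))

  A <- if (config$use_grm) stage("grm", compute_grm(data)) else NULL

  id_rows <- list(); biv_rows <- list(); first_resid <- NULL
  for (tr in config$traits) {
    rows <- stage(paste0("fit-id:", tr), {
      d <- build_design(tr, data$samples, config$model_specs[[tr]])
      Ai <- if (is.null(A)) NULL else A[d$rows, d$rows]
      s1 <- fit_polygenic(d$y, d$X, Ai)
      prof <- profile[d$rows, , drop = FALSE]
      overall <- fit_id(s1$residuals, prof, trait_sd = stats::sd(d$y),
                        trait = tr, stratum = "all")
      if (is.null(first_resid))
        first_resid <- list(resid = s1$residuals, rows = d$rows)
      biv <- tryCatch(fit_bivariate(s1$residuals, prof, trait = tr),
                      error = function(e) NULL)
      strat <- do.call(rbind, lapply(c("sex", "luminosity"), function(st)
        tryCatch(suppressWarnings(
          fit_stratified(tr, data$samples, profile,
                         config$model_specs[[tr]], strata = st,
                         luminosity_cutoff = config$luminosity_cutoff, A = A)),
          error = function(e) NULL)))
      list(id = rbind(overall, strat), biv = biv)
    })
    id_rows[[tr]] <- rows$id
    if (!is.null(rows$biv)) biv_rows[[tr]] <- rows$biv
  }
  id_results <- do.call(rbind, id_rows)
  bivariate <- if (length(biv_rows)) do.call(rbind, biv_rows) else NULL
  utils::write.table(id_results, file.path(config$outdir, "id_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bivariate))
    utils::write.table(bivariate, file.path(config$outdir, "bivariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  note("fit-id", traits = length(config$traits), rows = nrow(id_results))

  scan_res <- stage("scan", {
    windows <- make_windows(chrom_lengths, width = config$window_bp)
    long <- filter_roh(segments, config$froh_threshold_mb)
    frac <- window_roh_fraction(long, windows, data$samples$sample_id)
    resid <- rep(NA_real_, nrow(data$genotypes))
    resid[first_resid$rows] <- first_resid$resid
    keep <- !is.na(resid)
    scan_windows(resid[keep], frac[keep, , drop = FALSE], windows,
                 alpha = config$alpha)
  })
  utils::write.table(scan_res, file.path(config$outdir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  qq <- qq_points(scan_res$p[scan_res$tested])
  utils::write.table(qq, file.path(config$outdir, "qq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("scan", windows = nrow(scan_res), tested = sum(scan_res$tested),
       significant = sum(scan_res$significant, na.rm = TRUE))

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(id_results = id_results, bivariate = bivariate,
                 scan = scan_res, profile = profile, qc_report = qc_report,
                 manifest = manifest, outdir = config$outdir))
}

#' Summarize a pipeline result bundle
#'
#' Per-trait, per-stratum standardized effects with Bonferroni
#' significance asterisks (level `alpha / n_traits`), plus a one-line scan
#' summary.
#'
#' @param bundle result list from [run_pipeline()] or an output directory.
#' @param n_traits Bonferroni denominator across traits (default 14).
#' @param alpha family-wise level (default 0.05).
#' @return (invisibly) the formatted data.frame; printed as a side effect.
#' @export
summarize_pipeline <- function(bundle, n_traits = 14, alpha = 0.05) {
  if (is.character(bundle)) {
    id_path <- file.path(bundle, "id_results.tsv")
    scan_path <- file.path(bundle, "scan.tsv")
    bundle <- list(
      id_results = if (file.exists(id_path)) utils::read.delim(id_path) else NULL,
      scan = if (file.exists(scan_path)) utils::read.delim(scan_path) else NULL)
  }
  thr <- alpha / n_traits
  res <- bundle$id_results
  if (is.null(res) || nrow(res) == 0) {
    cat("trait stratum beta_std p sig\n(no results)\n")
    return(invisible(data.frame()))
  }
  out <- data.frame(trait = res$trait, stratum = res$stratum,
                    beta = signif(res$beta, 4),
                    beta_std = signif(res$beta_std, 4),
                    p = signif(res$p, 3),
                    sig = ifelse(res$p < thr, "*", ""), n = res$n)
  print(out, row.names = FALSE)
  cat(sprintf("\nper-trait Bonferroni threshold: %.3g (alpha %.2f / %d traits)\n",
              thr, alpha, n_traits))
  if (!is.null(bundle$scan) && nrow(bundle$scan) > 0) {
    cat(sprintf("regional scan: %d windows, %d tested, %d significant\n",
                nrow(bundle$scan), sum(bundle$scan$tested),
                sum(bundle$scan$significant, na.rm = TRUE)))
  }
  invisible(out)
}
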