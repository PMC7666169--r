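#' Genomic inbreeding coefficient from ROH (F_ROH)
#'
#' Fraction of the autosomal genome covered by qualifying ROH:
#' `F_ROH = sum(length of ROH > threshold) / genome length`. The
#' conventional denominator is a fixed 3 Gb autosomal length; pass the
#' summed covered length of your map to use that instead.
#'
#' @param segments ROH data.frame from [call_roh()].
#' @param sample_ids ids to report (samples without segments get 0).
#' @param genome_length_bp denominator, default 3e9.
#' @param threshold_mb qualifying-length threshold in Mb (strict).
#' @return data.frame: `sample_id`, `F_ROH`, `sum_roh_kb`, `n_roh`.
#' @export
compute_f_roh <- function(segments, sample_ids, genome_length_bp = 3e9,
                          threshold_mb = 1.5) {
  stopifnot(genome_length_bp > 0)
  if (nrow(segments) > 0 && any(segments$end_bp < segments$start_bp))
    stop("segment with negative length")
  keep <- filter_roh(segments, threshold_mb)
  len <- (keep$end_bp - keep$start_bp + 1)
  sums <- tapply(len, keep$sample_id, sum)
  cnts <- tapply(len, keep$sample_id, length)
  out <- data.frame(sample_id = sample_ids,
                    F_ROH = 0, sum_roh_kb = 0, n_roh = 0L,
                    stringsAsFactors = FALSE)
  i <- match(names(sums), sample_ids)
  ok <- !is.na(i)
  out$F_ROH[i[ok]] <- as.numeric(sums)[ok] / genome_length_bp
  out$sum_roh_kb[i[ok]] <- as.numeric(sums)[ok] / 1000
  out$n_roh[i[ok]] <- as.integer(cnts)[ok]
  out
}

#' GRM-based inbreeding coefficient (Fhat3)
#'
#' Per-sample estimator based on the correlation between uniting gametes,
#' computed from common SNPs:
#' `F_GRM = (1/N) sum_i (x_i^2 - (1+2p_i) x_i + 2 p_i^2) / (2 p_i (1-p_i))`
#' where `x_i` counts B alleles and `p_i` is the B-allele frequency. A
#' fully heterozygous sample gives exactly -1 at any frequencies; a fully
#' homozygous sample at p = 0.5 gives exactly +1. Loci with minor allele
#' frequency at or below `maf_min` are excluded; missing genotypes are
#' skipped with per-sample denominators.
#'
#' @param data a [genotype_dataset()].
#' @param freqs B-allele frequencies; default from the data. May be a
#'   vector or a samples-by-variants matrix (e.g. site-specific
#'   frequencies from [allele_freq()] with `by =`).
#' @param maf_min MAF exclusion threshold (default 0.05, strict).
#' @return named numeric vector of F_GRM per sample.
#' @export
compute_f_grm <- function(data, freqs = NULL, maf_min = 0.05) {
  g <- data$genotypes
  if (is.null(freqs)) freqs <- allele_freq(data)
  pm <- if (is.matrix(freqs)) freqs else
    matrix(freqs, nrow(g), ncol(g), byrow = TRUE)
  maf <- pmin(pm, 1 - pm)
  use <- !is.na(g) & maf > maf_min & pm > 0 & pm < 1
  if (!any(use)) stop("no usable loci after MAF filter")
  term <- (g^2 - (1 + 2 * pm) * g + 2 * pm^2) / (2 * pm * (1 - pm))
  term[!use] <- 0
  n_used <- rowSums(use)
  if (any(n_used == 0)) stop("sample(s) with zero usable loci")
  out <- rowSums(term) / n_used
  names(out) <- data$samples$sample_id
  out
}

#' Excess homozygosity outside ROH (F_outsideROH)
#'
#' Describes the homozygosity of SNPs *outside* called ROH — not an
#' inbreeding-coefficient estimator, but a probe that separates
#' common-variant homozygosity from autozygosity. With per-sample counts
#' over non-missing loci: `O'(HOM) = O(HOM) - N_SNP_ROH`,
#' `E'(HOM) = ((N - N_ROH)/N) E(HOM)`, `N' = N - N_ROH`, and the statistic
#' is `(O' - E') / (N' - E')` where `E(HOM) = sum_i (1 - 2 p_i (1 - p_i))`.
#' With no called ROH this reduces to the classic excess-homozygosity
#' coefficient `(O - E)/(N - E)`.
#'
#' @param data a [genotype_dataset()].
#' @param segments ROH data.frame for these samples (may be empty).
#' @param freqs B-allele frequencies; default computed from the data.
#' @return named numeric vector; `NA` (with a warning) where the
#'   denominator `N' - E'` is degenerate.
#' @export
compute_f_outside_roh <- function(data, segments, freqs = NULL) {
  g <- data$genotypes
  v <- data$variants
  if (is.null(freqs)) freqs <- allele_freq(data)
  n <- nrow(g)
  out <- rep(NA_real_, n)
  names(out) <- data$samples$sample_id
  ehom_term <- 1 - 2 * freqs * (1 - freqs)
  seg_by <- if (nrow(segments)) split(segments, segments$sample_id) else list()
  for (r in seq_len(n)) {
    gi <- g[r, ]
    ok <- !is.na(gi)
    N <- sum(ok)
    O <- sum(gi[ok] != 1L)
    E <- sum(ehom_term[ok])
    inroh <- rep(FALSE, ncol(g))
    sg <- seg_by[[data$samples$sample_id[r]]]
    if (!is.null(sg)) {
      for (k in seq_len(nrow(sg)))
        inroh <- inroh | (v$chrom == sg$chrom[k] & v$pos >= sg$start_bp[k] &
                          v$pos <= sg$end_bp[k])
    }
    N_roh <- sum(inroh & ok)
    N_snp_roh <- sum(inroh & ok & gi != 1L)
    O2 <- O - N_snp_roh
    E2 <- (N - N_roh) / N * E
    N2 <- N - N_roh
    if (abs(N2 - E2) < 1e-12) {
      warning("degenerate denominator (N' = E') for sample ",
              data$samples$sample_id[r])
      next
    }
    out[r] <- (O2 - E2) / (N2 - E2)
  }
  out
}

#' Genomic relationship matrix
#'
#' Frequency-standardized GRM:
#' `A[j,k] = (1/N) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1 - p_i))`,
#' with monomorphic (and sub-MAF) loci excluded and missing genotypes
#' handled by per-pair denominators.
#'
#' @param data a [genotype_dataset()].
#' @param freqs B-allele frequencies; default from the data.
#' @param maf_min MAF exclusion threshold (default 0.05, strict).
#' @return symmetric samples-by-samples matrix.
#' @export
compute_grm <- function(data, freqs = NULL, maf_min = 0.05) {
  g <- data$genotypes
  if (nrow(g) < 2) stop("GRM needs at least 2 samples")
  if (is.null(freqs)) freqs <- allele_freq(data)
  maf <- pmin(freqs, 1 - freqs)
  use <- which(!is.na(maf) & maf > maf_min)
  if (!length(use)) stop("no polymorphic loci above the MAF threshold")
  gs <- g[, use, drop = FALSE]
  p <- freqs[use]
  w <- sweep(gs, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(w)
  w[!obs] <- 0
  A <- tcrossprod(w) / tcrossprod(obs * 1)
  dimnames(A) <- list(data$samples$sample_id, data$samples$sample_id)
  A
}

# greedy LD pruning on squared genotype correlation, PLINK-style windows
ld_prune <- function(data, window = 50, step = 5, r2_max = 0.2) {
  g <- data$genotypes
  keep <- rep(TRUE, ncol(g))
  for (ch in unique(data$variants$chrom)) {
    cols <- which(data$variants$chrom == ch)
    start <- 1
    while (start <= length(cols)) {
      idx <- cols[start:min(start + window - 1, length(cols))]
      idx <- idx[keep[idx]]
      if (length(idx) > 1) {
        cc <- suppressWarnings(stats::cor(g[, idx, drop = FALSE],
                                          use = "pairwise.complete.obs"))
        cc[is.na(cc)] <- 0
        for (a in seq_len(length(idx) - 1)) {
          if (!keep[idx[a]]) next
          drop <- which(cc[a, ] ^ 2 > r2_max)
          drop <- drop[drop > a & keep[idx[drop]]]
          keep[idx[drop]] <- FALSE
        }
      }
      start <- start + step
    }
  }
  keep
}

#' Genotype principal components
#'
#' Top-k eigenvectors of the GRM, computed on common variants after greedy
#' LD pruning (window 50 SNPs, step 5, r-squared > 0.2 removed — the
#' conventional defaults; configurable). Coordinates are eigenvectors
#' scaled by the root eigenvalue, with a deterministic sign convention
#' (the largest-magnitude loading of each PC is positive).
#'
#' @param data a [genotype_dataset()].
#' @param k number of components (default 15; `k = 0` gives no columns).
#' @param maf_min MAF threshold for the underlying GRM.
#' @param prune apply LD pruning before the GRM (default TRUE).
#' @return n-by-k matrix with columns `pc1..pck`.
#' @export
compute_pcs <- function(data, k = 15, maf_min = 0.05, prune = TRUE) {
  n <- nrow(data$genotypes)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  if (k == 0)
    return(matrix(numeric(0), n, 0, dimnames = list(data$samples$sample_id, NULL)))
  ds <- if (prune) subset_dataset(data, variants = ld_prune(data)) else data
  A <- compute_grm(ds, maf_min = maf_min)
  ev <- eigen(A, symmetric = TRUE)
  lam <- pmax(ev$values[seq_len(k)], 0)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  pcs <- sweep(U, 2, sqrt(lam), "*")
  dimnames(pcs) <- list(data$samples$sample_id, paste0("pc", seq_len(k)))
  pcs
}

#' Assemble the per-sample inbreeding profile
#'
#' Bundles F_ROH, F_GRM and F_outsideROH with ROH summaries — the exposure
#' table of every downstream inbreeding-depression regression.
#'
#' @param data a [genotype_dataset()].
#' @param segments ROH data.frame from [call_roh()].
#' @param genome_length_bp denominator for F_ROH (default 3e9).
#' @param threshold_mb qualifying ROH length for F_ROH (default 1.5, strict).
#' @param freqs optional allele frequencies passed to the estimators.
#' @return data.frame: sample_id, F_ROH, F_GRM, F_outsideROH, sum_roh_kb,
#'   n_roh.
#' @export
inbreeding_profile <- function(data, segments, genome_length_bp = 3e9,
                               threshold_mb = 1.5, freqs = NULL) {
  fr <- compute_f_roh(segments, data$samples$sample_id,
                      genome_length_bp, threshold_mb)
  fr$F_GRM <- as.numeric(compute_f_grm(data, freqs = freqs))
  fr$F_outsideROH <- as.numeric(
    compute_f_outside_roh(data, filter_roh(segments, threshold_mb),
                          freqs = freqs))
  fr[, c("sample_id", "F_ROH", "F_GRM", "F_outsideROH",
         "sum_roh_kb", "n_roh")]
}
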