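#' Genotype dataset container
#'
#' Bundles a samples-by-variants genotype matrix with its variant map and
#' sample metadata. Genotypes are coded 0/1/2 as the count of the B allele;
#' missing calls are `NA`. This is the common currency of all pipeline
#' stages: QC, ROH calling, inbreeding coefficients and the trait models all
#' consume a `genotype_dataset`.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `variant_id`, `chrom`,
#'   `pos` (1-based bp), `allele_A`, `allele_B` and optionally `freq_B`.
#'   Positions must be strictly increasing within each chromosome.
#' @param samples data.frame with a unique `sample_id` column plus any
#'   covariate/trait columns.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, variants, samples) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  if (nrow(genotypes) != nrow(samples))
    stop("genotype rows (", nrow(genotypes), ") != samples (", nrow(samples), ")")
  if (ncol(genotypes) != nrow(variants))
    stop("genotype columns (", ncol(genotypes), ") != variants (", nrow(variants), ")")
  if (anyDuplicated(samples$sample_id))
    stop("sample_id values must be unique")
  bad <- !(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  req <- c("variant_id", "chrom", "pos")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord)) {
    variants <- variants[ord, , drop = FALSE]
    genotypes <- genotypes[, ord, drop = FALSE]
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- variants$variant_id
  structure(list(genotypes = genotypes, variants = variants, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' B-allele frequencies from observed genotypes
#'
#' Missing genotypes are ignored (per-variant denominators). Optionally
#' computed within groups of samples (e.g. per recruitment site) and mapped
#' back to each sample's group, which matters when allele frequencies are
#' population-specific.
#'
#' @param data a [genotype_dataset()].
#' @param by optional name of a grouping column in `data$samples`; when set,
#'   a samples-by-variants matrix of group-specific frequencies is returned.
#' @return numeric vector of length n_variants (or a matrix when `by` is set),
#'   values in `[0, 1]`; `NaN` where a variant has no calls.
#' @export
allele_freq <- function(data, by = NULL) {
  g <- data$genotypes
  if (is.null(by)) {
    colMeans(g, na.rm = TRUE) / 2
  } else {
    if (!by %in% names(data$samples)) stop("no column '", by, "' in samples")
    grp <- as.character(data$samples[[by]])
    out <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
    for (lev in unique(grp)) {
      rows <- grp == lev
      out[rows, ] <- rep(colMeans(g[rows, , drop = FALSE], na.rm = TRUE) / 2,
                         each = sum(rows))
    }
    out
  }
}

#' Subset a genotype dataset
#'
#' @param data a [genotype_dataset()].
#' @param samples logical/integer index into samples (optional).
#' @param variants logical/integer index into variants (optional).
#' @return a new `genotype_dataset`.
#' @export
subset_dataset <- function(data, samples = NULL, variants = NULL) {
  g <- data$genotypes; v <- data$variants; s <- data$samples
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    s <- s[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    g <- g[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  genotype_dataset(g, v, s)
}
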