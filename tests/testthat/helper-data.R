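# Shared fixtures, built in code.

# Wrap a raw genotype matrix (samples x variants) in a genotype_dataset.
toy_dataset <- function(g, pos = NULL, chrom = NULL, freq = NULL) {
  g <- as.matrix(g)
  m <- ncol(g)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(chrom)) chrom <- rep("1", m)
  v <- data.frame(variant_id = paste0("v", seq_len(m)), chrom = chrom,
                  pos = pos, allele_A = "A", allele_B = "B",
                  stringsAsFactors = FALSE)
  if (!is.null(freq)) v$freq_B <- freq
  s <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(g))),
                  stringsAsFactors = FALSE)
  genotype_dataset(g, v, s)
}

# One-sample dataset from a genotype vector with given positions.
one_sample <- function(g, pos, chrom = "1") {
  toy_dataset(matrix(g, nrow = 1), pos = pos, chrom = rep(chrom, length(g)))
}

# Random ROH-caller instance: runs of homozygosity of varying length mixed
# with heterozygous-rich and missing-rich stretches.
random_roh_instance <- function(n_snps, seed) {
  set.seed(seed)
  pos <- cumsum(sample(c(500, 2000, 10000, 40000), n_snps, replace = TRUE,
                       prob = c(0.3, 0.4, 0.25, 0.05)))
  g <- integer(n_snps)
  i <- 1
  while (i <= n_snps) {
    run <- min(sample(c(5, 40, 120), 1, prob = c(0.5, 0.3, 0.2)), n_snps - i + 1)
    kind <- sample(c("hom", "het", "noisy"), 1, prob = c(0.45, 0.35, 0.2))
    g[i:(i + run - 1)] <- switch(kind,
      hom = sample(c(0L, 2L), run, replace = TRUE),
      het = sample(c(0L, 1L, 2L), run, replace = TRUE, prob = c(0.3, 0.5, 0.2)),
      noisy = sample(c(0L, 1L, 2L, NA), run, replace = TRUE,
                     prob = c(0.4, 0.1, 0.4, 0.1)))
    i <- i + run
  }
  one_sample(g, pos)
}

# Independent Hardy-Weinberg exact-test oracle: Wigginton-style recurrence
# over heterozygote counts (different route from the package's direct
# log-gamma enumeration).
hwe_oracle_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  het_max <- min(rare, 2 * n - rare)
  hets <- seq(rare %% 2, het_max, by = 2)
  probs <- numeric(length(hets))
  mid_i <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(hets)) {
    for (k in mid_i:(length(hets) - 1)) {
      h <- hets[k]
      hr <- (rare - h) / 2; hc <- n - h - hr
      probs[k + 1] <- probs[k] * 4 * hr * hc / ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1) {
    for (k in mid_i:2) {
      h <- hets[k]
      hr <- (rare - h) / 2; hc <- n - h - hr
      probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Convert true-HBD segments to the ROH-segment column convention.
truth_as_segments <- function(hbd) {
  s <- hbd$segments
  if (nrow(s) == 0)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  data.frame(sample_id = s$sample_id, chrom = s$chrom,
             start_bp = s$start, end_bp = s$end,
             n_snps = NA_integer_, length_kb = (s$end - s$start + 1) / 1000,
             stringsAsFactors = FALSE)
}

roh_empty_for_test <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start_bp = numeric(0), end_bp = numeric(0),
             n_snps = integer(0), length_kb = numeric(0),
             stringsAsFactors = FALSE)
}
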