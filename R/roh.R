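#' Parameters of the sliding-window ROH caller
#'
#' Defaults reproduce the classic PLINK `--homozyg` parameterization used
#' for array data: 30-SNP windows allowing 1 heterozygote and 5 missing
#' calls, a SNP is "in homozygous state" when at least 5% of the windows
#' covering it are homozygous, stretches are split at inter-SNP gaps over
#' 1000 kb, and an emitted run must have at least 30 SNPs, span at least
#' 300 kb and have density at most 30 kb/SNP. No LD pruning is assumed.
#'
#' @param min_snps_in_roh minimum SNPs per emitted segment.
#' @param min_length_kb minimum segment span in kb.
#' @param max_density_kb_per_snp maximum kb per SNP inside a segment.
#' @param max_gap_kb split a stretch where adjacent SNPs are further apart.
#' @param window_snps sliding-window size in SNPs.
#' @param window_max_het maximum heterozygous calls per homozygous window.
#' @param window_max_missing maximum missing calls per homozygous window.
#' @param window_hit_threshold minimum fraction of covering windows that
#'   must be homozygous for a SNP to be in homozygous state.
#' @return object of class `roh_params`.
#' @export
roh_params <- function(min_snps_in_roh = 30,
                       min_length_kb = 300,
                       max_density_kb_per_snp = 30,
                       max_gap_kb = 1000,
                       window_snps = 30,
                       window_max_het = 1,
                       window_max_missing = 5,
                       window_hit_threshold = 0.05) {
  p <- list(min_snps_in_roh = min_snps_in_roh,
            min_length_kb = min_length_kb,
            max_density_kb_per_snp = max_density_kb_per_snp,
            max_gap_kb = max_gap_kb,
            window_snps = window_snps,
            window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            window_hit_threshold = window_hit_threshold)
  if (any(unlist(p[c(1, 2, 3, 4, 5)]) <= 0)) stop("counts must be positive")
  if (p$window_hit_threshold <= 0 || p$window_hit_threshold > 1)
    stop("window_hit_threshold must be in (0, 1]")
  structure(p, class = "roh_params")
}

roh_empty <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start_bp = numeric(0), end_bp = numeric(0),
             n_snps = integer(0), length_kb = numeric(0),
             snp1 = character(0), snp2 = character(0),
             stringsAsFactors = FALSE)
}

# stretches of in-state SNPs -> emitted segments, shared by both callers
emit_stretches <- function(in_state, pos, ids, params, sample_id, chrom) {
  r <- rle(in_state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    # split where adjacent-SNP gap exceeds max_gap_kb
    idx <- i0:i1
    gaps <- diff(pos[idx])
    cuts <- which(gaps > params$max_gap_kb * 1000)
    seg_start <- idx[c(1, cuts + 1)]
    seg_end <- idx[c(cuts, length(idx))]
    for (s in seq_along(seg_start)) {
      a <- seg_start[s]; b <- seg_end[s]
      nsnp <- b - a + 1
      len_kb <- (pos[b] - pos[a] + 1) / 1000
      if (nsnp >= params$min_snps_in_roh &&
          len_kb >= params$min_length_kb &&
          len_kb / nsnp <= params$max_density_kb_per_snp) {
        out[[length(out) + 1]] <- data.frame(
          sample_id = sample_id, chrom = chrom,
          start_bp = pos[a], end_bp = pos[b],
          n_snps = nsnp, length_kb = len_kb,
          snp1 = ids[a], snp2 = ids[b],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else roh_empty()
}

#' Call runs of homozygosity (sliding-window algorithm)
#'
#' Per sample and chromosome: (1) every window of `window_snps` consecutive
#' SNPs is classified homozygous if it contains at most `window_max_het`
#' heterozygous and `window_max_missing` missing calls; (2) each SNP's hit
#' fraction is the share of *existing* windows covering it that are
#' homozygous (near chromosome ends the denominator shrinks to the windows
#' that actually fit — the truncation dialect); a SNP is in homozygous
#' state when the fraction reaches `window_hit_threshold`; (3) maximal
#' stretches of in-state SNPs are split at gaps over `max_gap_kb`; (4)
#' stretches passing the SNP-count, length and density floors are emitted,
#' bounded by their first and last SNP positions. Adjacent stretches
#' separated by a single out-of-state SNP are never merged.
#'
#' @param data a [genotype_dataset()], variants sorted by (chrom, pos).
#' @param params a [roh_params()].
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive), `n_snps`, `length_kb`, `snp1`, `snp2`.
#' @export
call_roh <- function(data, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  g <- data$genotypes
  v <- data$variants
  w <- params$window_snps
  res <- list()
  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    if (length(cols) < w) {
      warning("chromosome ", ch, " has fewer SNPs (", length(cols),
              ") than the window size; skipped")
      next
    }
    pos <- v$pos[cols]
    ids <- v$variant_id[cols]
    nW <- length(cols) - w + 1
    csum <- function(x) {  # rolling window sums of length w
      cs <- cumsum(c(0, x))
      cs[(w + 1):(length(cols) + 1)] - cs[1:nW]
    }
    # per-SNP covering-window bookkeeping (same for all samples)
    i <- seq_along(cols)
    lo <- pmax(1L, i - w + 1L)
    hi <- pmin(nW, i)
    denom <- hi - lo + 1L
    for (r in seq_len(nrow(g))) {
      gi <- g[r, cols]
      het <- as.numeric(!is.na(gi) & gi == 1L)
      mis <- as.numeric(is.na(gi))
      hom_win <- csum(het) <= params$window_max_het &
                 csum(mis) <= params$window_max_missing
      cw <- cumsum(c(0, hom_win))
      hits <- cw[hi + 1L] - cw[lo]
      in_state <- hits / denom >= params$window_hit_threshold
      seg <- emit_stretches(in_state, pos, ids, params,
                            data$samples$sample_id[r], ch)
      if (nrow(seg)) res[[length(res) + 1]] <- seg
    }
  }
  if (length(res)) do.call(rbind, res) else roh_empty()
}

#' Brute-force reference ROH caller
#'
#' Literal, unoptimized re-execution of the sliding-window definition with
#' explicit per-SNP enumeration of covering windows. Intended only as a
#' test oracle on small inputs; must agree exactly with [call_roh()].
#'
#' @inheritParams call_roh
#' @return same as [call_roh()].
#' @export
brute_force_roh <- function(data, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  g <- data$genotypes
  v <- data$variants
  w <- params$window_snps
  res <- list()
  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    if (length(cols) < w) {
      warning("chromosome ", ch, " has fewer SNPs (", length(cols),
              ") than the window size; skipped")
      next
    }
    pos <- v$pos[cols]
    ids <- v$variant_id[cols]
    m <- length(cols)
    nW <- m - w + 1
    for (r in seq_len(nrow(g))) {
      gi <- g[r, cols]
      hom_win <- logical(nW)
      for (j in seq_len(nW)) {
        win <- gi[j:(j + w - 1)]
        hom_win[j] <- sum(win == 1L, na.rm = TRUE) <= params$window_max_het &&
                      sum(is.na(win)) <= params$window_max_missing
      }
      in_state <- logical(m)
      for (i in seq_len(m)) {
        covering <- max(1, i - w + 1):min(nW, i)
        in_state[i] <- mean(hom_win[covering]) >= params$window_hit_threshold
      }
      seg <- emit_stretches(in_state, pos, ids, params,
                            data$samples$sample_id[r], ch)
      if (nrow(seg)) res[[length(res) + 1]] <- seg
    }
  }
  if (length(res)) do.call(rbind, res) else roh_empty()
}

#' Filter ROH segments by length
#'
#' Retains segments strictly longer than the threshold; with the default
#' 1.5 Mb this selects the long ROH conventionally attributed to recent
#' parental relatedness (the F_ROH numerator). A segment of exactly the
#' threshold length is excluded.
#'
#' @param segments data.frame from [call_roh()].
#' @param min_length_mb length threshold in Mb (strict inequality).
#' @return filtered data.frame.
#' @export
filter_roh <- function(segments, min_length_mb = 1.5) {
  if (min_length_mb < 0) stop("threshold must be non-negative")
  if (nrow(segments) == 0) return(segments)
  segments[segments$length_kb > min_length_mb * 1000, , drop = FALSE]
}

#' Write ROH segments as a PLINK `.hom`-style TSV
#'
#' @param segments data.frame from [call_roh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roh <- function(segments, path) {
  out <- data.frame(FID = segments$sample_id, IID = segments$sample_id,
                    CHR = segments$chrom,
                    SNP1 = segments$snp1, SNP2 = segments$snp2,
                    POS1 = segments$start_bp, POS2 = segments$end_bp,
                    KB = segments$length_kb, NSNP = segments$n_snps,
                    DENSITY = segments$length_kb / segments$n_snps)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export ROH segments as BED (0-based half-open)
#'
#' @param segments data.frame from [call_roh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
roh_to_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom, start = segments$start_bp - 1,
                    end = segments$end_bp, name = segments$sample_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
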