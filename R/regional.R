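#' Tile the genome into fixed-width windows
#'
#' Consecutive non-overlapping windows per chromosome (default 3 Mb). A
#' terminal remainder shorter than `min_remainder` is merged into the
#' previous window (avoiding near-empty windows with unstable ROH
#' fractions); otherwise it is kept as a shorter terminal window. A 3000-Mb
#' genome with 3 Mb-divisible chromosomes tiles into exactly 1000 windows.
#'
#' @param chromosome_lengths named or unnamed vector of bp lengths.
#' @param width window width in bp (default 3e6).
#' @param min_remainder keep a terminal remainder only if at least this
#'   long (default 1e6).
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive), `index`.
#' @export
make_windows <- function(chromosome_lengths, width = 3e6, min_remainder = 1e6) {
  if (width <= 0) stop("width must be positive")
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  chroms <- names(chromosome_lengths)
  if (is.null(chroms)) chroms <- as.character(seq_along(chromosome_lengths))
  out <- list()
  for (i in seq_along(chromosome_lengths)) {
    L <- chromosome_lengths[i]
    n_full <- L %/% width
    rem <- L - n_full * width
    starts <- seq(1, by = width, length.out = n_full)
    ends <- starts + width - 1
    if (rem > 0) {
      if (rem >= min_remainder || n_full == 0) {
        starts <- c(starts, n_full * width + 1)
        ends <- c(ends, L)
      } else {
        ends[length(ends)] <- L
      }
    }
    out[[i]] <- data.frame(chrom = chroms[i], start = starts, end = ends,
                           stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, out)
  w$index <- seq_len(nrow(w))
  w
}

#' Fraction of each window covered by each sample's ROH
#'
#' Entry `[s, w]` is the overlap in bp between sample `s`'s ROH set and
#' window `w`, divided by the window length — in `[0, 1]`. Per sample, the
#' fractions times the window lengths sum back to the sample's total ROH bp
#' (conservation).
#'
#' @param segments ROH data.frame (use [filter_roh()] first to choose the
#'   length class entering the scan).
#' @param windows data.frame from [make_windows()].
#' @param sample_ids samples to report (rows of zeros where no ROH).
#' @return samples-by-windows numeric matrix.
#' @export
window_roh_fraction <- function(segments, windows, sample_ids) {
  M <- matrix(0, length(sample_ids), nrow(windows),
              dimnames = list(sample_ids, NULL))
  if (nrow(segments) == 0) return(M)
  wlen <- windows$end - windows$start + 1
  by_chrom <- split(seq_len(nrow(windows)), windows$chrom)
  rows <- match(segments$sample_id, sample_ids)
  for (ch in intersect(unique(segments$chrom), names(by_chrom))) {
    wi_all <- by_chrom[[ch]]
    ws <- windows$start[wi_all]; we <- windows$end[wi_all]
    for (k in which(segments$chrom == ch)) {
      r <- rows[k]
      if (is.na(r)) next
      # windows are sorted within a chromosome: locate the overlap range
      j1 <- findInterval(segments$start_bp[k], ws)
      j1 <- max(j1, 1L)
      j2 <- findInterval(segments$end_bp[k], ws)
      if (j2 < 1) next
      span <- j1:j2
      ov <- pmin(we[span], segments$end_bp[k]) -
            pmax(ws[span], segments$start_bp[k]) + 1
      keep <- ov > 0
      wi <- wi_all[span[keep]]
      M[r, wi] <- M[r, wi] + ov[keep] / wlen[wi]
    }
  }
  M
}

#' Scan windows for regional ROH-burden effects
#'
#' Per window, a simple linear regression of trait residuals on the
#' window's ROH fraction with a two-sided t-test. Windows with fewer than
#' `min_informative` samples carrying any ROH there, or with a
#' zero-variance fraction column, are reported untested. Significance is
#' Bonferroni at `alpha / number of tested windows`.
#'
#' @param residuals trait residual vector (from [fit_polygenic()]).
#' @param fraction_matrix samples-by-windows matrix from
#'   [window_roh_fraction()].
#' @param windows window table (carried into the output).
#' @param alpha family-wise error level (default 0.05).
#' @param min_informative minimum samples with nonzero fraction (default 25).
#' @return data.frame: window columns + `beta`, `se`, `p`,
#'   `n_informative`, `tested`, `significant`; attribute
#'   `"bonferroni_threshold"`.
#' @export
scan_windows <- function(residuals, fraction_matrix, windows, alpha = 0.05,
                         min_informative = 25) {
  stopifnot(length(residuals) == nrow(fraction_matrix),
            nrow(windows) == ncol(fraction_matrix))
  m <- ncol(fraction_matrix)
  beta <- se <- p <- rep(NA_real_, m)
  n_inf <- integer(m)
  for (j in seq_len(m)) {
    x <- fraction_matrix[, j]
    n_inf[j] <- sum(x > 0)
    if (n_inf[j] < min_informative || stats::var(x) == 0 ||
        stats::var(residuals) == 0) next
    fit <- stats::lm.fit(cbind(1, x), residuals)
    rss <- sum(fit$residuals^2)
    dfree <- length(residuals) - 2
    sxx <- sum((x - mean(x))^2)
    beta[j] <- fit$coefficients[2]
    se[j] <- sqrt(rss / dfree / sxx)
    p[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), dfree)
  }
  tested <- !is.na(p)
  thr <- if (any(tested)) alpha / sum(tested) else NA_real_
  out <- cbind(windows,
               data.frame(beta = beta, se = se, p = p,
                          n_informative = n_inf, tested = tested,
                          significant = tested & !is.na(p) & p < thr))
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Expected vs observed quantile pairs for a QQ plot
#'
#' Sorted observed `-log10(p)` against `-log10((i - 0.5) / m)` uniform
#' quantiles.
#'
#' @param p_values numeric vector in (0, 1].
#' @return data.frame: `expected`, `observed` (both -log10 scale).
#' @export
qq_points <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  m <- length(p_values)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = sort(-log10(p_values), decreasing = TRUE))
}
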