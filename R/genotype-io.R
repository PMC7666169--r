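#' Read PLINK 1 binary genotypes
#'
#' Decodes a `.bed`/`.bim`/`.fam` triple (SNP-major mode, magic bytes
#' `0x6c 0x1b 0x01`). Genotype codes count copies of the B allele, which is
#' taken to be the `.bim` allele-1 column (PLINK's A1): hom-A1 = 2,
#' het = 1, hom-A2 = 0, missing = `NA`.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return a [genotype_dataset()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("FID", "IID", "PAT", "MAT",
                                            "SEX", "PHENO"))
  if (nrow(fam_df) == 0) stop("empty .fam file: ", fam)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "variant_id", "cm",
                                            "pos", "allele1", "allele2"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * m)
    stop(".bed size does not match .bim/.fam dimensions")
  # 2-bit codes, sample 1 in the low bits: 00=homA1, 01=missing, 10=het, 11=homA2
  code_map <- c(2L, NA_integer_, 1L, 0L)
  byte_int <- as.integer(raw[-(1:3)])
  dim(byte_int) <- c(bpv, m)
  g <- matrix(NA_integer_, n, m)
  for (shift in 0:3) {
    rows <- seq.int(shift + 1, by = 4, length.out = bpv)
    keep <- rows <= n
    codes <- (byte_int %/% 4L^shift) %% 4L
    g[rows[keep], ] <- code_map[codes[keep, , drop = FALSE] + 1L]
  }
  variants <- data.frame(variant_id = bim_df$variant_id,
                         chrom = as.character(bim_df$chrom),
                         pos = bim_df$pos,
                         allele_A = bim_df$allele2,
                         allele_B = bim_df$allele1,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = fam_df$IID,
                        sex = c("male", "female", NA)[
                          match(fam_df$SEX, c(1, 2), nomatch = 3)],
                        stringsAsFactors = FALSE)
  ds <- genotype_dataset(g, variants, samples)
  ds$variants$freq_B <- allele_freq(ds)
  ds
}

#' Write PLINK 1 binary genotypes
#'
#' Inverse of [read_plink()]: the B allele is written as `.bim` allele-1.
#'
#' @param data a [genotype_dataset()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(data, prefix) {
  g <- data$genotypes; v <- data$variants; s <- data$samples
  n <- nrow(g); m <- ncol(g)
  sex_code <- if ("sex" %in% names(s))
    ifelse(is.na(s$sex), 0L, ifelse(s$sex == "male", 1L, 2L)) else rep(0L, n)
  utils::write.table(
    data.frame(s$sample_id, s$sample_id, 0L, 0L, sex_code, -9L),
    paste0(prefix, ".fam"), sep = " ", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(v$chrom, v$variant_id, 0L, v$pos, v$allele_B, v$allele_A),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  # map 0/1/2/NA -> 2-bit codes (homA2=3, het=2, homA1=0, missing=1)
  bits <- matrix(1L, n, m)
  bits[!is.na(g) & g == 2L] <- 0L
  bits[!is.na(g) & g == 1L] <- 2L
  bits[!is.na(g) & g == 0L] <- 3L
  bpv <- ceiling(n / 4)
  padded <- matrix(1L, bpv * 4, m)
  padded[seq_len(n), ] <- bits
  bytes <- padded[seq.int(1, by = 4, length.out = bpv), , drop = FALSE] +
    4L * padded[seq.int(2, by = 4, length.out = bpv), , drop = FALSE] +
    16L * padded[seq.int(3, by = 4, length.out = bpv), , drop = FALSE] +
    64L * padded[seq.int(4, by = 4, length.out = bpv), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read genotypes from a VCF file
#'
#' Uses `VariantAnnotation` to parse VCF 4.x; the GT field is required.
#' Genotypes are coded as the count of the ALT allele (so the B allele is
#' ALT on this route); `./.` becomes `NA`. Multiallelic records are skipped
#' with a warning giving the count.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return a [genotype_dataset()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  geno_names <- rownames(VariantAnnotation::geno(
    VariantAnnotation::header(vcf)))
  if (!"GT" %in% geno_names) stop("VCF has no GT format field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_alt <- S4Vectors::elementNROWS(rr$ALT)
  multi <- n_alt != 1
  if (any(multi)) {
    warning("skipped ", sum(multi), " multiallelic record(s)")
    vcf <- vcf[!multi, ]
    rr <- rr[!multi, ]
  }
  if (nrow(vcf) == 0) stop("no biallelic records in ", path)
  gt <- VariantAnnotation::geno(vcf)$GT  # variants x samples
  codes <- vapply(strsplit(as.vector(gt), "[/|]"), function(al) {
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  g <- t(matrix(codes, nrow = nrow(gt), ncol = ncol(gt)))
  variants <- data.frame(
    variant_id = rownames(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    allele_A = as.character(rr$REF),
    allele_B = vapply(seq_along(rr$ALT), function(i)
      as.character(rr$ALT[[i]][1]), character(1)),
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(vcf), stringsAsFactors = FALSE)
  ds <- genotype_dataset(g, variants, samples)
  ds$variants$freq_B <- allele_freq(ds)
  ds
}

#' Write a minimal VCF 4.2 (GT field only)
#'
#' @param data a [genotype_dataset()]; B allele is written as ALT.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(data, path) {
  g <- data$genotypes; v <- data$variants; s <- data$samples
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g) & g == 0] <- "0/0"
  gt[!is.na(g) & g == 1] <- "0/1"
  gt[!is.na(g) & g == 2] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", s$sample_id), collapse = "\t")), con)
  lines <- paste(v$chrom, v$pos, v$variant_id, v$allele_A, v$allele_B,
                 ".", "PASS", ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: the p-value is the total probability, under the
#' exact conditional distribution of heterozygote counts given allele
#' counts, of outcomes no more probable than the observed one (no mid-p
#' adjustment).
#'
#' @param n_het heterozygote count.
#' @param n_hom1,n_hom2 the two homozygote counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # log P(het) up to a constant: multinomial genotype prob given allele counts
  lp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2          # rare-allele homozygotes
    hc <- n - h - hr                # common-allele homozygotes
    h * log(2) + lgamma(n + 1) - lgamma(h + 1) - lgamma(hr + 1) - lgamma(hc + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Apply marker and sample quality-control filters
#'
#' Order of application: non-autosomal variants dropped first (optional),
#' then samples with high missingness, then variant filters (missingness,
#' minor allele frequency, Hardy-Weinberg exact test) computed on the
#' retained samples. Defaults are the conventional array-QC thresholds:
#' variant call-missingness > 0.01, MAF < 0.01, HWE exact p < 5e-4, sample
#' missingness > 0.02.
#'
#' @param data a [genotype_dataset()].
#' @param var_missing_max,maf_min,hwe_p_min,sample_missing_max thresholds.
#' @param autosomes_only drop chromosomes outside 1..22 (with a warning).
#' @return list with `data` (filtered dataset) and `report` (data.frame of
#'   removal counts per rule).
#' @export
qc_filter <- function(data, var_missing_max = 0.01, maf_min = 0.01,
                      hwe_p_min = 5e-4, sample_missing_max = 0.02,
                      autosomes_only = TRUE) {
  if (nrow(data$genotypes) == 0 || ncol(data$genotypes) == 0)
    stop("empty dataset")
  report <- data.frame(rule = character(0), removed = integer(0))
  add <- function(rule, k) rbind(report, data.frame(rule = rule, removed = k))

  if (autosomes_only) {
    chrom <- sub("^chr", "", as.character(data$variants$chrom))
    auto <- chrom %in% as.character(1:22)
    if (any(!auto)) {
      warning("dropping ", sum(!auto), " non-autosomal variant(s)")
      data <- subset_dataset(data, variants = auto)
      data$variants$chrom <- sub("^chr", "", as.character(data$variants$chrom))
    }
    report <- add("non_autosomal", sum(!auto))
  }

  smiss <- rowMeans(is.na(data$genotypes))
  keep_s <- smiss <= sample_missing_max
  report <- add("sample_missingness", sum(!keep_s))
  if (!any(keep_s)) stop("all samples removed by missingness filter")
  data <- subset_dataset(data, samples = keep_s)

  g <- data$genotypes
  vmiss <- colMeans(is.na(g))
  fail_miss <- vmiss > var_missing_max
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  fail_maf <- maf < maf_min
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    hwe_exact_p(sum(x == 1, na.rm = TRUE), sum(x == 0, na.rm = TRUE),
                sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  fail_hwe <- hwe_p < hwe_p_min
  report <- add("variant_missingness", sum(fail_miss))
  report <- add("maf", sum(fail_maf & !fail_miss))
  report <- add("hwe", sum(fail_hwe & !fail_miss & !fail_maf))
  keep_v <- !(fail_miss | fail_maf | fail_hwe)
  if (!any(keep_v)) {
    print(report)
    stop("all variants removed by QC filters")
  }
  data <- subset_dataset(data, variants = keep_v)
  data$variants$freq_B <- allele_freq(data)
  list(data = data, report = report)
}

#' Remove one sample of each highly related pair
#'
#' Takes a precomputed pairwise kinship/IBD table (computing IBD itself is
#' out of scope here) and drops the second member of every pair whose
#' proportion-IBD exceeds the threshold — the conventional duplicate screen.
#'
#' @param data a [genotype_dataset()].
#' @param kinship data.frame with columns `id1`, `id2`, `pihat`.
#' @param pihat_max threshold above which a pair is considered duplicate.
#' @return filtered [genotype_dataset()].
#' @export
filter_related <- function(data, kinship, pihat_max = 0.8) {
  stopifnot(all(c("id1", "id2", "pihat") %in% names(kinship)))
  drop <- character(0)
  for (i in seq_len(nrow(kinship))) {
    if (kinship$pihat[i] > pihat_max &&
        !(kinship$id1[i] %in% drop) && !(kinship$id2[i] %in% drop))
      drop <- c(drop, kinship$id2[i])
  }
  if (length(drop) == 0) return(data)
  subset_dataset(data, samples = !(data$samples$sample_id %in% drop))
}

#' Write / read a phenotype-covariate table (TSV with header)
#'
#' @param samples data.frame with `sample_id` plus trait/covariate columns.
#' @param path file path.
#' @return `path` invisibly (write); data.frame (read).
#' @export
write_phenotypes <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export simulated HBD truth
#'
#' Writes `<prefix>.truth.tsv` (sample_id, F_true) and `<prefix>.truth.bed`
#' with the true autozygous intervals in BED convention (0-based half-open).
#'
#' @param hbd a `true_hbd` from [simulate_hbd()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_truth <- function(hbd, prefix) {
  utils::write.table(
    data.frame(sample_id = names(hbd$f_true), F_true = hbd$f_true),
    paste0(prefix, ".truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = hbd$segments$chrom,
                    start = hbd$segments$start - 1,
                    end = hbd$segments$end,
                    name = hbd$segments$sample_id)
  utils::write.table(bed, paste0(prefix, ".truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
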