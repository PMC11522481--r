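# PLINK 1 binary layout: 3 header bytes (0x6c 0x1b, then 0x01 for
# variant-major storage), then ceil(n/4) bytes per variant, two bits per
# sample packed from the low-order end of each byte.
# 2-bit codes: 00 = homozygous a1, 01 = missing, 10 = het, 11 = homozygous a2.
.bed_magic <- as.raw(c(0x6c, 0x1b))

# 256 x 4 lookup: dosage of allele a1 for each byte value and in-byte slot
.bed_decode_lut <- local({
  map <- c(2L, NA_integer_, 1L, 0L)
  lut <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    for (s in 0:3) {
      lut[b + 1L, s + 1L] <- map[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L]
    }
  }
  lut
})

.bed_code_of_dosage <- function(d) {
  # inverse of the decode map; NA -> 01
  out <- integer(length(d))
  out[is.na(d)] <- 1L
  out[!is.na(d) & d == 2L] <- 0L
  out[!is.na(d) & d == 1L] <- 2L
  out[!is.na(d) & d == 0L] <- 3L
  out
}

#' Read a PLINK 1 binary genotype fileset
#'
#' Decodes a variant-major `.bed` file with its `.bim` and `.fam` sidecars
#' into a [genotype_matrix()]. Dosages count copies of the `a1` allele. When
#' `flip_to_minor` is `TRUE` (the default), any variant whose `a1` allele is
#' the major allele in the loaded samples is re-oriented (dosage mapped to
#' `2 - dosage`, alleles swapped) so that dosage always counts minor alleles;
#' the `is_flipped` metadata column records which variants were re-oriented.
#'
#' @param bed_path,bim_path,fam_path paths to the three fileset members. When
#'   only `bed_path` is given, `.bim`/`.fam` paths are derived from it.
#' @param flip_to_minor logical; orient dosages to count the minor allele.
#' @return A [genotype_matrix()] with dimensions (fam lines) x (bim lines).
#' @export
read_bed <- function(bed_path,
                     bim_path = sub("\\.bed$", ".bim", bed_path),
                     fam_path = sub("\\.bed$", ".fam", bed_path),
                     flip_to_minor = TRUE) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  n <- nrow(fam)
  d <- nrow(bim)
  samples <- fam[[2L]]

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], .bed_magic)) {
    stop("not a PLINK 1 bed file (bad magic bytes): ", bed_path)
  }
  if (raw[3L] != as.raw(0x01)) {
    stop("bed file is not in variant-major (SNP-major) mode; ",
         "individual-major files are not supported")
  }
  bpv <- ceiling(n / 4)  # bytes per variant
  payload <- raw[-(1:3)]
  if (length(payload) != bpv * d) {
    stop(sprintf("bed payload is %d bytes but %d samples x %d variants needs %d (truncated or corrupt file)",
                 length(payload), n, d, bpv * d))
  }
  bytes <- matrix(as.integer(payload), nrow = bpv, ncol = d)
  dos <- matrix(NA_integer_, n, d)
  for (slot in 1:4) {
    if (slot > n) next
    i_set <- seq.int(slot, n, by = 4L)
    byte_rows <- seq_along(i_set)
    dos[i_set, ] <- matrix(
      .bed_decode_lut[bytes[byte_rows, , drop = FALSE] + 1L, slot],
      length(i_set), d)
  }

  variants <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                         a1 = bim$a1, a2 = bim$a2, is_flipped = FALSE,
                         stringsAsFactors = FALSE)
  if (any(variants$a1 == variants$a2)) {
    stop("variant(s) with identical a1/a2 alleles; inputs must be biallelic")
  }
  G <- genotype_matrix(dos, variants, samples)
  if (flip_to_minor) G <- flip_to_minor_allele(G)
  G
}

#' Orient dosages to count minor alleles
#'
#' Flips every variant whose current effect-allele frequency exceeds 0.5:
#' dosages map to `2 - dosage`, `a1`/`a2` swap, and `is_flipped` toggles.
#'
#' @param G a [genotype_matrix()].
#' @return A re-oriented `genotype_matrix`.
#' @export
flip_to_minor_allele <- function(G) {
  nn <- colSums(!is.na(G$dosages))
  freq <- colSums(G$dosages, na.rm = TRUE) / (2 * pmax(nn, 1L))
  flip <- which(nn > 0 & freq > 0.5)
  if (length(flip) > 0) {
    G$dosages[, flip] <- 2L - G$dosages[, flip]
    tmp <- G$variants$a1[flip]
    G$variants$a1[flip] <- G$variants$a2[flip]
    G$variants$a2[flip] <- tmp
    G$variants$is_flipped[flip] <- !G$variants$is_flipped[flip]
  }
  G
}

#' Write a PLINK 1 binary genotype fileset
#'
#' Writes `G` in variant-major mode. Padding bits in the final byte of each
#' variant record are zero, so a fileset written here and read back with
#' [read_bed()] round-trips byte for byte.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @param pheno optional vector aligned with samples, written to the sixth
#'   fam column using the PLINK convention (1 = control, 2 = case); accepts
#'   either `{1,2}` codes or internal `{-1,+1}` labels. Defaults to `-9`
#'   (missing).
#' @param sex optional fam sex column (default 0 = unknown).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_bed <- function(G, prefix, pheno = NULL, sex = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- length(G$samples)
  d <- nrow(G$variants)
  paths <- c(bed = paste0(prefix, ".bed"),
             bim = paste0(prefix, ".bim"),
             fam = paste0(prefix, ".fam"))

  if (is.null(pheno)) {
    ph <- rep(-9L, n)
  } else {
    ph <- as.integer(pheno)
    if (all(ph %in% c(-1L, 1L))) ph <- ifelse(ph > 0, 2L, 1L)
    if (!all(ph %in% c(1L, 2L, -9L))) {
      stop("pheno must be coded 1/2 (PLINK) or -1/+1 (internal)")
    }
  }
  if (is.null(sex)) sex <- rep(0L, n)

  fam <- data.frame(fid = G$samples, iid = G$samples, pid = 0L, mid = 0L,
                    sex = sex, pheno = ph)
  utils::write.table(fam, paths["fam"], quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = G$variants$chrom, id = G$variants$id, cm = 0,
                    pos = G$variants$pos, a1 = G$variants$a1,
                    a2 = G$variants$a2)
  utils::write.table(bim, paths["bim"], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  bpv <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4L * bpv, ncol = d)  # pad slots stay code 00
  codes[seq_len(n), ] <- apply(G$dosages, 2L, .bed_code_of_dosage)
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, bpv, d)
  for (slot in 1:4) {
    bytes <- bytes + shift[slot] *
      codes[seq.int(slot, 4L * bpv, by = 4L), , drop = FALSE]
  }
  con <- file(paths["bed"], "wb")
  on.exit(close(con))
  writeBin(c(.bed_magic, as.raw(0x01), as.raw(as.vector(bytes))), con)
  invisible(paths)
}

#' Read a phenotype/covariate table
#'
#' Expects a header line and tab-separated columns, the first column being
#' the sample identifier. The phenotype column follows the PLINK convention
#' (1 = control, 2 = case) and is recoded to the internal -1/+1 labels.
#'
#' @param path file path.
#' @param pheno_col name of the phenotype column (default `"status"`).
#' @param covar_cols character vector of covariate column names; `NULL`
#'   selects every remaining numeric column.
#' @return A data.frame with columns `sample_id`, `y` (-1/+1) and the
#'   covariate columns.
#' @export
read_pheno_table <- function(path, pheno_col = "status", covar_cols = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!(pheno_col %in% names(tab))) {
    stop("phenotype column '", pheno_col, "' not found in ", path)
  }
  ph <- tab[[pheno_col]]
  if (!all(ph %in% c(1, 2))) {
    stop("phenotype must be coded 1 (control) / 2 (case)")
  }
  if (is.null(covar_cols)) {
    rest <- setdiff(names(tab)[-1L], pheno_col)
    covar_cols <- rest[vapply(tab[rest], is.numeric, logical(1))]
  } else {
    miss <- setdiff(covar_cols, names(tab))
    if (length(miss) > 0) {
      stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
    }
  }
  out <- data.frame(sample_id = as.character(tab[[1L]]),
                    y = ifelse(ph == 2, 1L, -1L),
                    stringsAsFactors = FALSE)
  for (cc in covar_cols) out[[cc]] <- tab[[cc]]
  attr(out, "covar_cols") <- covar_cols
  out
}

#' Extract the covariate matrix from a phenotype table
#'
#' @param pheno a phenotype table as returned by [read_pheno_table()] (or any
#'   data.frame with `sample_id`, `y` and covariate columns).
#' @return A numeric matrix with one column per covariate (possibly zero
#'   columns).
#' @export
covariate_matrix <- function(pheno) {
  covar_cols <- attr(pheno, "covar_cols")
  if (is.null(covar_cols)) {
    covar_cols <- setdiff(names(pheno), c("sample_id", "y"))
  }
  if (length(covar_cols) == 0) {
    return(matrix(numeric(0), nrow = nrow(pheno), ncol = 0))
  }
  as.matrix(pheno[, covar_cols, drop = FALSE])
}

#' Minor allele frequency of one dosage column
#'
#' @param column dosage vector in `{0,1,2,NA}`.
#' @return `min(p, 1 - p)` where `p` is the frequency of the counted allele
#'   among non-missing genotypes.
#' @export
compute_maf <- function(column) {
  ok <- !is.na(column)
  if (!any(ok)) stop("cannot compute MAF of an all-missing column")
  p <- sum(column[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of the observed
#' genotype counts against Hardy-Weinberg proportions computed from the
#' sample allele frequency. Monomorphic variants return `p = 1`.
#'
#' @param n0,n1,n2 genotype class counts (hom-major, het, hom-minor).
#' @return The p-value of the test.
#' @export
hwe_test <- function(n0, n1, n2) {
  stopifnot(n0 >= 0, n1 >= 0, n2 >= 0)
  n <- n0 + n1 + n2
  if (n < 1) stop("hwe_test needs at least one genotype")
  f <- (n1 + 2 * n2) / (2 * n)
  if (f <= 0 || f >= 1) return(1)
  expected <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  stat <- sum((c(n0, n1, n2) - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Variant quality-control parameters
#'
#' @param maf_min minimum minor allele frequency (exclusive bound).
#' @param hwe_p_min minimum Hardy-Weinberg test p-value (exclusive bound).
#' @param missing_max maximum missing-genotype fraction (exclusive bound).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(maf_min = 0.01, hwe_p_min = 1e-6, missing_max = 0.05) {
  for (v in c(maf_min, hwe_p_min, missing_max)) {
    if (!is.numeric(v) || v < 0 || v > 1) stop("QC thresholds must lie in [0,1]")
  }
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 missing_max = missing_max), class = "qc_params")
}

#' Variant quality-control filter
#'
#' A variant passes when its minor allele frequency exceeds `maf_min`, its
#' Hardy-Weinberg test p-value exceeds `hwe_p_min`, its missing fraction is
#' below `missing_max`, and both alleles are single canonical nucleobases
#' (unambiguous SNV check).
#'
#' @param G a [genotype_matrix()].
#' @param params a [qc_params()] object.
#' @return Logical mask over variants (`TRUE` = keep).
#' @export
qc_filter <- function(G, params = qc_params()) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  n <- nrow(dos)
  n0 <- colSums(dos == 0L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  nn <- n0 + n1 + n2
  miss_frac <- 1 - nn / n
  p <- ifelse(nn > 0, (n1 + 2 * n2) / (2 * pmax(nn, 1L)), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    if (nn[j] == 0) return(NA_real_)
    hwe_test(n0[j], n1[j], n2[j])
  }, numeric(1))
  snv_ok <- G$variants$a1 %in% c("A", "C", "G", "T") &
    G$variants$a2 %in% c("A", "C", "G", "T") &
    G$variants$a1 != G$variants$a2
  pass <- !is.na(maf) & maf > params$maf_min &
    !is.na(hwe_p) & hwe_p > params$hwe_p_min &
    miss_frac < params$missing_max &
    snv_ok
  unname(pass)
}
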