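#' Construct a genotype matrix
#'
#' Container for a biallelic genotype dosage matrix together with variant and
#' sample metadata. Dosages count copies of the effect allele `a1` (by
#' convention the minor allele after [read_bed()] orientation) and therefore
#' take values 0, 1, 2 or `NA` for missing genotypes.
#'
#' @param dosages integer or numeric matrix, samples in rows, variants in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param variants data.frame with one row per variant and columns `id`,
#'   `chrom`, `pos`, `a1`, `a2`; an `is_flipped` logical column is added when
#'   absent, recording whether minor-allele orientation required swapping the
#'   alleles at load time.
#' @param samples character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` and `samples`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) {
    stop("dosage entries must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad]), collapse = ", "))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "a1", "a2")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    stop("variant metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!("is_flipped" %in% names(variants))) variants$is_flipped <- FALSE
  samples <- as.character(samples)
  if (nrow(variants) != ncol(dosages)) {
    stop("variant metadata rows (", nrow(variants),
         ") do not match dosage columns (", ncol(dosages), ")")
  }
  if (length(samples) != nrow(dosages)) {
    stop("sample ids (", length(samples),
         ") do not match dosage rows (", nrow(dosages), ")")
  }
  if (anyDuplicated(samples)) {
    stop("sample ids must be unique")
  }
  if (any(variants$a1 == variants$a2)) {
    stop("a1 and a2 must differ for every variant")
  }
  dimnames(dosages) <- list(samples, variants$id)
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by variants
#'
#' @param G a [genotype_matrix()].
#' @param idx integer or logical index over variants.
#' @return A `genotype_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(G, idx) {
  genotype_matrix(G$dosages[, idx, drop = FALSE],
                  G$variants[idx, , drop = FALSE],
                  G$samples)
}

#' Subset a genotype matrix by samples
#'
#' @param G a [genotype_matrix()].
#' @param idx integer or logical index over samples, or a character vector of
#'   sample ids.
#' @return A `genotype_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(G, idx) {
  if (is.character(idx)) {
    pos <- match(idx, G$samples)
    if (anyNA(pos)) {
      stop("unknown sample id(s): ",
           paste(utils::head(idx[is.na(pos)], 5), collapse = ", "))
    }
    idx <- pos
  }
  genotype_matrix(G$dosages[idx, , drop = FALSE],
                  G$variants,
                  G$samples[idx])
}
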