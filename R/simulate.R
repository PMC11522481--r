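#' Configuration for a synthetic case-control cohort
#'
#' Parameters of the liability-threshold generative model used by
#' [simulate_genotypes()] and [simulate_phenotype()].
#'
#' @param n_samples number of individuals.
#' @param n_variants number of biallelic variants.
#' @param maf_range allele-frequency interval within (0, 0.5]; per-variant
#'   frequencies are drawn uniformly from it. The default keeps every
#'   genotype class populated at desk-scale sample sizes so that
#'   genotype-dependent scores (recessive effects in particular) are
#'   estimable.
#' @param n_causal number of causal variants (polygenicity).
#' @param h2_liability additive liability-scale heritability in `[0, 1)`.
#' @param dominance_fraction fraction of causal variants assigned a
#'   non-additive mode.
#' @param mode_weights weights over the non-additive modes
#'   (dominant, recessive, overdominant, overrecessive); normalized
#'   internally and converted to exact per-mode counts by largest-remainder
#'   rounding, so a given configuration always produces the same mode
#'   composition.
#' @param prevalence case fraction in (0, 1); cases are the samples whose
#'   realized liability falls in the top `ceil(prevalence * n)` (empirical
#'   quantile rule, exact case count).
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_variants, maf_range = c(0.1, 0.5),
                       n_causal = 0L, h2_liability = 0,
                       dominance_fraction = 0,
                       mode_weights = c(dominant = 0.25, recessive = 0.25,
                                        overdominant = 0.25,
                                        overrecessive = 0.25),
                       prevalence = 0.5, seed = 1L) {
  stopifnot(n_samples >= 1, n_variants >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_causal >= 0, n_causal <= n_variants,
            h2_liability >= 0, h2_liability < 1,
            dominance_fraction >= 0, dominance_fraction <= 1,
            prevalence > 0, prevalence < 1)
  modes <- c("dominant", "recessive", "overdominant", "overrecessive")
  w <- rep(0, 4); names(w) <- modes
  w[names(mode_weights)] <- mode_weights
  if (sum(w) > 0) w <- w / sum(w)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, n_causal = as.integer(n_causal),
                 h2_liability = h2_liability,
                 dominance_fraction = dominance_fraction,
                 mode_weights = w, prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# largest-remainder integer allocation of `total` among weights `w`
.allocate_counts <- function(total, w) {
  if (total == 0 || sum(w) == 0) return(stats::setNames(rep(0L, length(w)), names(w)))
  raw <- total * w / sum(w)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(w))
}

#' Simulate genotypes in Hardy-Weinberg proportions
#'
#' Draws a per-variant allele frequency uniformly from `maf_range` and
#' samples each genotype independently as Binomial(2, f), i.e. class
#' probabilities `((1-f)^2, 2f(1-f), f^2)`. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] with variant frequencies recorded in the
#'   metadata column `sim_maf`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  d <- cfg$n_variants
  f <- stats::runif(d, cfg$maf_range[1], cfg$maf_range[2])
  dos <- vapply(f, function(fj) stats::rbinom(n, 2L, fj), integer(n))
  bases <- c("A", "C", "G", "T")
  a2 <- sample(bases, d, replace = TRUE)
  a1 <- vapply(a2, function(b) sample(setdiff(bases, b), 1L), character(1))
  variants <- data.frame(id = sprintf("snv%05d", seq_len(d)),
                         chrom = "1", pos = 1000L * seq_len(d),
                         a1 = unname(a1), a2 = unname(a2),
                         is_flipped = FALSE, sim_maf = f,
                         stringsAsFactors = FALSE)
  samples <- sprintf("id%06d", seq_len(n))
  genotype_matrix(dos, variants, samples)
}

# mode-specific genotype encoding, standardized in-sample
.mode_encoding <- function(g, mode) {
  a <- switch(mode,
              additive = as.numeric(g),
              dominant = as.numeric(g >= 1),
              recessive = as.numeric(g == 2),
              overdominant = as.numeric(g == 1),
              overrecessive = as.numeric(g == 1))
  s <- stats::sd(a)
  if (!is.finite(s) || s == 0) return(rep(0, length(a)))
  (a - mean(a)) / s
}

#' Simulate a binary phenotype from a liability-threshold model
#'
#' Selects `n_causal` causal variants, assigns each an inheritance mode
#' (additive by default; a `dominance_fraction` of them receive
#' non-additive modes per `mode_weights`) and an effect size
#' `beta ~ N(0, h2/n_causal)` (sign forced positive for overdominant and
#' negative for overrecessive modes). The liability is
#' `L_i = sum_j beta_j a_j(g_ij) + e_i` with `a_j` the mode-specific
#' encoding standardized to mean 0, variance 1 in-sample and
#' `e ~ N(0, 1 - h2)`. Cases are the `ceil(prevalence * n)` samples with
#' the largest realized liabilities, so the case count is exact.
#'
#' Deterministic given `cfg$seed` (an offset of the genotype seed, so
#' genotype and phenotype draws come from distinct streams).
#'
#' @param G a [genotype_matrix()], typically from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return A list with `pheno` (data.frame `sample_id`, `y`) and `truth`
#'   (data.frame of causal `variant_id`, `index`, `mode`, `beta`).
#' @export
simulate_phenotype <- function(G, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  n <- length(G$samples)
  d <- nrow(G$variants)
  stopifnot(cfg$n_causal <= d)
  set.seed(cfg$seed + 1L)

  causal <- sort(sample(d, cfg$n_causal))
  n_nonadd <- round(cfg$dominance_fraction * cfg$n_causal)
  counts <- .allocate_counts(n_nonadd, cfg$mode_weights)
  modes <- c(rep(names(counts), counts),
             rep("additive", cfg$n_causal - n_nonadd))
  if (cfg$n_causal > 0) modes <- sample(modes)  # shuffle mode-to-variant map

  beta <- if (cfg$n_causal > 0) {
    stats::rnorm(cfg$n_causal, 0, sqrt(cfg$h2_liability / max(cfg$n_causal, 1)))
  } else numeric(0)
  beta[modes == "overdominant"] <- abs(beta[modes == "overdominant"])
  beta[modes == "overrecessive"] <- -abs(beta[modes == "overrecessive"])

  genetic <- rep(0, n)
  for (j in seq_along(causal)) {
    genetic <- genetic +
      beta[j] * .mode_encoding(G$dosages[, causal[j]], modes[j])
  }
  liability <- genetic + stats::rnorm(n, 0, sqrt(1 - cfg$h2_liability))
  n_case <- ceiling(cfg$prevalence * n)
  case <- rank(-liability, ties.method = "first") <= n_case
  pheno <- data.frame(sample_id = G$samples,
                      y = ifelse(case, 1L, -1L),
                      stringsAsFactors = FALSE)
  truth <- data.frame(variant_id = G$variants$id[causal], index = causal,
                      mode = modes, beta = beta, stringsAsFactors = FALSE)
  list(pheno = pheno, truth = truth, liability = liability)
}

#' Simulate a full cohort
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_phenotype()].
#'
#' @param cfg a [sim_config()].
#' @return A list with `G`, `pheno`, `truth`, `liability`.
#' @export
simulate_cohort <- function(cfg) {
  G <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(G, cfg)
  c(list(G = G), ph)
}

#' Write a cohort as a PLINK fileset plus phenotype table
#'
#' Writes `dir/<basename>.bed/.bim/.fam` and a tab-separated phenotype file
#' `dir/<basename>.pheno.tsv` (header `sample_id`, `status` with 1 =
#' control / 2 = case, plus any covariate columns), readable by
#' [read_bed()] and [read_pheno_table()].
#'
#' @param G a [genotype_matrix()].
#' @param pheno phenotype table with `sample_id` and `y` in `{-1,+1}`;
#'   additional numeric columns are written as covariates.
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @return A named character vector of the written paths.
#' @export
write_fixture <- function(G, pheno, dir, basename = "cohort") {
  stopifnot(inherits(G, "genotype_matrix"),
            all(G$samples %in% pheno$sample_id))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pheno <- pheno[match(G$samples, pheno$sample_id), , drop = FALSE]
  prefix <- file.path(dir, basename)
  paths <- write_bed(G, prefix, pheno = pheno$y)
  tab <- data.frame(sample_id = pheno$sample_id,
                    status = ifelse(pheno$y > 0, 2L, 1L))
  for (cc in setdiff(names(pheno), c("sample_id", "y"))) tab[[cc]] <- pheno[[cc]]
  ppath <- paste0(prefix, ".pheno.tsv")
  utils::write.table(tab, ppath, quote = FALSE, sep = "\t", row.names = FALSE)
  c(paths, pheno = ppath)
}
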