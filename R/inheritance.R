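.mode_levels <- c("additive", "dominant", "recessive",
                  "overdominant", "overrecessive", "null")

#' Classify the mode of inheritance from a cumulative score triplet
#'
#' The dominance position of a score triplet `(S0, S1, S2)` is
#' `theta = (S1 - S0) / (S2 - S0)`: 0.5 for a perfectly additive variant, 1
#' when the heterozygote effect matches the homozygous-minor effect
#' (dominant), and 0 when only the homozygous-minor genotype carries the
#' effect (recessive). Labels:
#'
#' * `null`: all three scores equal within `zero_tol`;
#' * `overdominant` / `overrecessive`: the heterozygote score lies outside
#'   the interval spanned by the two homozygote scores by more than the
#'   `tau_over` band (including the zero-span case), labelled by whether it
#'   lies above or below;
#' * `additive`: `|theta - 0.5| <= tau_add`;
#' * `dominant`: `theta` in `(0.5 + tau_add, 1 + tau_over]`;
#' * `recessive`: `theta` in `[-tau_over, 0.5 - tau_add)`.
#'
#' Under allele relabelling (triplet reversal) `theta` maps to `1 - theta`,
#' so dominant and recessive swap while additive, overdominant and
#' overrecessive are fixed, consistent with re-orienting the minor allele.
#' The classification is invariant to adding a constant to all three scores
#' and to positive rescaling.
#'
#' @param S numeric triplet `(S0, S1, S2)`, or a 3-column matrix /
#'   data.frame of triplets.
#' @param tau_add half-width of the additive `theta` band.
#' @param tau_over overshoot margin beyond the homozygote hull.
#' @param zero_tol absolute tolerance for "no effect".
#' @return A character vector of mode labels.
#' @export
classify_mode <- function(S, tau_add = 0.125, tau_over = 0.25,
                          zero_tol = 1e-8) {
  if (is.data.frame(S)) S <- as.matrix(S)
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  stopifnot(ncol(S) == 3)
  apply(S, 1L, function(s) {
    d1 <- s[2] - s[1]
    d2 <- s[3] - s[1]
    spread <- max(s) - min(s)
    if (spread <= zero_tol) return("null")
    if (abs(d2) <= zero_tol) {
      return(if (d1 > 0) "overdominant" else "overrecessive")
    }
    theta <- d1 / d2
    if (theta > 1 + tau_over || theta < -tau_over) {
      return(if (d1 > 0) "overdominant" else "overrecessive")
    }
    if (abs(theta - 0.5) <= tau_add) return("additive")
    if (theta > 0.5 + tau_add) return("dominant")
    "recessive"
  })
}

#' Genotype coding under an assumed inheritance model
#'
#' @param g dosage vector in `{0,1,2,NA}` (count of minor alleles).
#' @param coding one of `"additive"` (dosage as-is), `"dominant"`
#'   (`1{g >= 1}`), `"recessive"` (`1{g == 2}`), `"hetonly"` (`1{g == 1}`).
#' @return A numeric vector; missing genotypes propagate as `NA`.
#' @export
code_genotype <- function(g, coding = c("additive", "dominant", "recessive",
                                        "hetonly")) {
  coding <- match.arg(coding)
  stopifnot(all(g %in% c(0, 1, 2) | is.na(g)))
  switch(coding,
         additive = as.numeric(g),
         dominant = as.numeric(g >= 1),
         recessive = as.numeric(g == 2),
         hetonly = as.numeric(g == 1))
}

#' GWAS-based inference of the mode of inheritance
#'
#' Fits one logistic regression per genotype coding (additive, dominant,
#' recessive, heterozygote-only), each with the supplied covariates, and
#' takes the two-sided Wald p-value of the genotype term. The coding with
#' the smallest p-value gives the inferred mode; `hetonly` maps to
#' overdominant when its coefficient is positive with respect to the
#' minor-allele orientation and to overrecessive otherwise.
#'
#' @param column dosage vector in `{0,1,2,NA}` (minor-allele counts).
#' @param y labels in `{-1,+1}`.
#' @param covariates optional covariate matrix.
#' @param alpha significance level for the `significant` flag.
#' @return A list with `mode`, `p_values` (named by coding), `estimates`,
#'   `min_p` and `significant`.
#' @export
gwas_mode_infer <- function(column, y, covariates = NULL, alpha = 0.05) {
  codings <- c("additive", "dominant", "recessive", "hetonly")
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  p_values <- stats::setNames(rep(NA_real_, 4), codings)
  estimates <- stats::setNames(rep(NA_real_, 4), codings)
  for (cd in codings) {
    x <- code_genotype(column, cd)
    ok <- !is.na(x)
    X <- cbind(geno = x[ok],
               if (!is.null(covariates)) covariates[ok, , drop = FALSE])
    fit <- tryCatch(fit_logistic(X, y[ok]), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("coding '", cd, "' dropped (fit failed or did not converge)")
      next
    }
    p_values[cd] <- fit$wald$p[fit$wald$term == "geno"]
    estimates[cd] <- fit$wald$estimate[fit$wald$term == "geno"]
  }
  if (all(is.na(p_values))) stop("every genotype coding failed to fit")
  winner <- codings[which.min(p_values)]
  mode <- switch(winner,
                 additive = "additive",
                 dominant = "dominant",
                 recessive = "recessive",
                 hetonly = if (estimates["hetonly"] > 0) "overdominant"
                           else "overrecessive")
  min_p <- min(p_values, na.rm = TRUE)
  list(mode = mode, p_values = p_values, estimates = estimates,
       min_p = min_p, significant = min_p < alpha)
}

#' Concordance between two mode-of-inheritance label vectors
#'
#' @param labels_a,labels_b aligned character vectors of mode labels.
#' @param classes `"five"` keeps the full label set; `"three"` collapses
#'   overdominant into dominant and overrecessive into recessive before
#'   comparing (the additive/dominant/recessive comparison).
#' @return A list with the confusion `matrix` (rows = `labels_a`) and the
#'   `agreement` fraction (diagonal over total).
#' @export
mode_concordance <- function(labels_a, labels_b,
                             classes = c("five", "three")) {
  classes <- match.arg(classes)
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  lv <- .mode_levels
  if (classes == "three") {
    squash <- function(x) {
      x[x == "overdominant"] <- "dominant"
      x[x == "overrecessive"] <- "recessive"
      x
    }
    labels_a <- squash(labels_a)
    labels_b <- squash(labels_b)
    lv <- c("additive", "dominant", "recessive", "null")
  }
  fa <- factor(labels_a, levels = lv)
  fb <- factor(labels_b, levels = lv)
  if (anyNA(fa) || anyNA(fb)) stop("unknown mode label")
  m <- table(fa, fb, dnn = c("a", "b"))
  list(matrix = m, agreement = sum(diag(m)) / length(labels_a))
}
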