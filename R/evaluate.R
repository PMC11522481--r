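#' Covariate-adjusted pseudo-R-squared
#'
#' Nagelkerke-style likelihood-ratio index comparing a covariate-only
#' logistic model against the full model that adds the polygenic score:
#' `R2 = (1 - (L_covars/L_full)^(2/n)) / (1 - L_covars^(2/n))`, with `n` the
#' evaluation-set size. Both models are fit on a fitting set (typically the
#' validation fold) and their coefficients are frozen; the likelihoods
#' entering the formula are computed on the evaluation set. Likelihoods are
#' handled in log space and exponentiated only inside the `2/n` power, so
#' large `n` does not underflow.
#'
#' When the fitting-set arguments are omitted the evaluation set itself is
#' used for fitting, with a warning (toy usage).
#'
#' @param y evaluation-set labels in `{-1,+1}`.
#' @param pgs evaluation-set polygenic scores.
#' @param X_cov evaluation-set covariate matrix (zero columns allowed).
#' @param y_fit,pgs_fit,X_fit fitting-set counterparts.
#' @return The pseudo-R2 value (scalar).
#' @export
pseudo_r2 <- function(y, pgs, X_cov, y_fit = NULL, pgs_fit = NULL,
                      X_fit = NULL) {
  X_cov <- as.matrix(X_cov)
  if (length(unique(y)) < 2L) stop("evaluation set must contain both classes")
  if (is.null(y_fit)) {
    warning("no fitting set supplied; fitting coefficients on the evaluation set")
    y_fit <- y; pgs_fit <- pgs; X_fit <- X_cov
  }
  X_fit <- as.matrix(X_fit)
  fit_cov <- fit_logistic(X_fit, y_fit)
  fit_full <- fit_logistic(cbind(X_fit, pgs = pgs_fit), y_fit)
  ll_cov <- .loglik_pm1(linear_predictor(fit_cov, X_cov), y)
  ll_full <- .loglik_pm1(linear_predictor(fit_full, cbind(X_cov, pgs = pgs)), y)
  pseudo_r2_from_loglik(ll_cov, ll_full, length(y))
}

#' Pseudo-R-squared from log-likelihoods
#'
#' @param ll_cov log-likelihood of the covariate-only model on the
#'   evaluation set.
#' @param ll_full log-likelihood of the covariate-plus-score model.
#' @param n evaluation-set size.
#' @return `(1 - exp((2/n)(ll_cov - ll_full))) / (1 - exp((2/n) ll_cov))`.
#' @export
pseudo_r2_from_loglik <- function(ll_cov, ll_full, n) {
  if (!is.finite(ll_cov) || !is.finite(ll_full)) {
    stop("non-finite log-likelihood")
  }
  num <- 1 - exp((2 / n) * (ll_cov - ll_full))
  den <- 1 - exp((2 / n) * ll_cov)
  if (den == 0) return(ifelse(num == 0, 0, NaN))
  num / den
}

#' Odds ratio of the top score stratum
#'
#' Ranks samples by score (descending, ties broken by stable input order),
#' takes the top `ceil(q * n)` as the high-score group, and returns the odds
#' ratio of case status between that group and the remainder.
#'
#' @param pgs numeric score vector.
#' @param y labels in `{-1,+1}`.
#' @param q top fraction in (0, 1).
#' @return The odds ratio `(a/b)/(c/d)`.
#' @export
odds_ratio_top <- function(pgs, y, q) {
  stopifnot(q > 0, q < 1, length(pgs) == length(y))
  n <- length(pgs)
  top_n <- ceiling(q * n)
  ord <- order(-pgs, seq_len(n))  # stable under ties
  top <- logical(n)
  top[ord[seq_len(top_n)]] <- TRUE
  a <- sum(top & y > 0); b <- sum(top & y < 0)
  c_ <- sum(!top & y > 0); d <- sum(!top & y < 0)
  if (a == 0 || b == 0 || c_ == 0 || d == 0) {
    stop(sprintf("odds ratio undefined: zero cell in 2x2 table (a=%d b=%d c=%d d=%d)",
                 a, b, c_, d))
  }
  (a / b) / (c_ / d)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random case outranks a
#' random control, counting ties as one half.
#'
#' @param pgs numeric score vector.
#' @param y labels in `{-1,+1}`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pgs, y) {
  case <- y > 0
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(pgs)  # midranks handle ties
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated average precision over the score-ranked list: the sum of
#' `precision x recall-increment` evaluated at each distinct score
#' threshold, so tied scores are treated as a single operating point.
#'
#' @param pgs numeric score vector.
#' @param y labels in `{-1,+1}`.
#' @return AUPRC in `[0, 1]`; a constant score returns the case fraction,
#'   perfect separation returns 1.
#' @export
auprc <- function(pgs, y) {
  case <- y > 0
  n_case <- sum(case)
  if (n_case == 0) stop("AUPRC needs at least one case")
  ord <- order(-pgs, seq_along(pgs))
  s <- pgs[ord]
  hits <- cumsum(case[ord])
  k <- seq_along(s)
  # operating points: positions where the next score differs (block ends)
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- hits[ends] / ends
  rec <- hits[ends] / n_case
  sum(diff(c(0, rec)) * prec)
}

#' Held-out predictive performance of a polygenic score
#'
#' Convenience wrapper computing the covariate-adjusted pseudo-R2,
#' top-percentile odds ratios, AUC and AUPRC of a genotype-only polygenic
#' score on an evaluation set. An undefined odds ratio (zero contingency
#' cell) is reported as `NA` with a warning.
#'
#' @param y evaluation-set labels in `{-1,+1}`.
#' @param pgs evaluation-set polygenic scores.
#' @param X_cov evaluation-set covariate matrix.
#' @param y_fit,pgs_fit,X_fit fitting set for the pseudo-R2 coefficients
#'   (defaults to the evaluation set with a warning; see [pseudo_r2()]).
#' @param or_q top fractions for the odds ratios.
#' @return A list of class `eval_result` with `pseudo_r2`, `odds_ratio`
#'   (named by fraction), `auc`, `auprc`, `n`, `L_covars`, `L_full`
#'   (log-likelihoods).
#' @export
evaluate_pgs <- function(y, pgs, X_cov, y_fit = NULL, pgs_fit = NULL,
                         X_fit = NULL, or_q = c(0.01, 0.03, 0.05, 0.10)) {
  X_cov <- as.matrix(X_cov)
  if (is.null(y_fit)) {
    warning("no fitting set supplied; fitting coefficients on the evaluation set")
    y_fit <- y; pgs_fit <- pgs; X_fit <- X_cov
  }
  X_fit <- as.matrix(X_fit)
  fit_cov <- fit_logistic(X_fit, y_fit)
  fit_full <- fit_logistic(cbind(X_fit, pgs = pgs_fit), y_fit)
  ll_cov <- .loglik_pm1(linear_predictor(fit_cov, X_cov), y)
  ll_full <- .loglik_pm1(linear_predictor(fit_full, cbind(X_cov, pgs = pgs)), y)
  ors <- vapply(or_q, function(q) {
    tryCatch(odds_ratio_top(pgs, y, q), error = function(e) {
      warning("odds ratio at q=", q, " undefined: ", conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  names(ors) <- paste0("top", or_q * 100, "pct")
  structure(list(pseudo_r2 = pseudo_r2_from_loglik(ll_cov, ll_full, length(y)),
                 odds_ratio = ors,
                 auc = auc(pgs, y), auprc = auprc(pgs, y),
                 n = length(y), L_covars = ll_cov, L_full = ll_full),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result (n = %d)\n", x$n))
  cat(sprintf("  pseudo-R2: %.5f  AUC: %.4f  AUPRC: %.4f\n",
              x$pseudo_r2, x$auc, x$auprc))
  cat("  odds ratios:",
      paste(sprintf("%s = %.3f", names(x$odds_ratio), x$odds_ratio),
            collapse = ", "), "\n")
  invisible(x)
}
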