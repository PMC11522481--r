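# Logistic log-likelihood for labels in {-1,+1}: sum_i -log(1 + exp(-y_i eta_i))
.loglik_pm1 <- function(eta, y) {
  -sum(log1p(exp(-y * eta)))
}

#' Fit a logistic regression by damped Newton-Raphson
#'
#' Maximum-likelihood fit of `P(y = +1 | x) = 1 / (1 + exp(-(b0 + b'x)))` by
#' iteratively reweighted least squares with step-halving: whenever a full
#' Newton step decreases the log-likelihood the step is halved, which keeps
#' the iteration stable under near-separation. Covariates are
#' variance-standardized internally; coefficients are stored on the
#' standardized scale with the centering/scaling transform recorded, and
#' [coef()] returns them mapped back to the original scale.
#'
#' @param X numeric covariate matrix (`n` rows; zero columns allowed for an
#'   intercept-only fit).
#' @param y labels in `{-1, +1}`; both classes must be present.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param standardize variance-standardize columns before fitting.
#' @return An object of class `logistic_fit` with elements `intercept` and
#'   `coefficients` (standardized scale), `center`, `scale`,
#'   `log_likelihood`, `converged`, `iterations`, and `wald` (a data.frame of
#'   original-scale estimates, standard errors and two-sided p-values for the
#'   covariate terms).
#' @export
fit_logistic <- function(X, y, max_iter = 50L, tol = 1e-8,
                         standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || nrow(X) != length(y)) {
    stop("X rows must match length(y)")
  }
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: y contains a single class")
  }
  n <- nrow(X)
  c_ <- ncol(X)
  if (n < c_ + 1L) stop("need n >= number of covariates + 1")

  if (standardize && c_ > 0L) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
  } else {
    center <- rep(0, c_)
    scale <- rep(1, c_)
  }
  scale[!is.finite(scale) | scale == 0] <- 1  # constant columns left unscaled
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  keep <- if (c_ > 0L) apply(Xs, 2L, function(v) stats::sd(v) > 0) else logical(0)
  Xd <- cbind(`(Intercept)` = 1, Xs[, keep, drop = FALSE])

  y01 <- (y + 1) / 2
  b <- rep(0, ncol(Xd))
  eta <- drop(Xd %*% b)
  ll <- .loglik_pm1(eta, y)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(Xd, y01 - p))
    H <- crossprod(Xd, Xd * w)
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, ncol(H)), grad)
    })
    # step-halving guard
    lam <- 1
    repeat {
      b_new <- b + lam * step
      eta_new <- drop(Xd %*% b_new)
      ll_new <- .loglik_pm1(eta_new, y)
      if (ll_new >= ll - 1e-12 || lam < 2^-30) break
      lam <- lam / 2
    }
    delta <- ll_new - ll
    b <- b_new
    eta <- eta_new
    ll <- ll_new
    if (abs(delta) <= tol) {
      converged <- TRUE
      break
    }
  }

  # diverging coefficients on the standardized scale indicate separation:
  # the likelihood has no interior maximum, so the fit is not an MLE
  if (converged && length(b) > 1L && max(abs(b[-1L])) > 15) {
    converged <- FALSE
  }

  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  H <- crossprod(Xd, Xd * w)
  vcov_std <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, ncol(Xd), ncol(Xd))
  })

  coefficients <- rep(0, c_)
  names(coefficients) <- colnames(X)
  coefficients[keep] <- b[-1L]
  se_std <- rep(NA_real_, c_)
  se_std[keep] <- sqrt(diag(vcov_std))[-1L]

  est_raw <- coefficients / scale
  se_raw <- se_std / scale
  zval <- est_raw / se_raw
  terms <- colnames(X)
  if (is.null(terms) && c_ > 0L) terms <- paste0("x", seq_len(c_))
  wald <- data.frame(term = terms %||% character(0),
                     estimate = unname(est_raw), se = unname(se_raw),
                     z = unname(zval),
                     p = unname(2 * stats::pnorm(-abs(zval))),
                     stringsAsFactors = FALSE)

  structure(list(intercept = unname(b[1L]), coefficients = coefficients,
                 center = center, scale = scale, keep = keep,
                 log_likelihood = ll, converged = converged,
                 iterations = it, wald = wald, n = n),
            class = "logistic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.logistic_fit <- function(object, ...) {
  b_raw <- object$coefficients / object$scale
  b0_raw <- object$intercept - sum(b_raw * object$center)
  c(`(Intercept)` = unname(b0_raw), b_raw)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: %d covariates, log-likelihood %.4f (%s in %d iters)\n",
              length(x$coefficients), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(coef(x))
  invisible(x)
}

#' Linear predictor of a logistic fit
#'
#' @param fit a [fit_logistic()] object.
#' @param X covariate matrix with the same columns the fit was trained on.
#' @return Numeric vector `b0 + b'x` per sample (on the logit scale).
#' @export
linear_predictor <- function(fit, X) {
  stopifnot(inherits(fit, "logistic_fit"))
  X <- as.matrix(X)
  if (ncol(X) != length(fit$coefficients)) {
    stop("covariate matrix has ", ncol(X), " columns but the fit used ",
         length(fit$coefficients))
  }
  if (ncol(X) == 0L) {
    return(rep(fit$intercept, nrow(X)))
  }
  Xs <- sweep(sweep(X, 2L, fit$center, "-"), 2L, fit$scale, "/")
  drop(fit$intercept + Xs %*% fit$coefficients)
}
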