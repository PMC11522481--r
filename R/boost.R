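#' Boosting hyperparameters
#'
#' @param gamma learning rate in (0, 1].
#' @param iterations maximum number of boosting iterations `T`.
#' @param m_batch batch size for screening on wide datasets: a full scan over
#'   all variants is run at iteration 0 and every `m_batch` iterations;
#'   between full scans, selection is restricted to the `m_batch`
#'   best-scoring variants from the last full scan.
#' @param s2_clip optional non-negative bound on the homozygous-minor score
#'   relative to the homozygous-major baseline: each learner's `s2` is
#'   clamped so that `|s2 - s0| <= s2_clip`. `NULL` disables the
#'   regularization.
#' @param z_max clip bound on the absolute working response (numerical
#'   guard; see [compute_sample_state()]).
#' @param w_floor lower bound on the working weights.
#' @param full_scan_max_d batch screening is bypassed (every iteration scans
#'   all variants) when the variant count does not exceed this value.
#' @return A list of class `boost_params`.
#' @export
boost_params <- function(gamma = 0.1, iterations = 100L, m_batch = 50L,
                         s2_clip = NULL, z_max = 1e8, w_floor = 1e-10,
                         full_scan_max_d = 10000L) {
  stopifnot(gamma > 0, gamma <= 1, iterations >= 0, m_batch >= 1,
            z_max > 0, w_floor > 0)
  if (!is.null(s2_clip)) stopifnot(s2_clip >= 0)
  structure(list(gamma = gamma, iterations = as.integer(iterations),
                 m_batch = as.integer(m_batch), s2_clip = s2_clip,
                 z_max = z_max, w_floor = w_floor,
                 full_scan_max_d = as.integer(full_scan_max_d)),
            class = "boost_params")
}

#' Working responses and weights of the logistic loss
#'
#' Newton-step quantities of the logistic loss at the current score `F`:
#' `p = 1/(1+exp(-F))`, `z = 1/p` for cases and `-1/(1-p)` for controls
#' (then clipped to `|z| <= z_max`), and `w = p(1-p)` floored at `w_floor`.
#'
#' @param F numeric vector of current per-sample scores.
#' @param y labels in `{-1,+1}`.
#' @param z_max,w_floor stabilization bounds (see [boost_params()]). The
#'   default clip is a numerical guard only: an aggressive cap biases the
#'   class-wise gradient sums of badly classified samples and can make the
#'   training loss non-monotone.
#' @return A list with elements `p`, `z`, `w`.
#' @export
compute_sample_state <- function(F, y, z_max = 1e8, w_floor = 1e-10) {
  stopifnot(all(is.finite(F)), length(F) == length(y),
            all(y %in% c(-1, 1)))
  p <- stats::plogis(F)
  z <- ifelse(y > 0, 1 / p, -1 / (1 - p))
  z <- pmin(pmax(z, -z_max), z_max)
  w <- pmax(p * (1 - p), w_floor)
  list(p = p, z = z, w = w)
}

#' Per-genotype-class sufficient statistics for one variant
#'
#' Sums the working weights, weighted responses and weighted squared
#' responses within each genotype class. Samples with a missing genotype are
#' excluded from every class.
#'
#' @param column dosage vector in `{0,1,2,NA}` aligned with `state`.
#' @param state a [compute_sample_state()] list.
#' @return A list with numeric triples `W`, `U`, `Q` (indexed by genotype
#'   class 0/1/2) and integer class counts `n_k`.
#' @export
accumulate_stats <- function(column, state) {
  stopifnot(length(column) == length(state$w))
  W <- U <- Q <- numeric(3)
  n_k <- integer(3)
  wz <- state$w * state$z
  wzz <- wz * state$z
  for (k in 0:2) {
    idx <- which(!is.na(column) & column == k)
    n_k[k + 1L] <- length(idx)
    W[k + 1L] <- sum(state$w[idx])
    U[k + 1L] <- sum(wz[idx])
    Q[k + 1L] <- sum(wzz[idx])
  }
  list(W = W, U = U, Q = Q, n_k = n_k)
}

#' Closed-form additive genotype scores
#'
#' Minimizer of the weighted least squares `sum_k W_k (c + alpha k - U_k/W_k)^2`
#' over the intercept `c` and per-dosage slope `alpha`. The variant is
#' degenerate (no additive fit) when at most one genotype class carries
#' weight.
#'
#' @param stats an [accumulate_stats()] list (only `W` and `U` are used).
#' @return A list with `c`, `alpha` and a `degenerate` flag.
#' @export
solve_additive <- function(stats) {
  W <- stats$W; U <- stats$U
  denom <- W[1] * W[2] + W[2] * W[3] + 4 * W[3] * W[1]
  if (denom <= 0) {
    return(list(c = NA_real_, alpha = NA_real_, degenerate = TRUE))
  }
  cc <- ((W[2] + 4 * W[3]) * U[1] + 2 * W[3] * U[2] - W[2] * U[3]) / denom
  aa <- (-(W[2] + 2 * W[3]) * U[1] + (W[1] - W[3]) * U[2] +
           (2 * W[1] + W[2]) * U[3]) / denom
  list(c = cc, alpha = aa, degenerate = FALSE)
}

#' Non-additive genotype scores
#'
#' Per-class weighted mean of the working response, `s_k = U_k / W_k`. An
#' empty genotype class is imputed from its nearest populated class (class 2
#' from `s1`, class 0 from `s1`, class 1 from the midpoint of `s0` and
#' `s2`), which leaves the loss unchanged while keeping the score function
#' total. With `s2_clip` set, `s2` is clamped toward the homozygous-major
#' baseline so that `|s2 - s0| <= s2_clip`.
#'
#' @param stats an [accumulate_stats()] list.
#' @param s2_clip optional non-negative clamp (see [boost_params()]).
#' @return A list with `s` (numeric triple) and a `degenerate` flag (only
#'   set when every class is empty).
#' @export
solve_nonadditive <- function(stats, s2_clip = NULL) {
  W <- stats$W; U <- stats$U
  pop <- W > 0
  if (!any(pop)) {
    return(list(s = rep(NA_real_, 3), degenerate = TRUE))
  }
  s <- ifelse(pop, U / ifelse(pop, W, 1), NA_real_)
  if (!pop[2]) {
    s[2] <- if (pop[1] && pop[3]) (s[1] + s[3]) / 2 else if (pop[1]) s[1] else s[3]
  }
  if (!pop[1]) s[1] <- s[2]
  if (!pop[3]) s[3] <- s[2]
  if (!is.null(s2_clip)) {
    s[3] <- s[1] + min(max(s[3] - s[1], -s2_clip), s2_clip)
  }
  list(s = s, degenerate = FALSE)
}

#' Weighted least-squares loss of a genotype-score triple
#'
#' Computes `sum_i w_i (f(g_i) - z_i)^2` from class-level sufficient
#' statistics as `sum_k [Q_k - 2 f(k) U_k + f(k)^2 W_k]`.
#'
#' @param stats an [accumulate_stats()] list carrying `W`, `U`, `Q`.
#' @param scores numeric triple `(f(0), f(1), f(2))`.
#' @return The loss value.
#' @export
learner_loss <- function(stats, scores) {
  stopifnot(length(scores) == 3)
  sum(stats$Q - 2 * scores * stats$U + scores^2 * stats$W)
}

#' Select the variant with the smallest loss
#'
#' @param losses numeric vector of per-variant losses; degenerate or
#'   unscreened variants are marked `Inf` (or `NA`).
#' @return The index of the minimum; ties break toward the smallest index.
#' @export
select_variant <- function(losses) {
  losses[is.na(losses)] <- Inf
  if (!any(is.finite(losses))) {
    stop("no selectable variant: every screened variant is degenerate")
  }
  which.min(losses)
}

# Vectorized per-iteration screen over the active columns.
# M0/M1/M2 are n x d 0/1 indicator matrices (missing genotypes are 0 in all
# three). Returns losses plus the score triples per screened variant.
.screen_variants <- function(M0, M1, M2, active, state, model_kind, s2_clip) {
  w <- state$w
  wz <- w * state$z
  wzz <- wz * state$z
  sub <- function(M) if (length(active) == ncol(M)) M else M[, active, drop = FALSE]
  A0 <- sub(M0); A1 <- sub(M1); A2 <- sub(M2)
  W0 <- drop(crossprod(A0, w));  W1 <- drop(crossprod(A1, w));  W2 <- drop(crossprod(A2, w))
  U0 <- drop(crossprod(A0, wz)); U1 <- drop(crossprod(A1, wz)); U2 <- drop(crossprod(A2, wz))
  Q0 <- drop(crossprod(A0, wzz)); Q1 <- drop(crossprod(A1, wzz)); Q2 <- drop(crossprod(A2, wzz))

  if (model_kind == "additive") {
    denom <- W0 * W1 + W1 * W2 + 4 * W2 * W0
    ok <- denom > 0
    denom[!ok] <- 1
    cc <- ((W1 + 4 * W2) * U0 + 2 * W2 * U1 - W1 * U2) / denom
    aa <- (-(W1 + 2 * W2) * U0 + (W0 - W2) * U1 + (2 * W0 + W1) * U2) / denom
    f0 <- cc; f1 <- cc + aa; f2 <- cc + 2 * aa
    extra <- list(c = cc, alpha = aa)
  } else {
    p0 <- W0 > 0; p1 <- W1 > 0; p2 <- W2 > 0
    ok <- p0 | p1 | p2
    s0 <- ifelse(p0, U0 / pmax(W0, 1e-300), NA_real_)
    s1 <- ifelse(p1, U1 / pmax(W1, 1e-300), NA_real_)
    s2 <- ifelse(p2, U2 / pmax(W2, 1e-300), NA_real_)
    mid <- ifelse(p0 & p2, (s0 + s2) / 2, ifelse(p0, s0, s2))
    s1 <- ifelse(p1, s1, mid)
    s0 <- ifelse(p0, s0, s1)
    s2 <- ifelse(p2, s2, s1)
    if (!is.null(s2_clip)) {
      s2 <- s0 + pmin(pmax(s2 - s0, -s2_clip), s2_clip)
    }
    f0 <- s0; f1 <- s1; f2 <- s2
    extra <- list(c = rep(NA_real_, length(f0)), alpha = rep(NA_real_, length(f0)))
  }
  loss <- (Q0 - 2 * f0 * U0 + f0^2 * W0) +
    (Q1 - 2 * f1 * U1 + f1^2 * W1) +
    (Q2 - 2 * f2 * U2 + f2^2 * W2)
  loss[!ok] <- Inf
  f0[!ok] <- f1[!ok] <- f2[!ok] <- NA_real_
  list(loss = loss, f0 = f0, f1 = f1, f2 = f2,
       c = extra$c, alpha = extra$alpha, active = active)
}

#' Fit a boosted polygenic score model
#'
#' Iterative LogitBoost-style fit. The per-sample score is initialized at the
#' covariate-only logistic linear predictor. Each iteration computes the
#' working responses and weights of the logistic loss, screens variants by
#' the weighted least-squares loss of their optimal genotype-dependent
#' scores (closed form under the additive constraint, per-class weighted
#' means otherwise), selects the loss-minimizing variant, and adds its
#' scores shrunken by the learning rate to the model. A variant may be
#' selected repeatedly; its contributions accumulate.
#'
#' @param G a [genotype_matrix()].
#' @param pheno phenotype table aligned to `G` by `sample_id`, with label
#'   column `y` in `{-1,+1}` and optional covariate columns.
#' @param params a [boost_params()] object.
#' @param model_kind `"nonadditive"` (genotype-dependent score triple per
#'   learner) or `"additive"` (scores constrained to be linear in dosage).
#' @return An object of class `genoboost_model` with the covariate fit, the
#'   ordered learner table, and a per-iteration trace of training loss and
#'   log-likelihood.
#' @export
boost_fit <- function(G, pheno, params = boost_params(),
                      model_kind = c("nonadditive", "additive")) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(G, "genotype_matrix"), inherits(params, "boost_params"))
  ord <- match(G$samples, pheno$sample_id)
  if (anyNA(ord)) stop("phenotype table lacks sample(s) present in G")
  pheno <- pheno[ord, , drop = FALSE]
  y <- pheno$y
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop("phenotype must contain both classes coded -1/+1")
  }
  X_cov <- covariate_matrix(pheno)
  cov_fit <- fit_logistic(X_cov, y)
  Fvec <- linear_predictor(cov_fit, X_cov)

  n <- length(y)
  d <- nrow(G$variants)
  dos <- G$dosages
  M0 <- matrix(0, n, d); M0[!is.na(dos) & dos == 0L] <- 1
  M1 <- matrix(0, n, d); M1[!is.na(dos) & dos == 1L] <- 1
  M2 <- matrix(0, n, d); M2[!is.na(dos) & dos == 2L] <- 1

  use_batch <- d > params$full_scan_max_d
  batch_set <- seq_len(d)

  T_ <- params$iterations
  learners <- data.frame(iteration = integer(T_), variant_index = integer(T_),
                         variant_id = character(T_),
                         f0 = numeric(T_), f1 = numeric(T_), f2 = numeric(T_),
                         c = numeric(T_), alpha = numeric(T_),
                         loss = numeric(T_), stringsAsFactors = FALSE)
  trace_loss <- numeric(T_)
  trace_ll <- numeric(T_)

  for (t in seq_len(T_)) {
    state <- compute_sample_state(Fvec, y, params$z_max, params$w_floor)
    full_scan <- !use_batch || ((t - 1L) %% params$m_batch == 0L)
    active <- if (full_scan) seq_len(d) else batch_set
    sc <- .screen_variants(M0, M1, M2, active, state, model_kind,
                           params$s2_clip)
    if (full_scan && use_batch) {
      finite <- which(is.finite(sc$loss))
      take <- finite[order(sc$loss[finite])][seq_len(min(params$m_batch,
                                                         length(finite)))]
      batch_set <- sort(active[take])
    }
    best <- select_variant(sc$loss)
    j <- active[best]
    f <- c(sc$f0[best], sc$f1[best], sc$f2[best])
    learners$iteration[t] <- t
    learners$variant_index[t] <- j
    learners$variant_id[t] <- G$variants$id[j]
    learners$f0[t] <- f[1]; learners$f1[t] <- f[2]; learners$f2[t] <- f[3]
    learners$c[t] <- sc$c[best]; learners$alpha[t] <- sc$alpha[best]
    learners$loss[t] <- sc$loss[best]
    trace_loss[t] <- sc$loss[best]

    Fvec <- Fvec + params$gamma *
      (f[1] * M0[, j] + f[2] * M1[, j] + f[3] * M2[, j])
    trace_ll[t] <- .loglik_pm1(Fvec, y)
  }

  structure(list(covariate_fit = cov_fit, learners = learners,
                 gamma = params$gamma, model_kind = model_kind,
                 params = params,
                 variants = G$variants,
                 covar_cols = colnames(X_cov) %||% character(0),
                 trace = data.frame(iteration = seq_len(T_),
                                    loss = trace_loss,
                                    log_likelihood = trace_ll)),
            class = "genoboost_model")
}

#' @export
print.genoboost_model <- function(x, ...) {
  cat(sprintf("genoboost_model (%s): %d iterations, %d unique variants, gamma = %g\n",
              x$model_kind, nrow(x$learners),
              length(unique(x$learners$variant_index)), x$gamma))
  invisible(x)
}

#' Collapse a model to cumulative per-variant score triplets
#'
#' Sums the learning-rate-shrunken genotype scores of every learner per
#' variant, yielding one cumulative triplet `(S0, S1, S2)` per selected
#' variant. Predictions from the collapsed triplets equal predictions from
#' the iteration-ordered learner list.
#'
#' @param model a [boost_fit()] model.
#' @param n_iter optional truncation: use only the first `n_iter` learners.
#' @return A data.frame with variant metadata, `S0`, `S1`, `S2` and the
#'   selection count `n_selected`.
#' @export
collapse_model <- function(model, n_iter = NULL) {
  stopifnot(inherits(model, "genoboost_model"))
  lt <- model$learners
  if (!is.null(n_iter)) {
    stopifnot(n_iter >= 0, n_iter <= nrow(lt))
    lt <- lt[seq_len(n_iter), , drop = FALSE]
  }
  if (nrow(lt) == 0L) {
    out <- model$variants[0, c("id", "chrom", "pos", "a1", "a2")]
    out$S0 <- out$S1 <- out$S2 <- numeric(0)
    out$n_selected <- integer(0)
    names(out)[1] <- "variant_id"
    return(out)
  }
  g <- model$gamma
  idx <- sort(unique(lt$variant_index))
  pos <- match(lt$variant_index, idx)
  S0 <- as.vector(tapply(g * lt$f0, pos, sum))
  S1 <- as.vector(tapply(g * lt$f1, pos, sum))
  S2 <- as.vector(tapply(g * lt$f2, pos, sum))
  nsel <- as.vector(table(pos))
  vm <- model$variants[idx, , drop = FALSE]
  data.frame(variant_id = vm$id, chrom = vm$chrom, pos = vm$pos,
             a1 = vm$a1, a2 = vm$a2,
             S0 = S0, S1 = S1, S2 = S2, n_selected = nsel,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genotype-only polygenic score
#'
#' Sums, per sample, the cumulative genotype score `S_g` of every model
#' variant. Model variants are matched to `G` by id and alleles; a variant
#' stored with swapped alleles is flipped before lookup. A missing genotype
#' contributes 0.
#'
#' @param model a [boost_fit()] model or a [collapse_model()] data.frame.
#' @param G a [genotype_matrix()] containing every model variant.
#' @return Numeric vector of per-sample scores, aligned with `G$samples`.
#' @export
predict_genetic_score <- function(model, G) {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- if (inherits(model, "genoboost_model")) collapse_model(model) else model
  stopifnot(is.data.frame(tab))
  n <- length(G$samples)
  if (nrow(tab) == 0L) return(rep(0, n))
  pos <- match(tab$variant_id, G$variants$id)
  if (anyNA(pos)) {
    stop("variant(s) absent from genotype data: ",
         paste(utils::head(tab$variant_id[is.na(pos)], 10), collapse = ", "))
  }
  same <- G$variants$a1[pos] == tab$a1 & G$variants$a2[pos] == tab$a2
  swap <- G$variants$a1[pos] == tab$a2 & G$variants$a2[pos] == tab$a1
  if (any(!same & !swap)) {
    stop("allele mismatch for variant(s): ",
         paste(utils::head(tab$variant_id[!same & !swap], 10), collapse = ", "))
  }
  score <- rep(0, n)
  for (r in seq_len(nrow(tab))) {
    g <- G$dosages[, pos[r]]
    if (swap[r]) g <- 2L - g
    s <- c(tab$S0[r], tab$S1[r], tab$S2[r])[g + 1L]
    s[is.na(s)] <- 0
    score <- score + s
  }
  score
}

#' Per-sample model prediction on the logit scale
#'
#' Covariate linear predictor plus the genotype-only polygenic score.
#'
#' @param object a [boost_fit()] model.
#' @param G a [genotype_matrix()].
#' @param pheno phenotype table providing the covariate columns (aligned to
#'   `G` by `sample_id`).
#' @param ... unused.
#' @return Numeric vector of logit-scale predictions.
#' @export
predict.genoboost_model <- function(object, G, pheno = NULL, ...) {
  pgs <- predict_genetic_score(object, G)
  if (length(object$covar_cols) == 0L || is.null(pheno)) {
    return(object$covariate_fit$intercept + pgs)
  }
  ord <- match(G$samples, pheno$sample_id)
  if (anyNA(ord)) stop("phenotype table lacks sample(s) present in G")
  X <- as.matrix(pheno[ord, object$covar_cols, drop = FALSE])
  linear_predictor(object$covariate_fit, X) + pgs
}
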