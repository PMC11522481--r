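#' Default hyperparameter grids
#'
#' The learning-rate grid holds four values and the iteration-count grid 29
#' values (5, 10, then 20..100 by 10, 200..1000 by 100, 2000..10000 by
#' 1000); combined with the two model kinds this yields a 232-cell grid.
#'
#' @return `default_gamma_grid()` a numeric vector; `default_t_grid()` an
#'   integer vector.
#' @export
default_gamma_grid <- function() c(0.05, 0.1, 0.2, 0.5)

#' @rdname default_gamma_grid
#' @export
default_t_grid <- function() {
  as.integer(c(5, 10, seq(20, 100, by = 10), seq(200, 1000, by = 100),
               seq(2000, 10000, by = 1000)))
}

#' Train/validation/test split plan
#'
#' Randomly assigns a `test_fraction` of samples to a held-out test set and
#' partitions the remainder into `k` cross-validation folds of near-equal
#' size (differing by at most one). The split is a function of sample ids
#' and seed only; phenotypes are not used (no stratification).
#'
#' @param sample_ids character vector of sample identifiers.
#' @param k number of folds.
#' @param test_fraction fraction held out for testing, in `[0, 1)`; 0
#'   disables the test set.
#' @param seed integer RNG seed; the same call with the same seed returns an
#'   identical plan.
#' @return A list of class `split_plan` with `test_ids`, `folds` (list of
#'   `k` id vectors) and `seed`.
#' @export
make_split <- function(sample_ids, k = 5L, test_fraction = 0.2, seed = 1L) {
  n <- length(sample_ids)
  stopifnot(k >= 1, test_fraction >= 0, test_fraction < 1)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  n_test <- round(test_fraction * n)
  if (n - n_test < k + 1L) stop("too few samples for ", k, " folds")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  perm <- sample(sample_ids)
  test_ids <- if (n_test > 0) perm[seq_len(n_test)] else character(0)
  dev <- perm[setdiff(seq_len(n), seq_len(n_test))]
  fold_of <- rep(seq_len(k), length.out = length(dev))
  folds <- split(dev, fold_of)
  names(folds) <- NULL
  structure(list(test_ids = test_ids, folds = folds, seed = seed),
            class = "split_plan")
}

#' Snapshot a boosting run along its iteration path
#'
#' Boosting is a deterministic prefix algorithm: the model after `T`
#' iterations of a longer run equals an independent run stopped at `T`.
#' This extracts, from a single fitted model, the sub-models at each
#' requested iteration count.
#'
#' @param model a [boost_fit()] model trained for at least `max(t_grid)`
#'   iterations.
#' @param t_grid sorted ascending vector of iteration counts.
#' @return A list of collapsed score tables (see [collapse_model()]), one
#'   per grid value, named by the iteration count.
#' @export
path_snapshots <- function(model, t_grid) {
  stopifnot(inherits(model, "genoboost_model"))
  if (is.unsorted(t_grid, strictly = FALSE)) {
    stop("t_grid must be sorted ascending")
  }
  if (max(t_grid) > nrow(model$learners)) {
    stop("t_grid exceeds the number of iterations run")
  }
  out <- lapply(t_grid, function(T_) collapse_model(model, n_iter = T_))
  names(out) <- as.character(t_grid)
  out
}

#' Cross-validated grid search over learning rate, iterations and model kind
#'
#' For each fold, trains on the remaining folds at `max(t_grid)` iterations
#' once per (learning rate, model kind) pair, snapshots the boosting path at
#' every grid iteration count, and scores each cell by covariate-adjusted
#' pseudo-R2 on the held-out fold (coefficients fit on that same fold). The
#' per-fold winner is the cell with the highest validation pseudo-R2; ties
#' break toward smaller `T`, then smaller learning rate, then the additive
#' kind (the sparser, more regularized model).
#'
#' @param G a [genotype_matrix()] (development samples are selected from it
#'   by id).
#' @param pheno phenotype table covering the development samples.
#' @param split a [make_split()] plan.
#' @param gammas learning-rate grid.
#' @param t_grid iteration-count grid (sorted ascending).
#' @param kinds model kinds to consider; the default searches both and so
#'   performs the additive-versus-non-additive model choice.
#' @param params_base [boost_params()] template supplying the remaining
#'   hyperparameters.
#' @return A list of class `grid_search_result` with `results` (one row per
#'   cell and fold), `best` (one row per fold), `models` (per-fold collapsed
#'   score table of the winning cell), and `primary_fold` (defaults to the
#'   first fold).
#' @export
grid_search <- function(G, pheno, split,
                        gammas = default_gamma_grid(),
                        t_grid = default_t_grid(),
                        kinds = c("nonadditive", "additive"),
                        params_base = boost_params()) {
  stopifnot(inherits(split, "split_plan"))
  if (is.unsorted(t_grid)) stop("t_grid must be sorted ascending")
  kinds <- match.arg(kinds, c("nonadditive", "additive"), several.ok = TRUE)
  k <- length(split$folds)
  res <- list()
  models <- vector("list", k)
  best_rows <- list()
  for (f in seq_len(k)) {
    val_ids <- split$folds[[f]]
    train_ids <- unlist(split$folds[-f], use.names = FALSE)
    G_tr <- subset_samples(G, train_ids)
    G_va <- subset_samples(G, val_ids)
    ph_tr <- pheno[match(train_ids, pheno$sample_id), , drop = FALSE]
    ph_va <- pheno[match(val_ids, pheno$sample_id), , drop = FALSE]
    attr(ph_tr, "covar_cols") <- attr(pheno, "covar_cols")
    attr(ph_va, "covar_cols") <- attr(pheno, "covar_cols")
    X_va <- covariate_matrix(ph_va)
    fold_cells <- list()
    fold_models <- list()
    for (kind in kinds) {
      for (g in gammas) {
        cell <- tryCatch({
          prm <- params_base
          prm$gamma <- g
          prm$iterations <- max(t_grid)
          fit <- boost_fit(G_tr, ph_tr, prm, model_kind = kind)
          snaps <- path_snapshots(fit, t_grid)
          metric <- vapply(snaps, function(tab) {
            pgs_va <- predict_genetic_score(tab, G_va)
            pseudo_r2(ph_va$y, pgs_va, X_va,
                      y_fit = ph_va$y, pgs_fit = pgs_va, X_fit = X_va)
          }, numeric(1))
          list(df = data.frame(fold = f, kind = kind, gamma = g, T = t_grid,
                               metric = unname(metric),
                               stringsAsFactors = FALSE),
               snaps = snaps)
        }, error = function(e) {
          warning(sprintf("grid cell (fold %d, %s, gamma %g) failed: %s",
                          f, kind, g, conditionMessage(e)))
          NULL
        })
        if (is.null(cell)) next
        fold_cells[[length(fold_cells) + 1L]] <- cell$df
        fold_models[[paste(kind, g, sep = "_")]] <- cell$snaps
      }
    }
    if (length(fold_cells) == 0L) stop("every grid cell failed in fold ", f)
    fold_df <- do.call(rbind, fold_cells)
    # winner: max metric; ties toward smaller T, smaller gamma, additive kind
    ord <- order(-fold_df$metric, fold_df$T, fold_df$gamma,
                 match(fold_df$kind, c("additive", "nonadditive")))
    win <- fold_df[ord[1L], , drop = FALSE]
    best_rows[[f]] <- win
    models[[f]] <- fold_models[[paste(win$kind, win$gamma, sep = "_")]][[as.character(win$T)]]
    res[[f]] <- fold_df
  }
  structure(list(results = do.call(rbind, res),
                 best = do.call(rbind, best_rows),
                 models = models,
                 primary_fold = 1L,
                 split = split),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("grid_search_result: per-fold winners\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Number of cells in a hyperparameter grid
#'
#' @param gammas,t_grid,kinds the grid axes.
#' @return `length(gammas) * length(t_grid) * length(kinds)`.
#' @export
grid_size <- function(gammas = default_gamma_grid(),
                      t_grid = default_t_grid(),
                      kinds = c("nonadditive", "additive")) {
  length(gammas) * length(t_grid) * length(kinds)
}
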