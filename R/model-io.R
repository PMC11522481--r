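#' Write a fitted model's collapsed scores to TSV
#'
#' The main file holds one row per selected variant with header
#' `variant_id chrom pos a1 a2 score_0 score_1 score_2` (`a1` is the
#' minor/effect allele). A sidecar `<path>.covar.tsv` holds the covariate
#' intercept and original-scale coefficients.
#'
#' @param model a [boost_fit()] model or a [collapse_model()] table.
#' @param path output path for the score table.
#' @return Invisibly, the paths written.
#' @export
write_model <- function(model, path) {
  tab <- if (inherits(model, "genoboost_model")) collapse_model(model) else model
  out <- data.frame(variant_id = tab$variant_id, chrom = tab$chrom,
                    pos = tab$pos, a1 = tab$a1, a2 = tab$a2,
                    score_0 = tab$S0, score_1 = tab$S1, score_2 = tab$S2)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  paths <- path
  if (inherits(model, "genoboost_model")) {
    cpath <- paste0(path, ".covar.tsv")
    cf <- coef(model$covariate_fit)
    utils::write.table(data.frame(term = names(cf), coefficient = unname(cf)),
                       cpath, quote = FALSE, sep = "\t", row.names = FALSE)
    paths <- c(scores = path, covariates = cpath)
  }
  invisible(paths)
}

#' Read a collapsed score table written by [write_model()]
#'
#' @param path path to the score TSV.
#' @return A data.frame in [collapse_model()] layout.
#' @export
read_model <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(variant_id = "character",
                                          chrom = "character"))
  data.frame(variant_id = tab$variant_id, chrom = tab$chrom, pos = tab$pos,
             a1 = tab$a1, a2 = tab$a2,
             S0 = tab$score_0, S1 = tab$score_1, S2 = tab$score_2,
             stringsAsFactors = FALSE)
}

#' Export additive effect weights
#'
#' Collapses each variant's score triplet to the single per-allele weight
#' `(S2 - S0) / 2`, the scoring-file convention of additive polygenic score
#' repositories. Any dominance deviation (the departure of `S1` from the
#' midpoint of `S0` and `S2`) is lost; a warning reports how many variants
#' carry one.
#'
#' @param model a [boost_fit()] model or [collapse_model()] table.
#' @param path optional TSV output path.
#' @param zero_tol dominance deviations below this are not counted.
#' @return A data.frame `variant_id, chrom, pos, effect_allele, other_allele,
#'   effect_weight` (invisibly when `path` is given).
#' @export
export_additive_weights <- function(model, path = NULL, zero_tol = 1e-8) {
  tab <- if (inherits(model, "genoboost_model")) collapse_model(model) else model
  dev <- tab$S1 - (tab$S0 + tab$S2) / 2
  n_dom <- sum(abs(dev) > zero_tol)
  if (n_dom > 0) {
    warning(n_dom, " variant(s) carry dominance deviations that the ",
            "additive export discards")
  }
  out <- data.frame(variant_id = tab$variant_id, chrom = tab$chrom,
                    pos = tab$pos, effect_allele = tab$a1,
                    other_allele = tab$a2,
                    effect_weight = (tab$S2 - tab$S0) / 2,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
    return(invisible(out))
  }
  out
}
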