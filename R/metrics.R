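# Evaluation metrics and the compound-screening mode.

#' Root mean square error
#'
#' `sqrt(mean((predicted - observed)^2))`, the absolute-error measure used to
#' score affinity regression.
#'
#' @param observed numeric vector of observed affinities.
#' @param predicted numeric vector of model predictions, same length.
#' @return nonnegative scalar.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) == 0L) stop("empty input")
  if (length(observed) != length(predicted)) stop("length mismatch")
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination
#'
#' The primary form is `1 - SS_residual / SS_total`; it equals 1 for perfect
#' prediction, 0 for the mean predictor, and can be negative.  The secondary
#' form `SS_regression / SS_total` (the two coincide only for unbiased linear
#' fits) is available with `form = "regression"`.
#'
#' @inheritParams rmse
#' @param form `"residual"` (default) or `"regression"`.
#' @return scalar; at most 1 for the residual form.
#' @examples
#' rSquared(c(1, 2, 3), c(1.1, 1.9, 3.2))  # 0.97
#' @export
rSquared <- function(observed, predicted,
                     form = c("residual", "regression")) {
  form <- match.arg(form)
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least 2 observations")
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0) stop("zero total variance")
  if (form == "residual") {
    1 - sum((observed - predicted)^2) / ssTot
  } else {
    sum((predicted - mean(observed))^2) / ssTot
  }
}

#' Evaluate a model on a labeled dataset
#'
#' @param model a trained [CPIModel].
#' @param dataset a labeled [CPIDataset] (or sample data.frame).
#' @return list with `rmse`, `r2` (residual form), `r2_alt` (regression
#'   form) and `n`.
#' @export
evaluateModel <- function(model, dataset) {
  df <- .asSampleFrame(dataset)
  pred <- predictAffinity(model, df)
  list(rmse = rmse(df$label, pred),
       r2 = rSquared(df$label, pred),
       r2_alt = rSquared(df$label, pred, form = "regression"),
       n = nrow(df))
}

#' Write an evaluation report as JSON
#'
#' @param eval result of [evaluateModel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(eval, path) {
  jsonlite::write_json(eval, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rank candidate compounds against one protein
#'
#' Predicts the interaction strength of every compound with the given protein
#' and sorts strongest first.  Because the score is on the log IC50 scale,
#' lower predicted values mean stronger interaction and rank 1 is the lowest
#' score.  Ties are broken by input order.  Compounds whose SMILES cannot be
#' parsed are kept in the output with `status = "failed"` and an NA score,
#' ranked after all scored compounds.
#'
#' @param model a trained [CPIModel], or (for testing against a known
#'   mechanism) a function `f(smiles)` returning a score.
#' @param protein list with the protein's channel data: `sps` (words or a
#'   space-separated string) and, if the model uses the amino channel,
#'   `amino` (residue string).
#' @param compounds character vector of candidate SMILES.
#' @param ids optional compound identifiers (defaults to index).
#' @return data.frame with columns `rank`, `compound_id`, `smiles`, `score`,
#'   `status`, ordered by rank; one row per input compound.
#' @export
screenCompounds <- function(model, protein, compounds, ids = NULL) {
  if (length(compounds) == 0L) stop("no compounds to screen")
  if (is.null(ids)) ids <- as.character(seq_along(compounds))
  ok <- vapply(compounds, function(s) {
    !inherits(tryCatch(parseSmiles(s), error = function(e) e), "error")
  }, logical(1))
  score <- rep(NA_real_, length(compounds))
  if (any(ok)) {
    if (is.function(model)) {
      score[ok] <- vapply(compounds[ok], model, numeric(1))
    } else {
      sps <- paste(protein$sps, collapse = " ")
      df <- data.frame(
        compound_id = ids[ok], smiles = compounds[ok],
        protein_id = "target", sps = sps, label = 0,
        stringsAsFactors = FALSE
      )
      if (!is.null(protein$amino)) df$amino <- protein$amino
      score[ok] <- predictAffinity(model, df)
    }
  }
  okIdx <- which(ok)
  ord <- c(okIdx[order(score[okIdx], okIdx)], which(!ok))
  score <- unname(score)
  data.frame(
    row.names = NULL,
    rank = seq_along(compounds),
    compound_id = ids[ord],
    smiles = compounds[ord],
    score = score[ord],
    status = ifelse(ok[ord], "ok", "failed"),
    stringsAsFactors = FALSE
  )
}

#' Write a screening ranking as TSV
#'
#' @param ranking result of [screenCompounds()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScreenReport <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
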