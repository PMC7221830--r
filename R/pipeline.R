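#' End-to-end pharmacophore + 3D-QSAR workflow
#'
#' Convenience wrapper running the whole modelling sequence on a set of
#' annotated molecule records: perceive features, elucidate and score
#' common pharmacophores on the potent compounds, select the top
#' hypothesis, split into training and test sets, fit the occupancy-grid
#' PLS model, and evaluate the held-out test set (RMSE, Pearson r, Q2F3).
#'
#' @param records list of `molecule_record`s with ensembles and IC50
#'   annotations (e.g. from [generate_library()] or [read_dataset()] +
#'   [generate_conformers()]).
#' @param inactive_background optional records used as the
#'   inactive/background set for hypothesis scoring; defaults to the
#'   records classed inactive.
#' @param k pharmacophore site count (default 5).
#' @param bin_width distance-partition bin in Angstrom (default 1.0).
#' @param train_frac training fraction (default 0.7).
#' @param max_factors PLS factor scan upper end (default 7).
#' @param experimental_error factor-selection error scale (default 0.3).
#' @param tol alignment tolerance in Angstrom (default 2.0).
#' @param seed integer seed controlling the split and cross-validation.
#' @return list with `hypothesis`, `candidates`, `split`, `model` (a
#'   `qsar_model`) and `test_stats` (rmse, pearson_r, q2f3, r2_test).
#' @export
run_qsar_pipeline <- function(records, inactive_background = NULL, k = 5,
                              bin_width = 1.0, train_frac = 0.7,
                              max_factors = 7, experimental_error = 0.3,
                              tol = 2.0, seed = 1) {
  records <- lapply(records, function(r) {
    if (is.null(r$features)) r$features <- ensemble_features(r$ensemble)
    r
  })
  cls <- vapply(records, function(r) r$activity_class %||% NA_character_,
                character(1))
  actives <- records[!is.na(cls) & cls == "active"]
  inactives <- inactive_background %||% records[!is.na(cls) & cls == "inactive"]
  if (length(actives) < 2) stopf("need at least 2 potent compounds")
  entries <- function(rs) lapply(rs, function(r) {
    list(ensemble = r$ensemble, features = r$features, pic50 = r$pic50)
  })
  cands <- enumerate_hypotheses(entries(actives), k = k,
                                bin_width = bin_width, tolerance = tol)
  if (!length(cands)) stopf("no common pharmacophore found among the actives")
  cands <- lapply(cands, score_hypothesis, actives = entries(actives),
                  inactives = entries(inactives))
  hypo <- select_best(cands)
  split <- split_dataset(records, train_frac = train_frac,
                         seed = child_seed(seed, 1L))
  model <- qsar_fit(split$train, hypo, max_factors = max_factors,
                    experimental_error = experimental_error, tol = tol,
                    seed = child_seed(seed, 2L))
  y_test <- vapply(split$test, `[[`, numeric(1), "pic50")
  pred <- predict(model, split$test, partial = TRUE)
  rmse <- sqrt(mean((y_test - pred$pic50_pred)^2))
  pear <- stats::cor(y_test, pred$pic50_pred)
  list(
    hypothesis = hypo,
    candidates = cands,
    split = split,
    model = model,
    test_stats = list(
      rmse = rmse,
      pearson_r = pear,
      r2_test = pear^2,
      q2f3 = q2f3(y_test, pred$pic50_pred, model$y_train)
    )
  )
}
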