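#' Fit a pharmacophore-aligned atom-based 3D-QSAR model
#'
#' The full modelling pipeline behind a single fitting call: every training
#' record is aligned to the pharmacophore hypothesis (records that fail to
#' match are dropped with a message), the aligned heavy atoms are encoded
#' as binary occupancy descriptors on a 0.5-Angstrom grid, and partial
#' least squares models with 1 up to `max_factors` latent factors are
#' fitted and cross-validated. The working factor count is chosen by
#' [select_model()]: the smallest count whose regression SD reaches the
#' experimental error, falling back to the best cross-validated Q2.
#'
#' @param records list of `molecule_record`s with `ensemble` (conformers)
#'   and pIC50; features are perceived on demand.
#' @param hypo a `hypothesis` used as the alignment rule.
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @param max_factors largest latent-factor count scanned (default 7).
#' @param n_folds cross-validation folds (default 10).
#' @param experimental_error median assay error in pIC50 units used by the
#'   factor-selection rule (default 0.3).
#' @param tol alignment tolerance passed to [match_and_align()].
#' @param seed integer seed for the cross-validation folds.
#' @return an object of class `qsar_model`.
#' @seealso [predict.qsar_model()], [export_coefficient_field()]
#' @export
qsar_fit <- function(records, hypo, spacing = 0.5, max_factors = 7,
                     n_folds = 10, experimental_error = 0.3, tol = 2.0,
                     seed = 1) {
  stopifnot(inherits(hypo, "hypothesis"))
  aligned <- list()
  for (r in records) {
    if (is.null(r$ensemble)) stopf("record %s has no conformer ensemble", r$id)
    if (is.na(r$pic50)) stopf("record %s has no pIC50", r$id)
    feats <- r$features %||% ensemble_features(r$ensemble)
    pose <- match_and_align(r$ensemble, feats, hypo, tol = tol,
                            require_all = TRUE)
    if (is.null(pose)) next
    aligned[[length(aligned) + 1]] <- list(record = r, pose = pose)
  }
  if (length(aligned) < max_factors + 2) {
    stopf("only %d records aligned to the hypothesis; too few to fit",
          length(aligned))
  }
  if (length(aligned) < length(records)) {
    message(sprintf("%d of %d records failed to match the hypothesis and were dropped",
                    length(records) - length(aligned), length(records)))
  }
  pose_xyz <- list(); cls_list <- list(); radii_list <- list()
  for (i in seq_along(aligned)) {
    mol <- aligned[[i]]$record$mol
    hv <- heavy_idx(mol)
    pose_xyz[[i]] <- pose_coords(aligned[[i]]$pose,
                                 aligned[[i]]$record$ensemble)[hv, , drop = FALSE]
    cls_list[[i]] <- atom_classes(mol)
    radii_list[[i]] <- vdw_radius(mol$atoms$elem[hv])
  }
  grid <- make_grid(pose_xyz, spacing = spacing)
  key_list <- lapply(seq_along(aligned), function(i) {
    occupancy_keys(pose_xyz[[i]], cls_list[[i]], radii_list[[i]], grid)
  })
  active_keys <- sort(unique(unlist(key_list)))
  X <- descriptor_matrix(key_list, active_keys)
  y <- vapply(aligned, function(a) a$record$pic50, numeric(1))
  factors <- seq_len(min(max_factors, length(y) - 2))
  models <- list()
  for (a in factors) {
    fit <- tryCatch(fit_pls(X, y, a), error = function(e) NULL)
    if (is.null(fit)) break    # rank exhausted: stop the factor scan
    fit$q2 <- cross_validate(X, y, a, n_folds = n_folds,
                             seed = child_seed(seed, a))
    models[[a]] <- fit
  }
  chosen <- select_model(models, experimental_error)
  structure(
    list(
      hypothesis = hypo,
      grid = grid,
      active_keys = active_keys,
      fit = chosen,
      scan = lapply(models, function(m) c(n_factors = m$n_factors,
                                          unlist(m$stats), q2 = m$q2)),
      models = models,
      train_ids = vapply(aligned, function(a) a$record$id, character(1)),
      y_train = y,
      tol = tol,
      spacing = spacing,
      floor_prediction = min(y),
      call = match.call()
    ),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  s <- x$fit$stats
  cat(sprintf(
    "Atom-based 3D-QSAR model (%s alignment)\n  %d training molecules, %d occupancy bits, %d latent factors\n  R2 = %.4f, SD = %.4f, Q2 = %.4f\n",
    x$hypothesis$variant_label, length(x$y_train), length(x$active_keys),
    x$fit$n_factors, s$r2, s$sd, x$fit$q2 %||% NA_real_))
  invisible(x)
}

#' @export
summary.qsar_model <- function(object, ...) {
  scan <- do.call(rbind, object$scan)
  structure(list(model = object, scan = as.data.frame(scan)),
            class = "summary.qsar_model")
}

#' @export
print.summary.qsar_model <- function(x, ...) {
  print(x$model)
  cat("\nFactor scan:\n")
  print(round(x$scan, 4), row.names = FALSE)
  cat(sprintf("\nSelection: %s\n", x$model$fit$selection_rule %||% ""))
  invisible(x)
}

#' @export
coef.qsar_model <- function(object, ...) {
  stats::setNames(object$fit$coefficients,
                  paste0("bit", object$active_keys))
}

#' @export
residuals.qsar_model <- function(object, ...) {
  object$y_train - object$fit$fitted
}

#' Predict pIC50 for new molecules
#'
#' Each molecule is aligned to the model's hypothesis (partial matches
#' allowed when `partial = TRUE`, the screening convention), encoded on
#' the model's active cubes, and pushed through the linear model.
#' Molecules that fail to align receive the model's floor prediction (the
#' minimum training pIC50) and `matched = FALSE`, ranking them last.
#'
#' @param object a `qsar_model`.
#' @param newdata list of `molecule_record`s (with ensembles) or a single
#'   record.
#' @param partial allow k-1 feature matches (default FALSE).
#' @param ... unused.
#' @return data.frame `id`, `pic50_pred`, `matched`.
#' @export
predict.qsar_model <- function(object, newdata, partial = FALSE, ...) {
  if (inherits(newdata, "molecule_record")) newdata <- list(newdata)
  ids <- character(length(newdata))
  preds <- numeric(length(newdata))
  matched <- logical(length(newdata))
  for (i in seq_along(newdata)) {
    r <- newdata[[i]]
    ids[i] <- r$id
    feats <- r$features %||% ensemble_features(r$ensemble)
    pose <- match_and_align(r$ensemble, feats, object$hypothesis,
                            tol = object$tol, require_all = !partial)
    if (is.null(pose)) {
      preds[i] <- object$floor_prediction
      matched[i] <- FALSE
      next
    }
    mol <- r$mol
    hv <- heavy_idx(mol)
    xyz <- pose_coords(pose, r$ensemble)[hv, , drop = FALSE]
    keys <- occupancy_keys(xyz, atom_classes(mol),
                           vdw_radius(mol$atoms$elem[hv]), object$grid)
    xrow <- numeric(length(object$active_keys))
    xrow[match(intersect(keys, object$active_keys), object$active_keys)] <- 1
    preds[i] <- sum(xrow * object$fit$coefficients) + object$fit$intercept
    matched[i] <- TRUE
  }
  data.frame(id = ids, pic50_pred = preds, matched = matched,
             stringsAsFactors = FALSE)
}

#' Observed-versus-fitted plot for a 3D-QSAR model
#'
#' @param x a `qsar_model`.
#' @param ... passed to [plot()].
#' @method plot qsar_model
#' @export
plot.qsar_model <- function(x, ...) {
  plot(x$fit$fitted, x$y_train,
       xlab = "fitted pIC50", ylab = "experimental pIC50",
       main = sprintf("3D-QSAR (%d factors): R2 = %.3f",
                      x$fit$n_factors, x$fit$stats$r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize a fitted model to JSON (lossless round-trip)
#' @param model a `qsar_model`.
#' @param path output path; `NULL` returns the JSON string.
#' @export
write_qsar_model <- function(model, path = NULL) {
  obj <- list(
    version = 1L,
    hypothesis = jsonlite::fromJSON(write_hypothesis(model$hypothesis)),
    grid = list(origin = model$grid$origin, spacing = model$grid$spacing,
                extents = model$grid$extents,
                atom_classes = model$grid$atom_classes),
    active_keys = model$active_keys,
    n_factors = model$fit$n_factors,
    coefficients = model$fit$coefficients,
    intercept = model$fit$intercept,
    stats = model$fit$stats,
    q2 = model$fit$q2 %||% NA_real_,
    y_train = model$y_train,
    train_ids = model$train_ids,
    tol = model$tol,
    floor_prediction = model$floor_prediction
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a serialized model back
#' @param path file path or JSON string.
#' @export
read_qsar_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  h <- hypothesis(as.data.frame(obj$hypothesis$features),
                  tolerance = obj$hypothesis$tolerance,
                  ref_molecule = obj$hypothesis$ref_molecule,
                  ref_conformer = obj$hypothesis$ref_conformer,
                  ref_energy = obj$hypothesis$ref_energy,
                  matches = obj$hypothesis$matches)
  grid <- structure(
    list(origin = obj$grid$origin, spacing = obj$grid$spacing,
         extents = obj$grid$extents, atom_classes = obj$grid$atom_classes),
    class = "grid_spec")
  structure(
    list(
      hypothesis = h, grid = grid,
      active_keys = obj$active_keys,
      fit = list(n_factors = obj$n_factors,
                 coefficients = obj$coefficients,
                 intercept = obj$intercept,
                 stats = as.list(obj$stats), q2 = obj$q2,
                 fitted = NULL),
      y_train = obj$y_train, train_ids = obj$train_ids,
      tol = obj$tol, floor_prediction = obj$floor_prediction
    ),
    class = "qsar_model")
}
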