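#' Rank a library with a QSAR model and take the hit list
#'
#' Every molecule is predicted (partial pharmacophore matches allowed, the
#' screening convention; non-matching molecules get the floor prediction),
#' the library is sorted by descending predicted pIC50 with ties broken by
#' id, and the top of the ranking becomes the hit list.
#'
#' @param model a `qsar_model`.
#' @param library list of `molecule_record`s.
#' @param hit_fraction fraction of the library taken as hits (default
#'   0.01, rounded to nearest, minimum 1).
#' @param hit_count explicit hit-list size; overrides `hit_fraction`.
#' @return data.frame `rank`, `id`, `pic50_pred`, `matched`, `is_hit`.
#' @export
screen <- function(model, library, hit_fraction = 0.01, hit_count = NULL) {
  if (!length(library)) stopf("empty screening library")
  pred <- predict(model, library, partial = TRUE)
  ord <- order(-pred$pic50_pred, pred$id)
  pred <- pred[ord, , drop = FALSE]
  ht <- hit_list_size(nrow(pred), hit_fraction, hit_count)
  pred$rank <- seq_len(nrow(pred))
  pred$is_hit <- pred$rank <= ht
  rownames(pred) <- NULL
  pred[, c("rank", "id", "pic50_pred", "matched", "is_hit")]
}

#' Hit-list size for a screening run
#'
#' An explicit `hit_count` (the published protocol fixed the cutoff at the
#' top 30 ranks) overrides the fractional rule; otherwise the size is the
#' library fraction rounded to the nearest integer with a floor of one.
#'
#' @param n library size.
#' @param hit_fraction fraction of the library (default 0.01).
#' @param hit_count explicit cutoff, overrides the fraction.
#' @export
hit_list_size <- function(n, hit_fraction = 0.01, hit_count = NULL) {
  if (!is.null(hit_count)) return(as.integer(hit_count))
  max(1L, as.integer(round(hit_fraction * n)))
}

check_counts <- function(Ha, Ht, A, D) {
  if (Ht < 1 || A < 1 || D < A || Ht > D) {
    stopf("need 1 <= Ht <= D, A >= 1 and D >= A (got Ha=%s Ht=%s A=%s D=%s)",
          Ha, Ht, A, D)
  }
  if (Ha < 0 || Ha > min(Ht, A)) {
    stopf("Ha must lie in [0, min(Ht, A)] (got Ha=%s Ht=%s A=%s)", Ha, Ht, A)
  }
  # a hit list cannot contain more inactives than the library holds
  if ((Ht - Ha) > (D - A)) {
    stopf("impossible counts: Ht - Ha (%s) exceeds D - A (%s)",
          Ht - Ha, D - A)
  }
}

#' Enrichment factor
#'
#' `EF = (Ha / Ht) / (A / D)`: the active rate in the hit list over the
#' active rate in the whole library.
#'
#' @param Ha actives in the hit list.
#' @param Ht hit-list size.
#' @param A total actives in the library.
#' @param D library size.
#' @export
enrichment_factor <- function(Ha, Ht, A, D) {
  check_counts(Ha, Ht, A, D)
  (Ha / Ht) / (A / D)
}

#' Guner-Henry goodness-of-hit score
#'
#' `GH = [Ha (3A + Ht) / (4 Ht A)] * [1 - (Ht - Ha) / (D - A)]`, a
#' composite of the yield and ratio of actives penalized by false
#' positives; ranges from 0 (null model) to 1 (ideal retrieval).
#'
#' @inheritParams enrichment_factor
#' @export
gh_score <- function(Ha, Ht, A, D) {
  check_counts(Ha, Ht, A, D)
  if (D <= A) stopf("GH needs D > A")
  (Ha * (3 * A + Ht) / (4 * Ht * A)) * (1 - (Ht - Ha) / (D - A))
}

#' Percentage yield and ratio of actives
#'
#' `%YA = 100 Ha / Ht` (purity of the hit list) and `%RA = 100 Ha / A`
#' (recall of the actives).
#'
#' @inheritParams enrichment_factor
#' @return named numeric vector `c(pct_ya =, pct_ra =)`.
#' @export
yield_and_ratio <- function(Ha, Ht, A) {
  if (Ht < 1 || A < 1) stopf("need Ht >= 1 and A >= 1")
  if (Ha < 0 || Ha > min(Ht, A)) stopf("Ha must lie in [0, min(Ht, A)]")
  c(pct_ya = 100 * Ha / Ht, pct_ra = 100 * Ha / A)
}

#' ROC curve and AUC of a score ranking
#'
#' Threshold sweep over the unique scores, descending. Tied scores
#' contribute diagonal segments (the average-rank convention), so the
#' trapezoid AUC equals the normalized Mann-Whitney rank-sum statistic.
#'
#' @param scores named numeric vector of predictions (higher = more
#'   active-like), names are molecule ids.
#' @param active_ids character vector of known-active ids.
#' @return list with `roc_points` (data.frame fpr, tpr from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, active_ids) {
  lab <- names(scores) %in% active_ids
  npos <- sum(lab); nneg <- sum(!lab)
  if (npos == 0 || nneg == 0) {
    stopf("ROC needs at least one active and one inactive")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- numeric(length(thr) + 1)
  fpr <- numeric(length(thr) + 1)
  for (i in seq_along(thr)) {
    sel <- scores >= thr[i]
    tpr[i + 1] <- sum(lab & sel) / npos
    fpr[i + 1] <- sum(!lab & sel) / nneg
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Full enrichment report for a screening run
#'
#' Packages the decoy-screen bookkeeping (Ha, Ht, A, D) with EF, GH, %YA,
#' %RA and the ROC curve/AUC.
#'
#' @param ranking output of [screen()].
#' @param active_ids ids of the known actives in the library.
#' @return an `enrichment_report` (list).
#' @export
enrichment_report <- function(ranking, active_ids) {
  D <- nrow(ranking)
  A <- sum(ranking$id %in% active_ids)
  Ht <- sum(ranking$is_hit)
  Ha <- sum(ranking$is_hit & ranking$id %in% active_ids)
  roc <- roc_curve(stats::setNames(ranking$pic50_pred, ranking$id), active_ids)
  yr <- yield_and_ratio(Ha, Ht, A)
  structure(
    list(Ha = Ha, Ht = Ht, A = A, D = D,
         ef = enrichment_factor(Ha, Ht, A, D),
         gh = gh_score(Ha, Ht, A, D),
         pct_ya = unname(yr["pct_ya"]), pct_ra = unname(yr["pct_ra"]),
         roc_points = roc$roc_points, auc = roc$auc),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "Screening enrichment: Ha=%d of Ht=%d hits, A=%d actives in D=%d\n  EF = %.2f, GH = %.2f, %%YA = %.2f, %%RA = %.2f, AUC = %.3f\n",
    x$Ha, x$Ht, x$A, x$D, x$ef, x$gh, x$pct_ya, x$pct_ra, x$auc))
  invisible(x)
}

#' External-set validation
#'
#' Predicts an external set (disjoint from training by id; overlap is an
#' error) and returns the squared Pearson correlation between predicted
#' and experimental pIC50 along with the scatter data.
#'
#' @param model a `qsar_model`.
#' @param external_records list of `molecule_record`s with pIC50.
#' @return list with `r2_ext` and `scatter` (data.frame id, observed,
#'   predicted, matched).
#' @export
external_validation <- function(model, external_records) {
  ids <- vapply(external_records, `[[`, character(1), "id")
  overlap <- intersect(ids, model$train_ids)
  if (length(overlap)) {
    stopf("external set overlaps training ids: %s",
          paste(overlap, collapse = ", "))
  }
  obs <- vapply(external_records, function(r) r$pic50 %||% NA_real_, numeric(1))
  if (any(is.na(obs))) stopf("external records need pIC50")
  pred <- predict(model, external_records, partial = TRUE)
  if (stats::sd(pred$pic50_pred) == 0) {
    stopf("constant predictions on the external set: correlation undefined")
  }
  r <- stats::cor(obs, pred$pic50_pred)
  list(r2_ext = r^2,
       scatter = data.frame(id = ids, observed = obs,
                            predicted = pred$pic50_pred,
                            matched = pred$matched))
}
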