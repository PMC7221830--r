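#' Match a ligand onto a pharmacophore hypothesis and align it
#'
#' For every conformer of the ensemble, every kind-respecting assignment of
#' hypothesis features to ligand features is enumerated exhaustively and
#' scored by the RMSD of the least-squares rigid superposition of the
#' matched feature positions. A pose is a match when all `k` features are
#' mapped (`require_all = TRUE`) or at least `k - 1` in partial mode, and
#' its RMSD does not exceed `tol`. The best (lowest-RMSD, full matches
#' preferred) pose is returned, or `NULL` when nothing matches.
#'
#' The returned transform maps ligand coordinates into the hypothesis
#' reference frame; direction vectors take no part in the positional
#' least-squares (they only enter hypothesis scoring).
#'
#' @param ensemble a `conformer_ensemble`.
#' @param features list of per-conformer feature data.frames (from
#'   [ensemble_features()]); computed on the fly when `NULL`.
#' @param hypothesis a `hypothesis` object.
#' @param tol matching tolerance in Angstrom (default 2.0).
#' @param require_all require all k features matched (default TRUE; set
#'   FALSE for screening, allowing k-1 partial matches).
#' @return an `aligned_pose` (list with `molecule_id`, `conformer_index`,
#'   `rotation`, `translation`, `mapping`, `rmsd`, `matched_count`) or
#'   `NULL`.
#' @export
match_and_align <- function(ensemble, features = NULL, hypothesis,
                            tol = 2.0, require_all = TRUE) {
  stopifnot(inherits(hypothesis, "hypothesis"))
  if (is.null(features)) features <- ensemble_features(ensemble)
  hf <- hypothesis$features
  k <- nrow(hf)
  hpos <- as.matrix(hf[, c("x", "y", "z")])
  best <- NULL
  consider <- function(pose) {
    if (is.null(best)) { best <<- pose; return() }
    # full matches beat partial; then lower rmsd wins
    if (pose$matched_count > best$matched_count ||
        (pose$matched_count == best$matched_count && pose$rmsd < best$rmsd)) {
      best <<- pose
    }
  }
  for (ci in seq_along(ensemble$conformers)) {
    lf <- features[[ci]]
    subsets <- if (require_all) list(seq_len(k)) else
      c(list(seq_len(k)), lapply(seq_len(k), function(d) setdiff(seq_len(k), d)))
    for (sel in subsets) {
      if (length(sel) < 3) next
      maps <- enumerate_kind_assignments(hf$kind[sel], lf$kind)
      if (!length(maps)) next
      ref <- hpos[sel, , drop = FALSE]
      for (mp in maps) {
        mov <- as.matrix(lf[mp, c("x", "y", "z"), drop = FALSE])
        fit <- try(superpose(ref, mov), silent = TRUE)
        if (inherits(fit, "try-error")) next
        if (fit$rmsd <= tol) {
          consider(structure(list(
            molecule_id = ensemble$molecule_id,
            conformer_index = ci,
            rotation = fit$rotation,
            translation = fit$translation,
            mapping = stats::setNames(mp, sel),
            rmsd = fit$rmsd,
            matched_count = length(sel)
          ), class = "aligned_pose"))
        }
      }
      # in partial mode, stop dropping features once a full match was found
      if (!is.null(best) && best$matched_count == k) break
    }
  }
  best
}

#' Enumerate injective, kind-respecting assignments
#'
#' Maps each required feature kind to distinct candidate feature indices of
#' the same kind; the cartesian product over kinds gives all assignments.
#' Exhaustive by construction.
#' @noRd
enumerate_kind_assignments <- function(req_kinds, cand_kinds, limit = 5000L) {
  kinds <- unique(req_kinds)
  per_kind <- list()
  for (kd in kinds) {
    need <- which(req_kinds == kd)
    have <- which(cand_kinds == kd)
    if (length(have) < length(need)) return(list())
    perms <- permutations_of(have, length(need))
    per_kind[[kd]] <- list(slots = need, perms = perms)
  }
  out <- list(rep(NA_integer_, length(req_kinds)))
  for (kd in kinds) {
    slots <- per_kind[[kd]]$slots
    perms <- per_kind[[kd]]$perms
    nxt <- vector("list", length(out) * length(perms))
    m <- 0L
    for (base in out) {
      for (p in perms) {
        m <- m + 1L
        v <- base
        v[slots] <- p
        nxt[[m]] <- v
        if (m >= limit) break
      }
      if (m >= limit) break
    }
    out <- nxt[seq_len(m)]
  }
  out
}

# all ordered selections of `take` elements from `from`
permutations_of <- function(from, take) {
  if (take == 0) return(list(integer(0)))
  out <- list()
  rec <- function(chosen, left) {
    if (length(chosen) == take) {
      out[[length(out) + 1]] <<- chosen
      return()
    }
    for (i in seq_along(left)) {
      rec(c(chosen, left[i]), left[-i])
    }
  }
  rec(integer(0), from)
  out
}

#' @export
print.aligned_pose <- function(x, ...) {
  cat(sprintf("<aligned_pose %s: conformer %d, %d features matched, RMSD %.3f A>\n",
              x$molecule_id, x$conformer_index, x$matched_count, x$rmsd))
  invisible(x)
}

#' Ligand coordinates of a pose in the hypothesis frame
#'
#' @param pose an `aligned_pose`.
#' @param ensemble the pose's source ensemble.
#' @return n x 3 matrix of transformed atom coordinates.
#' @export
pose_coords <- function(pose, ensemble) {
  xyz <- ensemble$conformers[[pose$conformer_index]]$xyz
  apply_transform(xyz, pose$rotation, pose$translation)
}
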