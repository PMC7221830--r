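#' Pharmacophore hypothesis
#'
#' A k-point common pharmacophore: an ordered feature table (kinds,
#' positions, optional directions) in a reference frame, the inter-feature
#' distance matrix, the matching tolerance, a variant label (sorted feature
#' kinds, e.g. "ADDRR") and, after scoring, the component and survival
#' scores.
#'
#' @param features feature data.frame (`kind`, `x`, `y`, `z`, `dx`, `dy`,
#'   `dz`).
#' @param tolerance matching radius in Angstrom.
#' @param ref_molecule id of the ligand providing the reference geometry.
#' @param ref_conformer index of that conformer.
#' @param ref_energy its relative conformational energy (kJ/mol).
#' @param matches number of actives sharing the hypothesis.
#' @export
hypothesis <- function(features, tolerance = 2.0, ref_molecule = NA_character_,
                       ref_conformer = NA_integer_, ref_energy = NA_real_,
                       matches = NA_integer_) {
  pos <- as.matrix(features[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(pos))
  structure(
    list(
      features = features,
      distance_matrix = dm,
      tolerance = tolerance,
      variant_label = paste(sort(features$kind), collapse = ""),
      ref_molecule = ref_molecule,
      ref_conformer = ref_conformer,
      ref_energy = ref_energy,
      matches = matches,
      scores = NULL
    ),
    class = "hypothesis"
  )
}

#' @export
print.hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis %s: %d features, matches=%s%s>\n",
              x$variant_label, nrow(x$features),
              ifelse(is.na(x$matches), "?", x$matches),
              if (!is.null(x$scores))
                sprintf(", survival=%.3f, adj=%.3f",
                        x$scores$survival, x$scores$adjusted_survival)
              else ""))
  invisible(x)
}

#' Enumerate candidate common pharmacophores across active ligands
#'
#' For every conformer of every active, all k-subsets of its perceived
#' features are keyed by their feature-kind multiset together with the
#' sorted inter-feature distances discretized at `bin_width` (a
#' reproducible, order-independent realization of tree-based distance
#' partitioning). Keys shared by at least `min_matched` actives become
#' candidate hypotheses; each candidate's reference geometry is taken from
#' the lowest-energy contributing conformer.
#'
#' @param actives list of entries `list(ensemble=, features=)` where
#'   `features` is the per-conformer list from [ensemble_features()]
#'   (computed when missing); each entry may also carry `pic50`.
#' @param k number of pharmacophore sites (default 5).
#' @param bin_width distance discretization in Angstrom (default 1.0).
#' @param min_matched minimum number of actives sharing a key (default:
#'   all actives).
#' @param tolerance matching tolerance stored on the hypotheses.
#' @return list of unscored `hypothesis` objects (possibly empty).
#' @export
enumerate_hypotheses <- function(actives, k = 5, bin_width = 1.0,
                                 min_matched = length(actives),
                                 tolerance = 2.0) {
  if (length(actives) < 2) stopf("need at least 2 actives")
  actives <- lapply(actives, function(a) {
    if (is.null(a$features)) a$features <- ensemble_features(a$ensemble)
    a
  })
  # registry: key -> list(actives=set of ids, best=list(...))
  reg <- new.env(parent = emptyenv())
  for (ai in seq_along(actives)) {
    a <- actives[[ai]]
    ens <- a$ensemble
    for (ci in seq_along(ens$conformers)) {
      lf <- a$features[[ci]]
      n <- nrow(lf)
      if (n < k) next
      rel_e <- ens$conformers[[ci]]$rel_energy
      combos <- utils::combn(n, k, simplify = FALSE)
      pos_all <- as.matrix(lf[, c("x", "y", "z")])
      for (sel in combos) {
        kinds <- lf$kind[sel]
        ord <- order(kinds)
        sel <- sel[ord]
        kinds <- kinds[ord]
        d <- stats::dist(pos_all[sel, , drop = FALSE])
        key <- paste(
          paste(kinds, collapse = ""),
          paste(floor(sort(d) / bin_width), collapse = ","),
          sep = "|"
        )
        cur <- reg[[key]]
        if (is.null(cur)) {
          cur <- list(ids = character(), best = NULL)
        }
        cur$ids <- union(cur$ids, ens$molecule_id)
        if (is.null(cur$best) || rel_e < cur$best$rel_energy) {
          cur$best <- list(
            molecule_id = ens$molecule_id, conformer = ci,
            rel_energy = rel_e, sel = sel, features = lf[sel, , drop = FALSE],
            pic50 = a$pic50 %||% NA_real_
          )
        }
        reg[[key]] <- cur
      }
    }
  }
  keys <- ls(reg)
  out <- list()
  for (key in keys) {
    cur <- reg[[key]]
    if (length(cur$ids) < min_matched) next
    feats <- cur$best$features
    rownames(feats) <- NULL
    h <- hypothesis(feats, tolerance = tolerance,
                    ref_molecule = cur$best$molecule_id,
                    ref_conformer = cur$best$conformer,
                    ref_energy = cur$best$rel_energy,
                    matches = length(cur$ids))
    h$ref_pic50 <- cur$best$pic50
    h$key <- key
    out[[length(out) + 1]] <- h
  }
  # canonical order, independent of input ordering
  if (length(out)) {
    out <- out[order(vapply(out, `[[`, character(1), "key"))]
  }
  out
}

#' Analytic overlap volume of two spheres
#' @noRd
sphere_overlap <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    r <- min(r1, r2)
    return(4 / 3 * pi * r^3)
  }
  (pi * (r1 + r2 - d)^2 *
     (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2)) / (12 * d)
}

sphere_volume <- function(r) 4 / 3 * pi * r^3

#' Pairwise common-volume ratio of two aligned heavy-atom sets
#'
#' Sphere-overlap approximation: the common volume is the sum of analytic
#' pairwise sphere intersections, the union is the sum of atomic volumes
#' minus the common part; the ratio is clamped to [0, 1].
#' @noRd
volume_overlap_ratio <- function(xyz1, r1, xyz2, r2) {
  v1 <- sum(sphere_volume(r1)); v2 <- sum(sphere_volume(r2))
  common <- 0
  for (i in seq_len(nrow(xyz1))) {
    d <- sqrt(rowSums((xyz2 - matrix(xyz1[i, ], nrow(xyz2), 3, byrow = TRUE))^2))
    common <- common + sum(vapply(seq_along(d), function(j) {
      sphere_overlap(r1[i], r2[j], d[j])
    }, numeric(1)))
  }
  union <- v1 + v2 - common
  max(0, min(1, common / union))
}

#' Default survival-score weights
#'
#' All components weigh 1.0; the conformational-energy penalty is scaled
#' by `1 / (k * 2.5)` (2.5 kJ/mol is the thermal-energy scale at room
#' temperature), making survival magnitudes comparable across site counts.
#' @param k number of pharmacophore sites.
#' @export
default_score_weights <- function(k = 5) {
  list(site = 1, vector = 1, volume = 1, selectivity = 1, matches = 1,
       activity = 1, energy = 1 / (k * 2.5))
}

#' Score a hypothesis against actives and inactives
#'
#' Component scores follow the classical survival-score recipe:
#' * `site` - 1 minus the mean aligned feature RMSD over the matching
#'   actives, in units of the tolerance (clamped to [0, 1]);
#' * `vector` - mean |cosine| between matched direction vectors;
#' * `volume` - mean pairwise common-volume ratio of the aligned actives
#'   (sphere-overlap approximation over heavy atoms);
#' * `selectivity` - -log10 of the match rate in a background library;
#' * `matches` - number of actives matched;
#' * `energy` - mean relative conformational energy of the matched
#'   conformers (a penalty);
#' * `activity` - pIC50 of the reference ligand.
#'
#' `survival` is the weighted component sum minus the weighted energy
#' penalty. The same function applied to the inactive set (without the
#' selectivity and activity terms, which are active-set notions) gives
#' `inactive_score`, and `adjusted_survival = survival - inactive_score`
#' exactly.
#'
#' @param h a `hypothesis`.
#' @param actives,inactives lists of `list(ensemble=, features=, pic50=)`
#'   entries; `inactives` may be empty.
#' @param background optional background library (same shape) for the
#'   selectivity term; defaults to `inactives`.
#' @param weights weight list from [default_score_weights()].
#' @return the hypothesis with `$scores` filled in.
#' @export
score_hypothesis <- function(h, actives, inactives = list(),
                             background = NULL, weights = NULL) {
  k <- nrow(h$features)
  if (is.null(weights)) weights <- default_score_weights(k)
  comp_a <- alignment_components(h, actives)
  survival <-
    weights$site * comp_a$site +
    weights$vector * comp_a$vector +
    weights$volume * comp_a$volume +
    weights$matches * comp_a$match_fraction -
    weights$energy * comp_a$energy
  # selectivity: rarity of the pharmacophore in a background library
  bg <- background %||% inactives
  selectivity <- 0
  if (length(bg)) {
    nm <- sum(vapply(bg, function(b) {
      !is.null(match_and_align(b$ensemble, b$features, h,
                               tol = h$tolerance, require_all = TRUE))
    }, logical(1)))
    rate <- max(nm, 1) / length(bg)     # zero matches capped at 1/N
    selectivity <- -log10(rate)
  }
  activity <- h$ref_pic50 %||% NA_real_
  if (is.na(activity)) activity <- 0
  survival <- survival + weights$selectivity * selectivity +
    weights$activity * activity
  if (length(inactives)) {
    comp_i <- alignment_components(h, inactives)
    inactive_score <-
      weights$site * comp_i$site +
      weights$vector * comp_i$vector +
      weights$volume * comp_i$volume +
      weights$matches * comp_i$match_fraction -
      weights$energy * comp_i$energy
  } else {
    warnf("no inactives supplied; inactive score set to 0")
    inactive_score <- 0
  }
  h$scores <- list(
    site = comp_a$site, vector = comp_a$vector, volume = comp_a$volume,
    selectivity = selectivity, matches = comp_a$n_matched,
    energy = comp_a$energy, activity = activity,
    survival = survival, inactive_score = inactive_score,
    adjusted_survival = survival - inactive_score
  )
  h
}

alignment_components <- function(h, set) {
  poses <- list(); rmsds <- c(); coss <- c(); energies <- c()
  hv_sets <- list(); radii_sets <- list()
  hf <- h$features
  for (entry in set) {
    feats <- entry$features %||% ensemble_features(entry$ensemble)
    pose <- match_and_align(entry$ensemble, feats, h, tol = h$tolerance,
                            require_all = TRUE)
    if (is.null(pose)) next
    poses[[length(poses) + 1]] <- pose
    rmsds <- c(rmsds, pose$rmsd)
    energies <- c(energies,
                  entry$ensemble$conformers[[pose$conformer_index]]$rel_energy)
    # direction cosine over matched features that both carry directions
    lf <- feats[[pose$conformer_index]]
    cosv <- c()
    for (s in seq_along(pose$mapping)) {
      hi <- as.integer(names(pose$mapping)[s]); li <- pose$mapping[[s]]
      hd <- c(hf$dx[hi], hf$dy[hi], hf$dz[hi])
      ld <- c(lf$dx[li], lf$dy[li], lf$dz[li])
      if (any(is.na(hd)) || any(is.na(ld))) next
      ld_rot <- as.vector(pose$rotation %*% ld)
      cosv <- c(cosv, abs(sum(hd * ld_rot)))
    }
    if (length(cosv)) coss <- c(coss, mean(cosv))
    mol <- entry$ensemble$mol
    hv <- heavy_idx(mol)
    xyz <- pose_coords(pose, entry$ensemble)[hv, , drop = FALSE]
    hv_sets[[length(hv_sets) + 1]] <- xyz
    radii_sets[[length(radii_sets) + 1]] <- vdw_radius(mol$atoms$elem[hv])
  }
  n_matched <- length(poses)
  site <- if (n_matched) max(0, min(1, 1 - mean(rmsds) / h$tolerance)) else 0
  vector_score <- if (length(coss)) mean(coss) else 0
  volume <- 0
  if (n_matched >= 2) {
    vr <- c()
    for (i in seq_len(n_matched - 1)) {
      for (j in seq(i + 1, n_matched)) {
        vr <- c(vr, volume_overlap_ratio(hv_sets[[i]], radii_sets[[i]],
                                         hv_sets[[j]], radii_sets[[j]]))
      }
    }
    volume <- mean(vr)
  } else if (n_matched == 1) {
    volume <- 1
  }
  energy <- if (n_matched) mean(energies) else 0
  list(site = site, vector = vector_score, volume = volume,
       energy = energy, n_matched = n_matched,
       match_fraction = if (length(set)) n_matched / length(set) else 0)
}

#' Select the top-ranked hypothesis
#'
#' Argmax of adjusted survival score; ties are broken by lower reference
#' conformational energy, then lexicographic variant label.
#'
#' @param candidates list of scored `hypothesis` objects.
#' @return the selected `hypothesis`.
#' @export
select_best <- function(candidates) {
  if (!length(candidates)) stopf("no candidate hypotheses to select from")
  scored <- vapply(candidates, function(h) !is.null(h$scores), logical(1))
  if (!all(scored)) stopf("all candidates must be scored before selection")
  adj <- vapply(candidates, function(h) h$scores$adjusted_survival, numeric(1))
  en <- vapply(candidates, function(h) h$ref_energy %||% Inf, numeric(1))
  lab <- vapply(candidates, `[[`, character(1), "variant_label")
  ord <- order(-adj, en, lab)
  candidates[[ord[1]]]
}

#' Serialize a hypothesis to JSON (lossless round-trip)
#' @param h a `hypothesis`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @export
write_hypothesis <- function(h, path = NULL) {
  obj <- list(
    version = 1L,
    variant_label = h$variant_label,
    tolerance = h$tolerance,
    ref_molecule = h$ref_molecule,
    ref_conformer = h$ref_conformer,
    ref_energy = h$ref_energy,
    ref_pic50 = h$ref_pic50 %||% NA_real_,
    matches = h$matches,
    features = h$features[, c("kind", "x", "y", "z", "dx", "dy", "dz")],
    scores = h$scores
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a hypothesis back from JSON
#' @param path file path or JSON string.
#' @export
read_hypothesis <- function(path) {
  obj <- jsonlite::fromJSON(path)
  feats <- as.data.frame(obj$features)
  rownames(feats) <- NULL
  h <- hypothesis(feats, tolerance = obj$tolerance,
                  ref_molecule = obj$ref_molecule,
                  ref_conformer = obj$ref_conformer,
                  ref_energy = obj$ref_energy,
                  matches = obj$matches)
  h$ref_pic50 <- obj$ref_pic50
  if (!is.null(obj$scores)) h$scores <- obj$scores
  h
}
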