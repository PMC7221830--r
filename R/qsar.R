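#' Atom classes for occupancy descriptors
#'
#' Heavy atoms are partitioned into six classes: `D` donor-hydrogen
#' carriers (N/O bearing H), `N` negatively charged, `P` positively
#' charged, `W` acceptor / electron-withdrawing (other N, O, halogens),
#' `H` hydrophobic carbons (apolar, no double bond to heteroatoms) and `X`
#' everything else (aromatic and other carbons). The table is a package
#' convention, editable via the `classes` argument of [make_grid()].
#'
#' @param mol a [molgraph()].
#' @return character vector over heavy atoms (class per atom).
#' @export
atom_classes <- function(mol) {
  adj <- adjacency(mol)
  bo <- bond_order_matrix(mol)
  elem <- mol$atoms$elem
  charge <- mol$atoms$charge
  arom <- unique(unlist(aromatic_rings_safe(mol)))
  hv <- heavy_idx(mol)
  out <- character(length(hv))
  for (j in seq_along(hv)) {
    i <- hv[j]
    cls <- "X"
    if (charge[i] < 0) cls <- "N"
    else if (charge[i] > 0) cls <- "P"
    else if (elem[i] %in% c("N", "O") && h_count(mol, i, adj) > 0) cls <- "D"
    else if (elem[i] %in% c("N", "O", "F", "Cl", "Br", "I", "S")) cls <- "W"
    else if (elem[i] == "C" && !(i %in% arom) &&
             !any(elem[adj[[i]]] %in% c("N", "O")) && !any(bo[i, ] == 2L)) {
      cls <- "H"
    }
    out[j] <- cls
  }
  out
}

QSAR_CLASSES <- c("D", "H", "N", "P", "W", "X")

#' Build the occupancy grid specification from training poses
#'
#' The cubic grid (default spacing 0.5 Angstrom) covers all training-pose
#' heavy atoms with one van der Waals radius of margin on every side.
#'
#' @param pose_xyz list of heavy-atom coordinate matrices (hypothesis
#'   frame).
#' @param spacing cube edge in Angstrom (default 0.5).
#' @param margin extra margin in Angstrom (default 2.0, about one vdW
#'   radius).
#' @param classes ordered atom-class labels.
#' @return a `grid_spec` (origin, spacing, extents, atom_classes).
#' @export
make_grid <- function(pose_xyz, spacing = 0.5, margin = 2.0,
                      classes = QSAR_CLASSES) {
  stopifnot(spacing > 0, length(pose_xyz) >= 1)
  allxyz <- do.call(rbind, pose_xyz)
  lo <- apply(allxyz, 2, min) - margin
  hi <- apply(allxyz, 2, max) + margin
  extents <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  structure(
    list(origin = lo, spacing = spacing, extents = extents,
         atom_classes = classes),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec: %d x %d x %d cubes at %.2f A, %d atom classes>\n",
              x$extents[1], x$extents[2], x$extents[3], x$spacing,
              length(x$atom_classes)))
  invisible(x)
}

#' Occupancy bits of one pose on a grid
#'
#' A (cube, class) bit is set when any atom of that class has its van der
#' Waals sphere containing the cube's center. Returns the set of occupied
#' bit keys (linear indices over cube x class); atoms whose spheres extend
#' beyond the grid contribute only their in-grid cubes, and the number of
#' discarded out-of-grid cube centers is reported via the
#' `"n_outside"` attribute.
#'
#' @param xyz heavy-atom coordinates in the hypothesis frame.
#' @param cls atom classes (from [atom_classes()]), same length.
#' @param radii vdW radii, same length.
#' @param grid a `grid_spec`.
#' @return integer vector of occupied (cube, class) linear keys, sorted
#'   and unique, with attribute `n_outside`.
#' @export
occupancy_keys <- function(xyz, cls, radii, grid) {
  nx <- grid$extents[1]; ny <- grid$extents[2]; nz <- grid$extents[3]
  sp <- grid$spacing
  keys <- integer(0)
  n_outside <- 0L
  if (length(cls) == 0) {
    out <- integer(0)
    attr(out, "n_outside") <- 0L
    return(out)
  }
  class_index <- match(cls, grid$atom_classes)
  for (a in seq_len(nrow(xyz))) {
    if (is.na(class_index[a])) next
    r <- radii[a]
    cen <- xyz[a, ]
    # candidate index ranges per axis (cube centers = origin + idx*spacing)
    lo <- ceiling((cen - r - grid$origin) / sp)
    hi <- floor((cen + r - grid$origin) / sp)
    lo_c <- pmax(lo, 0); hi_c <- pmin(hi, c(nx, ny, nz) - 1L)
    if (any(lo_c > hi_c)) {
      n_outside <- n_outside + prod(pmax(hi - lo + 1, 0))
      next
    }
    ix <- seq(lo_c[1], hi_c[1]); iy <- seq(lo_c[2], hi_c[2]); iz <- seq(lo_c[3], hi_c[3])
    gxyz <- expand.grid(ix = ix, iy = iy, iz = iz)
    cx <- grid$origin[1] + gxyz$ix * sp
    cy <- grid$origin[2] + gxyz$iy * sp
    cz <- grid$origin[3] + gxyz$iz * sp
    inside <- (cx - cen[1])^2 + (cy - cen[2])^2 + (cz - cen[3])^2 <= r^2
    n_outside <- n_outside +
      (prod(pmax(hi - lo + 1, 0)) - nrow(gxyz))  # clipped candidates
    if (!any(inside)) next
    cube <- gxyz$ix[inside] + nx * (gxyz$iy[inside] + ny * gxyz$iz[inside])
    keys <- c(keys, cube * length(grid$atom_classes) + (class_index[a] - 1L))
  }
  out <- sort(unique(keys))
  attr(out, "n_outside") <- n_outside
  out
}

#' Decode (cube, class) keys back to cube centers and class labels
#' @noRd
decode_keys <- function(keys, grid) {
  ncls <- length(grid$atom_classes)
  cls_i <- keys %% ncls
  cube <- keys %/% ncls
  nx <- grid$extents[1]; ny <- grid$extents[2]
  ix <- cube %% nx
  iy <- (cube %/% nx) %% ny
  iz <- cube %/% (nx * ny)
  data.frame(
    x = grid$origin[1] + ix * grid$spacing,
    y = grid$origin[2] + iy * grid$spacing,
    z = grid$origin[3] + iz * grid$spacing,
    class = grid$atom_classes[cls_i + 1]
  )
}

#' Binary descriptor matrix from per-pose occupancy keys
#'
#' Active cubes are the union of keys occupied by at least one training
#' pose; the descriptor of each pose is its indicator vector over that
#' layout.
#' @noRd
descriptor_matrix <- function(key_list, active_keys = NULL) {
  if (is.null(active_keys)) active_keys <- sort(unique(unlist(key_list)))
  X <- matrix(0, length(key_list), length(active_keys))
  for (i in seq_along(key_list)) {
    X[i, match(intersect(key_list[[i]], active_keys), active_keys)] <- 1
  }
  X
}

#' Partial least squares regression (NIPALS, single response)
#'
#' Mean-centers X and y and extracts `n_factors` latent factors
#' iteratively. With `n_factors` equal to the rank of the centered X, the
#' fit coincides with ordinary least squares.
#'
#' @param X descriptor matrix (n x p).
#' @param y response vector.
#' @param n_factors number of latent variables, in 1..min(n-2, rank).
#' @return list with `coefficients` (p), `intercept`, `fitted`, `stats`
#'   (r2, sd, f, p), `x_mean`, `y_mean`, `n_factors`.
#' @export
fit_pls <- function(X, y, n_factors) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stopf("X and y dimensions disagree")
  if (n < n_factors + 2) stopf("need at least n_factors + 2 observations")
  if (stats::var(y) == 0) stopf("constant response: nothing to fit")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  E <- Xc; f <- yc
  W <- matrix(0, ncol(X), n_factors)
  P <- matrix(0, ncol(X), n_factors)
  Q <- numeric(n_factors)
  escale <- sum(Xc^2)
  for (a in seq_len(n_factors)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    t <- if (wn > 0) E %*% (w / wn) else 0
    # rank deficiency: the deflated X (or its covariance with y) vanished
    if (wn < 1e-12 || sum(t^2) < 1e-12 * max(escale, 1)) {
      stopf("n_factors (%d) exceeds the achievable rank (%d) of the descriptor matrix",
            n_factors, a - 1L)
    }
    w <- w / wn
    tt <- sum(t^2)
    p <- crossprod(E, t) / tt
    q <- sum(f * t) / tt
    E <- E - t %*% t(p)
    f <- f - q * t
    W[, a] <- w; P[, a] <- p; Q[a] <- q
  }
  # regression vector in original X space
  B <- W %*% solve(crossprod(P, W), Q)
  fitted <- as.vector(Xc %*% B) + y_mean
  rss <- sum((y - fitted)^2)
  tss <- sum((y - y_mean)^2)
  r2 <- 1 - rss / tss
  dof2 <- n - n_factors - 1
  sd_reg <- sqrt(rss / dof2)
  fstat <- ((tss - rss) / n_factors) / (rss / dof2)
  pval <- stats::pf(fstat, n_factors, dof2, lower.tail = FALSE)
  list(
    coefficients = as.vector(B), intercept = y_mean - sum(B * x_mean),
    fitted = fitted, x_mean = x_mean, y_mean = y_mean,
    n_factors = n_factors,
    stats = list(r2 = r2, sd = sd_reg, f = fstat, p = pval)
  )
}

pls_predict_raw <- function(fit, Xnew) {
  as.vector(as.matrix(Xnew) %*% fit$coefficients) + fit$intercept
}

# fit with at most n_factors, backing off when the fold matrix is rank
# deficient
fit_pls_capped <- function(X, y, n_factors) {
  for (a in seq(n_factors, 1)) {
    fit <- tryCatch(fit_pls(X, y, a), error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  stopf("PLS failed even with a single factor")
}

#' Cross-validated Q2 by stratified n-fold
#'
#' Leave-n-out realized as stratified k-fold: observations are ordered by
#' response and dealt round-robin into folds, so every fold covers the
#' response range. Q2 = 1 - PRESS / SS_tot over the concatenated held-out
#' predictions, with SS_tot about the full-sample mean. Deterministic per
#' seed.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param n_factors latent variables per fold model.
#' @param n_folds folds (default 10).
#' @param seed integer seed.
#' @return Q2 (numeric scalar).
#' @export
cross_validate <- function(X, y, n_factors, n_folds = 10, seed = 1) {
  n <- length(y)
  if (n_folds < 2) stopf("need at least 2 folds")
  if (n < n_folds) stopf("fewer observations than folds")
  folds <- integer(n)
  with_seed(seed, {
    ord <- order(y + stats::runif(n) * 1e-9)  # stable tie shuffling
    folds[ord] <- rep(seq_len(n_folds), length.out = n)
  })
  press <- 0
  pred <- numeric(n)
  for (f in seq_len(n_folds)) {
    hold <- which(folds == f)
    keep <- setdiff(seq_len(n), hold)
    fit <- fit_pls_capped(X[keep, , drop = FALSE], y[keep], n_factors)
    pred[hold] <- pls_predict_raw(fit, X[hold, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  1 - press / sum((y - mean(y))^2)
}

#' External predictive squared correlation Q2F3
#'
#' `Q2F3 = 1 - [sum_i (y_i - yhat_i)^2 / n_out] / [sum_j (y_j - ybar_tr)^2 / n_tr]`
#' where the denominator uses the training responses and their mean. The
#' scaling by the two sample sizes makes the metric independent of the
#' external-set size.
#'
#' @param y_out experimental responses of the external objects.
#' @param y_pred_out their predictions.
#' @param y_train training responses.
#' @return Q2F3 (at most 1; 1 iff predictions are exact).
#' @export
q2f3 <- function(y_out, y_pred_out, y_train) {
  if (length(y_out) != length(y_pred_out) || length(y_out) < 1) {
    stopf("y_out and y_pred_out must have equal positive length")
  }
  if (length(y_train) < 2) stopf("need at least 2 training responses")
  denom <- sum((y_train - mean(y_train))^2) / length(y_train)
  if (denom == 0) stopf("zero training variance")
  num <- sum((y_out - y_pred_out)^2) / length(y_out)
  1 - num / denom
}

#' Pick the working model across factor counts
#'
#' The smallest factor count whose regression standard deviation falls to
#' the experimental error wins; when none does, the factor count with the
#' best cross-validated Q2 is used.
#'
#' @param models list of fitted models (each with `stats$sd` and
#'   optionally `q2`).
#' @param experimental_error response error scale (pIC50 units), e.g. the
#'   median assay error.
#' @return the selected model, with `selection_rule` attached.
#' @export
select_model <- function(models, experimental_error) {
  stopifnot(length(models) >= 1)
  sds <- vapply(models, function(m) m$stats$sd, numeric(1))
  ok <- which(sds <= experimental_error)
  if (length(ok)) {
    m <- models[[min(ok)]]
    m$selection_rule <- sprintf(
      "smallest factor count with SD (%.3f) <= experimental error (%.3f)",
      m$stats$sd, experimental_error)
    return(m)
  }
  q2s <- vapply(models, function(m) m$q2 %||% NA_real_, numeric(1))
  if (all(is.na(q2s))) {
    m <- models[[length(models)]]
    m$selection_rule <- "no SD below threshold and no Q2 available; most factors"
    return(m)
  }
  m <- models[[which.max(q2s)]]
  m$selection_rule <- sprintf(
    "no SD below threshold; best cross-validated Q2 (%.3f)", max(q2s, na.rm = TRUE))
  m
}

#' Export the thresholded coefficient field
#'
#' Emits one record per active (cube, class) whose |coefficient| reaches
#' the threshold: cube center, atom class, coefficient and sign
#' (positive coefficients mark activity-enhancing occupancy, negative
#' coefficients detrimental occupancy). Counts of positive and negative
#' cubes are attached as attributes.
#'
#' @param model a fitted `qsar_model` (see [qsar_fit()]).
#' @param threshold absolute-coefficient cutoff (default 1.5e-2).
#' @return data.frame `x`, `y`, `z`, `class`, `coefficient`, `sign`.
#' @export
export_coefficient_field <- function(model, threshold = 1.5e-2) {
  stopifnot(inherits(model, "qsar_model"))
  keep <- which(abs(model$fit$coefficients) >= threshold)
  dec <- decode_keys(model$active_keys[keep], model$grid)
  out <- cbind(dec, coefficient = model$fit$coefficients[keep])
  out$sign <- ifelse(out$coefficient >= 0, "positive", "negative")
  attr(out, "n_positive") <- sum(out$coefficient > 0)
  attr(out, "n_negative") <- sum(out$coefficient < 0)
  rownames(out) <- NULL
  out
}

#' Write a coefficient field as PDB pseudo-atoms
#'
#' One HETATM per cube, B-factor = coefficient (scaled by 100 to survive
#' the fixed-width field), for inspection in any molecular viewer.
#'
#' @param field output of [export_coefficient_field()].
#' @param path output file.
#' @export
write_field_pdb <- function(field, path) {
  lines <- character(nrow(field))
  for (i in seq_len(nrow(field))) {
    lines[i] <- sprintf(
      "HETATM%5d  C   CUB A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, i %% 10000, field$x[i], field$y[i], field$z[i], 1.0,
      max(-99, min(99, field$coefficient[i] * 100)))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
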