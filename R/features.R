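#' Chemical feature perception
#'
#' Detects the six classical pharmacophore feature kinds on a 3D
#' conformation: hydrogen-bond acceptor (A), hydrogen-bond donor (D),
#' hydrophobic group (H), negatively charged group (N), positively charged
#' group (P) and aromatic ring (R). Detection is substructure-rule driven
#' (see [feature_rules()]), deterministic, and canonical in the output
#' ordering (sorted by kind, then position).
#'
#' Rules, in outline:
#' * A - neutral oxygen with a lone pair (carbonyl O, ether/hydroxyl O) and
#'   pyridine-type aromatic nitrogen without hydrogens. Direction: mean
#'   bond axis pointing away from the bonded heavy atoms.
#' * D - nitrogen or oxygen carrying at least one hydrogen and no positive
#'   charge; positioned on the heavy atom. Direction: mean N-H/O-H axis.
#' * R - aromatic ring centroid; direction: ring-plane normal.
#' * H - connected clusters of apolar carbons (sp3 carbons and attached
#'   halogens not adjacent to N/O or charged atoms); positioned at the
#'   cluster centroid.
#' * N / P - heavy atoms with negative / positive formal charge.
#'
#' @param mol a [molgraph()] with explicit hydrogens.
#' @param xyz optional coordinates overriding the stored geometry (used to
#'   perceive features on individual conformers).
#' @return data.frame with columns `kind`, `x`, `y`, `z`, `dx`, `dy`, `dz`
#'   (unit direction, NA when absent) and `atoms` (list-column of source
#'   atom indices).
#' @export
perceive_features <- function(mol, xyz = NULL) {
  if (!is.null(xyz)) mol <- set_coords(mol, xyz)
  elem <- mol$atoms$elem
  if (sum(elem == "H") == 0 && any(elem %in% c("N", "O"))) {
    # molecules with N/O but no hydrogens at all have almost surely not
    # been prepared
    stopf("molecule %s has no explicit hydrogens; run molecule preparation first",
          mol$id)
  }
  adj <- adjacency(mol)
  bo <- bond_order_matrix(mol)
  rings <- aromatic_rings(mol)
  arom <- unique(unlist(rings))
  xyzm <- coords(mol)
  feats <- list()
  add <- function(kind, pos, dir = NULL, atoms = integer()) {
    feats[[length(feats) + 1]] <<- list(
      kind = kind, pos = pos,
      dir = if (is.null(dir)) c(NA_real_, NA_real_, NA_real_) else dir,
      atoms = atoms
    )
  }

  charge <- mol$atoms$charge

  ## charged groups first (charged atoms are excluded from A/D)
  for (i in which(charge < 0 & elem != "H")) add("N", xyzm[i, ], atoms = i)
  for (i in which(charge > 0 & elem != "H")) add("P", xyzm[i, ], atoms = i)

  ## acceptors
  for (i in which(elem == "O" & charge == 0)) {
    heavies <- adj[[i]][elem[adj[[i]]] != "H"]
    if (length(heavies) > 2) next
    # direction: away from bonded heavy atoms (lone-pair side)
    v <- -colSums(matrix(xyzm[heavies, , drop = FALSE], ncol = 3) -
                    matrix(xyzm[i, ], length(heavies), 3, byrow = TRUE))
    dir <- if (vnorm(v) > 1e-6) unitv(v) else NULL
    add("A", xyzm[i, ], dir = dir, atoms = i)
  }
  for (i in which(elem == "N" & charge == 0)) {
    if (!(i %in% arom)) next
    if (h_count(mol, i, adj) > 0) next
    if (length(adj[[i]]) != 2) next     # pyridine-type ring N
    v <- -colSums(xyzm[adj[[i]], , drop = FALSE] -
                    matrix(xyzm[i, ], 2, 3, byrow = TRUE))
    add("A", xyzm[i, ], dir = unitv(v), atoms = i)
  }

  ## donors
  for (i in which(elem %in% c("N", "O") & charge == 0)) {
    hs <- adj[[i]][elem[adj[[i]]] == "H"]
    if (!length(hs)) next
    v <- colSums(matrix(xyzm[hs, , drop = FALSE], ncol = 3) -
                   matrix(xyzm[i, ], length(hs), 3, byrow = TRUE))
    dir <- if (vnorm(v) > 1e-6) unitv(v) else NULL
    add("D", xyzm[i, ], dir = dir, atoms = i)
  }

  ## aromatic rings
  for (ring in rings) {
    pts <- xyzm[ring, , drop = FALSE]
    cen <- colMeans(pts)
    sv <- svd(sweep(pts, 2, cen))
    add("R", cen, dir = sv$v[, 3], atoms = ring)
  }

  ## hydrophobic clusters
  apolar <- logical(length(elem))
  for (i in seq_along(elem)) {
    if (charge[i] != 0) next
    if (elem[i] == "C" && !(i %in% arom)) {
      nb <- adj[[i]]
      # sp3-ish carbon not bonded to N/O and with no double bond to O
      if (!any(elem[nb] %in% c("N", "O"))) apolar[i] <- TRUE
    }
    if (elem[i] %in% c("Cl", "Br", "I", "F")) apolar[i] <- TRUE
  }
  # also demand no double bonds on the carbon (exclude carbonyl/vinyl C)
  for (i in which(apolar & elem == "C")) {
    if (any(bo[i, ] == 2L)) apolar[i] <- FALSE
  }
  if (any(apolar)) {
    comp <- connected_components(which(apolar), adj)
    for (cl in comp) {
      pts <- xyzm[cl, , drop = FALSE]
      add("H", colMeans(pts), atoms = cl)
    }
  }

  if (!length(feats)) {
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), dx = numeric(), dy = numeric(),
                      dz = numeric(), atoms = I(list())))
  }
  df <- data.frame(
    kind = vapply(feats, `[[`, character(1), "kind"),
    x = vapply(feats, function(f) f$pos[1], numeric(1)),
    y = vapply(feats, function(f) f$pos[2], numeric(1)),
    z = vapply(feats, function(f) f$pos[3], numeric(1)),
    dx = vapply(feats, function(f) f$dir[1], numeric(1)),
    dy = vapply(feats, function(f) f$dir[2], numeric(1)),
    dz = vapply(feats, function(f) f$dir[3], numeric(1)),
    atoms = I(lapply(feats, `[[`, "atoms"))
  )
  # canonical ordering: by kind, then rounded position
  ord <- order(df$kind, round(df$x, 4), round(df$y, 4), round(df$z, 4))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

connected_components <- function(members, adj) {
  comp <- list()
  left <- members
  while (length(left)) {
    seed <- left[1]
    seen <- seed
    queue <- seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (w %in% left && !(w %in% seen)) {
          seen <- c(seen, w)
          queue <- c(queue, w)
        }
      }
    }
    comp[[length(comp) + 1]] <- sort(seen)
    left <- setdiff(left, seen)
  }
  comp
}

#' Documented feature-detection rule table
#'
#' Returns the rule table behind [perceive_features()] as a data.frame, so
#' the definitions are inspectable and the mapping from structural pattern
#' to feature kind is explicit.
#' @export
feature_rules <- function() {
  data.frame(
    kind = c("A", "A", "D", "R", "H", "N", "P"),
    pattern = c(
      "neutral O with <=2 heavy neighbours (carbonyl, ether, hydroxyl)",
      "aromatic N, no H, two ring bonds (pyridine-type)",
      "neutral N/O bearing >=1 H (amide NH, aniline NH2, OH)",
      "aromatic 5/6-ring (near-planar, sp2 members)",
      "connected cluster of apolar C (no N/O neighbours, no C=X) and halogens",
      "heavy atom with negative formal charge",
      "heavy atom with positive formal charge"
    ),
    direction = c("mean lone-pair axis", "lone-pair axis", "mean X-H axis",
                  "ring normal", "none", "none", "none")
  )
}

#' Perceive features for every conformer of an ensemble
#'
#' @param ensemble a `conformer_ensemble`.
#' @return list of feature data.frames, one per conformer.
#' @export
ensemble_features <- function(ensemble) {
  lapply(ensemble$conformers, function(cf) {
    perceive_features(ensemble$mol, xyz = cf$xyz)
  })
}
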