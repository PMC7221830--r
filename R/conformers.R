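#' Conformer ensembles
#'
#' Conformer generation works in torsion space: the input 3D geometry
#' (bond lengths, angles, ring geometry) is kept rigid and only acyclic
#' single bonds between non-terminal heavy atoms are rotated. Candidate
#' torsion vectors are drawn by a seeded Monte Carlo multiple-minimum
#' style search, each candidate is locally minimized under the package's
#' torsional + Lennard-Jones energy model, and the resulting pool is
#' pruned to the stated energy window and heavy-atom RMSD redundancy
#' cutoff.
#'
#' @name conformers
NULL

#' Find rotatable bonds
#'
#' A bond is rotatable when it is a single, acyclic bond whose two atoms
#' are both non-terminal heavy atoms (each has at least one further heavy
#' neighbour). Amide C-N bonds are excluded (kept planar).
#'
#' @param mol a [molgraph()].
#' @return data.frame with columns `a1`, `a2` (the bond) and `moving`
#'   (list-column of atom indices on the `a2` side).
#' @export
rotatable_bonds <- function(mol) {
  adj <- adjacency(mol)
  bo <- bond_order_matrix(mol)
  elem <- mol$atoms$elem
  ring_atoms <- unique(unlist(find_rings(mol)))
  res <- list()
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    if (mol$bonds$order[i] != 1L) next
    if (elem[a] == "H" || elem[b] == "H") next
    # acyclic: not both endpoints in one ring containing the bond
    in_ring <- FALSE
    for (ring in find_rings(mol)) {
      if (a %in% ring && b %in% ring) { in_ring <- TRUE; break }
    }
    if (in_ring) next
    heavy_a <- sum(elem[setdiff(adj[[a]], b)] != "H")
    heavy_b <- sum(elem[setdiff(adj[[b]], a)] != "H")
    if (heavy_a < 1 || heavy_b < 1) next
    # amide bond: N-C where C double-bonds O
    is_amide <- FALSE
    for (pair in list(c(a, b), c(b, a))) {
      nn <- pair[1]; cc <- pair[2]
      if (elem[nn] == "N" && elem[cc] == "C") {
        oth <- setdiff(adj[[cc]], nn)
        if (any(elem[oth] == "O" & bo[cc, oth] == 2)) is_amide <- TRUE
      }
    }
    if (is_amide) next
    moving <- side_atoms(adj, b, a)
    res[[length(res) + 1]] <- list(a1 = a, a2 = b, moving = moving)
  }
  if (!length(res)) {
    return(data.frame(a1 = integer(), a2 = integer(),
                      moving = I(list())))
  }
  data.frame(
    a1 = vapply(res, `[[`, integer(1), "a1"),
    a2 = vapply(res, `[[`, integer(1), "a2"),
    moving = I(lapply(res, `[[`, "moving"))
  )
}

# atoms reachable from `start` without crossing back through `block`
side_atoms <- function(adj, start, block) {
  seen <- c(block, start)
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!(w %in% seen)) {
        seen <- c(seen, w)
        queue <- c(queue, w)
      }
    }
  }
  setdiff(seen, c(block, start))
}

#' Set torsion angles on a geometry
#'
#' Rotates the moving side of each rotatable bond so that the dihedral
#' defined by (neighbour, a1, a2, neighbour) attains the requested value.
#' Applied in bond order; used by both the stochastic search and the
#' exhaustive torsion-scan oracle in the test-suite.
#' @noRd
set_torsions <- function(xyz, rot, angles) {
  for (i in seq_len(nrow(rot))) {
    a1 <- rot$a1[i]; a2 <- rot$a2[i]
    axis <- unitv(xyz[a2, ] - xyz[a1, ])
    cur <- current_torsion(xyz, rot, i)
    delta <- (angles[i] - cur) * pi / 180
    mv <- c(rot$moving[[i]], integer(0))
    if (!length(mv)) next
    pts <- xyz[mv, , drop = FALSE]
    pts <- sweep(pts, 2, xyz[a2, ])
    R <- rotation_about_axis(axis, delta)
    pts <- pts %*% t(R)
    xyz[mv, ] <- sweep(pts, 2, -xyz[a2, ])
  }
  xyz
}

current_torsion <- function(xyz, rot, i) {
  a1 <- rot$a1[i]; a2 <- rot$a2[i]
  ref1 <- attr(rot, "ref1")[i]; ref2 <- attr(rot, "ref2")[i]
  dihedral(xyz[ref1, ], xyz[a1, ], xyz[a2, ], xyz[ref2, ])
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

# attach dihedral reference atoms (a heavy neighbour on each side) to the
# rotatable-bond table
with_torsion_refs <- function(mol, rot) {
  adj <- adjacency(mol)
  elem <- mol$atoms$elem
  pick_ref <- function(center, exclude) {
    nb <- setdiff(adj[[center]], exclude)
    heavy <- nb[elem[nb] != "H"]
    if (length(heavy)) min(heavy) else min(nb)
  }
  attr(rot, "ref1") <- vapply(seq_len(nrow(rot)), function(i) {
    pick_ref(rot$a1[i], rot$a2[i])
  }, integer(1))
  attr(rot, "ref2") <- vapply(seq_len(nrow(rot)), function(i) {
    pick_ref(rot$a2[i], rot$a1[i])
  }, integer(1))
  rot
}

#' Conformer strain energy (kJ/mol)
#'
#' The package's internal energy model for torsional sampling: a threefold
#' torsional potential on each rotatable sp3-sp3 bond plus a truncated
#' Lennard-Jones nonbonded term over atom pairs separated by more than
#' three bonds (1-4 pairs scaled by 0.5). Parameters: V3 = 12 kJ/mol,
#' epsilon = 0.15 kJ/mol, contact distances at 0.8 of the Bondi-radius
#' sum (soft, so torsional minima stay at clean staggered rotamers).
#' Deliberately simple and
#' fully self-contained; only relative energies within one molecule are
#' meaningful.
#'
#' @param mol a [molgraph()].
#' @param xyz optional coordinate matrix overriding the stored geometry.
#' @return energy in kJ/mol (arbitrary zero).
#' @export
conformer_energy <- function(mol, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(mol)
  pre <- energy_precompute(mol)
  energy_eval(pre, xyz)
}

energy_precompute <- function(mol) {
  bd <- bond_distances(mol)
  n <- n_atoms(mol)
  elem <- mol$atoms$elem
  pairs <- which(upper.tri(bd) & bd >= 4, arr.ind = TRUE)
  pairs14 <- which(upper.tri(bd) & bd == 3, arr.ind = TRUE)
  radii <- vdw_radius(elem)
  # sigma: contact distance = 0.8 * sum of radii (soft; keeps torsional
  # minima at staggered rotamers instead of splitting under 1-5 clashes)
  sigma_full <- 0.8 * (radii[pairs[, 1]] + radii[pairs[, 2]])
  sigma_14 <- 0.8 * (radii[pairs14[, 1]] + radii[pairs14[, 2]])
  rot <- with_torsion_refs(mol, rotatable_bonds(mol))
  list(pairs = pairs, pairs14 = pairs14,
       sigma_full = sigma_full, sigma_14 = sigma_14,
       rot = rot, eps = 0.15, v3 = 12)
}

energy_eval <- function(pre, xyz) {
  e <- 0
  lj <- function(p, sigma, scale) {
    if (!nrow(p)) return(0)
    d2 <- rowSums((xyz[p[, 1], , drop = FALSE] - xyz[p[, 2], , drop = FALSE])^2)
    d2 <- pmax(d2, 0.4)  # guard against overlap singularities
    sr6 <- (sigma^2 / d2)^3
    sum(scale * 4 * pre$eps * (sr6^2 - sr6))
  }
  e <- e + lj(pre$pairs, pre$sigma_full, 1) + lj(pre$pairs14, pre$sigma_14, 0.5)
  rot <- pre$rot
  if (nrow(rot)) {
    for (i in seq_len(nrow(rot))) {
      phi <- current_torsion(xyz, rot, i) * pi / 180
      e <- e + pre$v3 / 2 * (1 + cos(3 * phi))
    }
  }
  e
}

#' Minimize torsions from a starting angle vector
#'
#' Quasi-Newton minimization of [conformer_energy()] over the torsion
#' angles, honouring a maximum iteration count and a gradient convergence
#' threshold (kJ/mol per degree).
#' @noRd
minimize_torsions <- function(xyz0, pre, angles, max_iter = 2000,
                              grad_tol = 1e-3) {
  if (!nrow(pre$rot)) {
    return(list(angles = angles, energy = energy_eval(pre, xyz0), xyz = xyz0))
  }
  fn <- function(a) energy_eval(pre, set_torsions(xyz0, pre$rot, a))
  res <- stats::optim(angles, fn, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-10))
  # explicit gradient-threshold check (numerical central difference)
  g <- numeric(length(res$par))
  h <- 1e-3
  for (j in seq_along(g)) {
    up <- res$par; up[j] <- up[j] + h
    dn <- res$par; dn[j] <- dn[j] - h
    g[j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  if (sqrt(sum(g^2)) > grad_tol) {
    res <- stats::optim(res$par, fn, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-14))
  }
  xyz <- set_torsions(xyz0, pre$rot, res$par)
  list(angles = res$par, energy = res$value, xyz = xyz)
}

#' Generate a pruned conformer ensemble
#'
#' Stochastic torsional search: starting from the input geometry, random
#' torsion vectors are drawn and locally minimized under
#' [conformer_energy()]; minima are pooled, sorted by energy, and pruned so
#' that every retained conformer lies within `window` kJ/mol of the global
#' minimum and every retained pair is at least `rmsd_cut` apart in
#' best-fit heavy-atom RMSD. Deterministic for a fixed seed.
#'
#' @param record a `molecule_record` or bare [molgraph()] with 3D
#'   coordinates.
#' @param max_confs maximum conformers retained (default 100).
#' @param window energy window in kJ/mol (default 21).
#' @param rmsd_cut redundancy cutoff in Angstrom (default 0.5).
#' @param seed integer seed (required).
#' @param max_iter minimizer iteration cap (default 2000).
#' @param grad_tol minimizer gradient threshold (default 0.001).
#' @param n_samples Monte Carlo starts; default scales with the number of
#'   rotatable bonds.
#' @return a `conformer_ensemble`: list with `molecule_id`, `mol` and
#'   `conformers` (each `list(xyz, rel_energy)`), energies in kJ/mol
#'   relative to the best conformer.
#' @export
generate_conformers <- function(record, max_confs = 100, window = 21.0,
                                rmsd_cut = 0.5, seed, max_iter = 2000,
                                grad_tol = 1e-3, n_samples = NULL) {
  mol <- if (inherits(record, "molecule_record")) record$mol else record
  xyz0 <- coords(mol)
  if (all(abs(xyz0) < 1e-9)) {
    stopf("molecule %s has no 3D coordinates; run 3D embedding first", mol$id)
  }
  pre <- energy_precompute(mol)
  rot <- pre$rot
  k <- nrow(rot)
  if (is.null(n_samples)) n_samples <- min(300L, max(20L, 25L * 3L^min(k, 3L)))
  start <- if (k) vapply(seq_len(k), function(i) current_torsion(xyz0, rot, i),
                         numeric(1)) else numeric(0)
  pool <- list()
  bases <- list()
  push <- function(fit) {
    pool[[length(pool) + 1]] <<- fit
    # usage-directed restarts: keep distinct minima as future starting
    # points (distinct = any torsion differing by more than 15 degrees)
    ang <- ((fit$angles + 180) %% 360) - 180
    for (b in bases) {
      d <- abs(((ang - b + 180) %% 360) - 180)
      if (max(d) < 15) return(invisible(NULL))
    }
    bases[[length(bases) + 1]] <<- ang
  }
  push(minimize_torsions(xyz0, pre, start, max_iter, grad_tol))
  if (k) {
    with_seed(seed, {
      for (s in seq_len(n_samples)) {
        base <- bases[[sample.int(length(bases), 1)]]
        ang <- base
        nmut <- sample(seq_len(k), 1)
        which_mut <- sample(seq_len(k), nmut)
        ang[which_mut] <- stats::runif(nmut, -180, 180)
        push(minimize_torsions(xyz0, pre, ang, max_iter, grad_tol))
      }
    })
  }
  energies <- vapply(pool, `[[`, numeric(1), "energy")
  ord <- order(energies)
  pool <- pool[ord]; energies <- energies[ord]
  emin <- energies[1]
  hv <- heavy_idx(mol)
  kept <- list(); kept_e <- numeric()
  for (i in seq_along(pool)) {
    if (energies[i] - emin > window) break
    xyz <- pool[[i]]$xyz
    redundant <- FALSE
    for (kx in kept) {
      if (bestfit_rmsd(xyz[hv, , drop = FALSE], kx[hv, , drop = FALSE]) < rmsd_cut) {
        redundant <- TRUE; break
      }
    }
    if (!redundant) {
      kept[[length(kept) + 1]] <- xyz
      kept_e <- c(kept_e, energies[i] - emin)
      if (length(kept) >= max_confs) break
    }
  }
  conformer_ensemble(mol, kept, kept_e)
}

#' Construct a conformer ensemble object
#' @param mol a [molgraph()].
#' @param xyz_list list of coordinate matrices.
#' @param rel_energies numeric vector, kJ/mol, minimum 0.
#' @export
conformer_ensemble <- function(mol, xyz_list, rel_energies) {
  stopifnot(length(xyz_list) == length(rel_energies))
  if (length(rel_energies)) {
    rel_energies <- rel_energies - min(rel_energies)
  }
  structure(
    list(
      molecule_id = mol$id,
      mol = mol,
      conformers = lapply(seq_along(xyz_list), function(i) {
        list(xyz = xyz_list[[i]], rel_energy = rel_energies[i])
      })
    ),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  e <- vapply(x$conformers, `[[`, numeric(1), "rel_energy")
  cat(sprintf("<conformer_ensemble %s: %d conformer(s), rel E 0..%.2f kJ/mol>\n",
              x$molecule_id, length(x$conformers),
              if (length(e)) max(e) else 0))
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ensemble a `conformer_ensemble`.
#' @export
n_conformers <- function(ensemble) length(ensemble$conformers)
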