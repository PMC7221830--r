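# Independent oracles used across the test-suite. Each reimplements the
# quantity under test by a different route than the package.

# Horn's quaternion characteristic-polynomial method for optimal rigid
# superposition RMSD (independent of the SVD route in the package)
quaternion_rmsd <- function(ref, mov) {
  n <- nrow(ref)
  a <- sweep(mov, 2, colMeans(mov))
  b <- sweep(ref, 2, colMeans(ref))
  M <- crossprod(a, b)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lambda) / n
  sqrt(max(0, msd))
}

# brute-force cube-center occupancy: triple loop over the whole grid
occupancy_bruteforce <- function(xyz, cls, radii, grid) {
  ncls <- length(grid$atom_classes)
  keys <- integer(0)
  for (ix in 0:(grid$extents[1] - 1)) {
    for (iy in 0:(grid$extents[2] - 1)) {
      for (iz in 0:(grid$extents[3] - 1)) {
        cen <- grid$origin + c(ix, iy, iz) * grid$spacing
        for (a in seq_len(nrow(xyz))) {
          ci <- match(cls[a], grid$atom_classes)
          if (is.na(ci)) next
          if (sum((xyz[a, ] - cen)^2) <= radii[a]^2) {
            cube <- ix + grid$extents[1] * (iy + grid$extents[2] * iz)
            keys <- c(keys, cube * ncls + (ci - 1L))
          }
        }
      }
    }
  }
  sort(unique(keys))
}

# AUC as the normalized Mann-Whitney rank-sum statistic with average ranks
ranksum_auc <- function(scores, labels) {
  r <- rank(scores)
  npos <- sum(labels); nneg <- sum(!labels)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# ordinary least squares predictions by the normal equations
ols_predictions <- function(X, y) {
  Xa <- cbind(1, X)
  beta <- solve(crossprod(Xa), crossprod(Xa, y))
  as.vector(Xa %*% beta)
}

# overlap volume of two spheres by numerical integration on a fine grid
sphere_overlap_numeric <- function(r1, r2, d, n = 120) {
  # sphere 1 at origin, sphere 2 at (d, 0, 0); integrate over sphere 1 box
  h <- 2 * r1 / n
  xs <- seq(-r1 + h / 2, r1 - h / 2, length.out = n)
  total <- 0
  for (x in xs) {
    for (y in xs) {
      inside1 <- x^2 + y^2 <= r1^2
      if (!any(inside1)) next
      z2max <- r1^2 - x^2 - y^2
      if (z2max <= 0) next
      zs <- seq(-sqrt(z2max) + h / 2, sqrt(z2max) - h / 2, by = h)
      if (!length(zs)) next
      in2 <- ((x - d)^2 + y^2 + zs^2) <= r2^2
      total <- total + sum(in2) * h^3
    }
  }
  total
}

# exhaustive torsion-grid conformer search with the package's energy model
# and pruning rules, as the independent route for the stochastic
# conformational search; a 60-degree grid is used so that symmetry-split
# gauche minima (syn-pentane-like distortions) are reached from at least
# one start
torsion_grid_conformers <- function(mol, window = 21, rmsd_cut = 0.5,
                                    step = 60) {
  pre <- pharmqsar:::energy_precompute(mol)
  rot <- pre$rot
  k <- nrow(rot)
  xyz0 <- pharmqsar:::coords(mol)
  start <- vapply(seq_len(k), function(i) {
    pharmqsar:::current_torsion(xyz0, rot, i)
  }, numeric(1))
  grid <- expand.grid(rep(list(seq(0, 359, by = step)), k))
  fits <- list()
  for (i in seq_len(nrow(grid))) {
    ang <- start + as.numeric(grid[i, ])
    fits[[i]] <- pharmqsar:::minimize_torsions(xyz0, pre, ang)
  }
  energies <- vapply(fits, `[[`, numeric(1), "energy")
  ord <- order(energies)
  fits <- fits[ord]; energies <- energies[ord]
  emin <- energies[1]
  hv <- pharmqsar:::heavy_idx(mol)
  kept <- list()
  for (i in seq_along(fits)) {
    if (energies[i] - emin > window) break
    xyz <- fits[[i]]$xyz
    dup <- FALSE
    for (kx in kept) {
      if (pharmqsar:::bestfit_rmsd(xyz[hv, , drop = FALSE],
                                   kx[hv, , drop = FALSE]) < rmsd_cut) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept[[length(kept) + 1]] <- xyz
  }
  kept
}

# best kind-respecting alignment by plain nested enumeration (no shared
# code with match_and_align's assignment generator)
bruteforce_best_rmsd <- function(hyp_kinds, hyp_pos, lig_kinds, lig_pos) {
  best <- Inf
  k <- length(hyp_kinds)
  rec <- function(slot, used) {
    if (slot > k) {
      fit <- try(pharmqsar::superpose(hyp_pos, lig_pos[used, , drop = FALSE]),
                 silent = TRUE)
      if (!inherits(fit, "try-error") && fit$rmsd < best) best <<- fit$rmsd
      return()
    }
    for (j in seq_along(lig_kinds)) {
      if (j %in% used) next
      if (lig_kinds[j] != hyp_kinds[slot]) next
      rec(slot + 1, c(used, j))
    }
  }
  rec(1, integer(0))
  best
}

# idealized all-anti n-alkane geometry built in code (3D embedding of
# SMILES via Open Babel is not deterministic across processes, so the
# conformer-enumeration comparison needs a fixed start geometry)
ideal_alkane <- function(n_carbons, id = sprintf("C%d", n_carbons)) {
  d <- 1.53
  theta <- 111.5 * pi / 180
  dx <- d * sin(theta / 2); dz <- d * cos(theta / 2)
  cpos <- t(vapply(seq_len(n_carbons), function(i) {
    c((i - 1) * dx, 0, (i %% 2) * dz)
  }, numeric(3)))
  atoms <- data.frame(elem = rep("C", n_carbons),
                      x = cpos[, 1], y = cpos[, 2], z = cpos[, 3],
                      charge = 0L)
  bonds <- data.frame(a1 = seq_len(n_carbons - 1),
                      a2 = seq_len(n_carbons - 1) + 1L, order = 1L)
  unit <- function(v) v / sqrt(sum(v^2))
  add_h <- function(pos) {
    atoms <<- rbind(atoms, data.frame(elem = "H", x = pos[1], y = pos[2],
                                      z = pos[3], charge = 0L))
    nrow(atoms)
  }
  for (i in seq_len(n_carbons)) {
    nb <- c(if (i > 1) i - 1, if (i < n_carbons) i + 1)
    C <- cpos[i, ]
    if (length(nb) == 2) {
      d1 <- unit(cpos[nb[1], ] - C); d2 <- unit(cpos[nb[2], ] - C)
      u <- unit(-(d1 + d2)); v <- unit(pracma_cross_test(d1, d2))
      for (s in c(1, -1)) {
        h <- add_h(C + 1.09 * unit(u + s * 1.1 * v))
        bonds <- rbind(bonds, data.frame(a1 = as.integer(i),
                                         a2 = as.integer(h), order = 1L))
      }
    } else {
      ax <- unit(C - cpos[nb, ])
      p <- unit(pracma_cross_test(ax, c(0, 1, 0)))
      q <- unit(pracma_cross_test(ax, p))
      for (phi in c(0, 2 * pi / 3, 4 * pi / 3)) {
        dir <- unit(ax * 0.336 + (cos(phi) * p + sin(phi) * q) * 0.942)
        h <- add_h(C + 1.09 * dir)
        bonds <- rbind(bonds, data.frame(a1 = as.integer(i),
                                         a2 = as.integer(h), order = 1L))
      }
    }
  }
  molgraph(atoms, bonds, id = id)
}

pracma_cross_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random proper rotation matrix
random_rotation_oracle <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
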