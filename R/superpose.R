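#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rotation `R` and translation `t` minimizing the
#' root-mean-square deviation between `mov` transformed as `mov %*% t(R) + t`
#' and `ref`. Reflections are never returned: when the optimal orthogonal
#' transform would be improper, the smallest singular direction is flipped,
#' giving the best proper rotation.
#'
#' @param ref n x 3 matrix of reference coordinates (Angstrom).
#' @param mov n x 3 matrix of moving coordinates, row-paired with `ref`.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom).
#' @examples
#' p <- matrix(rnorm(15), 5, 3)
#' fit <- superpose(p, p)
#' fit$rmsd  # 0
#' @export
superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3 || ncol(mov) != 3) {
    stopf("superpose needs two n x 3 matrices with equal n")
  }
  n <- nrow(ref)
  if (n < 3) stopf("superpose needs at least 3 point pairs, got %d", n)
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(ref, 2, cr); B <- sweep(mov, 2, cm)
  # collinearity check: rank of either centered set < 2
  if (svd(A)$d[2] < 1e-8 || svd(B)$d[2] < 1e-8) {
    stopf("superpose: point sets are collinear, rotation is underdetermined")
  }
  H <- crossprod(B, A)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cr - as.vector(R %*% cm)
  moved <- mov %*% t(R) + matrix(t, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - ref)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 rotation.
#' @param translation length-3 vector.
#' @export
apply_transform <- function(xyz, rotation, translation) {
  xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

#' Best-fit RMSD between two conformations of the same atom list
#'
#' Pairs rows as given; for fewer than 3 points, or collinear sets, falls
#' back to centroid-aligned RMSD without rotation fitting.
#' @noRd
bestfit_rmsd <- function(a, b) {
  n <- nrow(a)
  if (n == 1) return(0)
  ok <- n >= 3
  if (ok) {
    A <- sweep(a, 2, colMeans(a))
    ok <- svd(A)$d[2] >= 1e-8
  }
  if (!ok) {
    # centered distance profile; rotation cannot change it for <3 points
    da <- sweep(a, 2, colMeans(a)); db <- sweep(b, 2, colMeans(b))
    return(sqrt(abs(mean(rowSums(da^2)) + mean(rowSums(db^2)) -
                      2 * mean(sqrt(rowSums(da^2) * rowSums(db^2))))))
  }
  superpose(a, b)$rmsd
}
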