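# Kabsch superposition: closed-form least-squares rigid fit.

#' Optimal rigid superposition of two point sets
#'
#' Returns the proper rotation `R` and translation `t` minimising the RMSD of
#' `R %*% x + t` over the rows of `moving` against the corresponding rows of
#' `fixed` (SVD solution; the reflection case is corrected so that
#' `det(R) = +1`).
#'
#' @param moving,fixed n x 3 coordinate matrices with matched rows, n >= 3.
#' @return a list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (the minimised value, Angstrom).
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (ncol(moving) != 3L || ncol(fixed) != 3L)
    stopf("kabsch expects n x 3 matrices")
  n <- nrow(moving)
  if (n != nrow(fixed)) stopf("kabsch: point counts differ (%d vs %d)",
                              n, nrow(fixed))
  if (n < 3L) stopf("kabsch needs at least 3 points, got %d", n)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  # degenerate (collinear) sets have no unique rotation
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-8 * max(sv[1L], 1e-12))
    stopf("kabsch: degenerate (collinear) point set")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- as.numeric(cf - R %*% cm)
  fit <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param x an n x 3 matrix, or a `structure_model`.
#' @param transform a list with `rotation` and `translation` (as returned by
#'   [kabsch()]).
#' @return object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  R <- transform$rotation; t <- transform$translation
  if (inherits(x, "structure_model")) {
    xyz <- as.matrix(x[, c("x", "y", "z")]) %*% t(R)
    x$x <- xyz[, 1L] + t[1L]; x$y <- xyz[, 2L] + t[2L]; x$z <- xyz[, 3L] + t[3L]
    return(x)
  }
  sweep(as.matrix(x) %*% t(R), 2, -t)
}

# rotation matrix for angle (radians) about a unit axis (Rodrigues)
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  # uniform over SO(3) via QR of a Gaussian matrix
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
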