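#' Rigid transforms and least-squares superposition
#'
#' A `rigid_transform` is a proper rotation plus translation acting on row
#' vectors: `x' = x %*% R + t`.  `kabsch_superpose()` finds the transform
#' minimizing the RMSD between two paired coordinate sets (the Kabsch
#' SVD solution), the workhorse behind every conformational metric in the
#' package.
#'
#' @name superpose
NULL

#' Construct a rigid transform
#'
#' @param R 3x3 proper rotation matrix (det = +1).
#' @param t length-3 translation vector in Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(identical(dim(R), c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("R is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    stop("R is not a proper rotation (det != +1)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' Rotation matrix from axis and angle
#'
#' @param axis length-3 axis (need not be unit length).
#' @param angle_deg rotation angle in degrees, right-handed about `axis`.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("rotation axis must be non-zero")
  u <- u / nu
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix (rows are points).
#' @param tr a `rigid_transform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tr) {
  stopifnot(inherits(tr, "rigid_transform"))
  xyz <- as.matrix(xyz)
  sweep(xyz %*% tr$R, 2, -tr$t)
}

#' Compose a rigid transform rotating about a fixed center then translating
#'
#' Convenience for motion specs: `x' = (x - c) %*% R + c + shift`.
#'
#' @param R 3x3 rotation matrix.
#' @param center rotation center (length 3).
#' @param shift translation applied after the rotation (length 3).
#' @return A `rigid_transform`.
#' @export
transform_about_center <- function(R = diag(3), center = c(0, 0, 0),
                                   shift = c(0, 0, 0)) {
  center <- as.numeric(center); shift <- as.numeric(shift)
  rigid_transform(R = R, t = center - as.numeric(center %*% R) + shift)
}

#' Least-squares superposition of paired coordinate sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference`, which must be paired row-for-row.  The SVD of
#' the cross-covariance matrix gives the global optimum; a reflection is
#' corrected to a proper rotation via the sign of the determinant.
#'
#' @param mobile n x 3 matrix, or an `atom_set` (see [resolve_selection()]).
#' @param reference n x 3 matrix or `atom_set`, paired with `mobile`.
#' @return A `superposition_result`: list with `transform`
#'   (`rigid_transform` mapping mobile onto reference), `rmsd_fit`
#'   (Angstrom, over the alignment atoms), and `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- coords_of(mobile)
  Q <- coords_of(reference)
  if (nrow(P) != nrow(Q))
    stop("mobile and reference must be paired (equal number of atoms)")
  n <- nrow(P)
  if (n < 3) stop("degenerate alignment: need at least 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate alignment: atoms are collinear (rank < 2)")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cq - as.numeric(cp %*% R)
  fitted <- sweep(P %*% R, 2, -t)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(
    list(transform = rigid_transform(R, t), rmsd_fit = rmsd, n_atoms = n,
         provenance = list(mobile = attr(mobile, "provenance"),
                           reference = attr(reference, "provenance"))),
    class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms, rmsd_fit = %.3f A\n",
              x$n_atoms, x$rmsd_fit))
  invisible(x)
}

# Extract an n x 3 coordinate matrix from a matrix or atom_set.
coords_of <- function(x) {
  if (inherits(x, "atom_set")) x <- as.matrix(x$atoms[, c("x", "y", "z")])
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must be an n x 3 matrix")
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("coordinates contain non-finite values")
  x
}

#' Helix axis from consecutive C-alpha positions
#'
#' Estimates the axis of an alpha-helix as the principal direction of the
#' C-alpha trace after smoothing each position with its i-1/i+1 neighbours
#' (which suppresses the ~100 degree helical wobble of the raw trace).
#' The axis is oriented N-terminus to C-terminus.
#'
#' @param helix n x 3 C-alpha coordinate matrix in chain order, or an
#'   `atom_set`; at least 7 consecutive residues.
#' @return A `helix_geometry`: list with unit `axis`, `centroid`, and `n`.
#' @export
helix_axis <- function(helix) {
  X <- coords_of(helix)
  n <- nrow(X)
  if (n < 7) stop("insufficient helix: need >= 7 consecutive C-alpha atoms")
  # running mean over i-1, i, i+1 (ends dropped)
  S <- (X[1:(n - 2), , drop = FALSE] + X[2:(n - 1), , drop = FALSE] +
        X[3:n, , drop = FALSE]) / 3
  ctr <- colMeans(S)
  S0 <- sweep(S, 2, ctr)
  ev <- eigen(crossprod(S0), symmetric = TRUE)
  a <- ev$vectors[, 1]
  # orient N -> C
  if (sum(a * (S[nrow(S), ] - S[1, ])) < 0) a <- -a
  structure(list(axis = a / sqrt(sum(a^2)), centroid = colMeans(X), n = n),
            class = "helix_geometry")
}

#' Angle in degrees between two direction vectors
#'
#' Unsigned angle between N->C oriented axes, in [0, 180].
#'
#' @param a,b length-3 vectors.
#' @return Angle in degrees.
#' @export
angle_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  acos(min(1, max(-1, d))) * 180 / pi
}
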