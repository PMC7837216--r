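# Independent quaternion-method (Horn) superposition oracle.
# Solves the same least-squares problem as the package's SVD route via
# the eigen-decomposition of the 4x4 quaternion matrix, sharing no code
# with the implementation under test.
quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(P0, Q0)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sq <- sum(P0^2) + sum(Q0^2) - 2 * lam
  sqrt(max(0, sq) / nrow(P))
}

random_cloud <- function(n = 10) matrix(stats::rnorm(3 * n, sd = 5), n, 3)

# noisy copy of a cloud under a random rigid transform
transformed_cloud <- function(P, noise_sd = 0) {
  R <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
  t <- stats::runif(3, -20, 20)
  Q <- sweep(P %*% R, 2, -t)
  if (noise_sd > 0) Q <- Q + matrix(stats::rnorm(length(Q), 0, noise_sd),
                                    nrow(Q), 3)
  Q
}
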