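# Real spherical harmonics and real Wigner rotation matrices.
#
# Convention: S_{l,mu} with mu = -l..l; mu > 0 carries cos(mu phi), mu < 0
# carries sin(|mu| phi), and the associated Legendre functions are taken
# without the Condon-Shortley phase. In this real basis the l = 1 harmonics
# are proportional to (y, z, x).

# Associated Legendre P_l^m(x) without Condon-Shortley phase, m >= 0.
.assoc_legendre <- function(l, m, x) {
  if (m > l) return(rep(0, length(x)))
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(1 - x^2, 0))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

#' Real spherical harmonics
#'
#' Evaluates the 2l+1 real spherical harmonics at one or more unit vectors.
#' Inputs must already be normalized: a non-unit vector is an error, never
#' silently rescaled.
#'
#' @param l angular momentum (integer >= 0).
#' @param unit_vector a 3-vector, or a 3 x k matrix of unit column vectors.
#' @return a vector of length 2l+1 (components mu = -l..l), or a
#'   (2l+1) x k matrix.
#' @export
real_spherical_harmonics <- function(l, unit_vector) {
  u <- if (is.matrix(unit_vector)) unit_vector else matrix(unit_vector, 3, 1)
  if (nrow(u) != 3) stop("unit_vector must have 3 rows")
  nrm <- sqrt(colSums(u^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("unit_vector must be normalized to |u| = 1 (got |u| = ",
         format(nrm[which.max(abs(nrm - 1))]), ")")
  ct <- u[3, ]
  phi <- atan2(u[2, ], u[1, ])
  out <- matrix(0, 2 * l + 1, ncol(u))
  for (mu in (-l):l) {
    m <- abs(mu)
    nlm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    p <- .assoc_legendre(l, m, ct)
    v <- if (mu == 0) nlm * p
         else if (mu > 0) sqrt(2) * nlm * p * cos(m * phi)
         else sqrt(2) * nlm * p * sin(m * phi)
    out[mu + l + 1, ] <- v
  }
  if (!is.matrix(unit_vector)) out[, 1] else out
}

# Deterministic well-spread unit vectors (spherical Fibonacci lattice),
# used to solve for Wigner matrices without touching the RNG.
.fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Real Wigner rotation matrix
#'
#' The orthogonal matrix D^l(R) satisfying
#' `S_l(R u) = D^l(R) S_l(u)` for the real spherical harmonics S_l. It is
#' recovered by least squares from harmonics evaluated on a deterministic
#' spherical design, which keeps it exactly consistent with the phase
#' convention of [real_spherical_harmonics()].
#'
#' @param l angular momentum.
#' @param R a 3 x 3 rotation (or improper rotation) matrix.
#' @return orthogonal (2l+1) x (2l+1) matrix.
#' @export
wigner_d_real <- function(l, R) {
  if (l == 0) return(matrix(1, 1, 1))
  npts <- max(4 * (2 * l + 1), 32)
  U <- .fibonacci_sphere(npts)
  Y0 <- real_spherical_harmonics(l, U)
  Y1 <- real_spherical_harmonics(l, R %*% U)
  t(solve(Y0 %*% t(Y0), Y0 %*% t(Y1)))
}

#' Random rotation matrix from a quaternion
#'
#' Draws a uniform random rotation (used by equivariance tests); consumes
#' the current RNG stream.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
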