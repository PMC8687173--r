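#' Gaussian belief over the model state
#'
#' Mean and covariance of a Gaussian state estimate. The covariance is
#' symmetrized on construction; eigenvalues below -1e-9 raise an error,
#' smaller negative ripples are tolerated (and repaired where a matrix
#' square root is needed).
#'
#' @param mean numeric mean vector.
#' @param cov covariance matrix, `length(mean)` square.
#' @return An object of class `gaussian_belief` with fields `mean`, `cov`.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  n <- length(mean)
  if (!all(dim(cov) == n)) stop("covariance dimensions must match the mean")
  if (any(!is.finite(mean)) || any(!is.finite(cov)))
    stop("belief must be finite")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -1e-9 * scale)
    stop("covariance is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

# Lower-triangular matrix square root: Cholesky when possible, else a
# symmetric-eigenvalue factor with eigenvalues floored at 1e-10.
sqrt_psd <- function(P) {
  L <- tryCatch(t(chol(P)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  lam <- e$values
  scale <- max(abs(lam), 1)
  if (min(lam) < -1e-6 * scale)
    stop("covariance square root failed; smallest eigenvalue ",
         format(min(lam)))
  e$vectors %*% diag(sqrt(pmax(lam, 1e-10)), nrow = length(lam))
}

# Symmetrize and floor eigenvalues so downstream Cholesky succeeds.
# Fast path: if the symmetrized matrix is already Cholesky-factorizable it
# is returned untouched.
repair_psd <- function(P) {
  P <- (P + t(P)) / 2
  ok <- tryCatch({chol(P); TRUE}, error = function(e) FALSE)
  if (ok) return(P)
  e <- eigen(P, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, 1e-10), nrow = nrow(P)) %*% t(e$vectors)
}

# internal: belief without the O(n^3) validation pass (cov already repaired)
new_belief <- function(mean, cov) {
  structure(list(mean = as.numeric(mean), cov = cov),
            class = "gaussian_belief")
}

#' Unscented (sigma-point) representation of a Gaussian belief
#'
#' The classical `2n + 1` point set: the mean, plus symmetric excursions
#' along the columns of the lower-triangular square root of
#' `(n + kappa) * P`. Weights are `W0 = kappa/(n + kappa)` for the centre
#' and `1/(2(n + kappa))` for each symmetric point; they sum to one but
#' `W0` is negative for `kappa < 0` (the recommended `kappa = 3 - n`
#' gives `W0 = -3` at `n = 12`).
#'
#' @param belief a [gaussian_belief()].
#' @param kappa scaling parameter; `n + kappa` must be positive.
#' @return An object of class `quadrature_points`: list with `flavour`
#'   (`"unscented"`), `points` (n x (2n+1) matrix, columns are points)
#'   and `weights`.
#' @examples
#' b <- gaussian_belief(rep(0, 12), diag(12))
#' ncol(unscented_points(b, kappa = 3 - 12)$points)  # 25
#' @export
unscented_points <- function(belief, kappa) {
  n <- length(belief$mean)
  if (n + kappa <= 0) stop("n + kappa must be positive")
  L <- sqrt_psd((n + kappa) * belief$cov)
  pts <- cbind(belief$mean, belief$mean + L, belief$mean - L)
  w <- c(kappa / (n + kappa), rep(1 / (2 * (n + kappa)), 2 * n))
  structure(list(flavour = "unscented", points = unname(pts), weights = w),
            class = "quadrature_points")
}

#' Generalized Gauss-Laguerre nodes and weights
#'
#' Roots of the generalized (associated) Laguerre polynomial
#' `L^alpha_n'` and the matching quadrature weights for the weight
#' function `x^alpha * exp(-x)` on `(0, Inf)`, computed by the
#' Golub-Welsch symmetric-tridiagonal eigenvalue method. The weights sum
#' to `Gamma(alpha + 1)` and the rule is exact for polynomials up to
#' degree `2n' - 1`. Used as the radial rule of the cubature-quadrature
#' point set (there with `alpha = n/2 - 1`).
#'
#' @param nprime quadrature order (number of nodes), >= 1.
#' @param alpha exponent of the weight function, > -1.
#' @return List with `nodes` (strictly positive, increasing) and
#'   `weights`.
#' @examples
#' gauss_laguerre(1, 5)$nodes        # alpha + 1 = 6
#' gauss_laguerre(2, 5)$nodes        # 7 -/+ sqrt(7)
#' @export
gauss_laguerre <- function(nprime, alpha) {
  if (nprime < 1) stop("nprime must be at least 1")
  if (alpha <= -1) stop("alpha must exceed -1")
  k <- seq_len(nprime) - 1
  diag_main <- 2 * k + alpha + 1
  if (nprime == 1L) {
    J <- matrix(diag_main, 1, 1)
  } else {
    kk <- seq_len(nprime - 1)
    off <- sqrt(kk * (kk + alpha))
    J <- diag(diag_main)
    J[cbind(kk, kk + 1)] <- off
    J[cbind(kk + 1, kk)] <- off
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- e$values[ord]
  wts <- gamma(alpha + 1) * (e$vectors[1, ord])^2
  list(nodes = nodes, weights = wts)
}

#' Cubature-quadrature representation of a Gaussian belief
#'
#' Combines the third-degree spherical rule (the `2n` intersections of
#' the unit hypersphere with its axes, `+/- e_i`) with an `n'`-node
#' radial generalized Gauss-Laguerre rule at `alpha = n/2 - 1`. The
#' standard-Gaussian points are `eps = sqrt(2*chi) * (+/- e_i)` over all
#' (root, axis) pairs — `2*n*n'` points — with weights proportional to
#' the radial quadrature factors, normalized to sum to one
#' (`w/(2n*Gamma(n/2))` in closed form). With `n' = 1` the set reduces
#' to the familiar third-degree cubature rule `+/- sqrt(n) e_i` with
#' equal weights `1/(2n)`. Points are mapped through the belief's
#' Cholesky factor.
#'
#' @param belief a [gaussian_belief()].
#' @param nprime radial quadrature order, >= 1.
#' @return A `quadrature_points` object (`flavour = "cubature_quadrature"`,
#'   `2*n*nprime` points).
#' @examples
#' b <- gaussian_belief(rep(0, 12), diag(12))
#' ncol(cubature_quadrature_points(b, 2)$points)  # 48
#' @export
cubature_quadrature_points <- function(belief, nprime) {
  n <- length(belief$mean)
  gl <- gauss_laguerre(nprime, n / 2 - 1)
  radii <- sqrt(2 * gl$nodes)
  # unit Gaussian points: for each radial node, +/- each axis
  eps <- matrix(0, n, 2 * n * nprime)
  w <- numeric(2 * n * nprime)
  j <- 0L
  for (i in seq_len(nprime)) {
    for (ax in seq_len(n)) {
      eps[ax, j + 1L] <- radii[i]
      eps[ax, j + 2L] <- -radii[i]
      w[j + 1:2] <- gl$weights[i] / (2 * n * gamma(n / 2))
      j <- j + 2L
    }
  }
  w <- w / sum(w)  # guard rounding; exact normalization in theory
  L <- sqrt_psd(belief$cov)
  structure(list(flavour = "cubature_quadrature",
                 points = unname(belief$mean + L %*% eps), weights = w),
            class = "quadrature_points")
}

#' @export
print.quadrature_points <- function(x, ...) {
  cat(sprintf("%s point set: %d points in dimension %d (weight sum %.12f)\n",
              x$flavour, ncol(x$points), nrow(x$points), sum(x$weights)))
  invisible(x)
}

# Weighted mean/covariance of a point set (the inverse construction).
points_moments <- function(ps) {
  m <- drop(ps$points %*% ps$weights)
  dev <- ps$points - m
  P <- dev %*% (ps$weights * t(dev))
  list(mean = m, cov = (P + t(P)) / 2)
}
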