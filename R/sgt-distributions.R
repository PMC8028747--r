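#' Negative half moments of the gamma scale-mixing variable
#'
#' Computes \eqn{\tilde U_t = E\{U^{-t/2}\} = (\nu_0/2)^{t/2}
#' \Gamma((\nu-t)/2)/\Gamma(\nu/2)} for the mixing variable
#' \eqn{U \sim \mathrm{Gamma}(\nu/2, \nu_0/2)} of a (skew) generalized t
#' distribution.  These moments drive the mean, covariance and shape indices
#' of the whole family; they exist only for \eqn{t < \nu}.
#'
#' @param t moment order (real, may be negative); must satisfy `t < nu`.
#' @param nu degrees of freedom \eqn{\nu > 0}; `Inf` gives the normal limit
#'   where every moment equals 1.
#' @param nu0 second degrees-of-freedom parameter \eqn{\nu_0 > 0}; the
#'   default `nu0 = nu` is the skew-t case.
#' @return the moment value (vectorized over `t`).
#' @examples
#' mixing_moment(2, nu = 5)       # 5/3, the variance inflation of a t_5
#' mixing_moment(1, nu = 5)       # approximately 1.18943
#' @export
mixing_moment <- function(t, nu, nu0 = nu) {
  stopifnot(is.numeric(t), length(nu) == 1L, length(nu0) == 1L)
  if (is.infinite(nu)) return(rep(1, length(t)))
  if (nu <= 0 || nu0 <= 0) stop("degrees of freedom must be positive")
  if (any(t >= nu))
    stop("mixing moment of order t = ", max(t), " does not exist for nu = ", nu)
  exp((t / 2) * log(nu0 / 2) + lgamma((nu - t) / 2) - lgamma(nu / 2))
}

#' Map the working shape parameter to the shape parameter
#'
#' Converts the unrestricted working-shape parameterization
#' \eqn{(\delta, \bar\Omega)} of a skew (generalized) t distribution to the
#' usual shape parameterization \eqn{(\lambda, \Omega)} via
#' \eqn{\Omega = \bar\Omega + \delta\delta^\top} and
#' \eqn{\lambda = (1 + \delta^\top \bar\Omega^{-1}\delta)^{1/2}
#' \Omega^{-1/2}\delta}, with the symmetric matrix square root.
#'
#' @param delta working shape vector \eqn{\delta}.
#' @param omega_bar positive-definite matrix \eqn{\bar\Omega} (a scalar is
#'   promoted to a 1x1 matrix).
#' @return list with components `lambda` and `omega`.
#' @seealso [lambda_to_delta()] for the inverse map.
#' @export
delta_to_lambda <- function(delta, omega_bar) {
  delta <- as.numeric(delta)
  if (any(!is.finite(delta))) stop("delta must be finite")
  omega_bar <- as.matrix(omega_bar)
  .check_pd(omega_bar, "omega_bar")
  if (length(delta) != nrow(omega_bar))
    stop("dimensions of delta and omega_bar disagree")
  omega <- omega_bar + tcrossprod(delta)
  k <- sqrt(1 + sum(delta * solve(omega_bar, delta)))
  lambda <- as.numeric(k * .mat_sqrt(omega, inverse = TRUE) %*% delta)
  list(lambda = lambda, omega = omega)
}

#' Map the shape parameter to the working shape parameter
#'
#' Inverse of [delta_to_lambda()]:
#' \eqn{\delta = (1 + \lambda^\top\lambda)^{-1/2}\Omega^{1/2}\lambda} and
#' \eqn{\bar\Omega = \Omega - \delta\delta^\top}.  The returned working shape
#' always satisfies the admissibility constraint
#' \eqn{\delta^\top\Omega^{-1}\delta < 1}.
#'
#' @param lambda shape vector \eqn{\lambda}.
#' @param omega positive-definite scale matrix \eqn{\Omega}.
#' @return list with components `delta` and `omega_bar`.
#' @export
lambda_to_delta <- function(lambda, omega) {
  lambda <- as.numeric(lambda)
  if (any(!is.finite(lambda))) stop("lambda must be finite")
  omega <- as.matrix(omega)
  .check_pd(omega, "omega")
  if (length(lambda) != nrow(omega))
    stop("dimensions of lambda and omega disagree")
  delta <- as.numeric(.mat_sqrt(omega) %*% lambda) / sqrt(1 + sum(lambda^2))
  omega_bar <- omega - tcrossprod(delta)
  .check_pd(omega_bar, "omega - delta delta^T")
  list(delta = delta, omega_bar = omega_bar)
}

#' Mean and covariance of a skew generalized t vector
#'
#' First two moments of the skew scale mixture of normals
#' \eqn{Z = \mu + U^{-1/2}(\delta Z_0 + X)} with half-normal \eqn{Z_0},
#' \eqn{X \sim N_p(0, \bar\Omega)} and gamma mixing:
#' \eqn{E\{Z\} = \mu + c\tilde U_1\delta} and
#' \eqn{\mathrm{Var}\{Z\} = \tilde U_2\Omega - c^2\tilde U_1^2
#' \delta\delta^\top}, where \eqn{c = \sqrt{2/\pi}}.
#'
#' @param mu location vector.
#' @param omega_bar positive-definite matrix \eqn{\bar\Omega}.
#' @param delta working shape vector.
#' @inheritParams mixing_moment
#' @return list with components `mean` and `cov`.
#' @export
sgt_moments <- function(mu, omega_bar, delta, nu, nu0 = nu) {
  mu <- as.numeric(mu); delta <- as.numeric(delta)
  omega_bar <- as.matrix(omega_bar)
  if (is.finite(nu) && nu <= 2)
    stop("covariance requires nu > 2")
  u1 <- mixing_moment(1, nu, nu0)
  u2 <- mixing_moment(2, nu, nu0)
  cc <- .half_normal_mean
  omega <- omega_bar + tcrossprod(delta)
  list(mean = mu + cc * u1 * delta,
       cov = u2 * omega - (cc * u1)^2 * tcrossprod(delta))
}

#' Marginal skewness and kurtosis indices
#'
#' Skewness \eqn{\gamma_1} and excess-kurtosis-style index \eqn{\gamma_2} of
#' one margin of a skew generalized t vector, as functions of the marginal
#' working shape \eqn{\delta_k}, the marginal standard deviation
#' \eqn{\sigma_k} and the mixing moments \eqn{\tilde U_1,\dots,\tilde U_4}.
#' Both indices vanish in the normal limit and \eqn{\gamma_1 = 0} whenever
#' \eqn{\delta_k = 0}.
#'
#' @param delta_k marginal working shape.
#' @param sigma_k marginal standard deviation (square root of the
#'   corresponding diagonal entry of the covariance from [sgt_moments()]).
#' @inheritParams mixing_moment
#' @return named vector `c(gamma1, gamma2)`.
#' @export
sgt_shape_indices <- function(delta_k, sigma_k, nu, nu0 = nu) {
  if (is.finite(nu) && nu <= 4)
    stop("shape indices require nu > 4 (fourth mixing moment)")
  u1 <- mixing_moment(1, nu, nu0); u2 <- mixing_moment(2, nu, nu0)
  u3 <- mixing_moment(3, nu, nu0); u4 <- mixing_moment(4, nu, nu0)
  cc <- .half_normal_mean
  s2 <- sigma_k^2
  # marginal scale omega_k^2 recovered from the variance identity
  # sigma^2 = U~2 omega^2 - c^2 U~1^2 delta^2
  om2 <- (s2 + cc^2 * u1^2 * delta_k^2) / u2
  g1 <- cc * delta_k / s2^1.5 *
    (3 * om2 * (u3 - u1 * u2) - delta_k^2 * (u3 - 4 * u1^3 / pi))
  mu4 <- 3 * u4 * om2^2 -
    4 * cc^2 * u1 * u3 * delta_k^2 * (3 * om2 - delta_k^2) +
    6 * cc^2 * u1^2 * u2 * delta_k^2 * om2 - 3 * cc^4 * u1^4 * delta_k^4
  c(gamma1 = g1, gamma2 = mu4 / s2^2 - 3)
}

#' Density of the (skew) generalized t distribution
#'
#' Evaluates the p-variate skew generalized t density
#' \deqn{SGt_p(z) = 2\,Gt_p(z \mid \mu, \Omega, \nu)\,
#'   T\!\left(\alpha\left(\frac{p+\nu}{\nu_0 + z_0^\top z_0}\right)^{1/2}
#'   \,\Big|\, p+\nu\right),}
#' with \eqn{z_0 = \Omega^{-1/2}(z-\mu)}, \eqn{\alpha = \lambda^\top z_0} and
#' \eqn{Gt_p} the generalized t density.  `lambda = 0` gives the generalized
#' t density; `nu0 = nu` gives the skew-t density.
#'
#' @param z evaluation point: a vector of length p, or a matrix with p
#'   columns (one point per row).
#' @param mu location vector.
#' @param omega positive-definite scale matrix.
#' @param lambda shape vector.
#' @inheritParams mixing_moment
#' @param log if `TRUE` return the log density.
#' @return density value(s).
#' @export
dsgt <- function(z, mu = 0, omega = 1, lambda = 0, nu, nu0 = nu,
                 log = FALSE) {
  omega <- as.matrix(omega)
  p <- nrow(omega)
  z <- if (is.matrix(z)) z else matrix(z, ncol = p, byrow = (p > 1L))
  if (ncol(z) != p) stop("z has the wrong dimension")
  mu <- rep_len(as.numeric(mu), p)
  lambda <- rep_len(as.numeric(lambda), p)
  omh <- .mat_sqrt(omega, inverse = TRUE)
  z0 <- (z - matrix(mu, nrow(z), p, byrow = TRUE)) %*% omh
  qf <- rowSums(z0^2)
  ldet <- determinant(omega, logarithm = TRUE)$modulus
  lgt <- lgamma((p + nu) / 2) - lgamma(nu / 2) - (p / 2) * log(pi) -
    0.5 * as.numeric(ldet) + (nu / 2) * log(nu0) -
    ((p + nu) / 2) * log(nu0 + qf)
  alpha <- as.numeric(z0 %*% lambda)
  lsk <- pt(alpha * sqrt((p + nu) / (nu0 + qf)), df = p + nu, log.p = TRUE)
  out <- log(2) + lgt + lsk
  if (log) out else exp(out)
}

#' Cumulative distribution function of the (skew) t distribution
#'
#' Computes \eqn{P(Z \le q)} componentwise for
#' \eqn{Z \sim ST_p(\mu, \Omega, \lambda, \nu)} through the selection
#' identity: the skew-t probability equals twice a central (p+1)-variate t
#' probability over the augmented scale matrix
#' \eqn{[[1, -\delta^\top], [-\delta, \Omega]]} with
#' \eqn{\delta = (1+\lambda^\top\lambda)^{-1/2}\Omega^{1/2}\lambda}.
#' `psgt()` handles the generalized-t scale \eqn{\nu_0 \ne \nu} by the
#' rescaling \eqn{SGT_p(\mu,\Omega,\lambda,(\nu,\nu_0)) =
#' ST_p(\mu, (\nu_0/\nu)\Omega, \lambda, \nu)}.
#'
#' @param q upper limit vector (length p).
#' @inheritParams dsgt
#' @param abseps target absolute accuracy of the underlying multivariate t
#'   quadrature.
#' @return a probability.
#' @export
pst <- function(q, mu = 0, omega = 1, lambda = 0, nu, abseps = 1e-8) {
  omega <- as.matrix(omega)
  p <- nrow(omega)
  q <- as.numeric(q); mu <- rep_len(as.numeric(mu), p)
  lambda <- rep_len(as.numeric(lambda), p)
  if (length(q) != p) stop("q has the wrong dimension")
  if (all(q == Inf)) return(1)
  delta <- lambda_to_delta(lambda, omega)$delta
  sig <- rbind(c(1, -delta), cbind(-delta, omega))
  2 * .mvt_cdf(c(0, q - mu), sig, nu, abseps = abseps)
}

#' @rdname pst
#' @export
psgt <- function(q, mu = 0, omega = 1, lambda = 0, nu, nu0 = nu,
                 abseps = 1e-8) {
  omega <- as.matrix(omega)
  pst(q, mu, (nu0 / nu) * omega, lambda, nu, abseps = abseps)
}

#' Simulate skew generalized t vectors
#'
#' Draws from the constructive representation
#' \eqn{Z = \mu + U^{-1/2}(\delta Z_0 + X)} with \eqn{Z_0 \sim HN(0,1)},
#' \eqn{X \sim N_p(0, \bar\Omega)} and
#' \eqn{U \sim \mathrm{Gamma}(\nu/2, \nu_0/2)} (degenerate at 1 when
#' `nu = Inf`).
#'
#' @param n number of draws.
#' @inheritParams sgt_moments
#' @return an `n` x p matrix of draws (a vector when p = 1).
#' @export
rsgt <- function(n, mu = 0, omega_bar = 1, delta = 0, nu, nu0 = nu) {
  omega_bar <- as.matrix(omega_bar)
  p <- nrow(omega_bar)
  mu <- rep_len(as.numeric(mu), p)
  delta <- rep_len(as.numeric(delta), p)
  u <- if (is.infinite(nu)) rep(1, n) else rgamma(n, nu / 2, rate = nu0 / 2)
  z0 <- abs(rnorm(n))
  x <- matrix(rnorm(n * p), n, p) %*% chol(omega_bar)
  z <- (tcrossprod(z0, delta) + x) / sqrt(u) +
    matrix(mu, n, p, byrow = TRUE)
  if (p == 1L) drop(z) else z
}
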