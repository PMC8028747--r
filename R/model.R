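#' Model parameter container
#'
#' Collects the parameters of the skew generalized t-link mixed model
#' (SGTLM): fixed effects \eqn{\beta}, link skewness \eqn{\delta_\epsilon},
#' random-effects working shape \eqn{\delta}, random-effects scale matrix
#' \eqn{\bar D}, degrees of freedom \eqn{\nu} and the mixing family.  With
#' `mixing = "normal"` the scale-mixing variable degenerates at 1, which
#' gives the (skew-)probit limits of the family.
#'
#' @param beta fixed-effects vector.
#' @param delta_eps link skewness (scalar).
#' @param delta random-effects working shape (length q).
#' @param d_bar q x q positive-definite scale matrix.
#' @param nu degrees of freedom (> 2); ignored when `mixing = "normal"`.
#' @param mixing `"t"` for gamma scale mixing, `"normal"` for the probit
#'   limit.
#' @param fix_delta_eps freeze the link skewness at zero (identifiability
#'   restriction for binary-covariate designs; also used by the symmetric
#'   t-link and probit submodels).
#' @param fix_delta `"none"`, `"first"` (freeze the random-intercept
#'   skewness, the default remedy for random-intercept confounding) or
#'   `"all"` (symmetric random effects, as in the t-link and probit
#'   submodels).
#' @return an object of class `sgtlm_theta`.
#' @export
sgtlm_theta <- function(beta, delta_eps = 0, delta = 0, d_bar, nu = Inf,
                        mixing = c("t", "normal"), fix_delta_eps = FALSE,
                        fix_delta = c("none", "first", "all")) {
  mixing <- match.arg(mixing)
  fix_delta <- match.arg(fix_delta)
  d_bar <- as.matrix(d_bar)
  .check_pd(d_bar, "d_bar")
  delta <- rep_len(as.numeric(delta), nrow(d_bar))
  if (mixing == "t" && (!is.finite(nu) || nu <= 2))
    stop("t mixing requires finite nu > 2")
  if (mixing == "normal") nu <- Inf
  if (fix_delta_eps && delta_eps != 0)
    stop("delta_eps must be 0 under the fix_delta_eps restriction")
  if (fix_delta == "first" && delta[1] != 0)
    stop("delta[1] must be 0 under the fix_delta = 'first' restriction")
  if (fix_delta == "all" && any(delta != 0))
    stop("delta must be 0 under the fix_delta = 'all' restriction")
  structure(list(beta = as.numeric(beta), delta_eps = as.numeric(delta_eps),
                 delta = delta, d_bar = d_bar, nu = nu, mixing = mixing,
                 fix_delta_eps = fix_delta_eps, fix_delta = fix_delta),
            class = "sgtlm_theta")
}

# model constant U~1 (1 in the normal limit)
.u1c <- function(theta) {
  if (theta$mixing == "normal") 1 else mixing_moment(1, theta$nu)
}

#' Latent-scale unit-variance constant
#'
#' The scaling constant
#' \eqn{\upsilon_0 = [\tilde U_2 + (\tilde U_2 - c^2\tilde U_1^2)
#' \delta_\epsilon^2]^{-1/2}} that gives the conditional latent outcome
#' unit variance, so that fixed effects keep their probit-scale
#' interpretation.
#'
#' @param delta_eps link skewness.
#' @param nu degrees of freedom (> 2).
#' @param mixing `"t"` or `"normal"` (the probit/skew-probit limit, where
#'   \eqn{\tilde U_1 = \tilde U_2 = 1}).
#' @return the scalar \eqn{\upsilon_0}.
#' @examples
#' upsilon0(-2, 5)    # 0.4598
#' upsilon0(0, Inf)   # 1: the probit scale
#' @export
upsilon0 <- function(delta_eps, nu, mixing = if (is.finite(nu)) "t" else "normal") {
  if (mixing == "t" && nu <= 2) stop("upsilon0 requires nu > 2")
  u1 <- if (mixing == "normal") 1 else mixing_moment(1, nu)
  u2 <- if (mixing == "normal") 1 else mixing_moment(2, nu)
  cc <- .half_normal_mean
  1 / sqrt(u2 + (u2 - cc^2 * u1^2) * delta_eps^2)
}

#' Marginal covariance matrix of the random effects
#'
#' \eqn{\Sigma_b = \tilde U_2 \bar D + (\tilde U_2 - c^2\tilde U_1^2)
#' \delta\delta^\top}: the variance-covariance matrix of the skew-t
#' distributed random effects implied by the working parameters.
#'
#' @param d_bar random-effects scale matrix \eqn{\bar D}.
#' @param delta random-effects working shape.
#' @inheritParams upsilon0
#' @return the q x q covariance matrix.
#' @export
ranef_covariance <- function(d_bar, delta, nu,
                             mixing = if (is.finite(nu)) "t" else "normal") {
  d_bar <- as.matrix(d_bar)
  delta <- rep_len(as.numeric(delta), nrow(d_bar))
  u1 <- if (mixing == "normal") 1 else mixing_moment(1, nu)
  u2 <- if (mixing == "normal") 1 else mixing_moment(2, nu)
  cc <- .half_normal_mean
  u2 * d_bar + (u2 - cc^2 * u1^2) * tcrossprod(delta)
}

#' Latent intra-class correlation
#'
#' For a random-intercept-only model (q = 1, \eqn{\delta = 0}), the
#' proportion of latent-scale variance attributable to clustering:
#' \deqn{\rho = \frac{\tilde U_2\bar\sigma_b^2 +
#'   (\tilde U_2 - c^2\tilde U_1^2)\upsilon_0^2\delta_\epsilon^2}
#'   {\tilde U_2(\upsilon_0^2 + \bar\sigma_b^2) +
#'   (\tilde U_2 - c^2\tilde U_1^2)\upsilon_0^2\delta_\epsilon^2}.}
#'
#' @param sigma_bar_b2 random-intercept scale \eqn{\bar\sigma_b^2}
#'   (the 1 x 1 \eqn{\bar D}).
#' @inheritParams upsilon0
#' @return the latent intra-class correlation in [0, 1).
#' @export
latent_icc <- function(sigma_bar_b2, delta_eps, nu,
                       mixing = if (is.finite(nu)) "t" else "normal") {
  if (length(sigma_bar_b2) != 1L)
    stop("latent_icc applies to random-intercept-only models (q = 1)")
  u1 <- if (mixing == "normal") 1 else mixing_moment(1, nu)
  u2 <- if (mixing == "normal") 1 else mixing_moment(2, nu)
  cc <- .half_normal_mean
  v0sq <- upsilon0(delta_eps, nu, mixing)^2
  skew <- (u2 - cc^2 * u1^2) * v0sq * delta_eps^2
  (u2 * sigma_bar_b2 + skew) / (u2 * (v0sq + sigma_bar_b2) + skew)
}

#' Marginal latent-outcome parameters of one cluster
#'
#' Computes the location, scale and shape of the marginal skew-t law of a
#' cluster's latent outcome vector:
#' \eqn{\mu_i = X_i\beta - c\tilde U_1\Delta_i},
#' \eqn{\bar\Omega_i = \upsilon_0^2 I + W_i\bar D W_i^\top},
#' \eqn{\Delta_i = \upsilon_0\delta_\epsilon\mathbf 1 + W_i\delta},
#' \eqn{\Omega_i = \bar\Omega_i + \Delta_i\Delta_i^\top} and
#' \eqn{\lambda_i = (1+\Delta_i^\top\bar\Omega_i^{-1}\Delta_i)^{1/2}
#' \Omega_i^{-1/2}\Delta_i}.
#'
#' @param theta an [sgtlm_theta()].
#' @param X,W fixed and random design matrices of one cluster.
#' @param ups latent scale constant (1 on the internal EM scale).
#' @return list with `mu`, `omega_bar`, `Delta`, `omega`, `lambda`.
#' @export
cluster_params <- function(theta, X, W, ups = 1) {
  .cluster_params(theta, as.matrix(X), as.matrix(W), ups, full = TRUE)
}

# Marginal latent-outcome parameters of one cluster: the latent vector is
#   Z_i = mu_i + U^{-1/2} (V Delta_i + N(0, Omega_bar_i)),
# mu_i = X beta - c U~1 Delta_i, Omega_bar_i = ups^2 I + W Dbar W',
# Delta_i = ups delta_eps 1 + W delta.  `ups` is 1 during EM and the
# finalized upsilon0 on the reported scale.
.cluster_params <- function(theta, X, W, ups = 1, full = FALSE) {
  ni <- nrow(X)
  Delta <- ups * theta$delta_eps + as.numeric(W %*% theta$delta)
  omega_bar <- diag(ups^2, ni) + W %*% theta$d_bar %*% t(W)
  mu <- as.numeric(X %*% theta$beta) - .half_normal_mean * .u1c(theta) * Delta
  out <- list(mu = mu, omega_bar = omega_bar, Delta = Delta)
  if (full) {
    out$omega <- omega_bar + tcrossprod(Delta)
    out$lambda <- tryCatch(delta_to_lambda(Delta, omega_bar)$lambda,
                           error = function(e) NULL)
  }
  out
}

# log of the multivariate Bernoulli mass of one cluster's outcome pattern:
# the skew-t probability of the latent orthant, floored to avoid -Inf.
.cluster_loglik <- function(theta, y, X, W, ups = 1, npts = 8192L,
                            floor_p = 1e-300) {
  cp <- .cluster_params(theta, X, W, ups)
  orient <- as.integer(1 - 2 * y)
  p <- cpp_cluster_engine(cp$mu, cp$omega_bar, cp$Delta,
                          rep(0, length(y)), orient, theta$nu,
                          theta$mixing == "t", as.integer(npts), 1L)$alpha
  floored <- p < floor_p
  list(loglik = log(max(p, floor_p)), floored = floored)
}

#' Marginal log-likelihood of a panel
#'
#' Sums the cluster-level log masses
#' \eqn{\log f(y_i) = \log ST_{n_i}(0 \mid A_i\mu_i, A_i\Omega_iA_i,
#' A_i\lambda_i, \nu)}, \eqn{A_i = \mathrm{diag}(1-2y_{ij})}, evaluated by
#' the deterministic QMC rule.  Cluster probabilities below the floor
#' `1e-300` are floored and counted.
#'
#' @param theta an [sgtlm_theta()].
#' @param panel an [sgtlm_panel()].
#' @param ups latent scale constant (1 internally during EM, the
#'   finalized \eqn{\upsilon_0} on the reported scale).
#' @param npts lattice size of the QMC rule.
#' @return the log-likelihood, with attributes `clusters` (per-cluster
#'   values) and `n_floored`.
#' @export
sgtlm_loglik <- function(theta, panel, ups = 1, npts = 8192L) {
  ll <- vapply(panel$index, function(ix) {
    r <- .cluster_loglik(theta, panel$y[ix],
                         panel$X[ix, , drop = FALSE],
                         panel$W[ix, , drop = FALSE], ups, npts)
    c(r$loglik, r$floored)
  }, numeric(2))
  structure(sum(ll[1, ]), clusters = ll[1, ], n_floored = sum(ll[2, ]))
}

#' Marginal success probability of a single observation
#'
#' \eqn{P(Y = 1)} for one observation with fixed covariates `x` and random
#' covariates `w`, marginally over the random effects, link noise, skewing
#' and mixing variables.  Monotone increasing in \eqn{x^\top\beta}.
#'
#' @inheritParams sgtlm_loglik
#' @param x fixed covariate vector.
#' @param w random covariate vector.
#' @param ups latent scale; defaults to the finalized \eqn{\upsilon_0}.
#' @return a probability.
#' @export
success_prob <- function(theta, x, w,
                         ups = upsilon0(theta$delta_eps, theta$nu,
                                        theta$mixing)) {
  cp <- .cluster_params(theta, matrix(x, 1), matrix(w, 1), ups)
  st <- .st_box_moments(cp$mu, cp$omega_bar + tcrossprod(cp$Delta),
                        delta_to_lambda(cp$Delta, cp$omega_bar)$lambda,
                        theta$nu, a = 0, orient = 1, order = 0L)
  1 - st$alpha
}

#' Identifiability restrictions required by a design
#'
#' Inspects the fixed and random design matrices of a panel and reports
#' which skewness restrictions the design requires: a fixed design with
#' only intercept/binary columns cannot identify the link skewness
#' (\eqn{\delta_\epsilon = 0} advised), and a random-intercept column
#' confounds the link skewness with the intercept skewness (the default
#' remedy fixes the first element of \eqn{\delta} at zero).  The stacked
#' fixed design must have full column rank.
#'
#' @param panel an [sgtlm_panel()].
#' @return list with logical flags `fix_delta_eps`, `fix_delta0` and a
#'   character vector `reasons`.
#' @export
check_identifiability <- function(panel) {
  X <- panel$X; W <- panel$W
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design matrix is rank deficient")
  binary_only <- all(apply(X, 2, function(v) all(v %in% c(0, 1))))
  has_rint <- any(apply(W, 2, function(v) all(v == v[1] & v[1] != 0)))
  reasons <- character()
  if (binary_only)
    reasons <- c(reasons,
                 "fixed design has only intercept/binary columns: link skewness delta_eps is not identified (fix delta_eps = 0)")
  if (has_rint)
    reasons <- c(reasons,
                 "random design includes an intercept: only delta_eps + delta0 is identified (fix delta0 = 0, or choose an equivalent restriction)")
  list(fix_delta_eps = binary_only, fix_delta0 = has_rint,
       reasons = reasons)
}
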