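# Shared oracles and fixtures, all generated in code.

cc_hn <- sqrt(2 / pi)  # half-normal mean

# Rejection-sampling oracle for truncated skew generalized t laws: draw
# (U, V, Z) from the constructive representation with working shape
# parameters, keep in-region draws.  Independent of every analytic and
# QMC code path in the package.
oracle_tsgt <- function(n, mu, omega_bar, delta, nu, nu0 = nu, a, orient,
                        t_mixing = TRUE) {
  p <- length(mu)
  u <- if (t_mixing) rgamma(n, nu / 2, rate = nu0 / 2) else rep(1, n)
  v <- abs(rnorm(n))
  x <- matrix(rnorm(n * p), n, p) %*% chol(omega_bar)
  z <- (tcrossprod(v, delta) + x) / sqrt(u) +
    matrix(mu, n, p, byrow = TRUE)
  keep <- rep(TRUE, n)
  for (k in seq_len(p))
    keep <- keep & (if (orient[k] == 1) z[, k] <= a[k] else z[, k] > a[k])
  list(alpha = mean(keep), u = u[keep], v = v[keep],
       z = z[keep, , drop = FALSE], n_kept = sum(keep))
}

mc_se <- function(x) sd(x) / sqrt(length(x))

# Gauss-Hermite marginal log-likelihood of a probit GLMM with a single
# random intercept of variance sb2: the probit-limit oracle.
gh_probit_loglik <- function(beta, sb2, panel, nodes = 60) {
  gh <- pracma::gaussHermite(nodes)
  b <- gh$x * sqrt(2 * sb2)
  wts <- gh$w / sqrt(pi)
  ll <- 0
  for (ix in panel$index) {
    eta <- as.numeric(panel$X[ix, , drop = FALSE] %*% beta)
    y <- panel$y[ix]
    like_b <- vapply(b, function(bb) {
      prod(pnorm((eta + bb) * (2 * y - 1)))
    }, numeric(1))
    ll <- ll + log(sum(wts * like_b))
  }
  ll
}

# small random positive-definite matrix
rand_pd <- function(p, scale = 1) {
  a <- matrix(rnorm(p * p), p)
  crossprod(a) / p + diag(scale, p)
}

# small clustered binary panel with one continuous fixed covariate and a
# random slope (no intercept), so both skewness channels stay identified
make_small_panel <- function(n = 40, ni = 2, seed = 1, nu = 5,
                             mixing = "t", beta = c(-0.5, 1),
                             delta_eps = -1, delta1 = 1.5, sb = 0.8) {
  set.seed(seed)
  id <- rep(seq_len(n), each = ni)
  X <- cbind(1, rnorm(n * ni))
  W <- cbind(w1 = rnorm(n * ni))
  index <- split(seq_along(id), id)
  ups <- upsilon0(delta_eps, nu, mixing)
  u1c <- if (mixing == "normal") 1 else mixing_moment(1, nu)
  y <- numeric(length(id))
  for (i in seq_len(n)) {
    ix <- index[[i]]
    u <- if (mixing == "t") rgamma(1, nu / 2, rate = nu / 2) else 1
    v <- abs(rnorm(1))
    skew <- v / sqrt(u) - cc_hn * u1c
    b <- skew * delta1 + rnorm(1, 0, sqrt(sb)) / sqrt(u)
    z <- as.numeric(X[ix, ] %*% beta) + W[ix, 1] * b +
      skew * ups * delta_eps + ups * rnorm(length(ix)) / sqrt(u)
    y[ix] <- as.numeric(z > 0)
  }
  sgtlm_panel(y, X, W, id)
}

# in-session cache for the scaled-down simulation studies shared by the
# acceptance criteria (each is computed once per test run)
study_cache <- new.env(parent = emptyenv())

cached_study <- function(mechanism, fitters) {
  key <- paste(mechanism, paste(fitters, collapse = "."), sep = "_")
  if (is.null(study_cache[[key]])) {
    design <- sim_design(mechanism, n_clusters = 100, n_reps = 25,
                         seed = 20260922)
    ctl <- sgtlm_control(npts_estep = 256L, npts_final = 2048L)
    study_cache[[key]] <- run_study(design, fitters = fitters,
                                    control = ctl)
  }
  study_cache[[key]]
}

perf_row <- function(study, fitter, parameter) {
  pf <- study$fitters[[fitter]]$performance$parameters
  pf[pf$parameter == parameter, ]
}
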