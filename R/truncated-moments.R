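#' Box truncation region with per-coordinate orientation
#'
#' Describes a product region \eqn{A_1 \times \dots \times A_p} where each
#' \eqn{A_k} is a half-line: \eqn{(-\infty, a_k]} when `orient[k] = +1` and
#' \eqn{(a_k, \infty)} when `orient[k] = -1`.  For binary-outcome latent
#' variables the cutpoints are all zero and the orientation is
#' \eqn{1 - 2y_k}.
#'
#' @param a numeric vector of cutpoints.
#' @param orient vector of +1/-1 orientation signs, recycled to the length
#'   of `a`; the default truncates every coordinate from above.
#' @return an object of class `trunc_region`.
#' @export
trunc_region <- function(a, orient = 1) {
  a <- as.numeric(a)
  orient <- rep_len(as.integer(orient), length(a))
  if (!all(orient %in% c(-1L, 1L))) stop("orient must contain only +1 or -1")
  structure(list(a = a, orient = orient), class = "trunc_region")
}

.degenerate_tol <- 1e-12

# --- central right-truncated multivariate t (or normal, nu = Inf) moments --
#
# X ~ t_p(0, sigma, nu) given X <= a.  The first moment identity
#   alpha E{X} = -sigma q,  q_k = h_k T_{p-1}(a_{-k} - mu_k; S_k, nu - 1)
# and the second moment identity
#   alpha E{XX^T} = nu/(nu-2) T_p(a; nu/(nu-2) sigma, nu - 2) sigma
#                   - sigma B
# follow from the normal-theory boundary integrals averaged over the tilted
# gamma mixing; h_k collects the marginal edge density, and row k of B needs
# the (p-1)-dimensional truncated-t partial means at nu - 1 degrees of
# freedom.  This arrangement needs only nu > 1 for means and nu > 2 for
# second moments.
.tt_core <- function(a, sigma, nu, abseps = 1e-8, order = 2L) {
  p <- length(a)
  sigma <- as.matrix(sigma)
  if (is.finite(nu) && nu <= 1 && order >= 1L)
    stop("truncated t mean requires nu > 1")
  if (is.finite(nu) && nu <= 2 && order >= 2L)
    stop("truncated t second moment requires nu > 2")
  alpha <- .mvt_cdf(a, sigma, nu, abseps)
  if (alpha < .degenerate_tol)
    stop("degenerate truncation region (mass below ", .degenerate_tol, ")")
  if (order < 1L) return(list(alpha = alpha))
  sk <- sqrt(diag(sigma))
  at <- a / sk
  qv <- hk <- Gk <- numeric(p)
  cond <- vector("list", p)
  for (k in seq_len(p)) {
    if (is.finite(at[k])) {
      if (is.finite(nu)) {
        lK <- -log(2) - 0.5 * log(pi) + lgamma((nu - 1) / 2) -
          lgamma(nu / 2) + (nu / 2) * log(nu) -
          ((nu - 1) / 2) * log(nu + at[k]^2)
        hk[k] <- exp(lK) / sk[k]
      } else {
        hk[k] <- dnorm(at[k]) / sk[k]
      }
    } else hk[k] <- 0  # a_k = +Inf contributes no boundary mass
    if (p == 1L) {
      Gk[k] <- 1
    } else if (hk[k] > 0) {
      sig_k <- sigma[-k, k]
      muc <- sig_k * a[k] / sigma[k, k]
      Sc <- sigma[-k, -k, drop = FALSE] - tcrossprod(sig_k) / sigma[k, k]
      if (is.finite(nu)) {
        Sc <- Sc * (nu + at[k]^2) / (nu - 1)
        dfc <- nu - 1
      } else dfc <- Inf
      Gk[k] <- .mvt_cdf(a[-k] - muc, Sc, dfc, abseps)
      cond[[k]] <- list(muc = muc, S = Sc, df = dfc)
    }
    qv[k] <- hk[k] * Gk[k]
  }
  m1 <- -as.numeric(sigma %*% qv) / alpha
  out <- list(alpha = alpha, m1 = m1)
  if (order >= 2L) {
    lead <- if (is.finite(nu)) {
      nu / (nu - 2) * .mvt_cdf(a, sigma * nu / (nu - 2), nu - 2, abseps)
    } else alpha
    B <- matrix(0, p, p)
    for (k in seq_len(p)) {
      if (is.finite(at[k])) B[k, k] <- a[k] * qv[k]
      if (p > 1L && hk[k] > 0) {
        ck <- cond[[k]]
        sub <- .tt_core(a[-k] - ck$muc, ck$S, ck$df, abseps, order = 1L)
        B[k, -k] <- hk[k] * sub$alpha * (ck$muc + sub$m1)
      }
    }
    m2 <- (lead * sigma - sigma %*% B) / alpha
    out$m2 <- (m2 + t(m2)) / 2
  }
  out
}

# location version: Y = mu + X
.tt_moments <- function(a, mu, sigma, nu, abseps = 1e-8, order = 2L) {
  core <- .tt_core(a - mu, sigma, nu, abseps, order)
  if (order < 1L) return(list(alpha = core$alpha))
  out <- list(alpha = core$alpha, m1 = mu + core$m1)
  if (order >= 2L)
    out$m2 <- core$m2 + outer(mu, core$m1) + outer(core$m1, mu) +
      tcrossprod(mu)
  out
}

# --- truncated skew-t moments through the selection representation --------
#
# Z ~ ST_p(mu, omega, lambda, nu) truncated to the oriented box.  With
# delta = (1 + lambda'lambda)^{-1/2} omega^{1/2} lambda the augmented
# vector (W0, Z - mu) is central t_{p+1} with scale
# [[1, -delta'], [-delta, omega]], and the skew-t box probability/moments
# are those of the augmented t truncated to (W0 <= 0, Z <= a).
.st_box_moments <- function(mu, omega, lambda, nu, a, orient,
                            abseps = 1e-8, order = 2L) {
  p <- length(mu)
  A <- rep_len(orient, p)
  mu_f <- A * mu
  a_f <- A * a
  om_f <- omega * tcrossprod(A)
  lam_f <- A * rep_len(lambda, p)
  delta <- lambda_to_delta(lam_f, om_f)$delta
  sig <- rbind(c(1, -delta), cbind(-delta, om_f))
  core <- .tt_core(c(0, a_f - mu_f), sig, nu, abseps, order)
  if (order < 1L) return(list(alpha = 2 * core$alpha))
  m1_f <- mu_f + core$m1[-1]
  out <- list(alpha = 2 * core$alpha, m1 = A * m1_f)
  if (order >= 2L) {
    m2_f <- core$m2[-1, -1, drop = FALSE] + outer(mu_f, core$m1[-1]) +
      outer(core$m1[-1], mu_f) + tcrossprod(mu_f)
    out$m2 <- m2_f * tcrossprod(A)
  }
  out
}

#' Moments of a standardized truncated skew-t vector
#'
#' First and second raw moments of
#' \eqn{Z \sim TST_p(0, R, \lambda, \nu, a)}, the skew-t law with
#' correlation-scale `R` truncated from above at `a` in every coordinate.
#'
#' @param R scale (correlation) matrix.
#' @param lambda shape vector.
#' @param nu degrees of freedom; `Inf` gives the truncated skew-normal.
#' @param a vector of upper cutpoints.
#' @param abseps target absolute accuracy of the cdf quadratures.
#' @return list with components `alpha` (region probability), `m1`
#'   (\eqn{E\{Z\}}) and `m2` (\eqn{E\{ZZ^\top\}}).
#' @export
tst_moments <- function(R, lambda, nu, a, abseps = 1e-8) {
  R <- as.matrix(R)
  .check_pd(R, "R")
  .st_box_moments(rep(0, nrow(R)), R, lambda, nu, a, 1, abseps)
}

#' Moments of a truncated skew generalized t vector
#'
#' First and second raw moments of
#' \eqn{Z \sim SGT_p(\mu, \Omega, \lambda, (\nu, \nu_0))} restricted to an
#' oriented box region, obtained by the skew-t rescaling
#' \eqn{\Omega^* = (\nu_0/\nu)\Omega} and orientation flips.
#'
#' @param mu location vector.
#' @param omega positive-definite scale matrix.
#' @param lambda shape vector.
#' @inheritParams mixing_moment
#' @param region a [trunc_region()].
#' @inheritParams tst_moments
#' @return list with components `alpha`, `m1`, `m2`.
#' @export
tsgt_moments <- function(mu, omega, lambda, nu, nu0 = nu, region,
                         abseps = 1e-8) {
  omega <- as.matrix(omega)
  .check_pd(omega, "omega")
  ratio <- if (is.infinite(nu)) 1 else nu0 / nu
  .st_box_moments(as.numeric(mu), ratio * omega, lambda, nu,
                  region$a, region$orient, abseps)
}

#' Moments of a truncated skew-normal vector
#'
#' The \eqn{\nu \to \infty} limit of [tsgt_moments()]; used by the probit
#' and skew-probit model fits.
#'
#' @inheritParams tsgt_moments
#' @return list with components `alpha`, `m1`, `m2`.
#' @export
tsn_moments <- function(mu, omega, lambda, region, abseps = 1e-8) {
  tsgt_moments(mu, omega, lambda, nu = Inf, nu0 = Inf, region = region,
               abseps = abseps)
}

#' Joint gamma-mixed moments of a truncated skew generalized t vector
#'
#' For \eqn{Z} a truncated SGT vector and \eqn{U} its gamma mixing
#' variable, computes the joint-moment bundle
#' \eqn{\bar u_r = E\{U^{r/2}\}}, \eqn{\overline{u_r z^{(s)}}} and the
#' \eqn{\zeta_1}-weighted counterparts
#' \eqn{\bar\tau_r = E\{U^{r/2}\zeta_1(U^{1/2}\alpha)\}}, etc., where
#' \eqn{\zeta_1(x) = \phi(x)/\Phi(x)} and \eqn{\alpha =
#' \lambda^\top\Omega^{-1/2}(Z-\mu)}.  All six members reduce to moments of
#' auxiliary truncated skew-t (order-shifted degrees of freedom \eqn{\nu+r})
#' and truncated t laws, scaled by the constant \eqn{C_r(\nu)} and the cdf
#' normalizers \eqn{\alpha_{st}}, \eqn{\alpha_{u,r}}, \eqn{\alpha_{\tau,r}}.
#' These are the conditional expectations the EM algorithm needs.
#'
#' @inheritParams tsgt_moments
#' @param r moment order (real, `r > -nu`).
#' @param order 2 for first and second \eqn{z} moments, 1 for first only,
#'   0 for the scalar members only.
#' @return list with components `ur`, `urz1`, `urz2`, `taur`, `taurz1`,
#'   `taurz2`, the normalizer `alpha_st` and the order `r`.
#' @export
sgt_joint_moments <- function(mu, omega, lambda, nu, nu0 = nu, region, r,
                              abseps = 1e-8, order = 2L) {
  omega <- as.matrix(omega)
  p <- nrow(omega)
  mu <- rep_len(as.numeric(mu), p)
  lambda <- rep_len(as.numeric(lambda), p)
  if (is.finite(nu) && r <= -nu) stop("order r must exceed -nu")
  A <- rep_len(region$orient, p)
  tmix <- is.finite(nu)
  ratio <- if (tmix) nu0 / nu else 1
  shrink <- if (tmix) nu / (nu + r) else 1
  dfr <- if (tmix) nu + r else Inf

  om_star <- ratio * omega                      # skew-t rescaling of the scale
  wd <- lambda_to_delta(lambda, om_star)        # working shape on the skew-t scale
  delta <- wd$delta
  M <- 1 / sqrt(1 + sum(delta * solve(wd$omega_bar, delta)))
  Cr <- if (tmix) {
    exp((r / 2) * log(2 / nu0) + lgamma((nu + r) / 2) - lgamma(nu / 2))
  } else 1

  mu_f <- A * mu
  a_f <- A * region$a
  flip <- tcrossprod(A)

  # alpha_st: full skew-t region probability at the original nu
  sig_st <- rbind(c(1, -A * delta), cbind(-A * delta, om_star * flip))
  alpha_st <- 2 * .mvt_cdf(c(0, a_f - mu_f), sig_st, nu, abseps)
  if (alpha_st < .degenerate_tol)
    stop("degenerate truncation region in joint moments")

  # u-channel: truncated skew-t at nu + r with shrunken scale
  ust <- .st_box_moments(mu, shrink * om_star, lambda, dfr,
                         region$a, A, abseps, order = max(order, 0L))
  ur <- Cr * ust$alpha / alpha_st
  # tau-channel: truncated t at nu + r with shrunken Omega-bar scale
  tt <- .tt_moments(a_f, mu_f, shrink * (wd$omega_bar * flip), dfr,
                    abseps, order = max(order, 0L))
  taur <- .half_normal_mean * M * Cr * tt$alpha / alpha_st

  out <- list(r = r, alpha_st = alpha_st, ur = ur, taur = taur)
  if (order >= 1L) {
    out$urz1 <- ur * ust$m1
    out$taurz1 <- taur * (A * tt$m1)
  }
  if (order >= 2L) {
    out$urz2 <- ur * ust$m2
    out$taurz2 <- taur * (tt$m2 * flip)
  }
  out
}
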