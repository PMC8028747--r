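#' Control parameters for the EM fitter
#'
#' @param max_iter maximum number of EM iterations.
#' @param loglik_rtol relative log-likelihood change declaring convergence
#'   of the plain-EM phase.
#' @param px_tol threshold on the dominant eigenvalue of
#'   \eqn{\hat\alpha - I_q} below which the parameter-expansion phase hands
#'   over to plain EM.
#' @param npts_estep lattice size of the deterministic QMC rule used per
#'   cluster during EM iterations (the accuracy knob of the E-step).
#' @param npts_final lattice size for the final pass (reported
#'   log-likelihood, scores, empirical Bayes quantities).
#' @param estep_method `"qmc"` for the single-pass QMC engine (fast,
#'   default) or `"analytic"` for the cdf-recursion route through the
#'   truncated-moment formulas (slower, accuracy set by `abseps`).
#' @param abseps absolute cdf accuracy for the analytic route.
#' @param use_px run the parameter-expansion phase before plain EM
#'   (disable to compare the accelerated and plain algorithms).
#' @param verbose print the log-likelihood trace while fitting.
#' @return a list of class `sgtlm_control`.
#' @export
sgtlm_control <- function(max_iter = 1000L, loglik_rtol = 1e-6,
                          px_tol = 1e-2, npts_estep = 512L,
                          npts_final = 8192L,
                          estep_method = c("qmc", "analytic"),
                          abseps = 1e-8, use_px = TRUE, verbose = FALSE) {
  stopifnot(max_iter >= 1, loglik_rtol > 0, px_tol > 0)
  structure(list(max_iter = as.integer(max_iter),
                 loglik_rtol = loglik_rtol, px_tol = px_tol,
                 npts_estep = as.integer(npts_estep),
                 npts_final = as.integer(npts_final),
                 estep_method = match.arg(estep_method),
                 abseps = abseps, use_px = isTRUE(use_px),
                 verbose = isTRUE(verbose)),
            class = "sgtlm_control")
}

# analytic (cdf-recursion) E-step for one cluster: joint truncated-moment
# bundles at orders r = 2 (scale-mixing channel) and r = 1 (zeta_1
# channel), then the half-normal-channel identities
#   vu = M(u2a + tau), vuz = M(u2az + tauz), v2 = M^2(1 + taua + u2a2).
.estep_cluster_analytic <- function(theta, cp, orient, control, level) {
  m <- length(cp$mu)
  reg <- trunc_region(rep(0, m), orient)
  om <- cp$omega_bar + tcrossprod(cp$Delta)
  lam <- delta_to_lambda(cp$Delta, cp$omega_bar)$lambda
  nu <- theta$nu
  ab <- control$abseps
  if (theta$mixing == "t") {
    j2 <- sgt_joint_moments(cp$mu, om, lam, nu, nu, reg, r = 2,
                            abseps = ab, order = 2L)
    j1 <- sgt_joint_moments(cp$mu, om, lam, nu, nu, reg, r = 1,
                            abseps = ab, order = 1L)
    u2 <- j2$ur; u2z <- j2$urz1; u2z2 <- j2$urz2
    tau <- j1$taur; tauz <- j1$taurz1
    alpha <- j2$alpha_st
  } else {
    j <- sgt_joint_moments(cp$mu, om, lam, Inf, Inf, reg, r = 0,
                           abseps = ab, order = 2L)
    u2 <- 1; u2z <- j$urz1; u2z2 <- j$urz2
    tau <- j$taur; tauz <- j$taurz1
    alpha <- j$alpha_st
  }
  obi_d <- solve(cp$omega_bar, cp$Delta)
  M <- 1 / sqrt(1 + sum(cp$Delta * obi_d))
  mu <- cp$mu
  u2a <- M * sum(obi_d * (u2z - u2 * mu))
  taua <- M * sum(obi_d * (tauz - tau * mu))
  u2az <- M * as.numeric((u2z2 - outer(u2z, mu)) %*% obi_d)
  u2a2 <- M^2 * (u2 * sum(obi_d * mu)^2 +
                   sum(obi_d * ((u2z2 - 2 * outer(u2z, mu)) %*% obi_d)))
  mom <- list(alpha = alpha, u2 = u2, u2z = u2z, u2z2 = u2z2,
              vu = M * (u2a + tau), vuz = M * (u2az + tauz),
              v2 = M^2 * (1 + taua + u2a2))
  if (level >= 3L) {
    # E{V U^{-1/2} | y}: conditionally on (Z, U) the half-normal channel
    # has posterior mean M^2 U^{1/2} Delta' Omega_bar^{-1} (Z - mu)
    # + M zeta_1(U^{1/2} alpha), so the U^{+-1/2} factors cancel in the
    # first term and the unweighted conditional mean of Z enters
    j0 <- sgt_joint_moments(cp$mu, om, lam, nu, nu, reg, r = 0,
                            abseps = ab, order = 1L)
    if (theta$mixing == "t") {
      ju <- sgt_joint_moments(cp$mu, om, lam, nu, nu, reg, r = 1,
                              abseps = ab, order = 0L)
      jm1 <- sgt_joint_moments(cp$mu, om, lam, nu, nu, reg, r = -1,
                               abseps = ab, order = 0L)
      u1 <- ju$ur; taum1 <- jm1$taur
    } else {
      u1 <- 1; taum1 <- j0$taur
    }
    ua <- M * sum(obi_d * (j0$urz1 - mu))
    mom$z1 <- j0$urz1
    mom$u1 <- u1
    mom$vum1 <- M * (ua + taum1)
  }
  mom
}

# random-effects conditional-moment blocks of one cluster: exact
# normal-theory maps from the latent-outcome moments.
.ranef_moments <- function(theta, X, W, cp, mom, u1c) {
  cc <- .half_normal_mean
  q <- ncol(W)
  rW <- solve(cp$omega_bar, W)                 # Omega_bar^{-1} W
  ri <- theta$d_bar %*% t(rW)                  # q x n
  Lam <- (diag(1, q) - ri %*% W) %*% theta$d_bar
  s <- theta$delta - as.numeric(ri %*% cp$Delta)
  Xb <- as.numeric(X %*% theta$beta)
  cu <- cc * u1c
  S3 <- mom$v2 - 2 * cu * mom$vu + cu^2 * mom$u2
  u2b <- as.numeric(ri %*% (mom$u2z - mom$u2 * Xb)) +
    (mom$vu - cu * mom$u2) * s
  vub <- as.numeric(ri %*% (mom$vuz - mom$vu * Xb)) +
    (mom$v2 - cu * mom$vu) * s
  u2bz <- ri %*% (mom$u2z2 - outer(Xb, mom$u2z)) +
    outer(s, mom$vuz - cu * mom$u2z)
  h1 <- as.numeric(ri %*% ((mom$vuz - mom$vu * Xb) -
                             cu * (mom$u2z - mom$u2 * Xb)))
  u2b2 <- Lam + S3 * tcrossprod(s) +
    ri %*% (mom$u2z2 + mom$u2 * tcrossprod(Xb) - outer(mom$u2z, Xb) -
              outer(Xb, mom$u2z)) %*% t(ri) +
    outer(h1, s) + outer(s, h1)
  u2b2 <- (u2b2 + t(u2b2)) / 2
  list(ri = ri, s = s,
       u2b = u2b, vub = vub, u2bz = u2bz, u2b2 = u2b2,
       S1 = mom$u2z - as.numeric(W %*% u2b),
       S2 = mom$vu - cu * mom$u2,
       S3 = S3,
       S4 = mom$vuz - as.numeric(W %*% vub),
       vub_bar = vub - cu * u2b)
}

#' E-step of the EM algorithm
#'
#' Computes, for every cluster, the conditional expectations of the
#' complete-data sufficient statistics given the observed outcome pattern:
#' the scale-mixing weight \eqn{\hat u_2 = E\{U \mid y\}}, the weighted
#' latent moments \eqn{E\{UZ\}}, \eqn{E\{UZZ^\top\}}, the half-normal
#' channel \eqn{E\{VU^{1/2}\}}, \eqn{E\{VU^{1/2}Z\}}, \eqn{E\{V^2\}}, and
#' the derived random-effects blocks.  The per-cluster region probability
#' also yields the marginal log-likelihood of the current parameter.
#'
#' @param theta an [sgtlm_theta()] (internal scale, \eqn{\upsilon_0 = 1}).
#' @param panel an [sgtlm_panel()].
#' @param control an [sgtlm_control()].
#' @param level 2 for the EM bundle, 3 to add the empirical-Bayes
#'   expectations (orders \eqn{r \in \{0, 1, -1\}}).
#' @param ups latent scale constant (1 during EM).
#' @param cl optional pre-extracted cluster list (internal, avoids
#'   re-slicing the design matrices every EM iteration).
#' @return list with `clusters` (per-cluster moment bundles) and `loglik`.
#' @export
sgtlm_estep <- function(theta, panel, control = sgtlm_control(),
                        level = 2L, ups = 1, cl = NULL) {
  tmix <- theta$mixing == "t"
  u1c <- .u1c(theta)
  if (is.null(cl)) cl <- .split_clusters(panel)
  npts <- if (level >= 3L) control$npts_final else control$npts_estep
  out <- vector("list", length(cl))
  ll <- 0
  cu <- .half_normal_mean * u1c
  for (i in seq_along(cl)) {
    X <- cl[[i]]$X
    W <- cl[[i]]$W
    orient <- cl[[i]]$orient
    if (control$estep_method == "qmc") {
      mom <- cpp_cluster_estep(X, W, orient, theta$beta, theta$delta_eps,
                               theta$delta, theta$d_bar, theta$nu, tmix,
                               ups, cu, as.integer(npts),
                               as.integer(level))
      if (!is.finite(mom$alpha) || mom$alpha <= 0)
        stop("degenerate outcome-pattern probability in cluster '",
             names(cl)[i], "'")
      mom$u2z <- c(mom$u2z); mom$vuz <- c(mom$vuz)
      bm <- mom$bm
      for (nmv in c("s", "u2b", "vub", "S1", "S4", "vub_bar"))
        bm[[nmv]] <- c(bm[[nmv]])
      mom$bm <- bm
      if (level >= 3L) {
        mom$z1 <- c(mom$z1)
      }
    } else {
      cp <- .cluster_params(theta, X, W, ups)
      mom <- .estep_cluster_analytic(theta, cp, orient, control, level)
      if (!is.finite(mom$alpha) || mom$alpha <= 0)
        stop("degenerate outcome-pattern probability in cluster '",
             names(cl)[i], "'")
      mom$bm <- .ranef_moments(theta, X, W, cp, mom, u1c)
    }
    ll <- ll + log(mom$alpha)
    out[[i]] <- mom
  }
  list(clusters = out, loglik = ll, cl = cl)
}

# pre-extract per-cluster design blocks and static cross products
.split_clusters <- function(panel) {
  out <- lapply(panel$index, function(ix) {
    X <- panel$X[ix, , drop = FALSE]
    W <- panel$W[ix, , drop = FALSE]
    list(X = X, W = W, orient = as.integer(1 - 2 * panel$y[ix]),
         XtX = crossprod(X), csX = colSums(X), csW = colSums(W),
         ni = length(ix))
  })
  names(out) <- names(panel$index)
  out
}

# joint update of delta and Dbar: profile maximization of the Q-function
# over (delta, Dbar) given the aggregated blocks B = sum u2b2,
# h = sum (vub - c U~1 u2b), S = sum S3, with optional freezing of the
# first element (random-intercept skewness) or the whole vector.
.update_delta_dbar <- function(B, h, S, n, fix) {
  q <- length(h)
  if (fix == "all" || (fix == "first" && q == 1L)) {
    delta <- rep(0, q)
    d_bar <- B / n
  } else if (fix == "none") {
    delta <- h / S
    d_bar <- (B - tcrossprod(h) / S) / n
  } else {
    C0 <- B - tcrossprod(h) / S
    Qm <- solve((C0 + t(C0)) / 2)
    c1 <- -h[1] / S
    rstar <- c(c1, -solve(Qm[-1, -1, drop = FALSE], Qm[-1, 1]) * c1)
    delta <- h / S + rstar
    delta[1] <- 0
    d_bar <- (B - outer(delta, h) - outer(h, delta) +
                S * tcrossprod(delta)) / n
  }
  # guard positive definiteness in floating point
  d_bar <- (d_bar + t(d_bar)) / 2
  e <- eigen(d_bar, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    d_bar <- e$vectors %*% (pmax(e$values, 1e-8) * t(e$vectors))
    d_bar <- (d_bar + t(d_bar)) / 2
  }
  list(delta = delta, d_bar = d_bar)
}

#' M-step of the EM algorithm
#'
#' Maximizes the expected complete-data log-likelihood over
#' \eqn{(\beta, \delta_\epsilon, \delta, \bar D)}: the link-skewness and
#' fixed-effects updates solve one symmetric linear system (the link
#' skewness enters the fixed-effects normal equations), and
#' \eqn{(\delta, \bar D)} are updated by exact profile maximization,
#' honouring the restriction flags carried by `theta`.
#'
#' @param es output of [sgtlm_estep()].
#' @inheritParams sgtlm_estep
#' @return the updated [sgtlm_theta()].
#' @export
sgtlm_mstep <- function(es, panel, theta) {
  cc <- .half_normal_mean
  u1c <- .u1c(theta)
  p <- ncol(panel$X); q <- ncol(panel$W)
  n <- length(es$clusters)
  A <- matrix(0, p, p); Ub <- numeric(p); xi <- numeric(p)
  K <- 0; g <- 0
  B <- matrix(0, q, q); h <- numeric(q); S <- 0
  cl <- es$cl
  for (i in seq_len(n)) {
    X <- cl[[i]]$X
    m <- es$clusters[[i]]; bm <- m$bm
    A <- A + m$u2 * cl[[i]]$XtX
    Ub <- Ub + as.numeric(crossprod(X, bm$S1))
    xi <- xi + bm$S2 * cl[[i]]$csX
    K <- K + cl[[i]]$ni * bm$S3
    g <- g + sum(bm$S4 - cc * u1c * bm$S1)
    B <- B + bm$u2b2; h <- h + bm$vub_bar; S <- S + bm$S3
  }
  if (theta$fix_delta_eps) {
    beta <- solve(A, Ub)
    de <- 0
  } else {
    sol <- solve(rbind(cbind(A, xi), c(xi, K)), c(Ub, g))
    beta <- sol[seq_len(p)]
    de <- sol[p + 1]
  }
  dd <- .update_delta_dbar(B, h, S, n, theta$fix_delta)
  sgtlm_theta(beta, de, dd$delta, dd$d_bar, theta$nu, theta$mixing,
              theta$fix_delta_eps, theta$fix_delta)
}

#' Parameter-expanded M-step
#'
#' M-step of the PX-EM acceleration: the complete-data model is expanded
#' with a working q x q scale matrix \eqn{\alpha} in the linear predictor
#' (\eqn{\eta_i = X_i\beta_\star + W_i\alpha b_i}); the joint update of
#' \eqn{(\beta_\star, \mathrm{vec}\,\alpha, \delta_{\epsilon\star})}
#' solves one symmetric linear system, and the reduction
#' \eqn{\delta = \alpha\delta_\star},
#' \eqn{\bar D = \alpha\bar D_\star\alpha^\top} recovers the original
#' parameter.  Restrictions freeze the corresponding coordinates (for a
#' frozen random-intercept skewness the first row of \eqn{\alpha} keeps
#' only its diagonal entry).
#'
#' @inheritParams sgtlm_mstep
#' @return list with the updated `theta` and the working scale `alpha`.
#' @export
sgtlm_px_mstep <- function(es, panel, theta) {
  cc <- .half_normal_mean
  u1c <- .u1c(theta)
  p <- ncol(panel$X); q <- ncol(panel$W)
  n <- length(es$clusters)
  A11 <- matrix(0, p, p); A12 <- matrix(0, p, q * q)
  A22 <- matrix(0, q * q, q * q)
  U1 <- numeric(p); U2 <- matrix(0, q, q)
  xi1 <- numeric(p); xi2 <- numeric(q * q)
  K <- 0; g <- 0
  B <- matrix(0, q, q); h <- numeric(q); S <- 0
  cl <- es$cl
  for (i in seq_len(n)) {
    X <- cl[[i]]$X
    W <- cl[[i]]$W
    m <- es$clusters[[i]]; bm <- m$bm
    A11 <- A11 + m$u2 * cl[[i]]$XtX
    A12 <- A12 + crossprod(X, kronecker(matrix(bm$u2b, 1, q), W))
    A22 <- A22 + kronecker(bm$u2b2, crossprod(W))
    U1 <- U1 + as.numeric(crossprod(X, m$u2z))
    U2 <- U2 + crossprod(W, t(bm$u2bz))
    xi1 <- xi1 + bm$S2 * cl[[i]]$csX
    xi2 <- xi2 + kronecker(bm$vub_bar, cl[[i]]$csW)
    K <- K + cl[[i]]$ni * bm$S3
    g <- g + sum(m$vuz - cc * u1c * m$u2z)
    B <- B + bm$u2b2; h <- h + bm$vub_bar; S <- S + bm$S3
  }
  Amat <- rbind(cbind(A11, A12), cbind(t(A12), A22))
  bvec <- c(U1, as.numeric(U2))
  xiv <- c(xi1, xi2)
  # free coordinates: beta, vec(alpha) minus frozen first-row entries,
  # then delta_eps last
  free <- rep(TRUE, p + q * q)
  if (theta$fix_delta == "first" && q > 1L)
    free[p + ((2:q) - 1) * q + 1] <- FALSE  # alpha[1, 2:q] = 0
  fde <- theta$fix_delta_eps
  Mfull <- if (fde) Amat[free, free, drop = FALSE] else
    rbind(cbind(Amat[free, free, drop = FALSE], xiv[free]),
          c(xiv[free], K))
  rhs <- if (fde) bvec[free] else c(bvec[free], g)
  sol <- solve(Mfull, rhs)
  nf <- sum(free)
  xfull <- numeric(p + q * q)
  xfull[free] <- sol[seq_len(nf)]
  beta <- xfull[seq_len(p)]
  alpha <- matrix(xfull[-seq_len(p)], q, q)
  de <- if (fde) 0 else sol[nf + 1]
  dd <- .update_delta_dbar(B, h, S, n, theta$fix_delta)
  delta <- as.numeric(alpha %*% dd$delta)
  if (theta$fix_delta == "first") delta[1] <- 0
  if (theta$fix_delta == "all") delta[] <- 0
  d_bar <- alpha %*% dd$d_bar %*% t(alpha)
  d_bar <- (d_bar + t(d_bar)) / 2
  e <- eigen(d_bar, symmetric = TRUE)
  if (min(e$values) < 1e-8)
    d_bar <- e$vectors %*% (pmax(e$values, 1e-8) * t(e$vectors))
  list(theta = sgtlm_theta(beta, de, delta, d_bar, theta$nu, theta$mixing,
                           theta$fix_delta_eps, theta$fix_delta),
       alpha = alpha)
}

#' Fit a skew generalized t-link mixed model to a panel
#'
#' Maximum likelihood estimation by the six-step procedure: PX-EM
#' iterations until the working scale is within `px_tol` of the identity,
#' then plain EM until the relative log-likelihood change falls below
#' `loglik_rtol`, followed by the terminal rescaling
#' \eqn{\beta \leftarrow \upsilon_0\beta},
#' \eqn{\delta \leftarrow \upsilon_0\delta},
#' \eqn{\bar D \leftarrow \upsilon_0^2\bar D} that gives the link function
#' unit conditional variance (probit-comparable fixed effects).  The
#' internal EM scale uses \eqn{\upsilon_0 = 1}; the rescaling leaves the
#' marginal log-likelihood unchanged.
#'
#' @param panel an [sgtlm_panel()].
#' @param link one of `"sgt"` (skew generalized t), `"gt"` (symmetric
#'   generalized t), `"skew-probit"`, `"probit"`.
#' @param nu degrees of freedom for the t-mixing links (fixed during one
#'   fit; see [select_nu()] for grid selection).
#' @param restrictions optional list overriding the identifiability
#'   restrictions chosen by [check_identifiability()]: elements
#'   `fix_delta_eps` (logical) and `fix_delta`
#'   (`"none"`/`"first"`/`"all"`).
#' @param control an [sgtlm_control()].
#' @param theta0 optional starting [sgtlm_theta()] (internal scale); the
#'   default starts at \eqn{\beta = 0}, \eqn{\delta_\epsilon = 0},
#'   \eqn{\delta = 0}, \eqn{\bar D = I}.
#' @return an object of class `sgtlm`; see [summary.sgtlm()].
#' @export
sgtlm_fit <- function(panel, link = c("sgt", "gt", "skew-probit", "probit"),
                      nu = NULL, restrictions = NULL,
                      control = sgtlm_control(), theta0 = NULL) {
  link <- match.arg(link)
  stopifnot(inherits(panel, "sgtlm_panel"))
  mixing <- if (link %in% c("sgt", "gt")) "t" else "normal"
  if (mixing == "t") {
    if (is.null(nu) || !is.finite(nu) || nu <= 2)
      stop("links 'sgt' and 'gt' need finite nu > 2")
  } else nu <- Inf
  skewed <- link %in% c("sgt", "skew-probit")
  p <- ncol(panel$X); q <- ncol(panel$W)
  if (skewed) {
    chk <- check_identifiability(panel)
    fde <- if (!is.null(restrictions$fix_delta_eps))
      restrictions$fix_delta_eps else chk$fix_delta_eps
    fd <- if (!is.null(restrictions$fix_delta)) restrictions$fix_delta
    else if (chk$fix_delta0) "first" else "none"
  } else {
    fde <- TRUE; fd <- "all"
  }
  theta <- if (is.null(theta0)) {
    sgtlm_theta(rep(0, p), 0, rep(0, q), diag(1, q), nu, mixing, fde, fd)
  } else {
    sgtlm_theta(theta0$beta, if (fde) 0 else theta0$delta_eps,
                if (fd == "all") rep(0, q) else
                  replace(theta0$delta, if (fd == "first") 1 else integer(0), 0),
                theta0$d_bar, nu, mixing, fde, fd)
  }

  cl <- .split_clusters(panel)
  phase <- if (isTRUE(control$use_px)) "px" else "plain"
  trace <- numeric(0)
  converged <- FALSE
  px_iters <- 0L
  for (k in seq_len(control$max_iter)) {
    es <- sgtlm_estep(theta, panel, control, cl = cl)
    trace[k] <- es$loglik
    if (control$verbose)
      message(sprintf("iter %3d [%s] loglik %.6f", k, phase, es$loglik))
    if (phase == "plain" && k >= 2L &&
        abs(trace[k] - trace[k - 1]) <
          control$loglik_rtol * abs(trace[k - 1])) {
      converged <- TRUE
      break
    }
    if (phase == "px") {
      r <- tryCatch(sgtlm_px_mstep(es, panel, theta),
                    error = function(e) NULL)
      if (is.null(r)) {
        warning("PX system singular; falling back to plain EM")
        theta <- sgtlm_mstep(es, panel, theta)
        phase <- "plain"
      } else {
        theta <- r$theta
        px_iters <- k
        lam_max <- max(abs(eigen(r$alpha - diag(1, q),
                                 only.values = TRUE)$values))
        if (lam_max < control$px_tol) phase <- "plain"
      }
    } else {
      theta <- sgtlm_mstep(es, panel, theta)
    }
  }
  niter <- length(trace)

  # step 7: rescaling to the unit-conditional-variance link scale
  ups <- upsilon0(theta$delta_eps, theta$nu, theta$mixing)
  theta_rep <- theta
  theta_rep$beta <- ups * theta$beta
  theta_rep$delta <- ups * theta$delta
  theta_rep$d_bar <- ups^2 * theta$d_bar

  ctl_f <- control
  ctl_f$npts_estep <- control$npts_final
  es_f <- sgtlm_estep(theta, panel, ctl_f, level = 2L, cl = cl)
  loglik <- es_f$loglik
  inf <- .sgtlm_information(theta, panel, es_f, ups)
  eb <- .sgtlm_eb(theta_rep, panel, ctl_f, ups)
  np <- .n_free_params(theta)
  ic <- information_criteria(loglik, np, length(panel$y))

  structure(list(theta = theta_rep, theta_internal = theta,
                 upsilon0 = ups, link = link, nu = theta$nu,
                 loglik = loglik, trace = trace, niter = niter,
                 px_iters = px_iters, converged = converged,
                 coefficients = inf$estimates, se = inf$se,
                 vcov = inf$vcov, par_names = inf$par_names,
                 varcomp = inf$varcomp, ic = ic, n_params = np,
                 eb = eb, panel = panel, control = control,
                 restrictions = list(fix_delta_eps = theta$fix_delta_eps,
                                     fix_delta = theta$fix_delta)),
            class = "sgtlm")
}

#' Select the degrees of freedom on a grid
#'
#' Fits the model for every value of `nu` on a grid, warm-starting each
#' fit from the previous grid point, and returns the fit maximizing the
#' marginal log-likelihood together with the profile curve.  A maximum at
#' the lower grid edge is flagged: for the symmetric generalized-t link
#' the profiled log-likelihood can be unbounded as \eqn{\nu} decreases, in
#' which case no interior maximum exists.
#'
#' @inheritParams sgtlm_fit
#' @param nu_grid increasing grid of candidate degrees of freedom
#'   (all > 2).
#' @return list with `nu_hat`, `fit` (the selected [sgtlm_fit()] result),
#'   `profile` (data frame of nu and log-likelihood) and `edge` (`TRUE`
#'   when the maximum sits at the lower grid edge).
#' @export
select_nu <- function(panel, link = c("sgt", "gt"), nu_grid,
                      restrictions = NULL, control = sgtlm_control()) {
  link <- match.arg(link)
  nu_grid <- sort(as.numeric(nu_grid))
  if (length(nu_grid) < 1L || any(nu_grid <= 2))
    stop("nu_grid must contain values > 2")
  fits <- vector("list", length(nu_grid))
  ll <- rep(NA_real_, length(nu_grid))
  th <- NULL
  for (j in seq_along(nu_grid)) {
    fits[[j]] <- tryCatch(
      sgtlm_fit(panel, link, nu = nu_grid[j], restrictions = restrictions,
                control = control, theta0 = th),
      error = function(e) NULL)
    if (!is.null(fits[[j]])) {
      ll[j] <- fits[[j]]$loglik
      th <- fits[[j]]$theta_internal
    }
  }
  if (all(is.na(ll))) stop("no grid fit converged")
  best <- which.max(ll)
  list(nu_hat = nu_grid[best], fit = fits[[best]],
       profile = data.frame(nu = nu_grid, loglik = ll),
       edge = best == 1L && length(nu_grid) > 1L)
}

#' Fit a skew generalized t-link mixed model (formula interface)
#'
#' Front end to [sgtlm_fit()] and [select_nu()]: builds the panel from a
#' long-format data frame with a model formula for the fixed effects and a
#' one-sided formula for the random-effects covariates.
#'
#' @param fixed model formula for the binary outcome and fixed effects,
#'   e.g. `y ~ treat + baseline`.
#' @param random one-sided formula for the random-effects design, e.g.
#'   `~ 1` (random intercept) or `~ age` (random slope, no intercept).
#' @param data long-format data frame.
#' @param cluster cluster identifier: a column name or a vector.
#' @param link,nu,restrictions,control passed to [sgtlm_fit()]; a `nu`
#'   vector of length > 1 triggers grid selection via [select_nu()].
#' @return an object of class `sgtlm`.
#' @examples
#' \donttest{
#' d <- make_fixture("simdesign", seed = 1, n_clusters = 60)
#' f <- sgtlm(y ~ x1, random = ~ w1, data = d, cluster = "id",
#'            link = "probit")
#' summary(f)
#' }
#' @export
sgtlm <- function(fixed, random = ~1, data, cluster,
                  link = c("sgt", "gt", "skew-probit", "probit"),
                  nu = NULL, restrictions = NULL,
                  control = sgtlm_control()) {
  link <- match.arg(link)
  data <- as.data.frame(data)
  mf <- model.frame(fixed, data)
  y <- model.response(mf)
  X <- model.matrix(fixed, mf)
  W <- model.matrix(random, data)
  id <- if (is.character(cluster) && length(cluster) == 1L)
    data[[cluster]] else cluster
  panel <- sgtlm_panel(y, X, W, id)
  if (length(nu) > 1L) {
    sel <- select_nu(panel, link, nu_grid = nu,
                     restrictions = restrictions, control = control)
    fit <- sel$fit
    fit$profile <- sel$profile
    fit$nu_edge <- sel$edge
    fit
  } else {
    sgtlm_fit(panel, link, nu = nu, restrictions = restrictions,
              control = control)
  }
}
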