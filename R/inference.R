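#' Penalized-likelihood model selection criteria
#'
#' \eqn{AIC = -2\hat\ell + 2N_p}, \eqn{BIC = -2\hat\ell + N_p\log N},
#' \eqn{HQ = -2\hat\ell + 2N_p\log(\log N)} with \eqn{N} the total number
#' of observations and \eqn{N_p} the number of estimated parameters.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of estimated parameters \eqn{N_p}.
#' @param n_obs total number of observations \eqn{N > 1}.
#' @return named vector with elements `aic`, `bic`, `hq`.
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  if (n_obs <= 1) stop("n_obs must exceed 1")
  c(aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + n_params * log(n_obs),
    hq = -2 * loglik + 2 * n_params * log(log(n_obs)))
}

# number of free parameters: beta + unrestricted skewness entries +
# vech(Dbar).  nu is treated as known/grid-selected and not counted
# (count_nu = TRUE adds 1).
.n_free_params <- function(theta, count_nu = FALSE) {
  q <- length(theta$delta)
  nd <- switch(theta$fix_delta, none = q, first = q - 1L, all = 0L)
  length(theta$beta) + (!theta$fix_delta_eps) + nd + q * (q + 1L) / 2L +
    as.integer(count_nu)
}

.par_names <- function(theta, xnames, wnames) {
  q <- length(theta$delta)
  nm <- xnames
  if (!theta$fix_delta_eps) nm <- c(nm, "delta_eps")
  free_d <- switch(theta$fix_delta, none = seq_len(q),
                   first = seq_len(q)[-1], all = integer(0))
  nm <- c(nm, if (length(free_d)) paste0("delta.", wnames[free_d]))
  lt <- which(lower.tri(theta$d_bar, diag = TRUE), arr.ind = TRUE)
  c(nm, paste0("dbar.", lt[, 1], ".", lt[, 2]))
}

# per-cluster score of the expected complete-data log-likelihood at the
# (internal-scale) estimate: the building block of the empirical
# information matrix sum g_i g_i'.
.cluster_score <- function(theta, X, W, m) {
  cc <- .half_normal_mean
  u1c <- .u1c(theta)
  bm <- m$bm
  q <- length(theta$delta)
  Xb <- as.numeric(X %*% theta$beta)
  de <- theta$delta_eps
  g <- as.numeric(crossprod(X, bm$S1 - de * bm$S2)) -
    m$u2 * as.numeric(crossprod(X) %*% theta$beta)
  if (!theta$fix_delta_eps) {
    g <- c(g, sum(bm$S4 - cc * u1c * bm$S1) - bm$S2 * sum(Xb) -
             de * nrow(X) * bm$S3)
  }
  Dinv <- solve(theta$d_bar)
  free_d <- switch(theta$fix_delta, none = seq_len(q),
                   first = seq_len(q)[-1], all = integer(0))
  if (length(free_d)) {
    gd <- as.numeric(Dinv %*% (bm$vub_bar - bm$S3 * theta$delta))
    g <- c(g, gd[free_d])
  }
  GD <- -0.5 * Dinv + 0.5 * Dinv %*%
    (bm$u2b2 - outer(theta$delta, bm$vub_bar) -
       outer(bm$vub_bar, theta$delta) +
       bm$S3 * tcrossprod(theta$delta)) %*% Dinv
  # vech gradient of a symmetric-matrix derivative: off-diagonals doubled
  vech <- GD[lower.tri(GD, diag = TRUE)]
  mult <- (2 - diag(q)[lower.tri(diag(q), diag = TRUE)])
  c(g, vech * mult)
}

#' Empirical observed information matrix
#'
#' The score-based (empirical) information
#' \eqn{I_o(\hat\theta \mid y) = \sum_i \hat g_i\hat g_i^\top}, where
#' \eqn{\hat g_i} is the gradient of cluster i's contribution to the
#' expected complete-data log-likelihood, evaluated at the estimate on the
#' internal (\eqn{\upsilon_0 = 1}) scale.  Restricted coordinates are
#' excluded.
#'
#' @param theta internal-scale [sgtlm_theta()] (e.g. `fit$theta_internal`).
#' @param panel an [sgtlm_panel()].
#' @param control an [sgtlm_control()].
#' @return the information matrix over the free parameters.
#' @export
observed_information <- function(theta, panel, control = sgtlm_control()) {
  ctl <- control
  ctl$npts_estep <- control$npts_final
  es <- sgtlm_estep(theta, panel, ctl, level = 2L)
  .observed_information_es(theta, panel, es)
}

.observed_information_es <- function(theta, panel, es) {
  scores <- vapply(seq_along(es$clusters), function(i) {
    ix <- panel$index[[i]]
    .cluster_score(theta, panel$X[ix, , drop = FALSE],
                   panel$W[ix, , drop = FALSE], es$clusters[[i]])
  }, numeric(.n_free_params(theta)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  tcrossprod(scores)
}

# generalized inverse via eigendecomposition (dropping near-null space)
.safe_solve <- function(m) {
  out <- tryCatch(solve(m), error = function(e) NULL)
  if (!is.null(out) && all(is.finite(out)) && all(diag(out) >= 0))
    return(out)
  warning("singular information matrix: using a pseudo-inverse")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# Wald machinery on the reported scale.  Internal free parameters map to
# the reported ones through (beta, delta, vech Dbar) -> (ups beta,
# ups delta, ups^2 vech Dbar) with ups = upsilon0(delta_eps, nu), so the
# Jacobian has a delta_eps column from the chain rule.
.sgtlm_information <- function(theta, panel, es, ups) {
  q <- length(theta$delta)
  p <- length(theta$beta)
  Io <- .observed_information_es(theta, panel, es)
  V <- .safe_solve(Io)
  nm <- .par_names(theta, colnames(panel$X), colnames(panel$W))
  npar <- length(nm)
  J <- diag(npar)
  free_d <- switch(theta$fix_delta, none = seq_len(q),
                   first = seq_len(q)[-1], all = integer(0))
  i_beta <- seq_len(p)
  i_de <- if (!theta$fix_delta_eps) p + 1L else integer(0)
  i_delta <- p + (!theta$fix_delta_eps) + seq_along(free_d)
  i_vech <- seq.int(p + (!theta$fix_delta_eps) + length(free_d) + 1L, npar)
  J[cbind(i_beta, i_beta)] <- ups
  if (length(i_delta)) J[cbind(i_delta, i_delta)] <- ups
  J[cbind(i_vech, i_vech)] <- ups^2
  if (length(i_de)) {
    u1 <- .u1c(theta)
    u2 <- if (theta$mixing == "normal") 1 else mixing_moment(2, theta$nu)
    kap <- u2 - .half_normal_mean^2 * u1^2
    dups <- -ups^3 * kap * theta$delta_eps
    J[i_beta, i_de] <- theta$beta * dups
    if (length(i_delta)) J[i_delta, i_de] <- theta$delta[free_d] * dups
    vech_int <- theta$d_bar[lower.tri(theta$d_bar, diag = TRUE)]
    J[i_vech, i_de] <- vech_int * 2 * ups * dups
  }
  vcov <- J %*% V %*% t(J)
  dimnames(vcov) <- list(nm, nm)
  est <- c(ups * theta$beta,
           if (!theta$fix_delta_eps) theta$delta_eps,
           (ups * theta$delta)[free_d],
           (ups^2 * theta$d_bar)[lower.tri(theta$d_bar, diag = TRUE)])
  names(est) <- nm
  se <- sqrt(pmax(diag(vcov), 0))
  theta_rep <- theta
  theta_rep$beta <- ups * theta$beta
  theta_rep$delta <- ups * theta$delta
  theta_rep$d_bar <- ups^2 * theta$d_bar
  vc <- delta_method_varcomp(theta_rep, vcov)
  list(estimates = est, se = se, vcov = vcov, par_names = nm, varcomp = vc)
}

#' Delta-method standard errors of the random-effects covariances
#'
#' Maps the (reported-scale) covariance matrix of
#' \eqn{(\delta, \mathrm{vech}\,\bar D)} to standard errors of the
#' marginal random-effects variances and covariances
#' \eqn{\Sigma_b = \tilde U_2\bar D + (\tilde U_2 - c^2\tilde U_1^2)
#' \delta\delta^\top}.
#'
#' @param theta reported-scale [sgtlm_theta()].
#' @param vcov parameter covariance matrix with rows/columns named as in
#'   a fitted `sgtlm` object.
#' @return data frame with the entries of \eqn{\Sigma_b}, their estimates
#'   and standard errors.
#' @export
delta_method_varcomp <- function(theta, vcov) {
  q <- length(theta$delta)
  u1 <- .u1c(theta)
  u2 <- if (theta$mixing == "normal") 1 else mixing_moment(2, theta$nu)
  kap <- u2 - .half_normal_mean^2 * u1^2
  sig <- ranef_covariance(theta$d_bar, theta$delta, theta$nu, theta$mixing)
  nm <- colnames(vcov)
  lt <- which(lower.tri(sig, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(entry = paste0("sigma.", lt[, 1], ".", lt[, 2]),
                    estimate = sig[lt], se = NA_real_)
  for (r in seq_len(nrow(lt))) {
    k <- lt[r, 1]; l <- lt[r, 2]
    grad <- setNames(numeric(length(nm)), nm)
    dn <- paste0("dbar.", k, ".", l)
    if (dn %in% nm) grad[dn] <- u2
    dk <- theta$delta
    dnames <- grep("^delta\\.", nm, value = TRUE)
    if (length(dnames)) {
      free_d <- switch(theta$fix_delta, none = seq_len(q),
                       first = seq_len(q)[-1], all = integer(0))
      gd <- kap * (dk[l] * (free_d == k) + dk[k] * (free_d == l))
      grad[dnames] <- gd
    }
    out$se[r] <- sqrt(max(0, as.numeric(t(grad) %*% vcov %*% grad)))
  }
  out
}

# empirical Bayes pass: conditional means of the random effects and of
# the scale-mixing weights, on the reported parameter scale.
.sgtlm_eb <- function(theta_rep, panel, control, ups) {
  cc <- .half_normal_mean
  u1c <- .u1c(theta_rep)
  es <- sgtlm_estep(theta_rep, panel, control, level = 3L, ups = ups)
  q <- length(theta_rep$delta)
  n <- length(es$clusters)
  b_hat <- matrix(NA_real_, n, q,
                  dimnames = list(names(panel$index),
                                  colnames(panel$W)))
  u2_hat <- setNames(numeric(n), names(panel$index))
  for (i in seq_len(n)) {
    ix <- panel$index[[i]]
    m <- es$clusters[[i]]
    bm <- m$bm
    Xb <- as.numeric(panel$X[ix, , drop = FALSE] %*% theta_rep$beta)
    b_hat[i, ] <- as.numeric(bm$ri %*% (m$z1 - Xb)) +
      (m$vum1 - cc * u1c) * bm$s
    u2_hat[i] <- m$u2
  }
  list(b_hat = b_hat, u2_hat = u2_hat)
}

#' Empirical Bayes random-effects estimates
#'
#' Conditional means \eqn{\bar b_i = E\{b_i \mid Y_i = y_i, \hat\theta\}}
#' of the cluster random effects at the maximum likelihood estimate.
#'
#' @param fit a fitted `sgtlm` object.
#' @return matrix with one row per cluster.
#' @export
sgtlm_ranef <- function(fit) fit$eb$b_hat

#' Empirical Bayes scale-mixing weights
#'
#' Conditional means \eqn{\hat u_i = E\{U_i \mid y_i, \hat\theta\}} of the
#' gamma scale-mixing weights.  Weights below 1 mark clusters whose
#' response pattern is downweighted by the heavy-tailed link: candidate
#' outliers.
#'
#' @param fit a fitted `sgtlm` object.
#' @return data frame with the weight and an outlier flag per cluster.
#' @export
eb_weights <- function(fit) {
  data.frame(cluster = names(fit$eb$u2_hat), weight = fit$eb$u2_hat,
             outlier = fit$eb$u2_hat < 1, row.names = NULL)
}

#' @export
coef.sgtlm <- function(object, ...) object$coefficients

#' @export
logLik.sgtlm <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = length(object$panel$y), class = "logLik")
}

#' @export
vcov.sgtlm <- function(object, ...) object$vcov

#' @export
print.sgtlm <- function(x, ...) {
  cat("Skew generalized t-link mixed model (link: ", x$link,
      if (is.finite(x$nu)) paste0(", nu = ", format(x$nu)), ")\n", sep = "")
  cat("log-likelihood:", format(x$loglik, digits = 7),
      " AIC:", format(x$ic["aic"], digits = 7),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summary of a fitted skew generalized t-link mixed model
#'
#' @param object a fitted `sgtlm` object.
#' @param ... unused.
#' @return an object of class `summary.sgtlm` printed as a coefficient
#'   table (estimate, standard error, z value), the random-effects
#'   variance components with delta-method standard errors, and the
#'   information criteria.
#' @export
summary.sgtlm <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, se = object$se,
               `z value` = object$coefficients / object$se)
  structure(list(fit = object, table = tab), class = "summary.sgtlm")
}

#' @export
print.summary.sgtlm <- function(x, ...) {
  f <- x$fit
  cat("Skew generalized t-link mixed model\n")
  cat("  link:", f$link,
      if (is.finite(f$nu)) paste0("(nu = ", format(f$nu), ")"), "\n")
  cat("  clusters:", length(f$panel$index),
      " observations:", length(f$panel$y), "\n")
  cat("  upsilon0:", format(f$upsilon0, digits = 4),
      " EM iterations:", f$niter,
      if (!f$converged) " [NOT CONVERGED]", "\n\n")
  printCoefmat(x$table, digits = 4)
  cat("\nRandom-effects covariance (Sigma_b):\n")
  print(f$varcomp, digits = 4, row.names = FALSE)
  cat("\nlog-likelihood:", format(f$loglik, digits = 7), "\n")
  ic <- f$ic
  cat("AIC:", format(ic["aic"], digits = 7),
      " BIC:", format(ic["bic"], digits = 7),
      " HQ:", format(ic["hq"], digits = 7), "\n")
  invisible(x)
}
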