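# High-accuracy analytic control for small EM correctness problems
ctl_exact <- function(...) {
  sgtlm_control(estep_method = "analytic", abseps = 1e-8,
                npts_final = 65536L, ...)
}

test_that("QMC and analytic E-steps agree", {
  panel <- make_small_panel(n = 20, ni = 2, seed = 4)
  th <- sgtlm_theta(c(-0.3, 0.6), -0.8, 1.1, matrix(0.7), 5, "t")
  e1 <- sgtlm_estep(th, panel, sgtlm_control(npts_estep = 65536L),
                    level = 3L)
  e2 <- sgtlm_estep(th, panel, ctl_exact(), level = 3L)
  expect_equal(e1$loglik, e2$loglik, tolerance = 1e-5)
  for (i in c(1, 7, 20)) {
    a <- e1$clusters[[i]]; b <- e2$clusters[[i]]
    for (f in c("u2", "vu", "v2", "u2z", "vuz", "u2z2", "vum1", "z1"))
      expect_equal(a[[f]], b[[f]], tolerance = 1e-3,
                   label = paste0("cluster ", i, " field ", f))
    expect_equal(a$bm$u2b, b$bm$u2b, tolerance = 1e-3)
    expect_equal(a$bm$u2b2, b$bm$u2b2, tolerance = 1e-3)
  }
})

test_that("E-step expectations match a rejection oracle on one cluster", {
  # single cluster, n_i = 2, q = 1: all conditional expectations versus
  # rejection draws of (Z, b, U, V) given the observed pattern
  th <- sgtlm_theta(c(-0.4, 0.9), -1, 1.3, matrix(0.6), 5, "t")
  set.seed(31)
  X <- cbind(1, c(0.5, -0.8))
  W <- cbind(c(0.7, -0.4))
  y <- c(1, 0)
  panel <- sgtlm_panel(y, X, W, c(1, 1))
  es <- sgtlm_estep(th, panel, sgtlm_control(npts_estep = 65536L))$clusters[[1]]

  n <- 1.5e6
  u <- rgamma(n, 2.5, rate = 2.5)
  v <- abs(rnorm(n))
  skew <- v / sqrt(u) - cc_hn * mixing_moment(1, 5)
  b <- skew * th$delta + rnorm(n, 0, sqrt(0.6)) / sqrt(u)
  eta <- matrix(as.numeric(X %*% th$beta), n, 2, byrow = TRUE) +
    tcrossprod(b, W[, 1])
  z <- eta + skew * th$delta_eps + matrix(rnorm(2 * n), n, 2) / sqrt(u)
  keep <- z[, 1] > 0 & z[, 2] <= 0
  u <- u[keep]; v <- v[keep]; b <- b[keep]; z <- z[keep, ]

  expect_lt(abs(es$alpha - mean(keep)), 4 * sqrt(mean(keep) / length(keep)))
  expect_lt(abs(es$u2 - mean(u)), 4 * mc_se(u))
  expect_lt(abs(es$vu - mean(v * sqrt(u))), 4 * mc_se(v * sqrt(u)))
  expect_lt(abs(es$v2 - mean(v^2)), 4 * mc_se(v^2))
  for (k in 1:2) {
    expect_lt(abs(es$u2z[k] - mean(u * z[, k])), 4 * mc_se(u * z[, k]))
    expect_lt(abs(es$vuz[k] - mean(v * sqrt(u) * z[, k])),
              4 * mc_se(v * sqrt(u) * z[, k]))
    expect_lt(abs(es$u2z2[k, k] - mean(u * z[, k]^2)),
              4 * mc_se(u * z[, k]^2))
  }
  expect_lt(abs(es$bm$u2b - mean(u * b)), 4 * mc_se(u * b))
  expect_lt(abs(es$bm$vub - mean(v * sqrt(u) * b)),
            4 * mc_se(v * sqrt(u) * b))
  expect_lt(abs(es$bm$u2b2 - mean(u * b^2)), 4 * mc_se(u * b^2))
  for (k in 1:2)
    expect_lt(abs(es$bm$u2bz[1, k] - mean(u * b * z[, k])),
              4 * mc_se(u * b * z[, k]))
})

test_that("symmetric-link reduction: half-normal channel decouples", {
  # with delta_eps = 0 and delta = 0 the hidden half-normal V is
  # independent of the data: E{V U^{1/2}|y} = c E{U^{1/2}|y}, E{V^2} = 1
  panel <- make_small_panel(n = 15, ni = 2, seed = 6, delta_eps = 0,
                            delta1 = 0)
  th <- sgtlm_theta(c(-0.3, 0.6), 0, 0, matrix(0.7), 5, "t",
                    fix_delta_eps = TRUE, fix_delta = "all")
  es <- sgtlm_estep(th, panel, sgtlm_control(npts_estep = 32768L),
                    level = 3L)
  for (m in es$clusters[c(2, 9)]) {
    expect_equal(m$v2, 1, tolerance = 5e-3)
    expect_equal(m$vu, cc_hn * m$u1, tolerance = 5e-3)
  }
})

test_that("M-step respects restrictions and is self-consistent at truth", {
  # moments computed at the generating parameter update to (nearly) the
  # same parameter on a large panel
  panel <- make_small_panel(n = 600, ni = 4, seed = 8)
  th <- sgtlm_theta(c(-0.5, 1), -1, 1.5, matrix(0.8), 5, "t")
  es <- sgtlm_estep(th, panel, sgtlm_control())
  up <- sgtlm_mstep(es, panel, th)
  expect_lt(max(abs(up$beta - th$beta)), 0.2)
  expect_lt(abs(up$delta_eps - th$delta_eps), 0.35)
  expect_lt(abs(up$delta - th$delta), 0.35)
  expect_lt(abs(up$d_bar - th$d_bar), 0.3)
  # frozen coordinates stay exactly zero
  panel2 <- make_small_panel(n = 30, ni = 3, seed = 9)
  W2 <- cbind(1, panel2$W)
  panel2 <- sgtlm_panel(panel2$y, panel2$X, W2, panel2$id)
  th2 <- sgtlm_theta(c(0, 0), -0.5, c(0, 0.5), diag(2), 5, "t",
                     fix_delta = "first")
  es2 <- sgtlm_estep(th2, panel2, sgtlm_control())
  up2 <- sgtlm_mstep(es2, panel2, th2)
  expect_identical(up2$delta[1], 0)
  expect_false(up2$delta[2] == 0)
  up2px <- sgtlm_px_mstep(es2, panel2, th2)
  expect_identical(up2px$theta$delta[1], 0)
})

test_that("one PX step dominates one plain EM step from a distant start", {
  wins <- 0
  for (seed in 1:6) {
    panel <- make_small_panel(n = 40, ni = 3, seed = 100 + seed)
    th <- sgtlm_theta(c(0, 0), 0, 0, matrix(4), 5, "t")
    ctl <- sgtlm_control(npts_estep = 8192L)
    es <- sgtlm_estep(th, panel, ctl)
    th_em <- sgtlm_mstep(es, panel, th)
    th_px <- sgtlm_px_mstep(es, panel, th)$theta
    ll_em <- sgtlm_estep(th_em, panel, ctl)$loglik
    ll_px <- sgtlm_estep(th_px, panel, ctl)$loglik
    expect_gt(ll_px, es$loglik)   # PX is still an ascent step
    if (ll_px >= ll_em - 1e-8) wins <- wins + 1
  }
  expect_gte(wins, 5)
})

test_that("EM ascent, PX/plain agreement and rescaling invariance", {
  # skewed fit with exact (analytic) E-step: the log-likelihood trace is
  # monotone even along the weakly identified skewness ridge
  panel <- make_small_panel(n = 40, ni = 1, seed = 10, delta_eps = -1,
                            delta1 = 1)
  ctl <- ctl_exact(max_iter = 150)
  fit_px <- sgtlm_fit(panel, "sgt", nu = 5, control = ctl)
  expect_true(all(diff(fit_px$trace) > -1e-8))
  # symmetric t-link fit (well identified): PX-EM and plain EM converge
  # to the same maximum from the same start, both with monotone traces
  panel2 <- make_small_panel(n = 50, ni = 2, seed = 11, delta_eps = 0,
                             delta1 = 0)
  ctl2 <- sgtlm_control(npts_estep = 8192L, npts_final = 8192L,
                        max_iter = 1000, loglik_rtol = 1e-8)
  fit2_px <- sgtlm_fit(panel2, "gt", nu = 5, control = ctl2)
  ctl2_em <- ctl2; ctl2_em$use_px <- FALSE
  fit2_em <- sgtlm_fit(panel2, "gt", nu = 5, control = ctl2_em)
  expect_true(fit2_px$converged && fit2_em$converged)
  expect_lt(fit2_px$niter, fit2_em$niter)  # the acceleration accelerates
  expect_true(all(diff(fit2_px$trace) > -1e-8))
  expect_true(all(diff(fit2_em$trace) > -1e-8))
  expect_equal(fit2_px$loglik, fit2_em$loglik, tolerance = 1e-4)
  # near the maximum the PX working scale is close to the identity
  es <- sgtlm_estep(fit2_px$theta_internal, panel2, ctl2)
  alpha <- sgtlm_px_mstep(es, panel2, fit2_px$theta_internal)$alpha
  expect_lt(max(abs(eigen(alpha - diag(1), only.values = TRUE)$values)),
            1e-2)
  # terminal rescaling leaves the marginal log-likelihood unchanged
  ll_int <- sgtlm_loglik(fit2_px$theta_internal, panel2, ups = 1,
                         npts = 65536L)
  ll_rep <- sgtlm_loglik(fit2_px$theta, panel2, ups = fit2_px$upsilon0,
                         npts = 65536L)
  expect_equal(as.numeric(ll_int), as.numeric(ll_rep), tolerance = 1e-5)
})

test_that("probit fit recovers the generating fixed effects", {
  set.seed(44)
  design <- sim_design("probit", n_clusters = 250, n_reps = 1, seed = 44)
  panel <- simulate_panel(design, 1)
  fit <- sgtlm_fit(panel, "probit",
                   control = sgtlm_control(npts_estep = 256L,
                                           npts_final = 2048L))
  expect_true(fit$converged)
  # within 3 sampling SDs of the truth (single replicate)
  expect_lt(abs(fit$theta$beta[1] - (-1)), 3 * fit$se[1])
  expect_lt(abs(fit$theta$beta[2] - 1), 3 * fit$se[2])
})

test_that("degrees-of-freedom grid selection", {
  panel <- make_small_panel(n = 60, ni = 4, seed = 15, nu = 5)
  ctl <- sgtlm_control(npts_estep = 256L, npts_final = 2048L,
                       loglik_rtol = 1e-5)
  # single-point grid equals a plain fit
  sel1 <- select_nu(panel, "sgt", nu_grid = 5, control = ctl)
  fit1 <- sgtlm_fit(panel, "sgt", nu = 5, control = ctl)
  expect_equal(sel1$nu_hat, 5)
  expect_equal(sel1$fit$loglik, fit1$loglik, tolerance = 1e-6)
  # profile over a coarse grid: interior data-generating value wins over
  # the far tails in most replicates
  hits <- 0
  for (seed in 1:3) {
    p <- make_small_panel(n = 80, ni = 6, seed = 200 + seed, nu = 5,
                          delta_eps = -1.5, delta1 = 2)
    sel <- select_nu(p, "sgt", nu_grid = c(2.7, 5, 30), control = ctl)
    expect_equal(nrow(sel$profile), 3L)
    expect_true(all(is.finite(sel$profile$loglik)))
    if (sel$nu_hat == 5) hits <- hits + 1
  }
  expect_gte(hits, 2)
  # symmetric t link on very heavy-tailed data: the profile keeps rising
  # toward small degrees of freedom and the lower-edge maximum is flagged
  ph <- make_small_panel(n = 80, ni = 6, seed = 300, nu = 2.6,
                         delta_eps = -1.5, delta1 = 2)
  selh <- select_nu(ph, "gt", nu_grid = c(2.6, 4, 8), control = ctl)
  expect_true(selh$edge)
  expect_equal(selh$nu_hat, 2.6)
})
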