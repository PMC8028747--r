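test_that("information criteria arithmetic", {
  ic <- information_criteria(-100, 5, 60)
  expect_equal(unname(ic["aic"]), 210)
  expect_equal(unname(ic["bic"]), 200 + 5 * log(60), tolerance = 1e-12)
  expect_equal(unname(ic["hq"]), 200 + 10 * log(log(60)), tolerance = 1e-12)
  expect_equal(round(unname(ic["bic"]), 2), 220.47)
  expect_equal(round(unname(ic["hq"]), 2), 214.1)
  expect_error(information_criteria(-10, 2, 1), "n_obs")
})

test_that("cluster scores obey the Fisher identity", {
  # sum of the Q-gradient cluster scores equals the gradient of the
  # marginal log-likelihood (numerical differentiation oracle)
  skip_if_not_installed("numDeriv")
  panel <- make_small_panel(n = 12, ni = 2, seed = 23)
  th <- sgtlm_theta(c(-0.2, 0.5), -0.6, 0.9, matrix(0.8), 5, "t")
  ctl <- sgtlm_control(estep_method = "analytic", abseps = 1e-8)
  es <- sgtlm_estep(th, panel, ctl)
  sc <- rowSums(vapply(seq_along(es$clusters), function(i) {
    ix <- panel$index[[i]]
    sgtlm:::.cluster_score(th, panel$X[ix, , drop = FALSE],
                           panel$W[ix, , drop = FALSE],
                           es$clusters[[i]])
  }, numeric(5)))
  num <- numDeriv::grad(function(par) {
    t2 <- sgtlm_theta(par[1:2], par[3], par[4], matrix(par[5]), 5, "t")
    as.numeric(sgtlm_loglik(t2, panel, npts = 65536L))
  }, c(th$beta, th$delta_eps, th$delta, th$d_bar[1, 1]),
  method = "Richardson")
  expect_equal(sc, num, tolerance = 2e-3)
})

test_that("score sums vanish at the maximum likelihood estimate", {
  panel <- make_small_panel(n = 60, ni = 3, seed = 24)
  fit <- sgtlm_fit(panel, "sgt", nu = 5,
                   control = sgtlm_control(npts_estep = 4096L,
                                           npts_final = 8192L))
  th <- fit$theta_internal
  es <- sgtlm_estep(th, panel, sgtlm_control(npts_estep = 8192L))
  sc <- rowSums(vapply(seq_along(es$clusters), function(i) {
    ix <- panel$index[[i]]
    sgtlm:::.cluster_score(th, panel$X[ix, , drop = FALSE],
                           panel$W[ix, , drop = FALSE],
                           es$clusters[[i]])
  }, numeric(fit$n_params)))
  expect_lt(max(abs(sc)) / length(panel$index), 0.05)
  # information is invariant to cluster ordering
  Io1 <- sgtlm:::.observed_information_es(th, panel, es)
  perm <- sample(length(panel$index))
  panel_p <- sgtlm_panel(panel$y[unlist(panel$index[perm])],
                         panel$X[unlist(panel$index[perm]), ],
                         panel$W[unlist(panel$index[perm]), , drop = FALSE],
                         panel$id[unlist(panel$index[perm])])
  es_p <- sgtlm_estep(th, panel_p, sgtlm_control(npts_estep = 8192L))
  Io2 <- sgtlm:::.observed_information_es(th, panel_p, es_p)
  expect_equal(Io1, Io2, tolerance = 1e-6)
})

test_that("delta-method variance-component standard errors", {
  skip_if_not_installed("numDeriv")
  # symmetric t link (delta frozen): SE(sigma_kl) = U~2 SE(Dbar_kl)
  panel <- make_small_panel(n = 50, ni = 3, seed = 25, delta_eps = 0,
                            delta1 = 0)
  fit <- sgtlm_fit(panel, "gt", nu = 5,
                   control = sgtlm_control(npts_estep = 2048L))
  u2 <- mixing_moment(2, 5)
  se_dbar <- fit$se["dbar.1.1"]
  expect_equal(fit$varcomp$se[1], unname(u2 * se_dbar), tolerance = 1e-10)
  expect_equal(fit$varcomp$estimate[1],
               unname(u2 * fit$coefficients["dbar.1.1"]),
               tolerance = 1e-10)
  # general case: gradient matches numerical differentiation
  th <- sgtlm_theta(c(0, 0), -0.5, c(0, 1.2),
                    matrix(c(0.5, 0.2, 0.2, 1), 2), 5, "t",
                    fix_delta = "first")
  nm <- sgtlm:::.par_names(th, c("b0", "b1"), c("w0", "w1"))
  V <- diag(length(nm)) * 0.01
  dimnames(V) <- list(nm, nm)
  vc <- delta_method_varcomp(th, V)
  f_sig <- function(par) {
    t2 <- th
    t2$delta[2] <- par[1]
    t2$d_bar <- matrix(c(par[2], par[3], par[3], par[4]), 2)
    ranef_covariance(t2$d_bar, t2$delta, 5)[2, 2]
  }
  g <- numDeriv::grad(f_sig, c(1.2, 0.5, 0.2, 1))
  se_ref <- sqrt(sum(g^2) * 0.01)
  expect_equal(vc$se[vc$entry == "sigma.2.2"], se_ref, tolerance = 1e-6)
})

test_that("empirical Bayes random effects match quadrature and oracles", {
  skip_if_not_installed("pracma")
  # probit limit, n_i = 1: closed-form posterior mean by 1-d quadrature
  set.seed(26)
  X <- matrix(1); W <- matrix(1)
  beta <- 0.4; sb2 <- 0.9
  panel1 <- sgtlm_panel(1, X, W, 1)
  th <- sgtlm_theta(beta, 0, 0, matrix(sb2), Inf, "normal", TRUE, "all")
  eb <- sgtlm:::.sgtlm_eb(th, panel1, sgtlm_control(npts_final = 65536L),
                          ups = 1)
  gh <- pracma::gaussHermite(80)
  b <- gh$x * sqrt(2 * sb2); w <- gh$w / sqrt(pi)
  post <- sum(w * b * pnorm(beta + b)) / sum(w * pnorm(beta + b))
  expect_equal(unname(eb$b_hat[1, 1]), post, tolerance = 1e-4)
  # skewed heavy-tailed cluster against a rejection oracle
  th2 <- sgtlm_theta(c(-0.4, 0.9), -1, 1.3, matrix(0.6), 5, "t")
  X2 <- cbind(1, c(0.5, -0.8)); W2 <- cbind(c(0.7, -0.4))
  y2 <- c(1, 0)
  panel2 <- sgtlm_panel(y2, X2, W2, c(1, 1))
  ups <- upsilon0(th2$delta_eps, 5)
  thr <- th2; thr$beta <- ups * th2$beta; thr$delta <- ups * th2$delta
  thr$d_bar <- ups^2 * th2$d_bar
  eb2 <- sgtlm:::.sgtlm_eb(thr, panel2, sgtlm_control(npts_final = 65536L),
                           ups = ups)
  set.seed(27)
  n <- 2e6
  u <- rgamma(n, 2.5, rate = 2.5)
  v <- abs(rnorm(n))
  skew <- v / sqrt(u) - cc_hn * mixing_moment(1, 5)
  b <- skew * thr$delta + rnorm(n, 0, sqrt(thr$d_bar[1, 1])) / sqrt(u)
  eta <- matrix(as.numeric(X2 %*% thr$beta), n, 2, byrow = TRUE) +
    tcrossprod(b, W2[, 1])
  z <- eta + skew * ups * thr$delta_eps +
    ups * matrix(rnorm(2 * n), n, 2) / sqrt(u)
  keep <- z[, 1] > 0 & z[, 2] <= 0
  expect_lt(abs(eb2$b_hat[1, 1] - mean(b[keep])), 4 * mc_se(b[keep]))
  expect_lt(abs(eb2$u2_hat[1] - mean(u[keep])), 4 * mc_se(u[keep]))
})

test_that("empirical Bayes weights flag heavy-tail downweighting", {
  # normal mixing: weights are identically one
  panel <- make_small_panel(n = 20, ni = 2, seed = 28, mixing = "normal",
                            nu = Inf, delta_eps = 0, delta1 = 0)
  fit <- sgtlm_fit(panel, "probit",
                   control = sgtlm_control(npts_estep = 1024L))
  expect_equal(unname(eb_weights(fit)$weight), rep(1, 20))
  # t mixing: the panel average of E{U|y} stays near E{U} = 1
  panel2 <- make_small_panel(n = 150, ni = 3, seed = 29)
  th <- sgtlm_theta(c(-0.5, 1), -1, 1.5, matrix(0.8), 5, "t")
  es <- sgtlm_estep(th, panel2, sgtlm_control(npts_estep = 2048L))
  w <- vapply(es$clusters, `[[`, numeric(1), "u2")
  expect_lt(abs(mean(w) - 1), 0.1)
})

test_that("fit accessors and summaries are coherent", {
  panel <- make_small_panel(n = 30, ni = 3, seed = 30)
  fit <- sgtlm_fit(panel, "sgt", nu = 5,
                   control = sgtlm_control(npts_estep = 1024L,
                                           npts_final = 2048L))
  expect_s3_class(fit, "sgtlm")
  expect_equal(unname(coef(fit)), unname(fit$coefficients))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  expect_equal(attr(logLik(fit), "df"), fit$n_params)
  expect_equal(unname(fit$ic["aic"]),
               -2 * fit$loglik + 2 * fit$n_params)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("Random-effects covariance", out)))
  expect_true(any(grepl("delta_eps", out)))
})
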