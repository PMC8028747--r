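test_that("latent scale constant and random-effects covariance", {
  # the simulation-design value: delta_eps = -2, nu = 5
  expect_equal(round(upsilon0(-2, 5), 4), 0.4598)
  # symmetric t link: 1/sqrt(U~2)
  expect_equal(upsilon0(0, 5), sqrt(3 / 5), tolerance = 1e-12)
  # probit scale
  expect_equal(upsilon0(0, Inf), 1)
  expect_error(upsilon0(0, 2), "nu > 2")
  # marginal random-effects covariance at the simulation design truth
  S <- ranef_covariance(matrix(c(0.5, 0.25, 0.25, 1), 2), c(0, 2), 5)
  expect_equal(round(S[1, 1], 2), 0.83)
  expect_equal(round(S[2, 1], 2), 0.42)
  expect_equal(round(S[2, 2], 2), 4.73)
  # normal limit with no skewness returns Dbar itself
  db <- rand_pd(2)
  expect_equal(ranef_covariance(db, c(0, 0), Inf, "normal"), db)
  # positive semidefinite by construction
  set.seed(5)
  for (k in 1:5) {
    S <- ranef_covariance(rand_pd(3), rnorm(3), runif(1, 3, 10))
    expect_gt(min(eigen(S, only.values = TRUE)$values), 0)
  }
})

test_that("latent intra-class correlation", {
  # probit limit: classical sigma^2 / (1 + sigma^2)
  expect_equal(latent_icc(0.5, 0, Inf), 0.5 / 1.5)
  expect_equal(latent_icc(0, 0, 5), 0)
  # skewed heavy-tailed case against latent simulation from the
  # hierarchical representation (random intercept, delta = 0)
  sb2 <- 0.5; de <- -1; nu <- 5
  ups <- upsilon0(de, nu)
  u1 <- mixing_moment(1, nu)
  set.seed(9)
  n <- 4e5
  u <- rgamma(n, nu / 2, rate = nu / 2)
  v <- abs(rnorm(n))
  b <- rnorm(n, 0, sqrt(sb2)) / sqrt(u)
  skew <- (v / sqrt(u) - cc_hn * u1) * ups * de
  z1 <- b + skew + ups * rnorm(n) / sqrt(u)
  z2 <- b + skew + ups * rnorm(n) / sqrt(u)
  rho_mc <- cor(z1, z2)
  expect_equal(latent_icc(sb2, de, nu), rho_mc, tolerance = 0.02)
  expect_error(latent_icc(c(1, 1), 0, 5), "q = 1")
})

test_that("cluster marginal parameters and the confounding identity", {
  th <- sgtlm_theta(c(0.5, -1), delta_eps = 0, delta = c(0, 0),
                    d_bar = diag(2), nu = 5)
  X <- cbind(1, c(0.2, -0.1, 0.4))
  W <- cbind(1, c(1.1, 0.3, -0.5))
  cp <- sgtlm:::.cluster_params(th, X, W, ups = 1, full = TRUE)
  # no skewness anywhere: location is the linear predictor, shape zero
  expect_equal(cp$mu, as.numeric(X %*% th$beta))
  expect_equal(cp$lambda, rep(0, 3))
  # with a random intercept only, delta_eps and delta0 enter the marginal
  # law only through their sum
  W1 <- matrix(1, 3, 1)
  thA <- sgtlm_theta(c(0.5, -1), delta_eps = 0.7, delta = 0.2,
                     d_bar = matrix(1), nu = 5)
  thB <- sgtlm_theta(c(0.5, -1), delta_eps = 0.1, delta = 0.8,
                     d_bar = matrix(1), nu = 5)
  cpA <- sgtlm:::.cluster_params(thA, X, W1, ups = 1)
  cpB <- sgtlm:::.cluster_params(thB, X, W1, ups = 1)
  expect_equal(cpA$Delta, cpB$Delta)
  expect_equal(cpA$mu, cpB$mu)
  # Omega - Omega_bar has rank one
  thC <- sgtlm_theta(c(0.5, -1), delta_eps = -0.5, delta = c(0, 1.2),
                     d_bar = rand_pd(2), nu = 5)
  cpC <- sgtlm:::.cluster_params(thC, X, W, ups = 1, full = TRUE)
  d <- cpC$omega - cpC$omega_bar
  expect_equal(qr(d)$rank, 1L)
})

test_that("cluster likelihood sums to one over all outcome patterns", {
  th <- sgtlm_theta(c(-0.4, 0.8), delta_eps = -1.2, delta = c(0, 1.5),
                    d_bar = matrix(c(0.5, 0.2, 0.2, 0.9), 2), nu = 5)
  set.seed(21)
  for (ni in 1:3) {
    X <- cbind(1, rnorm(ni))
    W <- cbind(1, rnorm(ni))
    pats <- as.matrix(expand.grid(rep(list(0:1), ni)))
    tot <- sum(vapply(seq_len(nrow(pats)), function(r) {
      exp(sgtlm:::.cluster_loglik(th, pats[r, ], X, W, ups = 1,
                                  npts = 65536L)$loglik)
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  # same property on the reported scale (ups folded in)
  ups <- upsilon0(th$delta_eps, th$nu)
  X <- cbind(1, 0.3); W <- cbind(1, -0.2)
  p1 <- exp(sgtlm:::.cluster_loglik(th, 1, X, W, ups, npts = 65536L)$loglik)
  p0 <- exp(sgtlm:::.cluster_loglik(th, 0, X, W, ups, npts = 65536L)$loglik)
  expect_equal(p1 + p0, 1, tolerance = 1e-6)
})

test_that("cluster likelihood matches pattern frequencies from simulation", {
  th <- sgtlm_theta(c(-0.5, 1), delta_eps = -1.5, delta = c(0, 1.2),
                    d_bar = matrix(c(0.6, 0.2, 0.2, 1), 2), nu = 5)
  set.seed(12)
  ni <- 3
  X <- cbind(1, rnorm(ni))
  W <- cbind(1, rnorm(ni))
  # simulate the hierarchical representation (ups = 1 internal scale)
  n <- 4e5
  u <- rgamma(n, 5 / 2, rate = 5 / 2)
  v <- abs(rnorm(n))
  skew <- v / sqrt(u) - cc_hn * mixing_moment(1, 5)
  Lb <- chol(th$d_bar)
  b <- t(crossprod(Lb, matrix(rnorm(2 * n), 2)) / rep(sqrt(u), each = 2)) +
    tcrossprod(skew, th$delta)
  eta <- matrix(X %*% th$beta, n, ni, byrow = TRUE) + b %*% t(W)
  z <- eta + skew * th$delta_eps +
    matrix(rnorm(n * ni), n, ni) / sqrt(u)
  y_all <- (z > 0) + 0
  pat <- c(1, 0, 1)
  match_pat <- apply(y_all, 1, function(r) all(r == pat))
  p_hat <- mean(match_pat)
  p_mod <- exp(sgtlm:::.cluster_loglik(th, pat, X, W, ups = 1,
                                       npts = 65536L)$loglik)
  expect_lt(abs(p_mod - p_hat), 4 * sqrt(p_hat * (1 - p_hat) / n))
})

test_that("probit limit reproduces the Gauss-Hermite GLMM log-likelihood", {
  skip_if_not_installed("pracma")
  set.seed(14)
  n <- 30; ni <- 3
  id <- rep(seq_len(n), each = ni)
  X <- cbind(1, rnorm(n * ni))
  W <- matrix(1, n * ni, 1)
  beta <- c(-0.3, 0.7); sb2 <- 0.8
  b <- rnorm(n, 0, sqrt(sb2))
  y <- as.numeric(as.numeric(X %*% beta) + b[id] + rnorm(n * ni) > 0)
  panel <- sgtlm_panel(y, X, W, id)
  th <- sgtlm_theta(beta, 0, 0, matrix(sb2), Inf, "normal", TRUE, "all")
  ll <- sgtlm_loglik(th, panel, npts = 65536L)
  ll_gh <- gh_probit_loglik(beta, sb2, panel)
  expect_equal(as.numeric(ll), ll_gh, tolerance = 1e-3)
})

test_that("marginal success probability", {
  th0 <- sgtlm_theta(0, 0, 0, matrix(1e-8), Inf, "normal", TRUE, "all")
  # eta = 0, no skewness, vanishing random effects: one half
  expect_equal(success_prob(th0, 1, 0), 0.5, tolerance = 1e-6)
  # monotone increasing in the intercept
  th <- sgtlm_theta(c(0, 1), -1, 0.8, matrix(0.5), 5, "t")
  ps <- vapply(seq(-2, 2, by = 0.5), function(b0) {
    thb <- th; thb$beta <- c(b0, 1)
    success_prob(thb, c(1, 0.3), 0.5)
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
  # one skewed heavy-tailed configuration against simulation
  set.seed(18)
  nsim <- 4e5
  ups <- upsilon0(th$delta_eps, 5)
  u <- rgamma(nsim, 2.5, rate = 2.5)
  v <- abs(rnorm(nsim))
  skew <- v / sqrt(u) - cc_hn * mixing_moment(1, 5)
  b <- skew * 0.8 + rnorm(nsim, 0, sqrt(0.5)) / sqrt(u)
  z <- (1 * 0 + 0.3 * 1) + 0.5 * b + skew * ups * -1 +
    ups * rnorm(nsim) / sqrt(u)
  y <- z > 0
  thp <- th; thp$beta <- c(0, 1)
  p <- success_prob(thp, c(0, 0.3), 0.5)
  expect_lt(abs(p - mean(y)), 4 * mc_se(y))
})

test_that("identifiability checks recognize the problematic designs", {
  mk <- function(X, W) sgtlm_panel(rep(0:1, 10), X, W, rep(1:10, each = 2))
  set.seed(2)
  # binary-only fixed design: link skewness not identified
  chk <- check_identifiability(mk(cbind(1, rep(0:1, 10)),
                                  cbind(rnorm(20))))
  expect_true(chk$fix_delta_eps)
  expect_false(chk$fix_delta0)
  # random intercept present: intercept skewness restricted
  chk <- check_identifiability(mk(cbind(1, rnorm(20)),
                                  cbind(1, rnorm(20))))
  expect_false(chk$fix_delta_eps)
  expect_true(chk$fix_delta0)
  # continuous fixed covariate, slope-only random design: no restriction
  chk <- check_identifiability(mk(cbind(1, rnorm(20)), cbind(rnorm(20))))
  expect_false(chk$fix_delta_eps)
  expect_false(chk$fix_delta0)
  # rank-deficient fixed design is an error
  expect_error(check_identifiability(mk(cbind(rep(1, 20), rep(1, 20)),
                                        cbind(rnorm(20)))),
               "rank deficient")
})
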