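#' Simulation design for the performance experiment
#'
#' Describes one data-generating mechanism of the simulation experiment:
#' clusters of `n_per_cluster` binary outcomes with linear predictor
#' \eqn{\eta_{ij} = \beta_0 + \beta_1 X_{1i} + b_{0i} + b_{1i} W_{1ij}},
#' a cluster-level Bernoulli(0.5) covariate \eqn{X_1}, an
#' occasion-varying standard normal covariate \eqn{W_1}, and bivariate
#' random effects with scale matrix `d_bar`.  The `"probit"` mechanism
#' has a degenerate mixing variable and no skewness; the `"sgt"`
#' mechanism uses link skewness `delta_eps = -2`, random-slope skewness
#' `delta1 = 2` and `nu = 5` (so the latent scale constant is
#' \eqn{\upsilon_0 = 0.4598} and the marginal random-effects covariance
#' has entries 0.83, 0.42, 4.73).  One covariate set is drawn per
#' (mechanism, sample size) and reused across replicates.
#'
#' @param mechanism `"probit"` or `"sgt"`.
#' @param n_clusters number of clusters n.
#' @param n_per_cluster observations per cluster.
#' @param beta true fixed effects \eqn{(\beta_0, \beta_1)}.
#' @param d_bar true random-effects scale matrix.
#' @param delta_eps,delta1 true skewness parameters (forced to zero under
#'   the probit mechanism).
#' @param nu true degrees of freedom of the gamma mixing (sgt mechanism).
#' @param n_reps number of Monte Carlo replicates.
#' @param seed master seed: covariates use `seed + n_clusters`, replicate
#'   r draws with `seed + r`.
#' @return a list of class `sim_design`.
#' @export
sim_design <- function(mechanism = c("sgt", "probit"), n_clusters = 100,
                       n_per_cluster = 6, beta = c(-1, 1),
                       d_bar = matrix(c(0.5, 0.25, 0.25, 1), 2),
                       delta_eps = if (mechanism == "sgt") -2 else 0,
                       delta1 = if (mechanism == "sgt") 2 else 0,
                       nu = 5, n_reps = 25, seed = 1) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "probit" && (delta_eps != 0 || delta1 != 0))
    stop("the probit mechanism has no skewness parameters")
  structure(list(mechanism = mechanism, n_clusters = n_clusters,
                 n_per_cluster = n_per_cluster, beta = beta, d_bar = d_bar,
                 delta_eps = delta_eps, delta1 = delta1, nu = nu,
                 n_reps = n_reps, seed = seed),
            class = "sim_design")
}

# latent-representation sampler shared by the simulation engine and the
# fixture generator: per cluster draw (U, V, b), then the latent outcomes.
.simulate_latent <- function(beta, delta_eps, delta, d_bar, nu, mixing,
                             X, W, index, ups) {
  cc <- .half_normal_mean
  u1c <- if (mixing == "normal") 1 else mixing_moment(1, nu)
  q <- ncol(W)
  n <- length(index)
  Lb <- chol(d_bar)
  b <- matrix(0, n, q)
  y <- numeric(nrow(X))
  for (i in seq_len(n)) {
    ix <- index[[i]]
    ni <- length(ix)
    u <- if (mixing == "normal") 1 else rgamma(1, nu / 2, rate = nu / 2)
    v <- abs(rnorm(1))
    skew <- v / sqrt(u) - cc * u1c
    b[i, ] <- skew * delta + as.numeric(crossprod(Lb, rnorm(q))) / sqrt(u)
    eta <- as.numeric(X[ix, , drop = FALSE] %*% beta) +
      as.numeric(W[ix, , drop = FALSE] %*% b[i, ])
    z <- eta + skew * ups * delta_eps + ups * rnorm(ni) / sqrt(u)
    y[ix] <- as.numeric(z > 0)
  }
  list(y = y, b = b)
}

#' Simulate one replicate panel from a simulation design
#'
#' Covariates are regenerated deterministically from the design (shared
#' across replicates); the latent draws use the replicate seed
#' `seed + rep`.  The true random effects are attached for scoring the
#' empirical Bayes predictions.
#'
#' @param design a [sim_design()].
#' @param rep replicate index (1-based).
#' @return an [sgtlm_panel()] with attribute `"ranef"` (true random
#'   effects, one row per cluster).
#' @export
simulate_panel <- function(design, rep = 1) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_clusters
  ni <- design$n_per_cluster
  id <- base::rep(seq_len(n), each = ni)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed + n)
  x1 <- base::rep(rbinom(n, 1, 0.5), each = ni)
  w1 <- rnorm(n * ni)
  X <- cbind(`(Intercept)` = 1, x1 = x1)
  W <- cbind(`(Intercept)` = 1, w1 = w1)
  index <- split(seq_along(id), id)
  mixing <- if (design$mechanism == "sgt") "t" else "normal"
  ups <- upsilon0(design$delta_eps, design$nu, mixing)
  set.seed(design$seed + rep)
  sim <- .simulate_latent(design$beta, design$delta_eps,
                          c(0, design$delta1), design$d_bar, design$nu,
                          mixing, X, W, index, ups)
  panel <- sgtlm_panel(sim$y, X, W, id)
  attr(panel, "ranef") <- sim$b
  panel
}

#' Monte Carlo performance measures
#'
#' Implements the standard replicate-level performance measures of a
#' simulation study: mean estimate, percent relative bias
#' \eqn{100(\bar{\hat\theta} - \theta)/|\theta|}, root mean squared error,
#' sampling standard deviation (divisor R - 1), quadratic mean of the
#' reported standard errors, confidence-interval coverage probability,
#' mean squared Pearson correlation between simulated and predicted
#' random effects, and mean information criteria.
#'
#' @param estimates R x P matrix of estimates (one row per replicate),
#'   with column names.
#' @param truth named vector of true values covering the columns of
#'   `estimates`.
#' @param se optional R x P matrix of standard errors.
#' @param ci_lower,ci_upper optional R x P matrices of confidence bounds.
#' @param eb_pairs optional list (one element per replicate) of lists
#'   with matrices `true` and `est` of random effects.
#' @param ic optional R x 3 matrix of AIC/BIC/HQ values.
#' @return a list of class `sgtlm_perf` with elements `parameters` (data
#'   frame), `r2` and `ic`.
#' @export
performance_summary <- function(estimates, truth, se = NULL,
                                ci_lower = NULL, ci_upper = NULL,
                                eb_pairs = NULL, ic = NULL) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2L) stop("at least two replicates are required")
  pn <- colnames(estimates)
  truth <- truth[pn]
  mean_est <- colMeans(estimates)
  bias <- ifelse(truth != 0, 100 * (mean_est - truth) / abs(truth),
                 NA_real_)
  rmse <- sqrt(colMeans((estimates -
                           matrix(truth, nrow(estimates), ncol(estimates),
                                  byrow = TRUE))^2))
  sds <- apply(estimates, 2, sd)
  par <- data.frame(parameter = pn, truth = as.numeric(truth),
                    mean = mean_est, pct_bias = bias, rmse = rmse,
                    sd = sds, row.names = NULL)
  if (!is.null(se)) par$se_bar <- sqrt(colMeans(as.matrix(se)^2))[pn]
  if (!is.null(ci_lower)) {
    cov <- colMeans(ci_lower <= matrix(truth, nrow(estimates),
                                       ncol(estimates), byrow = TRUE) &
                      matrix(truth, nrow(estimates), ncol(estimates),
                             byrow = TRUE) <= ci_upper)
    par$cp <- cov[pn]
  }
  r2 <- NULL
  if (!is.null(eb_pairs) && length(eb_pairs)) {
    q <- ncol(eb_pairs[[1]]$true)
    r2m <- vapply(eb_pairs, function(pp)
      vapply(seq_len(q), function(j)
        cor(pp$true[, j], pp$est[, j])^2, numeric(1)), numeric(q))
    r2 <- rowMeans(matrix(r2m, nrow = q))
    names(r2) <- colnames(eb_pairs[[1]]$true)
  }
  icm <- if (!is.null(ic)) colMeans(as.matrix(ic)) else NULL
  structure(list(parameters = par, r2 = r2, ic = icm),
            class = "sgtlm_perf")
}

#' @export
print.sgtlm_perf <- function(x, ...) {
  print(x$parameters, digits = 4, row.names = FALSE)
  if (!is.null(x$r2)) {
    cat("mean R^2(b, b_hat):\n"); print(round(x$r2, 3))
  }
  if (!is.null(x$ic)) {
    cat("mean information criteria:\n"); print(round(x$ic, 2))
  }
  invisible(x)
}

# fitting configurations of the four competing models
.study_fitters <- list(
  PM = list(link = "probit", restrictions = NULL),
  SPM = list(link = "skew-probit",
             restrictions = list(fix_delta_eps = FALSE,
                                 fix_delta = "first")),
  GTLM = list(link = "gt", restrictions = NULL),
  SGTLM = list(link = "sgt",
               restrictions = list(fix_delta_eps = FALSE,
                                   fix_delta = "first")))

#' Run the simulation performance experiment
#'
#' Generates `design$n_reps` replicate panels and fits each with the
#' requested models: the probit (PM), skew-probit (SPM), generalized
#' t-link (GTLM) and skew generalized t-link (SGTLM) mixed models, with
#' the t-link degrees of freedom held at the design's `nu`.  Skewness is
#' initialized at zero and the random-effects scale at the identity;
#' skewed fits carry the random-intercept restriction
#' (\eqn{\delta_0 = 0}), with the link skewness left free as in the
#' experiment this engine reproduces.  Per-fit failures are recorded and
#' excluded from the summaries.
#'
#' @param design a [sim_design()].
#' @param fitters subset of `c("PM", "SPM", "GTLM", "SGTLM")`.
#' @param control an [sgtlm_control()].
#' @param progress print a line per replicate.
#' @return a list of class `sgtlm_study`: per fitter, a
#'   [performance_summary()] plus raw replicate results and the failure
#'   count.
#' @export
run_study <- function(design, fitters = c("PM", "SPM", "GTLM", "SGTLM"),
                      control = sgtlm_control(), progress = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  fitters <- match.arg(fitters, names(.study_fitters), several.ok = TRUE)
  if (design$n_reps < 1L) stop("design has zero replicates")
  truth <- c(beta0 = design$beta[1], beta1 = design$beta[2],
             .sigma_truth(design), delta_eps = design$delta_eps,
             delta1 = design$delta1)
  raw <- lapply(fitters, function(f) list())
  names(raw) <- fitters
  fails <- setNames(integer(length(fitters)), fitters)
  for (r in seq_len(design$n_reps)) {
    panel <- simulate_panel(design, r)
    btrue <- attr(panel, "ranef")
    for (f in fitters) {
      cfg <- .study_fitters[[f]]
      fit <- tryCatch(
        sgtlm_fit(panel, link = cfg$link,
                  nu = if (cfg$link %in% c("gt", "sgt")) design$nu,
                  restrictions = cfg$restrictions, control = control),
        error = function(e) e)
      if (inherits(fit, "error")) {
        fails[f] <- fails[f] + 1L
        next
      }
      raw[[f]][[length(raw[[f]]) + 1L]] <- .study_record(fit, btrue)
    }
    if (progress)
      message("replicate ", r, "/", design$n_reps, " done")
  }
  out <- lapply(fitters, function(f) {
    recs <- raw[[f]]
    if (length(recs) < 2L)
      return(list(performance = NULL, n_fits = length(recs),
                  failures = fails[f], raw = recs))
    est <- do.call(rbind, lapply(recs, `[[`, "est"))
    se <- do.call(rbind, lapply(recs, `[[`, "se"))
    lo <- est - 1.96 * se
    hi <- est + 1.96 * se
    eb <- lapply(recs, `[[`, "eb")
    ic <- do.call(rbind, lapply(recs, `[[`, "ic"))
    list(performance = performance_summary(est, truth, se, lo, hi, eb, ic),
         n_fits = length(recs), failures = fails[f], raw = recs)
  })
  names(out) <- fitters
  structure(list(design = design, fitters = out), class = "sgtlm_study")
}

.sigma_truth <- function(design) {
  mixing <- if (design$mechanism == "sgt") "t" else "normal"
  S <- ranef_covariance(design$d_bar, c(0, design$delta1), design$nu,
                        mixing)
  c(sigma11 = S[1, 1], sigma12 = S[2, 1], sigma22 = S[2, 2])
}

# one replicate's record: estimates aligned to the truth layout, standard
# errors for the Wald parameters, EB pairs and information criteria
.study_record <- function(fit, btrue) {
  th <- fit$theta
  S <- ranef_covariance(th$d_bar, th$delta, th$nu, th$mixing)
  est <- c(beta0 = unname(th$beta[1]), beta1 = unname(th$beta[2]),
           sigma11 = S[1, 1], sigma12 = S[2, 1], sigma22 = S[2, 2],
           delta_eps = th$delta_eps, delta1 = unname(th$delta[2]))
  se <- setNames(rep(NA_real_, length(est)), names(est))
  cf <- fit$se
  se["beta0"] <- cf[1]; se["beta1"] <- cf[2]
  if ("delta_eps" %in% names(cf)) se["delta_eps"] <- cf["delta_eps"]
  dn <- grep("^delta\\.", names(cf), value = TRUE)
  if (length(dn)) se["delta1"] <- cf[dn[1]]
  vc <- fit$varcomp
  se["sigma11"] <- vc$se[vc$entry == "sigma.1.1"]
  se["sigma12"] <- vc$se[vc$entry == "sigma.2.1"]
  se["sigma22"] <- vc$se[vc$entry == "sigma.2.2"]
  list(est = est, se = se,
       eb = list(true = btrue, est = fit$eb$b_hat),
       ic = fit$ic)
}

#' @export
print.sgtlm_study <- function(x, ...) {
  d <- x$design
  cat("Simulation study:", d$mechanism, "mechanism, n =", d$n_clusters,
      "clusters x", d$n_per_cluster, "obs,", d$n_reps, "replicates\n")
  for (f in names(x$fitters)) {
    cat("\n--", f, "(", x$fitters[[f]]$n_fits, "fits,",
        x$fitters[[f]]$failures, "failures )\n")
    if (!is.null(x$fitters[[f]]$performance))
      print(x$fitters[[f]]$performance)
  }
  invisible(x)
}

#' Generate synthetic fixture datasets
#'
#' `"simdesign"` draws one replicate of the skew generalized t simulation
#' mechanism as a long data frame.  `"respiratory_like"` emulates the
#' covariate structure of a respiratory illness panel study (111 patients
#' with four visits: binary center, baseline state, sex, treatment, a
#' sex-by-treatment interaction, and median-centered age as the random
#' slope covariate); the outcomes are generated from the model with a
#' user-adjustable parameter set, so the data are synthetic stand-ins,
#' not the real trial records.  Binary fixed covariates make the link
#' skewness unidentified, so fits to this fixture should carry
#' `delta_eps = 0` (as [check_identifiability()] reports).
#'
#' @param kind `"simdesign"` or `"respiratory_like"`.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param n_clusters number of clusters for `"simdesign"`.
#' @param theta optional [sgtlm_theta()] for `"respiratory_like"`.
#' @param path optional path: when given the data frame is also written
#'   as CSV.
#' @return a long-format data frame.
#' @export
make_fixture <- function(kind = c("simdesign", "respiratory_like"),
                         seed = 1, n_clusters = 100, theta = NULL,
                         path = NULL) {
  kind <- match.arg(kind)
  if (kind == "simdesign") {
    design <- sim_design("sgt", n_clusters = n_clusters, seed = seed)
    panel <- simulate_panel(design, rep = 1)
    df <- data.frame(id = panel$id, y = panel$y, x1 = panel$X[, "x1"],
                     w1 = panel$W[, "w1"])
  } else {
    n <- 111L; visits <- 4L
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    center <- rbinom(n, 1, 0.5)
    baseline <- rbinom(n, 1, 0.55)
    sex <- rbinom(n, 1, 0.79)
    treat <- rbinom(n, 1, 0.5)
    age <- round(runif(n, 15, 65))
    age_c <- age - median(age)
    id <- base::rep(seq_len(n), each = visits)
    X <- cbind(`(Intercept)` = 1, center = center[id],
               baseline = baseline[id], sex = sex[id], treat = treat[id],
               sex_treat = (sex * treat)[id])
    W <- cbind(age_c = age_c[id])
    if (is.null(theta)) {
      nu <- 3.7
      u2 <- mixing_moment(2, nu)
      u1 <- mixing_moment(1, nu)
      kap <- u2 - .half_normal_mean^2 * u1^2
      dlt <- 0.026
      dbar <- max((0.0118 - kap * dlt^2) / u2, 1e-4)
      theta <- sgtlm_theta(c(0.54, 0.60, 1.52, -1.01, -2.04, 1.34),
                           delta_eps = 0, delta = dlt,
                           d_bar = matrix(dbar), nu = nu, mixing = "t",
                           fix_delta_eps = TRUE)
    }
    index <- split(seq_along(id), id)
    ups <- upsilon0(theta$delta_eps, theta$nu, theta$mixing)
    sim <- .simulate_latent(theta$beta, theta$delta_eps, theta$delta,
                            theta$d_bar, theta$nu, theta$mixing,
                            X, W, index, ups)
    df <- data.frame(id = id, y = sim$y, center = center[id],
                     baseline = baseline[id], sex = sex[id],
                     treat = treat[id], sex_treat = (sex * treat)[id],
                     age_c = age_c[id])
  }
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
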