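---
title: "Skew generalized t-link mixed models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skew generalized t-link mixed models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`sgtlm` fits generalized linear mixed models for clustered binary
outcomes in which **both** the link function and the random-effects
distribution may be skewed and heavy tailed.  For cluster $i$ with
$n_i$ binary observations $Y_{ij}$, fixed design $X_i$ and random
design $W_i$, the latent-variable form of the model is

$$
Y_{ij} = I(Z_{ij} > 0), \qquad
Z_i = X_i\beta + W_i b_i + \left(\tfrac{V_i}{\sqrt{U_i}} - c\tilde U_1\right)
      \upsilon_0\,\delta_\epsilon\,\mathbf 1_{n_i}
      + \frac{\upsilon_0}{\sqrt{U_i}}\,\varepsilon_i ,
$$

$$
b_i = \left(\tfrac{V_i}{\sqrt{U_i}} - c\tilde U_1\right)\delta
      + U_i^{-1/2}\,\bar D^{1/2} \eta_i ,
$$

with $\varepsilon_i \sim N(0, I_{n_i})$, $\eta_i \sim N(0, I_q)$,
$V_i \sim HN(0,1)$ a standard half-normal variable,
$U_i \sim \mathrm{Gamma}(\nu/2, \nu/2)$ the scale-mixing weight, and
$c = \sqrt{2/\pi}$ the half-normal mean.  The crucial structural point
is that $U_i$ and $V_i$ are **shared** by the random effects and by
every latent outcome of the cluster: the whole cluster is one draw from
a multivariate skew-t law, which is what makes an exact EM algorithm
possible.  Marginally over $(U_i, V_i, b_i)$ the latent vector is
skew-t with location $\mu_i = X_i\beta - c\tilde U_1\Delta_i$, scale
$\Omega_i = \bar\Omega_i + \Delta_i\Delta_i^\top$,
$\bar\Omega_i = \upsilon_0^2 I + W_i\bar D W_i^\top$ and working shape
$\Delta_i = \upsilon_0\delta_\epsilon\mathbf 1 + W_i\delta$.

The parameters are $\theta = (\beta, \delta_\epsilon, \delta,
\mathrm{vech}\,\bar D)$ with the degrees of freedom $\nu$ held fixed
during one fit (grid-selected across fits).  Setting
$\delta_\epsilon = \delta = 0$ gives the symmetric t-link model;
letting $\nu \to \infty$ (the `"normal"` mixing) gives the skew-probit
model, and both together give the ordinary probit GLMM.  All four are
available through the `link` argument (`"sgt"`, `"gt"`,
`"skew-probit"`, `"probit"`).

**The scaling constant $\upsilon_0$.**  The mixing and skewing
variables inflate the conditional variance of $Z_{ij}$ given $b_i$ by
$\tilde U_2 + (\tilde U_2 - c^2\tilde U_1^2)\delta_\epsilon^2$, where
$\tilde U_t = E\{U^{-t/2}\} = (\nu/2)^{t/2}
\Gamma((\nu-t)/2)/\Gamma(\nu/2)$.  Choosing
$\upsilon_0 = [\tilde U_2 + (\tilde U_2 - c^2\tilde U_1^2)
\delta_\epsilon^2]^{-1/2}$ restores a unit conditional latent variance,
so the fixed effects keep their probit-scale interpretation.  At
$\delta_\epsilon = -2$, $\nu = 5$ this gives $\upsilon_0 = 0.4598$.
Internally the EM algorithm runs at $\upsilon_0 = 1$ and the estimates
are rescaled once at convergence
($\beta \leftarrow \upsilon_0\beta$, $\delta \leftarrow \upsilon_0
\delta$, $\bar D \leftarrow \upsilon_0^2\bar D$); the rescaling is a
pure reparameterization and leaves the marginal likelihood unchanged
(this invariance is asserted by the test suite).

A note on the constant $c$: it is the mean of a standard half-normal
variable, $\sqrt{2/\pi}$.  With this value the package reproduces the
internal consistency checks $\upsilon_0(-2, 5) = 0.4598$ and the
simulation-design random-effects covariance entries
$0.83$, $0.42$, $4.73$ from
$\Sigma_b = \tilde U_2\bar D + (\tilde U_2 - c^2\tilde U_1^2)
\delta\delta^\top$.

# Truncated moments: two routes

Conditional on the observed pattern $y_i$, the latent vector follows a
truncated skew-t law on the orthant $A_i = \prod_j A_{ij}$ with
$A_{ij} = (-\infty, 0]$ if $y_{ij} = 0$ and $(0, \infty)$ otherwise.
The E-step needs joint conditional moments of $(U_i, V_i, Z_i)$ on this
region.  The package computes them by two independent routes.

**The selection (augmentation) route.**  A skew-t vector with working
shape $\delta$ satisfies
$(W_0, Z - \mu) \stackrel d= U^{-1/2} N(0, S)$ conditioned on
$W_0 \le 0$, with
$S = \begin{pmatrix} 1 & -\delta^\top \\ -\delta & \Omega
\end{pmatrix}$ and $V = -\sqrt U\,W_0$ recovering the hidden
half-normal variable.  Truncating $Z$ to a box therefore embeds every
joint moment in a $(p{+}1)$-dimensional truncated multivariate t
problem.  The cdf-recursion route (`tst_moments()`, `tsgt_moments()`,
`sgt_joint_moments()`) evaluates these by closed-form boundary-integral
identities: for $X \sim t_p(0, \Sigma, \nu)$ truncated at $a$,

$$
\alpha\,E\{X\} = -\Sigma q, \qquad
\alpha\,E\{XX^\top\} = \tfrac{\nu}{\nu-2}
  T_p\!\big(a;\tfrac{\nu}{\nu-2}\Sigma, \nu-2\big)\,\Sigma - \Sigma B,
$$

where $q_k$ couples the marginal edge density (a rescaled t density at
$\nu - 2$ degrees of freedom) with a $(p{-}1)$-dimensional t cdf at
$\nu - 1$ degrees of freedom, and row $k$ of $B$ needs the
$(p{-}1)$-dimensional truncated-t partial means at $\nu - 1$ degrees of
freedom (one level of recursion).  These identities come from averaging
the multivariate-normal boundary integrals over the tilted gamma mixing
law; in this arrangement first moments exist for $\nu > 1$ and second
moments for $\nu > 2$, so the E-step (which evaluates them at shifted
degrees $\nu + 1$ and $\nu + 2$) is valid on the whole fitting grid
$\nu > 2$.  The gamma-mixed bundle
$\bar u_r = E\{U^{r/2}\},\ \overline{u_r z},\ \overline{u_r z^2},\
\bar\tau_r,\ \bar\tau_r z$ (with
$\zeta_1(x) = \phi(x)/\Phi(x)$ weights for the half-normal channel)
follows by the order-shift construction: the $U^{r/2}$-weighted law is
again truncated skew-t at $\nu + r$ degrees of freedom with a shrunken
scale, normalized by the constant
$C_r(\nu) = (2/\nu)^{r/2}\Gamma((\nu+r)/2)/\Gamma(\nu/2)$ and cdf
ratios.

**The single-pass QMC route.**  For fitting speed the package also
ships a deterministic quasi-Monte Carlo engine (C++): per cluster it
factors the augmented scale matrix, walks a fixed Kronecker lattice
through the sequential conditional probabilities (separation of
variables), reconstructs $(U, V, Z)$ per lattice point and accumulates
all EM moments in one pass.  The lattice is fixed, so repeated calls
are identical and the approximated log-likelihood surface is smooth in
$\theta$; the lattice size is the accuracy knob
(`npts_estep`, default 512 during EM sweeps, `npts_final`, default
8192, for the reported log-likelihood, standard errors and empirical
Bayes quantities).  At 512 points the relative moment error is around
$10^{-4}$–$10^{-3}$; at $2^{16}$ points around $10^{-6}$–$10^{-7}$.

The two routes are validated against each other and against
rejection-sampling oracles in the test suite.  The analytic route is
the reference (`estep_method = "analytic"`); the QMC route is the
default fitter.

**Multivariate t cdfs.**  Degrees of freedom are generally
non-integer, which rules out the randomized t cdf of `mvtnorm`
(integer-df only); the package therefore evaluates t cdfs with the same
deterministic lattice rule (dimension $\ge 3$) and a composite
Gauss-Legendre bivariate t cdf (absolute error around $10^{-9}$).
Multivariate *normal* cdfs defer to `mvtnorm::pmvnorm` under a fixed
quadrature seed; `mvtnorm::pmvt` remains an independent cross-check at
integer degrees of freedom in the tests.

# Estimation

The fitter follows a six-step scheme per sweep: E-step, M-step,
convergence tests, with a parameter-expanded (PX) opening phase.  The
M-step is exact: the link skewness and fixed effects solve one
symmetric linear system (the skewness enters the fixed-effects normal
equations), and $(\delta, \bar D)$ are updated by exact profile
maximization of the expected complete-data log-likelihood, honouring
any identifiability restrictions (frozen coordinates are solved out of
the restricted quadratic program, not just zeroed).  The PX phase
expands the complete-data model with a working $q \times q$ scale
matrix $\alpha$ in the linear predictor; the joint update of
$(\beta_\star, \mathrm{vec}\,\alpha, \delta_{\epsilon\star})$ is again
one symmetric linear system and the reduction
$\delta = \alpha\delta_\star$,
$\bar D = \alpha\bar D_\star\alpha^\top$ recovers the original
parameter.  PX hands over to plain EM once the dominant eigenvalue of
$\hat\alpha - I_q$ falls below $10^{-2}$; plain EM stops when the
relative log-likelihood change falls below $10^{-6}$.

Numerical choices: $\bar D$ updates are symmetrized and floored at
eigenvalue $10^{-8}$; cluster pattern probabilities are floored at
$10^{-300}$ before taking logs; a degenerate conditional region (mass
below $10^{-12}$) raises an error naming the cluster.  Starting values
are $\beta = 0$, $\delta_\epsilon = 0$, $\delta = 0$, $\bar D = I$.
The default iteration cap is 1000: under the simulation conditions
below the EM ascent rate is about $0.992$ per sweep, so reaching the
$10^{-6}$ relative tolerance typically takes 500–800 sweeps — the
slow, stable convergence that motivates the PX acceleration in the
first place.  Profiling $\nu$ inside the EM loop is deliberately not
implemented: the profiled likelihood can be unbounded as
$\nu \downarrow 2$ (the symmetric t link on heavy-tailed data shows
exactly this), so $\nu$ is selected on a grid (`select_nu()`), with
warm starts along the grid and an explicit flag when the maximum sits
at the lower edge.  The grid default mirrors common practice for this
model family: $2.5, 2.6, \dots, 15$.

**Identifiability.**  Two designs leave skewness parameters
unidentified: (i) a fixed design containing only intercept and binary
columns cannot identify the link skewness $\delta_\epsilon$ given the
random effects; (ii) a random-intercept column confounds
$\delta_\epsilon$ with the intercept skewness $\delta_0$ (only their
sum enters the marginal law).  `check_identifiability()` detects both;
the default remedy for (ii) fixes $\delta_0 = 0$, which keeps the
marginal link skewness free and recovers a pure fixed-effects skew
model when no random effects are present.  Equivalent restrictions
($\delta_\epsilon = 0$, or $\delta_\epsilon = \delta_0$) can be
imposed by the user instead via the `restrictions` argument.  The
simulation engine deliberately leaves $\delta_\epsilon$ free although
its fixed design contains a binary covariate, matching the experiment
it reproduces.

**Inference.**  Standard errors come from the empirical observed
information $I_o = \sum_i \hat g_i\hat g_i^\top$, where $\hat g_i$ is
the per-cluster gradient of the expected complete-data log-likelihood
at the estimate (the tests verify these scores against numerical
differentiation of the marginal log-likelihood via the Fisher
identity).  The covariance is transported to the reported scale with
the full Jacobian of the rescaling map, including the
$\partial\upsilon_0/\partial\delta_\epsilon$ chain term.  Marginal
random-effects variances get delta-method standard errors.  The
parameter count for AIC/BIC/HQ excludes $\nu$ (treated as known or
grid-selected), matching the reported-likelihood convention; a
`count_nu` switch in the internal counter provides the alternative.
Empirical Bayes predictions use the conditional means
$\bar b_i = r_i(\bar z_i - X_i\beta) + (\overline{vu^{-1}}_i -
c\tilde U_1)s_i$ and the weights $\hat u_i = E\{U_i \mid y_i\}$;
weights below 1 flag clusters that the heavy-tailed link downweights.

# The simulation engine

`sim_design()` encodes the performance experiment: clusters of six
binary outcomes, a cluster-level Bernoulli(0.5) fixed covariate, an
occasion-varying standard normal random-slope covariate, true fixed
effects $(\beta_0, \beta_1) = (-1, 1)$, random-effects scale
$\bar D = [[0.5, 0.25], [0.25, 1]]$ and, under the `"sgt"` mechanism,
$\delta_\epsilon = -2$, $\delta_1 = 2$, $\nu = 5$ (the table-style
truth convention for the signs of $\beta$ is used; the marginal
random-effects covariance is then $0.83/0.42/4.73$).  Covariates are
drawn once per sample size and shared across replicates; replicate
$r$ uses seed `seed + r`.  `run_study()` fits the four competing
models (probit, skew-probit, symmetric generalized-t, skew generalized
t, the latter two with $\nu$ fixed at the design value) and
`performance_summary()` computes percent bias, RMSE, sampling SD, mean
reported SE, 95% interval coverage, the mean squared correlation
between simulated and predicted random effects, and mean information
criteria.

What the generator does and does not emulate: it draws from the exact
stated hierarchical model, including the cluster-shared mixing and
skewing variables.  A consequence worth knowing is that the shared
link-skewness channel makes the latent outcomes of a cluster strongly
positively correlated *conditional on the random effects*
($\rho_0 = 0.648$ at $\delta_\epsilon = -2$, $\nu = 5$); a probit fit
to such data absorbs this exchangeable correlation into its
random-effects covariance, inflating it severalfold (our exact-likelihood
probit fit and an independent Laplace fit agree on this).  Real
clustered binary data need not carry this structure, so passing
simulation checks here demonstrates correctness of the machinery under
this model, not robustness claims about arbitrary data.  The default
replication (25) is a scaled-down study size chosen so a full
performance run completes in minutes; the engine accepts any
replication count.

The problem sizes used by the package's own checks are deliberately
modest — panels of 100 clusters, 25 Monte Carlo replicates, EM lattices
of 256–512 points — and every such choice is a documented control
parameter, not a hidden constant.

# Known limitations

* Fitting requires $\nu > 2$; the moment identities used by the E-step
  do not extend to $1 < \nu \le 2$.
* Cluster sizes are capped by the cdf-accuracy envelope of the lattice
  rule (dimension 14 including the augmentation and mixing
  coordinates); larger clusters need a faster, more accurate
  multivariate skew-t cdf.
* The skewness directions converge slowly (EM ascent rate near 1), so
  fits on large panels take hundreds of sweeps; PX acceleration helps
  early, not near the optimum.
* Only half-line box truncations arise in the binary model, and only
  those are implemented.
* The respiratory-illness application data are not redistributed with
  the package; `make_fixture("respiratory_like")` generates a clearly
  synthetic stand-in with the same covariate structure for examples
  and tests.
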