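// Deterministic quasi-Monte Carlo engine for truncated skew-t integrals.
//
// A p-variate skew-t vector Z ~ ST(mu, Omega, lambda, nu) with working shape
// delta and Omega = Omega_bar + delta delta^T admits the selection form
//   (W0, Z - mu) = U^{-1/2} * N(0, S),   S = [[1, -delta^T], [-delta, Omega]],
// conditioned on W0 <= 0, with U ~ Gamma(nu/2, nu/2) and V = -U^{1/2} W0 the
// hidden half-normal.  Truncating Z to a box region therefore reduces every
// joint moment E{U^{r/2} V^s g(Z) | Z in region} to an integral over a
// (p+1)-dimensional truncated normal scale mixture, which is evaluated here
// by separation-of-variables (sequential conditioning) along the Cholesky
// factor, averaged over a fixed Kronecker (Richtmyer) lattice.  The lattice
// is deterministic, so repeated calls give identical results and the
// approximated log-likelihood surface is smooth in the parameters.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <map>
#include <vector>

using namespace Rcpp;

static const int kPrimes[32] = {2,   3,   5,   7,   11,  13,  17,  19,
                                23,  29,  31,  37,  41,  43,  47,  53,
                                59,  61,  67,  71,  73,  79,  83,  89,
                                97,  101, 103, 107, 109, 113, 127, 131};

static inline double frac_part(double x) { return x - std::floor(x); }

struct LatticeConsts {
  double alpha[16], shift[16];
  LatticeConsts() {
    for (int j = 0; j < 16; ++j) {
      alpha[j] = frac_part(std::sqrt((double)kPrimes[j]));
      shift[j] = frac_part(std::sqrt((double)kPrimes[j + 16]));
    }
  }
};
static const LatticeConsts kLat;

// reflected Kronecker coordinate j of point i (both 0-based)
static inline double qmc_coord(int i, int j) {
  return std::fabs(
      2.0 * frac_part((i + 1.0) * kLat.alpha[j] + kLat.shift[j]) - 1.0);
}

// standard normal cdf via erfc (fast path of the inner loop)
static inline double fast_pnorm(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// standard normal quantile, rational approximation (Acklam-type);
// absolute accuracy about 1e-9, well below the lattice-rule error.
static double fast_qnorm(double p) {
  static const double a[6] = {-3.969683028665376e+01, 2.209460984245205e+02,
                              -2.759285104469687e+02, 1.383577518672690e+02,
                              -3.066479806614716e+01, 2.506628277459239e+00};
  static const double b[5] = {-5.447609879822406e+01, 1.615858368580409e+02,
                              -1.556989798598866e+02, 6.680131188771972e+01,
                              -1.328068155288572e+01};
  static const double c[6] = {-7.784894002430293e-03, -3.223964580411365e-01,
                              -2.400758277161838e+00, -2.549732539343734e+00,
                              4.374664141464968e+00,  2.938163982698783e+00};
  static const double d[4] = {7.784695709041462e-03, 3.224671290700398e-01,
                              2.445134137142996e+00, 3.754408661907416e+00};
  const double plow = 0.02425, phigh = 1.0 - plow;
  double x;
  if (p < plow) {
    const double q = std::sqrt(-2.0 * std::log(p));
    x = (((((c[0] * q + c[1]) * q + c[2]) * q + c[3]) * q + c[4]) * q + c[5]) /
        ((((d[0] * q + d[1]) * q + d[2]) * q + d[3]) * q + 1.0);
  } else if (p > phigh) {
    const double q = std::sqrt(-2.0 * std::log(1.0 - p));
    x = -(((((c[0] * q + c[1]) * q + c[2]) * q + c[3]) * q + c[4]) * q + c[5]) /
        ((((d[0] * q + d[1]) * q + d[2]) * q + d[3]) * q + 1.0);
  } else {
    const double q = p - 0.5, r = q * q;
    x = (((((a[0] * r + a[1]) * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) *
        q /
        (((((b[0] * r + b[1]) * r + b[2]) * r + b[3]) * r + b[4]) * r + 1.0);
  }
  return x;
}

// sqrt of Gamma(nu/2, rate nu/2) quantiles along lattice coordinate 0,
// cached per (nu, npts): the gamma quantile function otherwise dominates
// the cost of small calls.
static std::map<std::pair<long long, int>, std::vector<double> > s_cache;

static const std::vector<double>& mixing_sqrt_u(double nu, int npts) {
  std::pair<long long, int> key(llround(nu * 1e6), npts);
  std::map<std::pair<long long, int>, std::vector<double> >::iterator it =
      s_cache.find(key);
  if (it != s_cache.end()) return it->second;
  std::vector<double> s((size_t)npts);
  for (int i = 0; i < npts; ++i) {
    double w0 = qmc_coord(i, 0);
    w0 = std::min(std::max(w0, 1e-15), 1.0 - 1e-15);
    double u = R::qgamma(w0, nu / 2.0, 2.0 / nu, 1, 0);
    s[(size_t)i] = std::sqrt(u);
  }
  if (s_cache.size() > 64) s_cache.clear();
  return s_cache.insert(std::make_pair(key, s)).first->second;
}

// Joint truncated moments of (U, V, Z) for Z ~ ST_m(mu, Omega_bar + dd^T,
// lambda(delta), nu) restricted to the box with per-coordinate half-lines
// (-Inf, a_k] when orient_k = +1 and (a_k, Inf) when orient_k = -1.
// t_mixing = false gives the skew-normal limit (U == 1).
// level: 1 = region probability only, 2 = EM bundle, 3 = + EB extras.
// [[Rcpp::export]]
List cpp_cluster_engine(const arma::vec& mu, const arma::mat& omega_bar,
                        const arma::vec& delta, const arma::vec& a,
                        const arma::ivec& orient, double nu, bool t_mixing,
                        int npts, int level) {
  const int m = (int)mu.n_elem;
  const int d = m + 1;
  const int joff = t_mixing ? 1 : 0;  // lattice coordinate 0 feeds the mixing
  if (d + joff > 16) stop("cluster dimension too large for the QMC engine");

  // orientation flip: work with Az <= Aa, A = diag(orient)
  arma::vec A = arma::conv_to<arma::vec>::from(orient);
  arma::vec mu_f = A % mu, d_f = A % delta, a_f = A % a;
  arma::mat ob_f = omega_bar;
  ob_f.each_col() %= A;
  ob_f.each_row() %= A.t();

  arma::mat S(d, d);
  S(0, 0) = 1.0;
  S.submat(1, 0, m, 0) = -d_f;
  S.submat(0, 1, 0, m) = -d_f.t();
  S.submat(1, 1, m, m) = ob_f + d_f * d_f.t();

  arma::mat L;
  if (!arma::chol(L, S, "lower"))
    stop("augmented scale matrix is not positive definite");

  arma::vec upper(d);  // limits for mu_aug + s^{-1} L e <= (0, a_f)
  upper(0) = 0.0;
  upper.subvec(1, m) = a_f - mu_f;

  const std::vector<double>* squ = NULL;
  if (t_mixing) squ = &mixing_sqrt_u(nu, npts);

  // hot loop works on flat local buffers (dimension cap 16)
  double Lf[256], up[16], muf[16], Af[16], e[16], z[16];
  for (int k = 0; k < d; ++k) {
    up[k] = upper(k);
    for (int j = 0; j <= k; ++j) Lf[k * 16 + j] = L(k, j);
  }
  for (int k = 0; k < m; ++k) { muf[k] = mu_f(k); Af[k] = A(k); }

  double S0 = 0.0, Su2 = 0.0, Svu = 0.0, Sv2 = 0.0, Su1 = 0.0, Svum1 = 0.0;
  double Su2z[16] = {0}, Svuz[16] = {0}, Su1z[16] = {0}, Sz[16] = {0};
  double Su2zz[256] = {0}, Szz[256] = {0};

  for (int i = 0; i < npts; ++i) {
    const double s = t_mixing ? (*squ)[(size_t)i] : 1.0;
    double w = 1.0;
    bool dead = false;
    for (int k = 0; k < d; ++k) {
      double lim = s * up[k];
      for (int j = 0; j < k; ++j) lim -= Lf[k * 16 + j] * e[j];
      lim /= Lf[k * 16 + k];
      double pk = fast_pnorm(lim);
      w *= pk;
      if (w < 1e-300) { dead = true; break; }
      if (level <= 1 && k == d - 1) break;  // weight complete, z not needed
      double q = qmc_coord(i, k + joff) * pk;
      q = std::min(std::max(q, 1e-16), 1.0 - 1e-16);
      e[k] = fast_qnorm(q);
    }
    if (dead) continue;
    S0 += w;
    if (level <= 1) continue;

    // rebuild z on the original (unflipped) scale; V = -e_0
    for (int k = 0; k < m; ++k) {
      double acc = 0.0;
      for (int j = 0; j <= k + 1; ++j) acc += Lf[(k + 1) * 16 + j] * e[j];
      z[k] = Af[k] * (muf[k] + acc / s);
    }
    const double u = s * s, V = -e[0];

    const double wu = w * u, wvs = w * V * s;
    Su2 += wu;
    Svu += wvs;
    Sv2 += w * V * V;
    for (int k = 0; k < m; ++k) {
      Su2z[k] += wu * z[k];
      Svuz[k] += wvs * z[k];
      const double wuz = wu * z[k];
      for (int l = 0; l <= k; ++l) Su2zz[k * 16 + l] += wuz * z[l];
    }
    if (level >= 3) {
      Su1 += w * s;
      Svum1 += w * V / s;
      for (int k = 0; k < m; ++k) {
        Su1z[k] += w * s * z[k];
        Sz[k] += w * z[k];
        for (int l = 0; l <= k; ++l) Szz[k * 16 + l] += w * z[k] * z[l];
      }
    }
  }

  List out;
  out["alpha"] = 2.0 * S0 / npts;  // region probability of the skew-t law
  if (level >= 2 && S0 > 0.0) {
    NumericVector u2z(m), vuz(m);
    NumericMatrix u2z2(m, m);
    for (int k = 0; k < m; ++k) {
      u2z[k] = Su2z[k] / S0;
      vuz[k] = Svuz[k] / S0;
      for (int l = 0; l <= k; ++l)
        u2z2(k, l) = u2z2(l, k) = Su2zz[k * 16 + l] / S0;
    }
    out["u2"] = Su2 / S0;
    out["u2z"] = u2z;
    out["u2z2"] = u2z2;
    out["vu"] = Svu / S0;
    out["vuz"] = vuz;
    out["v2"] = Sv2 / S0;
  }
  if (level >= 3 && S0 > 0.0) {
    NumericVector u1z(m), z1(m);
    NumericMatrix z2(m, m);
    for (int k = 0; k < m; ++k) {
      u1z[k] = Su1z[k] / S0;
      z1[k] = Sz[k] / S0;
      for (int l = 0; l <= k; ++l)
        z2(k, l) = z2(l, k) = Szz[k * 16 + l] / S0;
    }
    out["u1"] = Su1 / S0;
    out["u1z"] = u1z;
    out["z1"] = z1;
    out["z2"] = z2;
    out["vum1"] = Svum1 / S0;
  }
  return out;
}

// Central multivariate t cdf P(X <= upper), X ~ t_m(0, sigma, nu), by the
// same separation-of-variables Kronecker rule.  nu <= 0 requests the
// multivariate normal cdf.
// [[Rcpp::export]]
double cpp_mvt_cdf(const arma::vec& upper, const arma::mat& sigma, double nu,
                   int npts) {
  const int m = (int)upper.n_elem;
  const bool t_mixing = (nu > 0) && std::isfinite(nu);
  const int joff = t_mixing ? 1 : 0;
  if (m + joff > 16) stop("dimension too large for the QMC cdf");
  arma::mat L;
  if (!arma::chol(L, sigma, "lower")) stop("scale matrix not positive definite");
  const std::vector<double>* squ = NULL;
  if (t_mixing) squ = &mixing_sqrt_u(nu, npts);
  double Lf[256], up[16], e[16];
  for (int k = 0; k < m; ++k) {
    up[k] = upper(k);
    for (int j = 0; j <= k; ++j) Lf[k * 16 + j] = L(k, j);
  }
  double S0 = 0.0;
  for (int i = 0; i < npts; ++i) {
    const double s = t_mixing ? (*squ)[(size_t)i] : 1.0;
    double w = 1.0;
    for (int k = 0; k < m; ++k) {
      double lim = s * up[k];
      for (int j = 0; j < k; ++j) lim -= Lf[k * 16 + j] * e[j];
      lim /= Lf[k * 16 + k];
      double pk = fast_pnorm(lim);
      w *= pk;
      if (w < 1e-300) { w = 0.0; break; }
      if (k == m - 1) break;
      double q = qmc_coord(i, k + joff) * pk;
      q = std::min(std::max(q, 1e-16), 1.0 - 1e-16);
      e[k] = fast_qnorm(q);
    }
    S0 += w;
  }
  return S0 / npts;
}

// Standardized bivariate t cdf T_2(b1, b2; rho, nu) by adaptive-free
// composite Gauss-Legendre on the probability transform of the first
// coordinate: with u = T_nu(x),
//   T_2 = int_0^{T_nu(b1)} T_{nu+1}( (b2 - rho x(u)) * g(x(u)) ) du,
// g(x) = sqrt((nu+1) / ((1-rho^2)(nu+x^2))).  Deterministic, absolute
// error around 1e-12 for the degrees of freedom used here.
// [[Rcpp::export]]
double cpp_bvt_cdf(double b1, double b2, double rho, double nu) {
  if (!std::isfinite(b1) && b1 > 0) return R::pt(b2, nu, 1, 0);
  if (!std::isfinite(b2) && b2 > 0) return R::pt(b1, nu, 1, 0);
  if (!std::isfinite(b1) || !std::isfinite(b2)) return 0.0;
  if (rho > 0.999999) {
    return R::pt(std::min(b1, b2), nu, 1, 0);
  }
  if (rho < -0.999999) {
    double s = R::pt(b1, nu, 1, 0) + R::pt(b2, nu, 1, 0) - 1.0;
    return std::max(s, 0.0);
  }
  static const double gl_x[16] = {
      0.0483076656877383162, 0.1444719615827964934, 0.2392873622521370745,
      0.3318686022821276498, 0.4213512761306353454, 0.5068999089322293900,
      0.5877157572407623290, 0.6630442669302152009, 0.7321821187402896804,
      0.7944837959679424069, 0.8493676137325699701, 0.8963211557660521240,
      0.9349060759377396892, 0.9647622555875064307, 0.9856115115452683354,
      0.9972638618494815635};
  static const double gl_w[16] = {
      0.0965400885147278006, 0.0956387200792748594, 0.0938443990808045654,
      0.0911738786957638847, 0.0876520930044038111, 0.0833119242269467552,
      0.0781938957870703065, 0.0723457941088485062, 0.0658222227763618468,
      0.0586840934785355471, 0.0509980592623761762, 0.0428358980222266807,
      0.0342738629130214331, 0.0253920653092620595, 0.0162743947309056706,
      0.0070186100094700966};
  const double utop = R::pt(b1, nu, 1, 0);
  if (utop <= 0.0) return 0.0;
  const double gfac = (nu + 1.0) / (1.0 - rho * rho);
  // 12 panels, geometrically refined toward u = 0 (the heavy lower tail)
  const int npan = 12;
  double total = 0.0;
  double edges[13];
  edges[0] = 0.0;
  for (int k = 1; k <= npan; ++k)
    edges[k] = utop * std::pow(2.0, (double)(k - npan));
  for (int pan = 0; pan < npan; ++pan) {
    const double lo = edges[pan], hi = edges[pan + 1];
    const double c = 0.5 * (hi + lo), h = 0.5 * (hi - lo);
    if (h <= 0) continue;
    double acc = 0.0;
    for (int j = 0; j < 16; ++j) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        const double u = c + sgn * h * gl_x[j];
        if (u <= 0.0 || u >= 1.0) continue;
        const double x = R::qt(u, nu, 1, 0);
        const double arg = (b2 - rho * x) * std::sqrt(gfac / (nu + x * x));
        acc += gl_w[j] * R::pt(arg, nu + 1.0, 1, 0);
      }
    }
    total += acc * h;
  }
  return std::min(std::max(total, 0.0), 1.0);
}

// Full per-cluster E-step: marginal latent skew-t parameters,
// QMC moment bundle, and the conditional random-effects blocks
//   u2b, vub, u2bz, u2b2 and the M-step statistics S1..S4,
// assembled by the exact conditional-normal maps.  One call per cluster
// per EM iteration.
// [[Rcpp::export]]
List cpp_cluster_estep(const arma::mat& X, const arma::mat& W,
                       const arma::ivec& orient, const arma::vec& beta,
                       double delta_eps, const arma::vec& delta_b,
                       const arma::mat& d_bar, double nu, bool t_mixing,
                       double ups, double cu, int npts, int level) {
  const int n = (int)X.n_rows, q = (int)W.n_cols;
  arma::vec Delta = ups * delta_eps * arma::ones(n) + W * delta_b;
  arma::mat omega_bar = W * d_bar * W.t();
  omega_bar.diag() += ups * ups;
  arma::vec Xb = X * beta;
  arma::vec mu = Xb - cu * Delta;
  List mom = cpp_cluster_engine(mu, omega_bar, Delta, arma::zeros(n),
                                orient, nu, t_mixing, npts, level);
  double alpha = as<double>(mom["alpha"]);
  if (!(alpha > 0) || level < 2) return mom;

  const double u2 = as<double>(mom["u2"]), vu = as<double>(mom["vu"]),
               v2 = as<double>(mom["v2"]);
  arma::vec u2z = as<arma::vec>(mom["u2z"]), vuz = as<arma::vec>(mom["vuz"]);
  arma::mat u2z2 = as<arma::mat>(mom["u2z2"]);

  arma::mat rW = arma::solve(omega_bar, W);
  arma::mat ri = d_bar * rW.t();                       // q x n
  arma::mat Lam = (arma::eye(q, q) - ri * W) * d_bar;
  arma::vec s = delta_b - ri * Delta;
  const double S3 = v2 - 2.0 * cu * vu + cu * cu * u2;
  arma::vec u2b = ri * (u2z - u2 * Xb) + (vu - cu * u2) * s;
  arma::vec vub = ri * (vuz - vu * Xb) + (v2 - cu * vu) * s;
  arma::mat u2bz = ri * (u2z2 - Xb * u2z.t()) + s * (vuz - cu * u2z).t();
  arma::vec h1 = ri * ((vuz - vu * Xb) - cu * (u2z - u2 * Xb));
  arma::mat u2b2 = Lam + S3 * (s * s.t()) +
    ri * (u2z2 + u2 * (Xb * Xb.t()) - u2z * Xb.t() - Xb * u2z.t()) * ri.t() +
    h1 * s.t() + s * h1.t();
  u2b2 = 0.5 * (u2b2 + u2b2.t());

  List bm;
  bm["ri"] = ri;
  bm["s"] = s;
  bm["u2b"] = u2b;
  bm["vub"] = vub;
  bm["u2bz"] = u2bz;
  bm["u2b2"] = u2b2;
  bm["S1"] = arma::vec(u2z - W * u2b);
  bm["S2"] = vu - cu * u2;
  bm["S3"] = S3;
  bm["S4"] = arma::vec(vuz - W * vub);
  bm["vub_bar"] = arma::vec(vub - cu * u2b);
  mom["bm"] = bm;
  return mom;
}
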