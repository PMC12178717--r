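// Discretized-TMRCA coalescent HMM core.
//
// States are atomic time intervals [t_j, t_{j+1}) in units of 2*N0
// generations (the last interval extends to infinity). The chain's
// equilibrium distribution is the pairwise coalescent prior under
// piecewise-constant relative sizes lambda_j; emissions are per-bin
// het indicators; transitions follow the SMC kernel evaluated at the
// interval-conditional mean TMRCA: with probability exp(-rho*tbar_k) the
// bin keeps its state, otherwise one lineage is erased at a uniform time
// u in [0, tbar_k] and re-coalesces under the same piecewise hazard.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG_EPS = -745.0;

static inline double log_expm1_over_c(double c, double d) {
  // log((exp(c*d) - 1)/c), stable for small and large c*d
  double cd = c * d;
  if (cd < 1e-10) return std::log(d);
  if (cd > 33.0) return cd - std::log(c);
  return std::log(std::expm1(cd) / c);
}

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp(-(std::fabs(a - b))));
}

static inline double logdiffexp(double a, double b) {
  // log(exp(a) - exp(b)), a >= b
  if (b == R_NegInf) return a;
  double d = b - a;
  if (d >= 0) return R_NegInf;
  return a + std::log1p(-std::exp(d));
}

struct PsmcMats {
  std::vector<double> pi, tbar, emitK;
  std::vector<double> Q;  // row-major n x n
  int n;
};

// hazard bookkeeping shared by builders
struct Hazard {
  int n;
  std::vector<double> b;     // boundaries t_0..t_n (t_n used only as grid top)
  std::vector<double> c;     // per-interval coalescent rate 1/lambda_j
  std::vector<double> H;     // cumulative hazard at boundaries, H[0] = 0
  std::vector<double> logG;  // log int_0^{b_j} exp(H(u)) du at boundaries

  double Hat(double x) const {
    int j = find(x);
    return H[j] + c[j] * (x - b[j]);
  }
  double logGat(double x) const {
    int j = find(x);
    if (x <= b[j]) return logG[j];
    double seg = H[j] + log_expm1_over_c(c[j], x - b[j]);
    return logsumexp2(logG[j], seg);
  }
  int find(double x) const {
    // interval index whose hazard applies at x; last interval is open-ended
    int j = n - 1;
    for (int i = 0; i < n; ++i) {
      if (x < b[i + 1]) { j = i; break; }
    }
    return j;
  }
};

static Hazard make_hazard(const NumericVector &bounds, const NumericVector &lambda) {
  Hazard hz;
  hz.n = lambda.size();
  hz.b.assign(bounds.begin(), bounds.end());
  hz.c.resize(hz.n);
  hz.H.resize(hz.n + 1);
  hz.logG.resize(hz.n + 1);
  hz.H[0] = 0.0;
  hz.logG[0] = R_NegInf;
  for (int j = 0; j < hz.n; ++j) {
    hz.c[j] = 1.0 / lambda[j];
    double d = hz.b[j + 1] - hz.b[j];
    hz.H[j + 1] = hz.H[j] + hz.c[j] * d;
    double seg = hz.H[j] + log_expm1_over_c(hz.c[j], d);
    hz.logG[j + 1] = logsumexp2(hz.logG[j], seg);
  }
  return hz;
}

static PsmcMats build_mats(const NumericVector &bounds, const NumericVector &lambda,
                           double theta, double rho) {
  int n = lambda.size();
  Hazard hz = make_hazard(bounds, lambda);
  PsmcMats m;
  m.n = n;
  m.pi.resize(n);
  m.tbar.resize(n);
  m.emitK.resize(n);
  m.Q.assign((size_t)n * n, 0.0);

  for (int j = 0; j < n; ++j) {
    double a = hz.b[j];
    if (j < n - 1) {
      double d = hz.b[j + 1] - a, c = hz.c[j];
      double eH = std::exp(-hz.H[j]);
      m.pi[j] = eH - std::exp(-hz.H[j + 1]);
      // conditional mean of a rate-c exponential truncated to [0, d]
      double cd = c * d;
      double mcond;
      if (cd < 1e-8) mcond = d / 2.0;
      else mcond = 1.0 / c - d / std::expm1(cd);
      m.tbar[j] = a + mcond;
    } else {
      m.pi[j] = std::exp(-hz.H[j]);
      m.tbar[j] = a + lambda[j];
    }
    m.emitK[j] = -std::expm1(-theta * m.tbar[j]);
  }

  for (int k = 0; k < n; ++k) {
    double T = m.tbar[k];
    double stay = std::exp(-rho * T);
    for (int l = 0; l < n; ++l) {
      double a = hz.b[l];
      double Ha = hz.H[l];
      bool last = (l == n - 1);
      double Hb = last ? R_PosInf : hz.H[l + 1];
      double A = 0.0, B = 0.0;
      double ua = std::min(a, T);
      if (ua > 0) {
        // integral of P(T' in [a,b) | u) over u in [0, min(a,T)]
        double lg = hz.logGat(ua);
        double mass = last ? 1.0 : -std::expm1(-(Hb - Ha));
        A = std::exp(lg - Ha) * mass;
      }
      if (T > a) {
        double ub = last ? T : std::min(hz.b[l + 1], T);
        double du = ub - a;
        if (last) {
          B = du;
        } else {
          double lgdiff = logdiffexp(hz.logGat(ub), hz.logGat(a));
          B = du - std::exp(lgdiff - Hb);
        }
      }
      double Mkl = (A + B) / T;
      m.Q[(size_t)k * n + l] = (k == l ? stay : 0.0) + (1.0 - stay) * Mkl;
    }
  }
  return m;
}

// [[Rcpp::export]]
List psmc_matrices_cpp(NumericVector bounds, NumericVector lambda,
                       double theta, double rho) {
  PsmcMats m = build_mats(bounds, lambda, theta, rho);
  int n = m.n;
  NumericMatrix Q(n, n);
  for (int k = 0; k < n; ++k)
    for (int l = 0; l < n; ++l) Q(k, l) = m.Q[(size_t)k * n + l];
  return List::create(_["pi"] = NumericVector(m.pi.begin(), m.pi.end()),
                      _["tbar"] = NumericVector(m.tbar.begin(), m.tbar.end()),
                      _["emitK"] = NumericVector(m.emitK.begin(), m.emitK.end()),
                      _["Q"] = Q);
}

// Forward-backward with per-bin scaling. obs: 0 = hom bin (T), 1 = het bin
// (K), 2 = missing (N, emitted with probability 1 in every state).
// [[Rcpp::export]]
List psmc_fwdback_cpp(IntegerVector obs, NumericVector pi, NumericMatrix Q,
                      NumericVector emitK, bool return_gamma = false) {
  int n = pi.size();
  R_xlen_t Tn = obs.size();
  if (Tn == 0) stop("empty observation sequence");
  std::vector<double> Qv((size_t)n * n);
  for (int k = 0; k < n; ++k)
    for (int l = 0; l < n; ++l) Qv[(size_t)k * n + l] = Q(k, l);

  std::vector<double> eK(n), eT(n), eN(n, 1.0);
  for (int j = 0; j < n; ++j) { eK[j] = emitK[j]; eT[j] = 1.0 - emitK[j]; }
  const double *emis[3] = { eT.data(), eK.data(), eN.data() };

  std::vector<double> alpha((size_t)Tn * n);
  std::vector<double> scale(Tn);
  double loglik = 0.0;

  {
    const double *e = emis[obs[0]];
    double s = 0.0;
    for (int j = 0; j < n; ++j) { alpha[j] = pi[j] * e[j]; s += alpha[j]; }
    if (s <= 0 || !std::isfinite(s)) stop("non-finite likelihood at bin 1");
    for (int j = 0; j < n; ++j) alpha[j] /= s;
    scale[0] = s;
    loglik += std::log(s);
  }
  for (R_xlen_t t = 1; t < Tn; ++t) {
    const double *ap = &alpha[(size_t)(t - 1) * n];
    double *an = &alpha[(size_t)t * n];
    const double *e = emis[obs[t]];
    for (int l = 0; l < n; ++l) an[l] = 0.0;
    for (int k = 0; k < n; ++k) {
      double ak = ap[k];
      if (ak == 0.0) continue;
      const double *qk = &Qv[(size_t)k * n];
      for (int l = 0; l < n; ++l) an[l] += ak * qk[l];
    }
    double s = 0.0;
    for (int l = 0; l < n; ++l) { an[l] *= e[l]; s += an[l]; }
    if (s <= 0 || !std::isfinite(s))
      stop("non-finite likelihood at bin %d", (int)(t + 1));
    for (int l = 0; l < n; ++l) an[l] /= s;
    scale[t] = s;
    loglik += std::log(s);
  }

  std::vector<double> beta(n, 1.0), beta_next(n);
  NumericVector gamma1(n), ek(n), et(n);
  NumericMatrix xi(n, n);
  std::vector<double> xiv((size_t)n * n, 0.0);
  NumericMatrix gamma_full;
  if (return_gamma) gamma_full = NumericMatrix(Tn, n);

  // t = Tn - 1 contribution
  {
    const double *aT = &alpha[(size_t)(Tn - 1) * n];
    if (obs[Tn - 1] == 1) for (int j = 0; j < n; ++j) ek[j] += aT[j];
    if (obs[Tn - 1] == 0) for (int j = 0; j < n; ++j) et[j] += aT[j];
    if (return_gamma) for (int j = 0; j < n; ++j) gamma_full(Tn - 1, j) = aT[j];
  }

  for (R_xlen_t t = Tn - 2; t >= 0; --t) {
    const double *e = emis[obs[t + 1]];
    const double *an = &alpha[(size_t)t * n];
    double sc = scale[t + 1];
    // xi and new beta in one sweep
    std::vector<double> eb(n);
    for (int l = 0; l < n; ++l) eb[l] = e[l] * beta[l] / sc;
    for (int k = 0; k < n; ++k) {
      const double *qk = &Qv[(size_t)k * n];
      double bk = 0.0, ak = an[k];
      double *xk = &xiv[(size_t)k * n];
      for (int l = 0; l < n; ++l) {
        double w = qk[l] * eb[l];
        bk += w;
        xk[l] += ak * w;
      }
      beta_next[k] = bk;
    }
    std::swap(beta, beta_next);
    double gsum = 0.0;
    std::vector<double> g(n);
    for (int j = 0; j < n; ++j) { g[j] = an[j] * beta[j]; gsum += g[j]; }
    for (int j = 0; j < n; ++j) g[j] /= gsum;  // guard drift
    if (obs[t] == 1) for (int j = 0; j < n; ++j) ek[j] += g[j];
    if (obs[t] == 0) for (int j = 0; j < n; ++j) et[j] += g[j];
    if (return_gamma) for (int j = 0; j < n; ++j) gamma_full(t, j) = g[j];
    if (t == 0) for (int j = 0; j < n; ++j) gamma1[j] = g[j];
  }
  if (Tn == 1) for (int j = 0; j < n; ++j) gamma1[j] = alpha[j];

  for (int k = 0; k < n; ++k)
    for (int l = 0; l < n; ++l) xi(k, l) = xiv[(size_t)k * n + l];

  List out = List::create(_["loglik"] = loglik, _["gamma1"] = gamma1,
                          _["xi"] = xi, _["ek"] = ek, _["et"] = et);
  if (return_gamma) out["gamma"] = gamma_full;
  return out;
}

// Expected complete-data negative log-likelihood given sufficient
// statistics from the E-step; the M-step minimizes this over
// (theta, rho, lambda).
// [[Rcpp::export]]
double psmc_eneg_loglik_cpp(NumericVector bounds, NumericVector lambda,
                            double theta, double rho,
                            NumericVector gamma1, NumericMatrix xi,
                            NumericVector ek, NumericVector et) {
  PsmcMats m = build_mats(bounds, lambda, theta, rho);
  int n = m.n;
  double ll = 0.0;
  for (int j = 0; j < n; ++j) {
    if (gamma1[j] > 0) ll += gamma1[j] * std::max(std::log(m.pi[j]), LOG_EPS);
    if (ek[j] > 0) ll += ek[j] * std::max(std::log(m.emitK[j]), LOG_EPS);
    if (et[j] > 0) ll += et[j] * std::max(std::log(1.0 - m.emitK[j]), LOG_EPS);
  }
  for (int k = 0; k < n; ++k) {
    const double *qk = &m.Q[(size_t)k * n];
    for (int l = 0; l < n; ++l) {
      double x = xi(k, l);
      if (x > 0) ll += x * std::max(std::log(qk[l]), LOG_EPS);
    }
  }
  return -ll;
}
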