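#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Selfing-rate mixture likelihood from multilocus heterozygosity patterns.
//
// An individual whose last outbred ancestor is n selfing generations back is
// heterozygous at locus l with probability h_l * 2^-n; n follows a truncated
// (renormalised) geometric distribution with parameter s. The profile
// likelihood maximises the nuisance h (outbred heterozygosities) at each s by
// EM, warm-started along the grid.

static int nmax_for_s(double s, double tail_tol, int cap) {
  if (s <= 0.0) return 0;
  int n = (int)std::ceil(std::log(tail_tol) / std::log(s)) - 1;
  if (n < 1) n = 1;
  if (n > cap) n = cap;
  return n;
}

struct HetData {
  int N, L;
  // per individual: indices of observed-het and observed-hom loci
  std::vector<std::vector<int>> het, hom;
};

static HetData build_data(const IntegerMatrix &X) {
  HetData d;
  d.N = X.nrow(); d.L = X.ncol();
  d.het.resize(d.N); d.hom.resize(d.N);
  for (int i = 0; i < d.N; ++i)
    for (int l = 0; l < d.L; ++l) {
      if (X(i, l) == NA_INTEGER) continue;
      if (X(i, l) == 1) d.het[i].push_back(l); else d.hom[i].push_back(l);
    }
  return d;
}

// log-likelihood of all individuals at (s, h); optionally EM-update h in place
// until max |dh| < tol or maxit reached. Returns final loglik.
static double em_fit(const HetData &d, double s, std::vector<double> &h,
                     double tail_tol, int cap, double tol, int maxit) {
  int nm = nmax_for_s(s, tail_tol, cap);
  int K = nm + 1;
  std::vector<double> logw(K);
  if (s <= 0.0) logw[0] = 0.0;
  else {
    double norm = 1.0 - std::pow(s, nm + 1);
    for (int n = 0; n < K; ++n)
      logw[n] = std::log1p(-s) + n * std::log(s) - std::log(norm);
  }
  const double log2v = std::log(2.0);
  std::vector<double> pw(K);
  for (int n = 0; n < K; ++n) pw[n] = std::pow(0.5, n);
  double loglik = R_NegInf;
  std::vector<double> lh(d.L), B(d.L * K);
  std::vector<double> lin(K), q(d.N * K);
  std::vector<double> c1(d.L * K), c0(d.L * K);
  for (int it = 0; it < maxit; ++it) {
    for (int l = 0; l < d.L; ++l) {
      lh[l] = std::log(h[l]);
      for (int n = 0; n < K; ++n) {
        double p = h[l] * pw[n];
        B[l * K + n] = (p >= 1.0) ? R_NegInf : std::log1p(-p);
      }
    }
    loglik = 0.0;
    for (int i = 0; i < d.N; ++i) {
      double A = 0.0; int H = (int)d.het[i].size();
      for (int l : d.het[i]) A += lh[l];
      for (int n = 0; n < K; ++n) lin[n] = logw[n] + A - n * log2v * H;
      for (int l : d.hom[i]) {
        const double *Bl = &B[l * K];
        for (int n = 0; n < K; ++n) lin[n] += Bl[n];
      }
      double m = lin[0];
      for (int n = 1; n < K; ++n) if (lin[n] > m) m = lin[n];
      double sum = 0.0;
      for (int n = 0; n < K; ++n) { lin[n] = std::exp(lin[n] - m); sum += lin[n]; }
      loglik += m + std::log(sum);
      double *qi = &q[i * K];
      for (int n = 0; n < K; ++n) qi[n] = lin[n] / sum;
    }
    // M-step
    std::fill(c1.begin(), c1.end(), 0.0);
    std::fill(c0.begin(), c0.end(), 0.0);
    for (int i = 0; i < d.N; ++i) {
      const double *qi = &q[i * K];
      for (int l : d.het[i]) { double *cl = &c1[l * K]; for (int n = 0; n < K; ++n) cl[n] += qi[n]; }
      for (int l : d.hom[i]) { double *cl = &c0[l * K]; for (int n = 0; n < K; ++n) cl[n] += qi[n]; }
    }
    double dh_max = 0.0;
    for (int l = 0; l < d.L; ++l) {
      double C1 = 0.0, C0 = 0.0;
      for (int n = 0; n < K; ++n) { C1 += c1[l * K + n]; C0 += c0[l * K + n]; }
      double hnew;
      if (C1 <= 0.0) hnew = 1e-8;          // no heterozygote: h -> 0 boundary
      else if (C0 <= 0.0) hnew = 1.0;      // always heterozygous
      else {
        // solve C1/h = sum_n c0_n w_n/(1 - h w_n), w_n = 2^-n; decreasing f
        double lo = 1e-10, hi = 1.0 - 1e-12, x = h[l];
        if (x <= lo || x >= hi) x = 0.5 * (lo + hi);
        for (int k = 0; k < 60; ++k) {
          double f = C1 / x, fp = -C1 / (x * x);
          for (int n = 0; n < K; ++n) {
            double w = pw[n], den = 1.0 - x * w, cn = c0[l * K + n];
            if (cn == 0.0) continue;
            f -= cn * w / den;
            fp -= cn * w * w / (den * den);
          }
          if (f > 0) lo = x; else hi = x;
          double step = f / fp;
          double xn = x - step;
          if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
          if (std::fabs(xn - x) < 1e-12) { x = xn; break; }
          x = xn;
        }
        hnew = x;
      }
      double dh = std::fabs(hnew - h[l]);
      if (dh > dh_max) dh_max = dh;
      h[l] = hnew;
    }
    if (dh_max < tol) break;
  }
  // recompute loglik at final h (one E-step without update)
  for (int l = 0; l < d.L; ++l) {
    lh[l] = std::log(h[l]);
    for (int n = 0; n < K; ++n) {
      double p = h[l] * pw[n];
      B[l * K + n] = (p >= 1.0) ? R_NegInf : std::log1p(-p);
    }
  }
  loglik = 0.0;
  for (int i = 0; i < d.N; ++i) {
    double A = 0.0; int H = (int)d.het[i].size();
    for (int l : d.het[i]) A += lh[l];
    for (int n = 0; n < K; ++n) lin[n] = logw[n] + A - n * log2v * H;
    for (int l : d.hom[i]) {
      const double *Bl = &B[l * K];
      for (int n = 0; n < K; ++n) lin[n] += Bl[n];
    }
    double m = lin[0];
    for (int n = 1; n < K; ++n) if (lin[n] > m) m = lin[n];
    double sum = 0.0;
    for (int n = 0; n < K; ++n) sum += std::exp(lin[n] - m);
    loglik += m + std::log(sum);
  }
  return loglik;
}

// [[Rcpp::export(name = ".rmes_profile_cpp")]]
List rmes_profile_cpp(IntegerMatrix X, NumericVector grid, double tail_tol,
                      int nmax_cap, double em_tol, int em_maxit) {
  HetData d = build_data(X);
  // init h at s = 0 MLE: observed heterozygote frequency per locus
  std::vector<double> h(d.L, 0.5);
  for (int l = 0; l < d.L; ++l) {
    int nhet = 0, nobs = 0;
    for (int i = 0; i < d.N; ++i) {
      bool ishet = false, found = false;
      for (int ll : d.het[i]) if (ll == l) { ishet = true; found = true; break; }
      if (!found) for (int ll : d.hom[i]) if (ll == l) { found = true; break; }
      if (found) { nobs++; if (ishet) nhet++; }
    }
    double f = nobs > 0 ? (double)nhet / nobs : 0.5;
    h[l] = std::min(1.0, std::max(1e-6, f));
  }
  int G = grid.size();
  NumericVector ll(G);
  NumericMatrix hmat(d.L, G);
  for (int g = 0; g < G; ++g) {
    // warm start from previous grid point; converge fully at the first point,
    // then a few refreshing iterations suffice (h moves O(grid step))
    int maxit = (g == 0) ? em_maxit : 6;
    double tol = (g == 0) ? em_tol : std::max(em_tol, 2e-5);
    ll[g] = em_fit(d, grid[g], h, tail_tol, nmax_cap, tol, maxit);
    for (int l = 0; l < d.L; ++l) hmat(l, g) = h[l];
  }
  return List::create(_["loglik"] = ll, _["h"] = hmat);
}

// [[Rcpp::export(name = ".rmes_loglik_at_cpp")]]
List rmes_loglik_at_cpp(IntegerMatrix X, double s, NumericVector h_init,
                        double tail_tol, int nmax_cap, double em_tol, int em_maxit) {
  HetData d = build_data(X);
  std::vector<double> h(h_init.begin(), h_init.end());
  double ll = em_fit(d, s, h, tail_tol, nmax_cap, em_tol, em_maxit);
  return List::create(_["loglik"] = ll, _["h"] = NumericVector(h.begin(), h.end()));
}
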