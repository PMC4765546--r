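#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Correlated mixed-mating model for progeny arrays.
//
// Latent structure per family: with probability r_t the whole sibship shares
// one Bernoulli(1 - t_m) selfing draw; with probability r_p all outcrossed
// sibs share one father drawn from the pollen pool at inbreeding F_p. The
// maternal genotype, when unknown, is marginalised per locus over ovule
// genotype frequencies at inbreeding F_m.
//
// The sib-pair likelihood is exact under this model and linear in F_m and
// F_p, so each (pair, locus) reduces to 12 precomputed coefficients:
//   ss0 ss1 so0 so1 os0 os1 oo0 oo1 sf00 sf01 sf10 sf11
// where suffix 0/1 picks the Hardy-Weinberg / forced-homozygote component of
// the maternal prior, and sfAB the (mother, father) component pair.
// Singletons carry 4 coefficients: s0 s1 o0 o1.

// genotype list for A alleles: unordered pairs (i <= j), 1-based alleles
static void geno_list(int A, std::vector<int> &g1, std::vector<int> &g2) {
  g1.clear(); g2.clear();
  for (int i = 1; i <= A; ++i)
    for (int j = i; j <= A; ++j) { g1.push_back(i); g2.push_back(j); }
}

// [[Rcpp::export(name = ".progeny_build_tables_cpp")]]
List progeny_build_tables_cpp(List families, List freqs) {
  int L = freqs.size();
  int nf = families.size();
  List out(nf);
  // per-locus genotype machinery
  std::vector<std::vector<int>> G1(L), G2(L);
  std::vector<std::vector<double>> prHW(L), prHom(L), P(L);
  std::vector<std::vector<double>> MgHW(L), Mghom(L); // A x A moment matrices
  for (int l = 0; l < L; ++l) {
    NumericVector p = freqs[l];
    int A = p.size();
    P[l] = std::vector<double>(p.begin(), p.end());
    geno_list(A, G1[l], G2[l]);
    int ng = G1[l].size();
    prHW[l].resize(ng); prHom[l].resize(ng);
    for (int g = 0; g < ng; ++g) {
      int a = G1[l][g], b = G2[l][g];
      prHW[l][g] = (a == b) ? p[a - 1] * p[a - 1] : 2.0 * p[a - 1] * p[b - 1];
      prHom[l][g] = (a == b) ? p[a - 1] : 0.0;
    }
    MgHW[l].resize(A * A); Mghom[l].resize(A * A);
    for (int a = 0; a < A; ++a)
      for (int b = 0; b < A; ++b) {
        MgHW[l][a * A + b] = 2.0 * p[a] * p[b] + (a == b ? 2.0 * p[a] : 0.0);
        Mghom[l][a * A + b] = (a == b) ? 4.0 * p[a] : 0.0;
      }
  }
  for (int f = 0; f < nf; ++f) {
    List fam = families[f];
    IntegerMatrix geno = fam["geno"];      // k x 2L
    IntegerVector mother = fam["mother"];  // 2L, 0 = unknown at that locus
    int k = geno.nrow();
    int npair = k * (k - 1) / 2;
    NumericVector pairtab(Dimension(std::max(npair, 1), L, 12));
    NumericVector singtab(Dimension(k, L, 4));
    IntegerMatrix bad(k, L); // 1 if progeny genotype impossible at locus
    for (int l = 0; l < L; ++l) {
      int A = P[l].size();
      int ng = G1[l].size();
      int m1 = mother[2 * l], m2 = mother[2 * l + 1];
      bool mknown = (m1 > 0);
      // mother states: either the known genotype or all ng genotypes
      int nm = mknown ? 1 : ng;
      // per progeny and mother state: S and O; per progeny: allele pair
      std::vector<double> S(k * nm), O(k * nm);
      std::vector<int> px(k), py(k); // observed progeny alleles (0 = missing)
      for (int j = 0; j < k; ++j) {
        px[j] = geno(j, 2 * l); py[j] = geno(j, 2 * l + 1);
      }
      // counts n_a(m) per mother state
      std::vector<double> N(nm * A, 0.0);
      for (int m = 0; m < nm; ++m) {
        int a = mknown ? m1 : G1[l][m], b = mknown ? m2 : G2[l][m];
        N[m * A + a - 1] += 1.0; N[m * A + b - 1] += 1.0;
      }
      for (int j = 0; j < k; ++j) {
        for (int m = 0; m < nm; ++m) {
          if (px[j] == 0) { S[j * nm + m] = 1.0; O[j * nm + m] = 1.0; continue; }
          double nx = N[m * A + px[j] - 1], ny = N[m * A + py[j] - 1];
          if (px[j] == py[j]) {
            S[j * nm + m] = 0.25 * nx * nx;
            O[j * nm + m] = 0.5 * nx * P[l][px[j] - 1];
          } else {
            S[j * nm + m] = 0.5 * nx * ny;
            O[j * nm + m] = 0.5 * (nx * P[l][py[j] - 1] + ny * P[l][px[j] - 1]);
          }
        }
        // feasibility under any mother state and any path
        double mx = 0.0;
        for (int m = 0; m < nm; ++m) mx += S[j * nm + m] + O[j * nm + m];
        if (px[j] != 0 && mx <= 0.0) bad(j, l) = 1;
      }
      // shared-father pair factor per mother state, for both father components
      // sf(m) = E_G[B_j B_j'] with B_j = 1 for missing genotypes
      auto sf_pair = [&](int j, int jp, int m, const std::vector<double> &Mg) {
        bool oj = px[j] > 0, ojp = px[jp] > 0;
        if (!oj && !ojp) return 1.0;
        if (!oj) return O[jp * nm + m];
        if (!ojp) return O[j * nm + m];
        // sum over ordered allele splits of each genotype
        int ax[2] = {px[j], py[j]}, bx[2] = {py[j], px[j]};
        int axp[2] = {px[jp], py[jp]}, bxp[2] = {py[jp], px[jp]};
        int no1 = (px[j] == py[j]) ? 1 : 2, no2 = (px[jp] == py[jp]) ? 1 : 2;
        double acc = 0.0;
        for (int u = 0; u < no1; ++u)
          for (int v = 0; v < no2; ++v) {
            double nm1 = N[m * A + ax[u] - 1], nm2 = N[m * A + axp[v] - 1];
            acc += nm1 * nm2 * Mg[(bx[u] - 1) * A + (bxp[v] - 1)];
          }
        return acc / 16.0;
      };
      // accumulate coefficients over the maternal prior components
      int pi = 0;
      for (int j = 0; j < k; ++j)
        for (int jp = j + 1; jp < k; ++jp, ++pi) {
          double ss0 = 0, ss1 = 0, so0 = 0, so1 = 0, os0 = 0, os1 = 0,
                 oo0 = 0, oo1 = 0, sf00 = 0, sf01 = 0, sf10 = 0, sf11 = 0;
          for (int m = 0; m < nm; ++m) {
            double w0 = mknown ? 1.0 : prHW[l][m];
            double w1 = mknown ? 1.0 : prHom[l][m];
            double sj = S[j * nm + m], sjp = S[jp * nm + m];
            double oj = O[j * nm + m], ojp = O[jp * nm + m];
            double fHW = sf_pair(j, jp, m, MgHW[l]);
            double fH  = sf_pair(j, jp, m, Mghom[l]);
            ss0 += w0 * sj * sjp; ss1 += w1 * sj * sjp;
            so0 += w0 * sj * ojp; so1 += w1 * sj * ojp;
            os0 += w0 * oj * sjp; os1 += w1 * oj * sjp;
            oo0 += w0 * oj * ojp; oo1 += w1 * oj * ojp;
            sf00 += w0 * fHW; sf01 += w0 * fH;
            sf10 += w1 * fHW; sf11 += w1 * fH;
          }
          int base = pi + std::max(npair, 1) * L * 0;
          int stride = std::max(npair, 1) * L;
          pairtab[pi + std::max(npair, 1) * l + stride * 0] = ss0;
          pairtab[pi + std::max(npair, 1) * l + stride * 1] = ss1;
          pairtab[pi + std::max(npair, 1) * l + stride * 2] = so0;
          pairtab[pi + std::max(npair, 1) * l + stride * 3] = so1;
          pairtab[pi + std::max(npair, 1) * l + stride * 4] = os0;
          pairtab[pi + std::max(npair, 1) * l + stride * 5] = os1;
          pairtab[pi + std::max(npair, 1) * l + stride * 6] = oo0;
          pairtab[pi + std::max(npair, 1) * l + stride * 7] = oo1;
          pairtab[pi + std::max(npair, 1) * l + stride * 8] = sf00;
          pairtab[pi + std::max(npair, 1) * l + stride * 9] = sf01;
          pairtab[pi + std::max(npair, 1) * l + stride * 10] = sf10;
          pairtab[pi + std::max(npair, 1) * l + stride * 11] = sf11;
          (void)base;
        }
      for (int j = 0; j < k; ++j) {
        double s0 = 0, s1 = 0, o0 = 0, o1 = 0;
        for (int m = 0; m < nm; ++m) {
          double w0 = mknown ? 1.0 : prHW[l][m];
          double w1 = mknown ? 1.0 : prHom[l][m];
          s0 += w0 * S[j * nm + m]; s1 += w1 * S[j * nm + m];
          o0 += w0 * O[j * nm + m]; o1 += w1 * O[j * nm + m];
        }
        singtab[j + k * l + k * L * 0] = s0;
        singtab[j + k * l + k * L * 1] = s1;
        singtab[j + k * l + k * L * 2] = o0;
        singtab[j + k * l + k * L * 3] = o1;
      }
    }
    out[f] = List::create(_["pair"] = pairtab, _["sing"] = singtab,
                          _["k"] = k, _["bad"] = bad);
  }
  return out;
}

// [[Rcpp::export(name = ".progeny_composite_loglik_cpp")]]
double progeny_composite_loglik_cpp(List tables, double t, double rt,
                                    double rp, double Fp, double Fm,
                                    NumericVector weights, int locus) {
  int nf = tables.size();
  double pSS = rt * (1 - t) + (1 - rt) * (1 - t) * (1 - t);
  double pOO = rt * t + (1 - rt) * t * t;
  double pSO = (1 - rt) * (1 - t) * t;
  double cm0 = 1 - Fm, cm1 = Fm, cp0 = 1 - Fp, cp1 = Fp;
  double total = 0.0;
  for (int f = 0; f < nf; ++f) {
    double w = weights.size() ? weights[f] : 1.0;
    if (w == 0.0) continue;
    List tb = tables[f];
    int k = tb["k"];
    NumericVector pair = tb["pair"], sing = tb["sing"];
    IntegerVector dims = pair.attr("dim");
    int npair_sl = dims[0], L = dims[1];
    int l0 = 0, l1 = L;
    if (locus > 0) { l0 = locus - 1; l1 = locus; }
    double famll = 0.0;
    int npair = k * (k - 1) / 2;
    int stride = npair_sl * L;
    for (int pi = 0; pi < npair; ++pi) {
      double Pss = 1, Pso = 1, Pos = 1, Poo = 1, Psf = 1;
      for (int l = l0; l < l1; ++l) {
        const double *c = &pair[pi + npair_sl * l];
        Pss *= cm0 * c[stride * 0] + cm1 * c[stride * 1];
        Pso *= cm0 * c[stride * 2] + cm1 * c[stride * 3];
        Pos *= cm0 * c[stride * 4] + cm1 * c[stride * 5];
        Poo *= cm0 * c[stride * 6] + cm1 * c[stride * 7];
        Psf *= cm0 * cp0 * c[stride * 8] + cm0 * cp1 * c[stride * 9] +
               cm1 * cp0 * c[stride * 10] + cm1 * cp1 * c[stride * 11];
      }
      double Pp = pSS * Pss + pSO * (Pso + Pos) +
                  pOO * (rp * Psf + (1 - rp) * Poo);
      if (!(Pp > 0.0)) return R_NegInf;
      famll += std::log(Pp);
    }
    if (k == 1) {
      double Ps = 1, Po = 1;
      for (int l = l0; l < l1; ++l) {
        Ps *= cm0 * sing[0 + k * l + k * L * 0] + cm1 * sing[0 + k * l + k * L * 1];
        Po *= cm0 * sing[0 + k * l + k * L * 2] + cm1 * sing[0 + k * l + k * L * 3];
      }
      double Pj = (1 - t) * Ps + t * Po;
      if (!(Pj > 0.0)) return R_NegInf;
      famll += std::log(Pj);
    }
    total += w * famll;
  }
  return total;
}

// Full-family log-likelihood with the shared-father term estimated by
// importance sampling (fixed, seeded father draws built in R). Per family
// the tables hold: exact per-progeny selfing/outcross probabilities S, O;
// per-draw shared-father products PB (k x M); the sampled fathers' prior
// components HW, HM (M x L) and log proposal constants LCm; and the exact
// all-outcrossed shared-father per-locus components A0, A1 (linear in F_p).
// [[Rcpp::export(name = ".progeny_full_loglik_cpp")]]
double progeny_full_loglik_cpp(List tabs, double t, double rt, double rp,
                               double Fp, NumericVector weights) {
  int nf = tabs.size();
  double total = 0.0;
  for (int f = 0; f < nf; ++f) {
    double wf = weights.size() ? weights[f] : 1.0;
    if (wf == 0.0) continue;
    List tb = tabs[f];
    NumericVector S = tb["S"], O = tb["O"], LCm = tb["LCm"];
    NumericVector A0 = tb["A0"], A1 = tb["A1"];
    NumericMatrix PB = tb["PB"], HW = tb["HW"], HM = tb["HM"];  // HW/HM: L x M
    int k = S.size(), M = PB.ncol(), L = A0.size();
    // per-progeny mixture base (independent-selfing, independent-father)
    double lbase = 0.0, R_self = (1 - t), R_ind = t;
    std::vector<double> base(k), aj(k), bj(k);
    for (int j = 0; j < k; ++j) {
      base[j] = (1 - t) * S[j] + t * O[j];
      if (!(base[j] > 0.0)) return R_NegInf;
      lbase += std::log(base[j]);
      R_self *= S[j] / base[j];
      R_ind *= O[j] / base[j];
      aj[j] = (1 - t) * S[j] / base[j];
      bj[j] = t / base[j];
    }
    // all-outcrossed shared father: exact per-locus marginal
    double lPsh = 0.0;
    for (int l = 0; l < L; ++l) {
      double v = (1 - Fp) * A0[l] + Fp * A1[l];
      if (!(v > 0.0)) { lPsh = R_NegInf; break; }
      lPsh += std::log(v);
    }
    double R_sh = (lPsh == R_NegInf) ? 0.0 : t * std::exp(lPsh - lbase);
    // independent selfing x shared father, relative to the base product:
    // (1/M) sum_m w_m(Fp) prod_j [((1-t)S_j + t PB_jm) / base_j]
    double lse_max = R_NegInf;
    const double lg200 = std::log(1e200);
    std::vector<double> lvals(M);
    for (int m = 0; m < M; ++m) {
      double wprod = 1.0;
      const double *hw = &HW(0, m), *hm = &HM(0, m);  // L x M layout
      for (int l = 0; l < L; ++l)
        wprod *= (1 - Fp) * hw[l] + Fp * hm[l];
      if (!(wprod > 0.0)) { lvals[m] = R_NegInf; continue; }
      double prod = 1.0; int ex = 0;
      const double *pb = &PB(0, m);
      for (int j = 0; j < k; ++j) {
        prod *= aj[j] + bj[j] * pb[j];
        if (prod > 1e200) { prod *= 1e-200; ex += 1; }
        else if (prod < 1e-200 && prod > 0.0) { prod *= 1e200; ex -= 1; }
      }
      lvals[m] = (prod > 0.0)
        ? LCm[m] + std::log(wprod * prod) + ex * lg200
        : R_NegInf;
      if (lvals[m] > lse_max) lse_max = lvals[m];
    }
    double R5 = 0.0;
    if (lse_max > R_NegInf) {
      double acc = 0.0;
      for (int m = 0; m < M; ++m)
        if (lvals[m] > R_NegInf) acc += std::exp(lvals[m] - lse_max);
      R5 = std::exp(lse_max + std::log(acc / M));
    }
    double Lrel = rt * (R_self + rp * R_sh + (1 - rp) * R_ind) +
                  (1 - rt) * (rp * R5 + (1 - rp) * 1.0);
    if (!(Lrel > 0.0)) return R_NegInf;
    total += wf * (lbase + std::log(Lrel));
  }
  return total;
}
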