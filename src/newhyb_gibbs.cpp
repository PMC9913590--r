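#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for Bayesian assignment of diploid individuals to
// genotypic classes defined by gene-origin probability vectors
// (z11, z12, z22) over two parental gene pools.
//
// Latent structure sampled each sweep:
//   * per-individual class labels (categorical, given pool frequencies
//     and mixing proportions),
//   * per-(individual, locus) gene-copy origins (given the class),
//   * per-pool allele frequencies (Dirichlet, Jeffreys prior 1/2),
//   * class mixing proportions (Dirichlet, flat prior), unless fixed.
//
// a1/a2: N x L matrices of 0-based allele indices, -1 = missing (both).
// z: C x 3 matrix of class gene-origin vectors.
// f1/f2 init: list of per-locus frequency vectors (also used, unchanged,
// when fix_freqs is true). cfix: per-individual fixed class (-1 = free).
// Uses R's RNG; posterior q = class-label occupancy after burn-in.

static void rdirichlet(std::vector<double>& out, const std::vector<double>& alpha) {
  double s = 0.0;
  for (size_t i = 0; i < alpha.size(); i++) {
    out[i] = R::rgamma(alpha[i], 1.0);
    s += out[i];
  }
  for (size_t i = 0; i < alpha.size(); i++) out[i] = (out[i] > 0 || s > 0) ? out[i] / s : 1.0 / alpha.size();
}

// [[Rcpp::export]]
List newhyb_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2, IntegerVector nall,
                      NumericMatrix z, List f1_init, List f2_init,
                      int iters, int burn, bool fix_freqs, bool fix_pi,
                      IntegerVector cfix, double freq_prior) {
  const int N = a1.nrow(), L = a1.ncol(), C = z.nrow();
  RNGScope scope;

  std::vector< std::vector<double> > f1(L), f2(L);
  for (int l = 0; l < L; l++) {
    NumericVector v1 = f1_init[l], v2 = f2_init[l];
    f1[l] = std::vector<double>(v1.begin(), v1.end());
    f2[l] = std::vector<double>(v2.begin(), v2.end());
  }
  std::vector<double> pi(C, 1.0 / C);
  std::vector<int> cls(N, 0);
  NumericMatrix qacc(N, C);
  std::vector<double> pisum(C, 0.0);
  int kept = 0;

  // workspaces
  std::vector<double> p11(N * L), p12(N * L), p22(N * L);
  std::vector<double> logw(C);
  std::vector<double> alpha1, alpha2, fr;
  std::vector< std::vector<double> > cnt1(L), cnt2(L);
  for (int l = 0; l < L; l++) { cnt1[l].resize(nall[l]); cnt2[l].resize(nall[l]); }
  std::vector<double> pidir(C);
  int ntrace = (iters - burn) / 50 + 1;
  NumericVector lltrace(ntrace); int tr = 0;

  for (int it = 0; it < iters; it++) {
    // genotype probabilities under each origin state, current freqs
    for (int i = 0; i < N; i++) {
      for (int l = 0; l < L; l++) {
        int x = a1(i, l), y = a2(i, l), idx = i * L + l;
        if (x < 0) { p11[idx] = p12[idx] = p22[idx] = 1.0; continue; }
        const std::vector<double>& g1 = f1[l];
        const std::vector<double>& g2 = f2[l];
        if (x == y) {
          p11[idx] = g1[x] * g1[x];
          p22[idx] = g2[x] * g2[x];
          p12[idx] = g1[x] * g2[x];
        } else {
          p11[idx] = 2.0 * g1[x] * g1[y];
          p22[idx] = 2.0 * g2[x] * g2[y];
          p12[idx] = g1[x] * g2[y] + g1[y] * g2[x];
        }
      }
    }
    // class labels
    double lltot = 0.0;
    for (int i = 0; i < N; i++) {
      double mx = -1e300;
      for (int c = 0; c < C; c++) {
        double ll = std::log(pi[c] > 0 ? pi[c] : 1e-300);
        for (int l = 0; l < L; l++) {
          int idx = i * L + l;
          double lik = z(c, 0) * p11[idx] + z(c, 1) * p12[idx] + z(c, 2) * p22[idx];
          ll += std::log(lik > 0 ? lik : 1e-300);
        }
        logw[c] = ll;
        if (ll > mx) mx = ll;
      }
      if (cfix[i] >= 0) { cls[i] = cfix[i]; lltot += logw[cls[i]]; continue; }
      double s = 0.0;
      for (int c = 0; c < C; c++) { logw[c] = std::exp(logw[c] - mx); s += logw[c]; }
      double u = unif_rand() * s, acc = 0.0;
      int pick = C - 1;
      for (int c = 0; c < C; c++) { acc += logw[c]; if (u <= acc) { pick = c; break; } }
      cls[i] = pick;
      lltot += mx + std::log(s / C);
    }
    // gene-copy origins -> pool allele counts
    for (int l = 0; l < L; l++) {
      std::fill(cnt1[l].begin(), cnt1[l].end(), 0.0);
      std::fill(cnt2[l].begin(), cnt2[l].end(), 0.0);
    }
    for (int i = 0; i < N; i++) {
      int c = cls[i];
      for (int l = 0; l < L; l++) {
        int x = a1(i, l), y = a2(i, l), idx = i * L + l;
        if (x < 0) continue;
        double w11 = z(c, 0) * p11[idx], w12 = z(c, 1) * p12[idx], w22 = z(c, 2) * p22[idx];
        double tot = w11 + w12 + w22;
        if (tot <= 0) continue;
        double u = unif_rand() * tot;
        if (u <= w11) {
          cnt1[l][x] += 1.0; cnt1[l][y] += 1.0;
        } else if (u <= w11 + w12) {
          if (x == y) { cnt1[l][x] += 1.0; cnt2[l][x] += 1.0; }
          else {
            double pxy = f1[l][x] * f2[l][y];
            double pyx = f1[l][y] * f2[l][x];
            if (unif_rand() * (pxy + pyx) <= pxy) { cnt1[l][x] += 1.0; cnt2[l][y] += 1.0; }
            else { cnt1[l][y] += 1.0; cnt2[l][x] += 1.0; }
          }
        } else {
          cnt2[l][x] += 1.0; cnt2[l][y] += 1.0;
        }
      }
    }
    // pool frequencies
    if (!fix_freqs) {
      for (int l = 0; l < L; l++) {
        int K = nall[l];
        alpha1.assign(K, freq_prior); alpha2.assign(K, freq_prior);
        for (int a = 0; a < K; a++) { alpha1[a] += cnt1[l][a]; alpha2[a] += cnt2[l][a]; }
        fr.resize(K);
        rdirichlet(fr, alpha1); f1[l] = fr;
        rdirichlet(fr, alpha2); f2[l] = fr;
      }
    }
    // mixing proportions
    if (!fix_pi) {
      std::vector<double> ac(C, 1.0);
      for (int i = 0; i < N; i++) ac[cls[i]] += 1.0;
      rdirichlet(pidir, ac);
      pi = pidir;
    }
    // accumulate
    if (it >= burn) {
      for (int i = 0; i < N; i++) qacc(i, cls[i]) += 1.0;
      for (int c = 0; c < C; c++) pisum[c] += pi[c];
      kept++;
      if ((it - burn) % 50 == 0 && tr < ntrace) lltrace[tr++] = lltot;
    }
  }
  for (int i = 0; i < N; i++)
    for (int c = 0; c < C; c++) qacc(i, c) /= kept;
  NumericVector pim(C);
  for (int c = 0; c < C; c++) pim[c] = pisum[c] / kept;
  List ff1(L), ff2(L);
  for (int l = 0; l < L; l++) { ff1[l] = wrap(f1[l]); ff2[l] = wrap(f2[l]); }
  return List::create(_["q"] = qacc, _["pi"] = pim,
                      _["loglik_trace"] = lltrace[Range(0, std::max(tr - 1, 0))],
                      _["f1"] = ff1, _["f2"] = ff2);
}
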