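#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Markov-chain Monte Carlo exact test of Hardy-Weinberg proportions.
//
// The null conditional distribution of genotype tables given the allele
// counts (Levene) is exactly the distribution induced by pairing the
// observed gene copies at random. The chain therefore walks over
// assignments of gene copies to individuals: each step picks two
// distinct individuals, one gene copy of each, and swaps them -- a
// symmetric proposal whose stationary distribution is uniform over
// copy arrangements, hence Levene's distribution over tables. No
// rejection step is needed.
//
// The chain runs `demem` dememorization steps, then `batches` batches
// of `iters` steps; the one-sided p-value is the mean occupancy of
// tables whose heterozygote count is as extreme as the observed one
// (deficit: H <= H_obs; excess: H >= H_obs), with a standard error
// from the batch means.
//
// g1, g2: 0-based allele indices per individual, no missing calls.
// Uses R's RNG (seed via set.seed in R).

// [[Rcpp::export]]
List hw_chain_cpp(IntegerVector g1, IntegerVector g2, int k,
                  int demem, int batches, int iters, bool deficit) {
  (void)k;  // allele count, kept for the call signature
  int n = g1.size();
  std::vector<int> a(g1.begin(), g1.end()), b(g2.begin(), g2.end());
  int H = 0;
  for (int i = 0; i < n; i++)
    if (a[i] != b[i]) H++;
  const int H0 = H;
  RNGScope scope;

  auto step = [&]() {
    int i = (int)(unif_rand() * n); if (i == n) i--;
    int j = (int)(unif_rand() * (n - 1)); if (j >= i) j++;
    int *pi = (unif_rand() < 0.5) ? &a[i] : &b[i];
    int *pj = (unif_rand() < 0.5) ? &a[j] : &b[j];
    int dh = -(a[i] != b[i]) - (a[j] != b[j]);
    std::swap(*pi, *pj);
    dh += (a[i] != b[i]) + (a[j] != b[j]);
    H += dh;
  };

  for (int s = 0; s < demem; s++) step();
  NumericVector bm(batches);
  for (int bt = 0; bt < batches; bt++) {
    long hit = 0;
    for (int s = 0; s < iters; s++) {
      step();
      bool extreme = deficit ? (H <= H0) : (H >= H0);
      if (extreme) hit++;
    }
    bm[bt] = (double)hit / iters;
  }
  double p = mean(bm);
  double se = (batches > 1) ? sd(bm) / std::sqrt((double)batches) : NA_REAL;
  return List::create(_["p"] = p, _["se"] = se, _["batch_means"] = bm);
}
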