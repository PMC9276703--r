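#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for differential proportion analysis.
//
// Each iteration draws a subsample fraction f ~ Uniform(w, 1), picks
// ceil(f * n) cells uniformly without replacement, shuffles the cluster
// labels within that subsample (group labels stay fixed), and recomputes the
// per-cluster proportion difference between groups A and B. Returns, per
// cluster, the count of iterations whose |null difference| is at least the
// observed |difference|. Uses R's RNG so results are reproducible under
// set.seed().
//
// cl: 1-based cluster codes; grp: 0 = other, 1 = group A, 2 = group B.
// [[Rcpp::export(name = ".dpa_null_count")]]
IntegerVector dpa_null_count(IntegerVector cl, IntegerVector grp,
                             int n_clusters, double w, int n_iter,
                             NumericVector obs_abs_diff) {
  int n = cl.size();
  int nA = 0, nB = 0;
  for (int i = 0; i < n; ++i) { if (grp[i] == 1) ++nA; else if (grp[i] == 2) ++nB; }
  IntegerVector exceed(n_clusters);
  std::vector<int> perm(n), labels(n), cntA(n_clusters), cntB(n_clusters);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int it = 0; it < n_iter; ++it) {
    double f = w + unif_rand() * (1.0 - w);
    int m = (int)std::ceil(f * n);
    if (m > n) m = n;
    // partial Fisher-Yates: first m entries of perm are the subsample
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < n; ++i) labels[i] = cl[i];
    // shuffle cluster labels within the subsample
    for (int i = m - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(labels[perm[i]], labels[perm[j]]);
    }
    std::fill(cntA.begin(), cntA.end(), 0);
    std::fill(cntB.begin(), cntB.end(), 0);
    for (int i = 0; i < n; ++i) {
      if (grp[i] == 1) ++cntA[labels[i] - 1];
      else if (grp[i] == 2) ++cntB[labels[i] - 1];
    }
    for (int k = 0; k < n_clusters; ++k) {
      double d = (double)cntA[k] / nA - (double)cntB[k] / nB;
      if (std::fabs(d) >= obs_abs_diff[k]) ++exceed[k];
    }
  }
  return exceed;
}
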