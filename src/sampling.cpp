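#include <Rcpp.h>
using namespace Rcpp;

// Intersection sizes of repeatedly drawn pairs of uniform random subsets.
//
// Each iteration draws two independent subsets of sizes n1 and n2 from a
// universe of u elements (each subset sampled without replacement, the two
// subsets independent of each other) and records the size of their
// intersection. Uses R's RNG so results are reproducible from set.seed().
//
// Subsets are drawn by partial Fisher-Yates shuffles over a shared index
// array; a partial shuffle with fresh randomness yields a uniform subset
// whatever the array's starting order, so the array is simply reused.
// [[Rcpp::export]]
IntegerVector pair_intersection_sizes(int u, int n1, int n2, int n_samples) {
  if (u < 1 || n1 < 0 || n2 < 0 || n1 > u || n2 > u || n_samples < 1)
    stop("invalid sampling sizes");
  IntegerVector out(n_samples);
  std::vector<int> perm(u);
  for (int i = 0; i < u; ++i) perm[i] = i;
  std::vector<char> member(u, 0);

  for (int s = 0; s < n_samples; ++s) {
    // draw set 1: first n1 slots after a partial shuffle
    for (int j = 0; j < n1; ++j) {
      int k = j + (int)(unif_rand() * (u - j));
      if (k >= u) k = u - 1;  // guard against unif_rand() == 1.0
      std::swap(perm[j], perm[k]);
      member[perm[j]] = 1;
    }
    // draw set 2 the same way and count overlap with set 1
    int inter = 0;
    for (int j = 0; j < n2; ++j) {
      int k = j + (int)(unif_rand() * (u - j));
      if (k >= u) k = u - 1;
      std::swap(perm[j], perm[k]);
      if (member[perm[j]]) ++inter;
    }
    out[s] = inter;
    std::fill(member.begin(), member.end(), 0);
  }
  return out;
}
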