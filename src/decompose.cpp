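#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Mendelian decomposition of inbreeding.
//
// For a candidate ancestor j, theta_j(a, b) is the probability that a
// random gamete of a and a random gamete of b are identical by descent
// with the shared allele copy created by j's Mendelian sampling (the
// "first shared allele-copy node" lies in j).  Tabular recursion with
// the self term 1/2 placed only at j:
//   theta(x, y) = 0.5 (theta(s_x, y) + theta(d_x, y))      (x later, x != y)
//   theta(c, c) = 0.5 [c == j] + 0.5 theta(s_c, d_c)
// The partial inbreeding coefficient of animal x for ancestor j is
// theta_j(s_x, d_x); summing over all j gives the parents' kinship,
// i.e. x's inbreeding coefficient, exactly.
//
// sire/dam: 1-based sorted parent indices (0 unknown);
// candidates, inbred: 1-based indices.  Returns triplets (x, j, F).
// [[Rcpp::export(name = ".partial_inbreeding_cpp")]]
List partial_inbreeding_cpp(IntegerVector sire, IntegerVector dam,
                            IntegerVector candidates, IntegerVector inbred) {
  const int n = sire.size();
  std::vector<double> th((size_t)n * n, 0.0);
  std::vector<int> outi, outj;
  std::vector<double> outx;

  for (int c = 0; c < candidates.size(); ++c) {
    const int j = candidates[c] - 1;
    // zero the active block (descendant indices >= j)
    for (int x = j; x < n; ++x)
      for (int y = j; y <= x; ++y) th[(size_t)x * n + y] = 0.0;
    for (int x = j; x < n; ++x) {
      const int s = sire[x] - 1, d = dam[x] - 1;
      for (int y = j; y < x; ++y) {
        double v = 0.0;
        if (s >= j) v += 0.5 * (s >= y ? th[(size_t)s * n + y] : th[(size_t)y * n + s]);
        if (d >= j) v += 0.5 * (d >= y ? th[(size_t)d * n + y] : th[(size_t)y * n + d]);
        th[(size_t)x * n + y] = v;
      }
      double self = (x == j) ? 0.5 : 0.0;
      if (s >= j && d >= j) {
        self += 0.5 * (s >= d ? th[(size_t)s * n + d] : th[(size_t)d * n + s]);
      }
      th[(size_t)x * n + x] = self;
    }
    for (int k = 0; k < inbred.size(); ++k) {
      const int x = inbred[k] - 1;
      const int s = sire[x] - 1, d = dam[x] - 1;
      if (s < j || d < j) continue;
      const double v = (s >= d) ? th[(size_t)s * n + d] : th[(size_t)d * n + s];
      if (v > 0.0) {
        outi.push_back(x + 1);
        outj.push_back(j + 1);
        outx.push_back(v);
      }
    }
  }
  return List::create(_["i"] = wrap(outi), _["j"] = wrap(outj), _["x"] = wrap(outx));
}

// Gene-dropping Monte Carlo oracle for the decomposition.
//
// Each replicate drops uniquely labelled allele copies through the
// pedigree: every transmission picks one of the parent's two slots.  An
// animal is autozygous when its two allele-copy lineages share a node;
// the replicate is attributed to the individual containing the first
// shared node (walking both lineages rootwards).  Counts are returned as
// a dense (animal x ancestor) matrix of autozygosity events.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gene_drop_cpp")]]
NumericMatrix gene_drop_cpp(IntegerVector sire, IntegerVector dam,
                            IntegerVector inbred, int nRep) {
  const int n = sire.size();
  NumericMatrix counts(n, n);
  // slot choice per (animal, own slot): which parental slot the copy came from
  std::vector<signed char> pick((size_t)2 * n);
  std::vector<int> stampArr((size_t)2 * n, -1);
  std::vector<int> pathNode;
  pathNode.reserve(64);
  int stamp = 0;

  for (int rep = 0; rep < nRep; ++rep) {
    for (size_t k = 0; k < pick.size(); ++k)
      pick[k] = (unif_rand() < 0.5) ? 0 : 1;
    for (int kk = 0; kk < inbred.size(); ++kk) {
      const int x = inbred[kk] - 1;
      if (sire[x] == 0 || dam[x] == 0) continue;
      ++stamp;
      // lineage of x's paternal allele: starts at (sire, chosen slot of sire)
      int ind = sire[x] - 1;
      int slot = pick[(size_t)2 * x + 0];
      while (ind >= 0) {
        const int node = 2 * ind + slot;
        stampArr[node] = stamp;
        const int par = (slot == 0) ? sire[ind] : dam[ind];
        if (par == 0) break;
        slot = pick[(size_t)2 * ind + slot];
        ind = par - 1;
      }
      // lineage of the maternal allele: stop at first node seen above
      ind = dam[x] - 1;
      slot = pick[(size_t)2 * x + 1];
      while (ind >= 0) {
        const int node = 2 * ind + slot;
        if (stampArr[node] == stamp) {
          counts(x, ind) += 1.0;
          break;
        }
        const int par = (slot == 0) ? sire[ind] : dam[ind];
        if (par == 0) break;
        slot = pick[(size_t)2 * ind + slot];
        ind = par - 1;
      }
    }
  }
  return counts;
}
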