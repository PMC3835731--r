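#include <Rcpp.h>
#include <unordered_set>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Degree-preserving randomization of a discretized bipartite miRNA-target
// graph. Double-edge swaps are proposed only between edges sharing a score
// level, so per-level family degrees and per-level gene degrees are conserved
// exactly. A proposal is rejected when it would duplicate an existing
// (family, gene) edge at ANY level: replicates must stay simple bipartite
// graphs or target-set sizes would change. Uses R's RNG, so results are
// reproducible under set.seed().
//
// Edge existence is tracked in a dense family x gene byte map when that fits
// comfortably in memory (the common case for family/gene universes of this
// method), falling back to a hash set otherwise.
//
// fam, gene: 0-based edge endpoints; level: integer score level per edge.
// Returns the permuted gene endpoint per edge (families stay put).
// [[Rcpp::export]]
IntegerVector stratified_swap_cpp(IntegerVector fam, IntegerVector gene,
                                  IntegerVector level, int n_fam,
                                  int n_genes, double swaps_per_edge) {
  const int n = fam.size();
  IntegerVector g = clone(gene);

  const long long cells = static_cast<long long>(n_fam) * n_genes;
  const bool dense = cells <= 200000000LL;
  std::vector<char> bitmap;
  std::unordered_set<long long> edgeset;
  if (dense) {
    bitmap.assign(static_cast<size_t>(cells), 0);
  } else {
    edgeset.reserve(static_cast<size_t>(n) * 2);
  }
  auto key = [n_genes](int f, int gg) {
    return static_cast<long long>(f) * n_genes + gg;
  };
  auto has = [&](int f, int gg) {
    return dense ? bitmap[key(f, gg)] != 0
                 : edgeset.count(key(f, gg)) > 0;
  };
  auto put = [&](int f, int gg, bool on) {
    if (dense) bitmap[key(f, gg)] = on ? 1 : 0;
    else if (on) edgeset.insert(key(f, gg));
    else edgeset.erase(key(f, gg));
  };
  for (int e = 0; e < n; ++e) put(fam[e], g[e], true);

  // deterministic level order (std::map is sorted)
  std::map<int, std::vector<int> > by_level;
  for (int e = 0; e < n; ++e) by_level[level[e]].push_back(e);

  for (std::map<int, std::vector<int> >::iterator it = by_level.begin();
       it != by_level.end(); ++it) {
    const std::vector<int>& idx = it->second;
    const int len = static_cast<int>(idx.size());
    if (len < 2) continue;  // frozen level, nothing to randomize
    const long nsw = static_cast<long>(std::ceil(swaps_per_edge * len));
    for (long t = 0; t < nsw; ++t) {  // budget counts attempted swaps
      int i = static_cast<int>(unif_rand() * len);
      int j = static_cast<int>(unif_rand() * len);
      if (i >= len) i = len - 1;
      if (j >= len) j = len - 1;
      if (i == j) continue;
      const int e1 = idx[i], e2 = idx[j];
      const int f1 = fam[e1], f2 = fam[e2];
      const int g1 = g[e1], g2 = g[e2];
      if (f1 == f2 || g1 == g2) continue;
      if (has(f1, g2) || has(f2, g1)) continue;
      put(f1, g1, false);
      put(f2, g2, false);
      put(f1, g2, true);
      put(f2, g1, true);
      g[e1] = g2;
      g[e2] = g1;
    }
  }
  return g;
}

// Enrichment scores for one gene assignment: ES[f, j] = sum over edges
// (f, g) with g in signature j of the edge's discretized score. Signature
// membership comes in as a compressed gene -> signatures list.
// [[Rcpp::export]]
NumericMatrix es_sparse_cpp(IntegerVector fam, IntegerVector gene,
                            IntegerVector level, int n_fam, int n_sig,
                            IntegerVector memb_ptr, IntegerVector memb_sig) {
  NumericMatrix es(n_fam, n_sig);
  const int n = fam.size();
  for (int e = 0; e < n; ++e) {
    const int f = fam[e];
    const double s = level[e];
    for (int k = memb_ptr[gene[e]]; k < memb_ptr[gene[e] + 1]; ++k)
      es(f, memb_sig[k]) += s;
  }
  return es;
}
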