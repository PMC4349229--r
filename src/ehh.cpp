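// Extended haplotype homozygosity decay away from a core allele.
//
// Among the n_c carriers of the core allele, EHH at an extension covering
// site set Sset is sum_h C(n_h, 2) / C(n_c, 2) over the distinct extended
// haplotypes h. Computed outward site-by-site on one flank by refining a
// partition of the carriers: two carriers stay in the same group iff they
// are identical over every site seen so far.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".ehh_flank_cpp")]]
List ehh_flank_cpp(const IntegerMatrix &haps, int core, int dir,
                   const IntegerVector &carriers, const NumericVector &pos,
                   double cutoff) {
  // core: 0-based site; dir: -1 left, +1 right; carriers: 0-based rows
  const int n = carriers.size();
  const int S = haps.ncol();
  const double denom = (double) n * (n - 1) / 2.0;
  std::vector<int> g(n, 0);
  std::vector<int> remap(2 * n + 2);
  std::vector<double> off, ehh;
  int trunc = 1;  // 1 = chromosome edge, 2 = reached cutoff
  for (int j = core + dir; j >= 0 && j < S; j += dir) {
    int ng = 0;
    std::fill(remap.begin(), remap.end(), -1);
    for (int i = 0; i < n; ++i) {
      int key = 2 * g[i] + haps(carriers[i], j);
      if (remap[key] < 0) remap[key] = ng++;
      g[i] = remap[key];
    }
    std::vector<int> sz(ng, 0);
    for (int i = 0; i < n; ++i) ++sz[g[i]];
    double num = 0.0;
    for (int k = 0; k < ng; ++k) num += (double) sz[k] * (sz[k] - 1) / 2.0;
    double e = num / denom;
    off.push_back(std::fabs(pos[j] - pos[core]));
    ehh.push_back(e);
    if (e < cutoff) { trunc = 2; break; }
    if (e == 0.0) { trunc = 2; break; }
  }
  return List::create(_["offset"] = wrap(off), _["ehh"] = wrap(ehh),
                      _["truncation"] = trunc == 2 ? "cutoff" : "edge");
}
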