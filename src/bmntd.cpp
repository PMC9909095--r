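#include <Rcpp.h>
using namespace Rcpp;

// Pairwise beta mean nearest taxon distance (bMNTD) between all sample pairs.
//
// coph: pool_size x pool_size cophenetic distance matrix over the regional
//       taxon pool (rows of `ab` index into it).
// ab:   pool_size x n_samples relative abundances (zero = absent).
// perm: 0-based permutation of pool indices; taxon i is treated as sitting on
//       tip perm[i]. The identity permutation gives the observed bMNTD; a
//       shuffled permutation gives one draw from the tip-shuffle null.
// weighted: abundance-weight the per-taxon nearest-taxon distances.
//
// bMNTD(u, v) = 0.5 * (mean_i w_i min_j d(i, j) + mean_j w_j min_i d(j, i))
// with i over taxa present in u and j over taxa present in v.
// [[Rcpp::export]]
NumericMatrix cpp_bmntd_pairs(const NumericMatrix& coph, const NumericMatrix& ab,
                              const IntegerVector& perm, bool weighted) {
  const int nt = ab.nrow(), ns = ab.ncol();
  std::vector< std::vector<int> > pres(ns);
  std::vector< std::vector<double> > w(ns);
  for (int s = 0; s < ns; s++) {
    for (int i = 0; i < nt; i++) {
      if (ab(i, s) > 0.0) { pres[s].push_back(perm[i]); w[s].push_back(ab(i, s)); }
    }
  }
  NumericMatrix out(ns, ns);
  for (int u = 0; u < ns; u++) {
    for (int v = u + 1; v < ns; v++) {
      double dir[2];
      for (int k = 0; k < 2; k++) {
        const std::vector<int>& A = (k == 0) ? pres[u] : pres[v];
        const std::vector<int>& B = (k == 0) ? pres[v] : pres[u];
        const std::vector<double>& wa = (k == 0) ? w[u] : w[v];
        double acc = 0.0, wtot = 0.0;
        for (size_t i = 0; i < A.size(); i++) {
          const double* col = &coph(0, A[i]);
          double mn = R_PosInf;
          for (size_t j = 0; j < B.size(); j++) {
            const double d = col[B[j]];
            if (d < mn) mn = d;
          }
          const double wi = weighted ? wa[i] : 1.0;
          acc += wi * mn; wtot += wi;
        }
        dir[k] = acc / wtot;
      }
      out(u, v) = out(v, u) = 0.5 * (dir[0] + dir[1]);
    }
  }
  return out;
}
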