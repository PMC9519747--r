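#include <Rcpp.h>
using namespace Rcpp;

// Curveball trades on a binary matrix, preserving row and column sums
// exactly. Rows are kept as sets of active column indices; one trade picks
// two distinct rows, pools the columns unique to each, and redistributes the
// pool at random between them. Uses R's RNG so results are reproducible from
// set.seed().
// [[Rcpp::export]]
IntegerMatrix curveball_shuffle(const IntegerMatrix& A, int n_trades) {
  const int nr = A.nrow(), nc = A.ncol();
  std::vector< std::vector<int> > rows(nr);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (A(i, j) != 0) rows[i].push_back(j);
    }
  }
  if (nr >= 2 && n_trades > 0) {
    std::vector<char> mark(nc, 0);
    std::vector<int> shared, pool;
    for (int t = 0; t < n_trades; ++t) {
      int i = (int)(unif_rand() * nr); if (i >= nr) i = nr - 1;
      int j = (int)(unif_rand() * (nr - 1)); if (j >= nr - 1) j = nr - 2;
      if (j >= i) ++j;
      std::vector<int>& ri = rows[i];
      std::vector<int>& rj = rows[j];
      for (size_t k = 0; k < rj.size(); ++k) mark[rj[k]] = 1;
      shared.clear(); pool.clear();
      for (size_t k = 0; k < ri.size(); ++k) {
        if (mark[ri[k]]) { shared.push_back(ri[k]); mark[ri[k]] = 2; }
        else pool.push_back(ri[k]);
      }
      const int n_only_i = (int)pool.size();
      for (size_t k = 0; k < rj.size(); ++k) {
        if (mark[rj[k]] == 1) pool.push_back(rj[k]);
        mark[rj[k]] = 0;
      }
      // Fisher-Yates on the pooled exclusive columns
      for (int k = (int)pool.size() - 1; k > 0; --k) {
        int m = (int)(unif_rand() * (k + 1)); if (m > k) m = k;
        std::swap(pool[k], pool[m]);
      }
      ri.assign(shared.begin(), shared.end());
      rj.assign(shared.begin(), shared.end());
      for (int k = 0; k < n_only_i; ++k) ri.push_back(pool[k]);
      for (int k = n_only_i; k < (int)pool.size(); ++k) rj.push_back(pool[k]);
    }
  }
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (size_t k = 0; k < rows[i].size(); ++k) out(i, rows[i][k]) = 1;
  }
  return out;
}
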