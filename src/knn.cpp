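#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Per-row selection of the k-1 smallest scores (excluding the diagonal),
// self index first, ties broken by ascending point index. Semantics must
// match the documented contract of knn_graph() exactly.
// [[Rcpp::export(name = ".knn_select")]]
IntegerMatrix knn_select(NumericMatrix m, int k) {
  const int n = m.nrow();
  IntegerMatrix idx(n, k);
  std::vector<int> ord(n);
  std::vector<double> s(n);
  for (int i = 0; i < n; ++i) {
    idx(i, 0) = i + 1;
    if (k == 1) continue;
    for (int j = 0; j < n; ++j) s[j] = m(i, j);
    s[i] = R_PosInf;
    std::iota(ord.begin(), ord.end(), 0);
    std::partial_sort(
        ord.begin(), ord.begin() + (k - 1), ord.end(),
        [&](int a, int b) {
          return s[a] < s[b] || (s[a] == s[b] && a < b);
        });
    for (int j = 0; j < k - 1; ++j) idx(i, j + 1) = ord[j] + 1;
  }
  return idx;
}
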