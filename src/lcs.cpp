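#include <Rcpp.h>
#include <string>
#include <vector>

// Longest-common-subsequence length by bottom-up dynamic programming.
// Only lengths are needed downstream (no traceback), so two rolling rows
// suffice; the full matrix variant lives in R for inspection and teaching.
// [[Rcpp::export(name = ".lcs_length_cpp")]]
int lcs_length_cpp(const std::string& a, const std::string& b) {
  const size_t m = a.size(), n = b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (size_t i = 1; i <= m; ++i) {
    for (size_t j = 1; j <= n; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
      } else {
        cur[j] = std::max(prev[j], cur[j - 1]);
      }
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
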