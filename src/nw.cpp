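#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Tie-breaking in the traceback is fixed: diagonal, then up (gap in b),
// then left (gap in a), so results are deterministic across platforms.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  std::vector<double> S((n + 1) * (m + 1));
  // 0 = diagonal, 1 = up (consume a, gap in b), 2 = left (gap in a)
  std::vector<unsigned char> T((n + 1) * (m + 1));
  const int W = m + 1;

  for (int i = 1; i <= n; ++i) { S[i * W] = i * gap; T[i * W] = 1; }
  for (int j = 1; j <= m; ++j) { S[j] = j * gap;     T[j] = 2; }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double diag = S[(i - 1) * W + (j - 1)] + (ai == b[j - 1] ? match : mismatch);
      double up   = S[(i - 1) * W + j] + gap;
      double left = S[i * W + (j - 1)] + gap;
      double best = diag; unsigned char tb = 0;
      if (up > best)   { best = up;   tb = 1; }
      if (left > best) { best = left; tb = 2; }
      S[i * W + j] = best;
      T[i * W + j] = tb;
    }
  }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  int matches = 0, mismatches = 0, gap_cols = 0;
  while (i > 0 || j > 0) {
    unsigned char tb = T[i * W + j];
    if (i > 0 && j > 0 && tb == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      --i; --j;
    } else if (i > 0 && (tb == 1 || j == 0)) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      ++gap_cols; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      ++gap_cols; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(
    _["aligned_a"] = ra,
    _["aligned_b"] = rb,
    _["score"] = S[n * W + m],
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["gap_columns"] = gap_cols);
}
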