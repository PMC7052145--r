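#include <Rcpp.h>
using namespace Rcpp;

// Maximal runs of 1s in a binary integer matrix along a given direction:
// 0 = diagonals (parallel to the main diagonal), 1 = columns, 2 = rows.
// Returns the lengths of all maximal runs (length >= 1).
// [[Rcpp::export(name = ".run_lengths")]]
IntegerVector run_lengths(const IntegerMatrix& r, const int direction) {
  const int n = r.nrow(), m = r.ncol();
  const int* x = INTEGER(r);
  std::vector<int> out;
  out.reserve(256);

  if (direction == 0) {
    // walk each diagonal; element (i, j) sits at x[i + j * n]
    for (int d = -(n - 1); d <= m - 1; ++d) {
      int i = d < 0 ? -d : 0;
      int j = d < 0 ? 0 : d;
      int len = std::min(n - i, m - j);
      const int* p = x + i + (std::size_t)j * n;
      int run = 0;
      for (int k = 0; k < len; ++k, p += n + 1) {
        if (*p) {
          ++run;
        } else if (run > 0) {
          out.push_back(run);
          run = 0;
        }
      }
      if (run > 0) out.push_back(run);
    }
  } else if (direction == 1) {
    const int* p = x;
    for (int j = 0; j < m; ++j) {
      int run = 0;
      for (int i = 0; i < n; ++i, ++p) {
        if (*p) {
          ++run;
        } else if (run > 0) {
          out.push_back(run);
          run = 0;
        }
      }
      if (run > 0) out.push_back(run);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      const int* p = x + i;
      int run = 0;
      for (int j = 0; j < m; ++j, p += n) {
        if (*p) {
          ++run;
        } else if (run > 0) {
          out.push_back(run);
          run = 0;
        }
      }
      if (run > 0) out.push_back(run);
    }
  }
  return wrap(out);
}
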