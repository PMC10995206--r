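#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Dense linear assignment by shortest augmenting paths with dual updates
// (Jonker-Volgenant style). Requires nrow <= ncol; entries >= LAP_FORBID are
// treated as forbidden. Returns 0-based column index per row, -1 if the row
// could only be matched through a forbidden edge.
static const double LAP_FORBID = 1e30;

// [[Rcpp::export]]
IntegerVector cpp_lap(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n > m) stop("cpp_lap: need nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n, 0.0), v(m, 0.0);
  std::vector<int> col4row(n, -1), row4col(m, -1);
  std::vector<double> shortest(m);
  std::vector<int> path(m);
  std::vector<char> SR(n), SC(m);

  for (int cur = 0; cur < n; ++cur) {
    std::fill(shortest.begin(), shortest.end(), INF);
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    std::fill(path.begin(), path.end(), -1);

    int sink = -1, i = cur;
    double minVal = 0.0;
    while (sink == -1) {
      SR[i] = 1;
      int index = -1;
      double lowest = INF;
      for (int j = 0; j < m; ++j) {
        if (SC[j]) continue;
        double cij = cost(i, j);
        if (cij >= LAP_FORBID) cij = INF;
        double r = minVal + cij - u[i] - v[j];
        if (r < shortest[j]) { path[j] = i; shortest[j] = r; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1)) {
          lowest = shortest[j];
          index = j;
        }
      }
      if (!std::isfinite(lowest)) stop("cpp_lap: infeasible cost matrix");
      minVal = lowest;
      sink = index;
      SC[sink] = 1;
      if (row4col[sink] != -1) { i = row4col[sink]; sink = -1; }
    }

    u[cur] += minVal;
    for (int k = 0; k < n; ++k)
      if (SR[k] && k != cur) u[k] += minVal - shortest[col4row[k]];
    for (int j = 0; j < m; ++j)
      if (SC[j]) v[j] -= minVal - shortest[j];

    // augment along the alternating path
    int j = sink;
    while (true) {
      int irow = path[j];
      row4col[j] = irow;
      int tmp = col4row[irow];
      col4row[irow] = j;
      if (irow == cur) break;
      j = tmp;
    }
  }

  IntegerVector out(n);
  for (int k = 0; k < n; ++k) out[k] = col4row[k];
  return out;
}
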