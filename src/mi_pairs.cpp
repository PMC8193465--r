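#include <Rcpp.h>
using namespace Rcpp;

// Plug-in mutual information (bits) between every column of `a` and every
// column of `b`. Columns are transcripts, rows are samples; entries are
// equal-frequency bin labels in 1..n_bins. Returns an ncol(a) x ncol(b)
// matrix of MI estimates. Joint/marginal counts are integers bounded by the
// sample count, so all logarithms come from one precomputed table.
// [[Rcpp::export]]
NumericMatrix mi_all_pairs_labels(IntegerMatrix a, IntegerMatrix b, int n_bins) {
  const int na = a.ncol(), nb = b.ncol(), n = a.nrow();
  if (b.nrow() != n) stop("label matrices must share the sample dimension");
  if (n_bins < 2) stop("n_bins must be >= 2");
  for (int i = 0; i < na * n; ++i)
    if (a[i] < 1 || a[i] > n_bins) stop("labels out of range");
  for (int i = 0; i < nb * n; ++i)
    if (b[i] < 1 || b[i] > n_bins) stop("labels out of range");

  std::vector<double> lg(n + 1, 0.0); // lg[i] = log2(i)
  const double ln2 = std::log(2.0);
  for (int i = 1; i <= n; ++i) lg[i] = std::log((double)i) / ln2;
  const double lgn = lg[n];

  NumericMatrix out(na, nb);
  std::vector<int> joint(n_bins * n_bins);
  std::vector<int> ma(n_bins), mb(n_bins);
  for (int i = 0; i < na; ++i) {
    const int *ai = &a(0, i);
    std::fill(ma.begin(), ma.end(), 0);
    for (int s = 0; s < n; ++s) ma[ai[s] - 1]++;
    for (int j = 0; j < nb; ++j) {
      const int *bj = &b(0, j);
      std::fill(joint.begin(), joint.end(), 0);
      std::fill(mb.begin(), mb.end(), 0);
      for (int s = 0; s < n; ++s) {
        joint[(ai[s] - 1) * n_bins + (bj[s] - 1)]++;
        mb[bj[s] - 1]++;
      }
      double mi = 0.0;
      for (int x = 0; x < n_bins; ++x) {
        if (ma[x] == 0) continue;
        const int *row = &joint[x * n_bins];
        const double lmx = lg[ma[x]];
        for (int y = 0; y < n_bins; ++y) {
          const int c = row[y];
          if (c == 0) continue;
          mi += (double)c * (lg[c] + lgn - lmx - lg[mb[y]]);
        }
      }
      mi /= n;
      out(i, j) = mi > 0.0 ? mi : 0.0;
    }
  }
  return out;
}

// Equal-frequency bin labels for every column of `x` (samples in rows).
// Rank-based with minimum-rank tie handling: label = ceil(rank * n_bins / n),
// so tied values always share one bin.
// [[Rcpp::export]]
IntegerMatrix discretize_columns(NumericMatrix x, int n_bins) {
  const int n = x.nrow(), p = x.ncol();
  if (n_bins < 2 || n_bins > n) stop("need 2 <= n_bins <= n");
  IntegerMatrix out(n, p);
  std::vector<int> ord(n);
  for (int j = 0; j < p; ++j) {
    const double *col = &x(0, j);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [col](int u, int v) { return col[u] < col[v]; });
    int r = 0; // minimum rank of the current tie run (0-based)
    for (int i = 0; i < n; ++i) {
      if (i > 0 && col[ord[i]] != col[ord[i - 1]]) r = i;
      out(ord[i], j) = (int)std::ceil((double)(r + 1) * n_bins / n);
    }
  }
  return out;
}
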