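#include <Rcpp.h>
using namespace Rcpp;

// Rosenstein-style mean log-divergence curve. emb is the M x d delay
// embedding; for each point the nearest Euclidean neighbour with temporal
// separation > min_tsep is found, then the mean over points of
// log(distance after k steps) is returned for k = 1..kmax (NaN where no
// pair remains in range or all distances are zero).
// [[Rcpp::export]]
NumericVector lyap_divergence(NumericMatrix emb, int min_tsep, int kmax) {
  const int M = emb.nrow(), d = emb.ncol();
  std::vector<int> nb(M, -1);
  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= min_tsep) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = emb(i, c) - emb(j, c);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; nb[i] = j; }
    }
  }
  NumericVector curve(kmax, NA_REAL);
  for (int k = 1; k <= kmax; ++k) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < M; ++i) {
      int j = nb[i];
      if (j < 0 || i + k >= M || j + k >= M) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = emb(i + k, c) - emb(j + k, c);
        s += diff * diff;
      }
      if (s > 0.0) { acc += 0.5 * std::log(s); ++cnt; }
    }
    if (cnt > 0) curve[k - 1] = acc / cnt;
  }
  return curve;
}
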