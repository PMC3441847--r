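#include <Rcpp.h>
using namespace Rcpp;

// Log-odds scores at every start position of one coded sequence.
// codes: 1..4 for A,C,G,T; anything else (e.g. 0 for N) poisons the window.
// lo: L x 4 log-odds matrix. Positions overlapping an invalid code score -Inf.
// [[Rcpp::export]]
NumericVector scan_scores_cpp(IntegerVector codes, NumericMatrix lo) {
  const int n = codes.size(), L = lo.nrow();
  const int np = n - L + 1;
  if (np < 1) return NumericVector(0);
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double s = 0.0;
    bool ok = true;
    for (int i = 0; i < L; ++i) {
      const int c = codes[p + i];
      if (c < 1 || c > 4) { ok = false; break; }
      s += lo(i, c - 1);
    }
    out[p] = ok ? s : R_NegInf;
  }
  return out;
}

// Hits (score >= cutoff) over a list of coded sequences.
// Returns parallel vectors: 1-based sequence index, 0-based start, score.
// [[Rcpp::export]]
List scan_set_cpp(List codes, NumericMatrix lo, double cutoff) {
  const int L = lo.nrow();
  std::vector<int> seq_idx, starts;
  std::vector<double> scores;
  for (int s = 0; s < codes.size(); ++s) {
    IntegerVector cs = codes[s];
    const int np = cs.size() - L + 1;
    for (int p = 0; p < np; ++p) {
      double sc = 0.0;
      bool ok = true;
      for (int i = 0; i < L; ++i) {
        const int c = cs[p + i];
        if (c < 1 || c > 4) { ok = false; break; }
        sc += lo(i, c - 1);
      }
      if (ok && sc >= cutoff) {
        seq_idx.push_back(s + 1);
        starts.push_back(p);
        scores.push_back(sc);
      }
    }
  }
  return List::create(_["seq"] = wrap(seq_idx), _["start"] = wrap(starts),
                      _["score"] = wrap(scores));
}

// All finite scores pooled over a list of coded sequences, plus the number of
// scoreable (N-free) positions. Used for empirical threshold calibration.
// [[Rcpp::export]]
List pool_scores_cpp(List codes, NumericMatrix lo) {
  const int L = lo.nrow();
  std::vector<double> scores;
  long long nvalid = 0;
  for (int s = 0; s < codes.size(); ++s) {
    IntegerVector cs = codes[s];
    const int np = cs.size() - L + 1;
    for (int p = 0; p < np; ++p) {
      double sc = 0.0;
      bool ok = true;
      for (int i = 0; i < L; ++i) {
        const int c = cs[p + i];
        if (c < 1 || c > 4) { ok = false; break; }
        sc += lo(i, c - 1);
      }
      if (ok) { scores.push_back(sc); ++nvalid; }
    }
  }
  return List::create(_["scores"] = wrap(scores),
                      _["n_valid"] = (double)nvalid);
}
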