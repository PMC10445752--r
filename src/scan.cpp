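#include <Rcpp.h>
using namespace Rcpp;

// Motif hit scanning over integer-encoded sequences (A=0, C=1, G=2, T=3,
// anything else = N). Scores are pre-discretized integer log-odds; a
// sequence is a hit for a motif if any window on either strand reaches the
// motif's integer threshold. Windows containing N never match.

// [[Rcpp::export]]
LogicalMatrix scan_hits_cpp(List seqs, List mats, List rcmats,
                            IntegerVector thresholds) {
  const int nseq = seqs.size();
  const int nmot = mats.size();
  LogicalMatrix out(nseq, nmot);
  for (int m = 0; m < nmot; ++m) {
    IntegerMatrix S = mats[m];
    IntegerMatrix R = rcmats[m];
    const int L = S.ncol();
    const long long thr = thresholds[m];
    for (int s = 0; s < nseq; ++s) {
      IntegerVector q = seqs[s];
      const int n = q.size();
      bool hit = false;
      for (int pos = 0; pos + L <= n && !hit; ++pos) {
        long long fs = 0, rs = 0;
        bool ok = true;
        for (int j = 0; j < L; ++j) {
          const int b = q[pos + j];
          if (b < 0 || b > 3) { ok = false; break; }
          fs += S(b, j);
          rs += R(b, j);
        }
        if (ok && (fs >= thr || rs >= thr)) hit = true;
      }
      out(s, m) = hit;
    }
  }
  return out;
}
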