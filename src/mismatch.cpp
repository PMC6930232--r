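#include <Rcpp.h>
using namespace Rcpp;

// Batch ungapped comparison: candidate i compares query bytes
// [q_start[i], q_start[i]+len[i]) against target bytes starting at
// t_start[i]. Offsets are 0-based into the concatenated raw vectors.
// [[Rcpp::export(name = ".mismatch_counts")]]
IntegerVector mismatch_counts(RawVector target, IntegerVector t_start,
                              RawVector query, IntegerVector q_start,
                              IntegerVector len) {
  const int n = t_start.size();
  if (q_start.size() != n || len.size() != n)
    stop("t_start, q_start and len must have equal length");
  IntegerVector out(n);
  const Rbyte *tp = RAW(target), *qp = RAW(query);
  const R_xlen_t tn = target.size(), qn = query.size();
  for (int i = 0; i < n; ++i) {
    const int L = len[i];
    if (t_start[i] < 0 || q_start[i] < 0 || t_start[i] + L > tn ||
        q_start[i] + L > qn)
      stop("candidate %d out of bounds", i + 1);
    const Rbyte *a = tp + t_start[i], *b = qp + q_start[i];
    int mm = 0;
    for (int j = 0; j < L; ++j) mm += (a[j] != b[j]);
    out[i] = mm;
  }
  return out;
}
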