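#include <Rcpp.h>
using namespace Rcpp;

// All-pairs interval overlap join on 0-based half-open intervals.
//
// Inputs are parallel vectors (integer chromosome codes, starts, ends) for
// a query and a subject set, each sorted by (chrom, start); `ord_*` give
// the original 1-based row indices so callers can report in input order.
// A pair is emitted when both intervals share >= min_overlap bases on the
// same chromosome. Within a chromosome block the scan for each query
// starts at the first subject whose end can still reach it, so the cost is
// near-linear for peak-like data where interval widths are bounded.
// [[Rcpp::export]]
List interval_overlap_pairs(IntegerVector chr_q, IntegerVector s_q, IntegerVector e_q,
                            IntegerVector ord_q,
                            IntegerVector chr_s, IntegerVector s_s, IntegerVector e_s,
                            IntegerVector ord_s,
                            int min_overlap) {
  const int nq = chr_q.size(), ns = chr_s.size();
  std::vector<int> qi, si, ov;
  int block = 0;  // start of the current subject chromosome block
  for (int i = 0; i < nq; ++i) {
    // advance to the subject block for this query's chromosome
    while (block < ns && chr_s[block] < chr_q[i]) ++block;
    if (block == ns) break;
    if (chr_s[block] > chr_q[i]) continue;
    for (int j = block; j < ns && chr_s[j] == chr_q[i]; ++j) {
      if (s_s[j] > e_q[i] - min_overlap) break;  // sorted by start: no more hits
      int o = std::min(e_q[i], e_s[j]) - std::max(s_q[i], s_s[j]);
      if (o >= min_overlap) {
        qi.push_back(ord_q[i]);
        si.push_back(ord_s[j]);
        ov.push_back(o);
      }
    }
  }
  return List::create(_["query"] = wrap(qi), _["subject"] = wrap(si),
                      _["overlap"] = wrap(ov));
}
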