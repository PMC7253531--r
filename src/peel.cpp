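#include <Rcpp.h>
using namespace Rcpp;

// Iterative peeling on a dF/F0 trace (percent units).
//
// A Schmitt trigger locates events: the detector arms when the residual
// rises above `high`, and releases when it falls below `low`; an event is
// accepted if it stays armed for at least `min_dur` frames (or runs to the
// end of the trace). A spike is registered at the event-onset frame, the
// single-spike template is subtracted from the residual starting at that
// frame, and scanning resumes at the onset. At most one spike is registered
// per frame; if an onset frame is already taken, scanning moves past it.
//
// [[Rcpp::export(name = ".peel_core")]]
List peel_core(NumericVector x, double high, double low, int min_dur,
               NumericVector templ, int max_iter) {
  int n = x.size();
  NumericVector res = clone(x);
  std::vector<int> onsets;           // 1-based frame indices
  std::vector<bool> taken(n, false);
  int pos = 0;                       // 0-based scan position
  int iter = 0;
  bool converged = true;

  while (pos < n) {
    // find next armed onset at or after pos (detector assumed released)
    int onset = -1;
    for (int i = pos; i < n; ++i) {
      if (res[i] > high) { onset = i; break; }
    }
    if (onset < 0) break;

    // measure armed run length: from onset until release below `low`
    int end = onset;
    while (end < n && res[end] >= low) ++end;
    int run = end - onset;
    // events truncated by the end of the trace are kept
    bool accepted = (run >= min_dur) || (end == n);

    if (!accepted) { pos = end; continue; }

    if (taken[onset]) {              // one spike per frame at most
      pos = onset + 1;
      continue;
    }

    if (++iter > max_iter) { converged = false; break; }

    taken[onset] = true;
    onsets.push_back(onset + 1);
    int m = templ.size();
    for (int k = 0; k < m && onset + k < n; ++k) res[onset + k] -= templ[k];
    pos = onset;                     // re-scan from the onset
  }

  std::sort(onsets.begin(), onsets.end());
  return List::create(_["onsets"] = wrap(onsets),
                      _["residual"] = res,
                      _["converged"] = converged);
}
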