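#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right matcher against a cyclic key pattern.
//
// A press matching the expected pattern position advances the position;
// completing the pattern increments the sequence count and wraps to the
// start.  A mismatching press resets the position and is immediately
// re-tested as a potential pattern start ("reset-then-retest"), so a
// stray press never hides a genuinely completed following sequence.
// Keys outside the pattern alphabet are ordinary mismatches.
//
// Returns the number of completed sequences, the length of the trailing
// partial match, and the 1-based press indices bounding each completed
// sequence (used downstream for per-sequence tapping speeds).
// [[Rcpp::export]]
List match_pattern_cpp(IntegerVector keys, IntegerVector pattern) {
  const int L = pattern.size();
  const int n = keys.size();
  int pos = 0, complete = 0, cur_start = 0;
  std::vector<int> starts, ends;
  for (int i = 0; i < n; ++i) {
    const int k = keys[i];
    if (k != NA_INTEGER && k == pattern[pos]) {
      if (pos == 0) cur_start = i + 1;
      ++pos;
      if (pos == L) {
        ++complete;
        starts.push_back(cur_start);
        ends.push_back(i + 1);
        pos = 0;
      }
    } else {
      pos = 0;
      if (k != NA_INTEGER && k == pattern[0]) {
        pos = 1;
        cur_start = i + 1;
      }
    }
  }
  return List::create(_["complete"] = complete,
                      _["partial"] = pos,
                      _["seq_start"] = wrap(starts),
                      _["seq_end"] = wrap(ends));
}

// Batch form over a concatenated event stream.  trial_start/trial_end are
// 1-based bounds of each trial's slice of `keys`; an empty trial is
// encoded as trial_start > trial_end.  Sequence bounds are returned as
// global indices into `keys` together with the trial they belong to.
// [[Rcpp::export]]
List score_events_cpp(IntegerVector keys, IntegerVector trial_start,
                      IntegerVector trial_end, IntegerVector pattern) {
  const int L = pattern.size();
  const int m = trial_start.size();
  IntegerVector complete(m), partial(m), total(m);
  std::vector<int> seq_trial, seq_s, seq_e;
  for (int t = 0; t < m; ++t) {
    int pos = 0, comp = 0, cur_start = 0;
    const int a = trial_start[t], b = trial_end[t];
    for (int i = a - 1; i < b; ++i) {
      const int k = keys[i];
      if (k != NA_INTEGER && k == pattern[pos]) {
        if (pos == 0) cur_start = i + 1;
        ++pos;
        if (pos == L) {
          ++comp;
          seq_trial.push_back(t + 1);
          seq_s.push_back(cur_start);
          seq_e.push_back(i + 1);
          pos = 0;
        }
      } else {
        pos = 0;
        if (k != NA_INTEGER && k == pattern[0]) {
          pos = 1;
          cur_start = i + 1;
        }
      }
    }
    complete[t] = comp;
    partial[t] = pos;
    total[t] = (b >= a) ? (b - a + 1) : 0;
  }
  return List::create(_["complete"] = complete,
                      _["partial"] = partial,
                      _["total"] = total,
                      _["seq_trial"] = wrap(seq_trial),
                      _["seq_start"] = wrap(seq_s),
                      _["seq_end"] = wrap(seq_e));
}
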