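#include <Rcpp.h>
using namespace Rcpp;

// Single-window (SW) coincidence walk over a time-sorted event list.
// An event arriving with no open window opens a window of length tau;
// events with time - t_open <= tau fall inside (closed boundary). When the
// window closes with exactly one extra event the opener and that event form
// a prompt; with two or more extras all involved singles are discarded as a
// multiple coincidence; with none the opener is dropped. The next
// unconsumed event opens the next window, so no single is used twice.
// Returns 1-based indices of the two members of each prompt.

// [[Rcpp::export(name = ".windowWalk")]]
List window_walk(NumericVector time, double tau) {
  const int n = time.size();
  std::vector<int> a, b;
  a.reserve(n / 4 + 1);
  b.reserve(n / 4 + 1);
  int multiples = 0;
  int i = 0;
  while (i < n) {
    const double t0 = time[i];
    int j = i + 1;
    while (j < n && time[j] - t0 <= tau) ++j;
    const int extra = j - i - 1;
    if (extra == 1) {
      a.push_back(i + 1);
      b.push_back(i + 2);
    } else if (extra >= 2) {
      ++multiples;
    }
    i = j;
  }
  return List::create(_["a"] = wrap(a), _["b"] = wrap(b),
                      _["nMultiples"] = multiples);
}
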