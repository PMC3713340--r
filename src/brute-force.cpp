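#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Independent brute-force oracle for the background model: enumerates every
// sequence of length n over {A,C,G,T} and scans each one literally for
// maximal cores (TGAC/TTGAC plus strand, GTCA/GTCAA minus strand), testing
// all core pairs for a linker in [0, max_linker]. Shares no machinery with
// the dynamic-programming computation it validates.
//
// Base encoding: 0=A, 1=C, 2=G, 3=T.

static bool has_dyad(const int* s, int n, int max_linker) {
  std::vector<int> starts, ends;
  for (int i = 0; i + 3 < n; ++i) {
    if (s[i] == 3 && s[i + 1] == 2 && s[i + 2] == 0 && s[i + 3] == 1) {
      // TGAC; maximal start one base left when preceded by T (TTGAC)
      int st = (i > 0 && s[i - 1] == 3) ? i - 1 : i;
      starts.push_back(st);
      ends.push_back(i + 3);
    } else if (s[i] == 2 && s[i + 1] == 3 && s[i + 2] == 1 && s[i + 3] == 0) {
      // GTCA; maximal end one base right when followed by A (GTCAA)
      int en = (i + 4 < n && s[i + 4] == 0) ? i + 4 : i + 3;
      starts.push_back(i);
      ends.push_back(en);
    }
  }
  int k = (int)starts.size();
  for (int a = 0; a < k; ++a)
    for (int b = a + 1; b < k; ++b) {
      int linker = starts[b] - ends[a] - 1;
      if (linker >= 0 && linker <= max_linker) return true;
    }
  return false;
}

static void recurse(std::vector<int>& s, int pos, int n, double prob,
                    const double* p, int max_linker, double& acc) {
  if (prob == 0.0) return;
  if (pos == n) {
    if (has_dyad(s.data(), n, max_linker)) acc += prob;
    return;
  }
  for (int b = 0; b < 4; ++b) {
    s[pos] = b;
    recurse(s, pos + 1, n, prob * p[b], p, max_linker, acc);
  }
}

// [[Rcpp::export(name = ".dyad_rate_exhaustive")]]
double dyad_rate_exhaustive(int n, NumericVector base_probs, int max_linker) {
  if (n < 1 || base_probs.size() != 4) stop("bad arguments");
  if (n > 14) stop("exhaustive enumeration capped at n = 14");
  std::vector<int> s(n, 0);
  double acc = 0.0;
  recurse(s, 0, n, 1.0, REAL(base_probs), max_linker, acc);
  return acc;
}
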