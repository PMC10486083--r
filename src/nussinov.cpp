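#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization (Nussinov) over Watson-Crick (+ optional G:U)
// pairs with a minimum hairpin loop. Returns the 0-based partner index for
// each position (-1 when unpaired) from a deterministic traceback:
// pairing (i,j) is preferred, then leaving an end unpaired, then the
// bifurcation with the smallest split point.

static inline bool can_pair(char a, char b, bool allow_gu) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if (allow_gu && ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'))) return true;
  return false;
}

// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerVector nussinov_pairs(std::string seq, int min_loop, bool allow_gu) {
  int n = (int) seq.size();
  IntegerVector partner(n, -1);
  if (n < min_loop + 2) return partner;

  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];                       // i unpaired
      if (M[i][j - 1] > best) best = M[i][j - 1];   // j unpaired
      if (j - i > min_loop && can_pair(seq[i], seq[j], allow_gu)) {
        int v = (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0) + 1;
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {             // bifurcation
        int v = M[i][k] + M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // iterative traceback
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    int m = M[i][j];
    if (m == 0) continue;
    if (j - i > min_loop && can_pair(seq[i], seq[j], allow_gu) &&
        m == (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0) + 1) {
      partner[i] = j; partner[j] = i;
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    if (m == M[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
    if (m == M[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
    bool done = false;
    for (int k = i + 1; k < j && !done; ++k) {
      if (M[i][k] + M[k + 1][j] == m) {
        stack.push_back(std::make_pair(k + 1, j));
        stack.push_back(std::make_pair(i, k));
        done = true;
      }
    }
    if (!done) stop("traceback failed (internal error)");
  }
  return partner;
}
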