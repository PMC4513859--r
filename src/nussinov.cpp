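#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Watson-Crick plus GU wobble on the DNA alphabet (T stands for U).
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default:  return false; // N and friends never pair
  }
}

// Base-pair maximization (Nussinov) with a minimum hairpin loop of
// `min_loop` unpaired nucleotides, i.e. no pair (i, j) with j - i < min_loop + 1.
// Traceback is deterministic: at each subproblem the leftmost base is paired
// whenever some optimal structure pairs it, and to its leftmost optimal
// partner, so ties always resolve to the structure whose sorted pair list is
// lexicographically earliest.
//
// Returns a 1-based partner table, 0 = unpaired.
// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerVector nussinov_pairs(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  IntegerVector pt(n);
  std::fill(pt.begin(), pt.end(), 0);
  if (n < min_loop + 2) return pt;

  // M[i][j] = max pairs within seq[i..j], 0-based inclusive.
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = M[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int cand = 1;
        cand += M[i + 1][k - 1];
        if (k < j) cand += M[k + 1][j];
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }

  // Iterative traceback, leftmost-first.
  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int cand = 1 + M[i + 1][k - 1] + (k < j ? M[k + 1][j] : 0);
      if (cand == M[i][j]) {
        pt[i] = k + 1;
        pt[k] = i + 1;
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        stack.push_back(std::make_pair(i + 1, k - 1));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return pt;
}

// All exact occurrences of `pattern` in `subject` with at most `max_mismatch`
// mismatches (ungapped, same length windows). Returns 1-based start positions
// interleaved with mismatch counts: c(pos1, mm1, pos2, mm2, ...).
// [[Rcpp::export(name = ".mismatch_scan")]]
IntegerVector mismatch_scan(std::string subject, std::string pattern,
                            int max_mismatch = 0) {
  const int n = (int) subject.size(), m = (int) pattern.size();
  std::vector<int> out;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int k = 0; k < m; ++k) {
      if (subject[s + k] != pattern[k] && ++mm > max_mismatch) break;
    }
    if (mm <= max_mismatch) { out.push_back(s + 1); out.push_back(mm); }
  }
  return wrap(out);
}
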