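#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

// Base-pair maximization (Nussinov) with a minimum hairpin loop and an
// optional GU wobble.  Returns a 1-based pair table: p[i] = j if (i, j)
// are paired, 0 if i is unpaired.  Traceback is deterministic: at each
// interval the 5' base is paired with the smallest admissible partner
// achieving the maximum, otherwise left unpaired.

static inline int code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': case 'U': return 3;
    case 'N': return 4;
    default: return -1;
  }
}

static inline bool pairable(int a, int b, bool gu) {
  if (a > 3 || b > 3) return false;             // N never pairs
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return true;  // A:T
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return true;  // C:G
  if (gu && ((a == 2 && b == 3) || (a == 3 && b == 2))) return true; // G:T
  return false;
}

// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerVector nussinov_pairs(std::string seq, int min_loop, bool allow_gu) {
  const int n = (int) seq.size();
  IntegerVector pairs(n, 0);
  if (n == 0) return pairs;

  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    int c = code(seq[i]);
    if (c < 0) stop("non-nucleotide symbol '%s' at position %d",
                    std::string(1, seq[i]).c_str(), i + 1);
    s[i] = c;
  }

  // M[i*n + j] = max pairs on s[i..j]; MT is the transpose so the
  // bifurcation term M[k+1][j] is a contiguous scan.
  std::vector<int> M((size_t) n * n, 0), MT((size_t) n * n, 0);
  // ok[b*n + k]: can base code b pair with s[k]?
  std::vector<unsigned char> ok((size_t) 5 * n, 0);
  for (int b = 0; b < 5; ++b)
    for (int k = 0; k < n; ++k)
      ok[(size_t) b * n + k] = pairable(b, s[k], allow_gu) ? 1 : 0;
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      const int *Mi1 = &M[(size_t)(i + 1) * n];
      const int *MTj = &MT[(size_t) j * n];
      const unsigned char *oki = &ok[(size_t) s[i] * n];
      int best = Mi1[j];  // i unpaired
      for (int k = i + min_loop + 1; k < j; ++k) {
        if (!oki[k]) continue;
        const int v = 1 + Mi1[k - 1] + MTj[k + 1];
        if (v > best) best = v;
      }
      if (oki[j]) {
        const int v = 1 + Mi1[j - 1];
        if (v > best) best = v;
      }
      M[(size_t) i * n + j] = best;
      MT[(size_t) j * n + i] = best;
    }
  }

  // Iterative traceback; prefer pairing the 5' base with its most
  // distant admissible partner (pairing (i, j) wins over a
  // bifurcation), else leave it unpaired.  This keeps long designed or
  // biological stems intact when equal-count local alternatives exist.
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = M[(size_t) i * n + j];
    if (target == 0) continue;
    bool paired = false;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!pairable(s[i], s[k], allow_gu)) continue;
      int v = 1 + M[(size_t)(i + 1) * n + (k - 1)];
      if (k < j) v += M[(size_t)(k + 1) * n + j];
      if (v == target) {
        pairs[i] = k + 1;
        pairs[k] = i + 1;
        stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return pairs;
}
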