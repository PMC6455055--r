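#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Simplified per-pair energy model: GC -3, AU -2, GU -1 kcal/mol, 0 otherwise.
static inline int pair_energy_code(int a, int b) {
  // codes: A=0, C=1, G=2, U=3
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1;
  return 0;
}

static inline int encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': return 3;
    default: return -1;
  }
}

// Nussinov-style minimum-energy folding with a per-pair energy model and a
// minimum hairpin loop of `min_loop` unpaired bases.  Ties in the traceback
// are broken toward pairing the 5'-most base (and its closest admissible
// partner), which makes the reported structure deterministic.
// [[Rcpp::export(name = ".fold_nussinov_cpp")]]
List fold_nussinov_cpp(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = encode_base(seq[i]);
    if (s[i] < 0) stop("non-RNA character '%s' at position %d",
                       std::string(1, seq[i]).c_str(), i + 1);
  }
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);

  // E[i][j] = minimum energy of subsequence i..j (0-based, inclusive)
  std::vector<std::vector<int> > E(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = E[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int e = pair_energy_code(s[i], s[k]);
        if (e == 0) continue;
        int inner = (k - i - 1 > min_loop) ? E[i + 1][k - 1] : 0;
        int rest = (k < j) ? E[k + 1][j] : 0;
        int cand = e + inner + rest;
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }

  // traceback, preferring to pair position i whenever that attains E[i][j]
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = E[i][j];
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int e = pair_energy_code(s[i], s[k]);
      if (e == 0) continue;
      int inner = (k - i - 1 > min_loop) ? E[i + 1][k - 1] : 0;
      int rest = (k < j) ? E[k + 1][j] : 0;
      if (e + inner + rest == target) {
        db[i] = '(';
        db[k] = ')';
        if (k - i - 1 > min_loop) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired && E[i + 1][j] == target) {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }

  return List::create(_["structure"] = db, _["mfe"] = (double) E[0][n - 1]);
}
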