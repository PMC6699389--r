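#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) used by the internal
// folding backend. Pair weights GC=3, AU=2, GU=1; minimum hairpin loop of
// 3 unpaired nucleotides. Reported "energy" is the negated pair-weight sum,
// a coarse stand-in for kcal/mol on the same ordering.

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  // M[i][j]: best score on [i, j]
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];            // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int w = pair_weight(seq[k], seq[j]);
        if (w == 0) continue;
        int sc = w + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
        if (sc > best) best = sc;        // strict: deterministic tie-break
      }
      M[i][j] = best;
    }
  }

  IntegerVector pt(n, 0);                // 1-based partner, 0 = unpaired
  std::string db(n, '.');
  // iterative traceback
  std::stack< std::pair<int,int> > st;
  if (n > 0) st.push(std::make_pair(0, n - 1));
  while (!st.empty()) {
    int i = st.top().first, j = st.top().second;
    st.pop();
    if (j - i < min_loop + 1) continue;
    if (M[i][j] == M[i][j - 1]) {        // prefer j unpaired on ties
      st.push(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      int w = pair_weight(seq[k], seq[j]);
      if (w == 0) continue;
      int sc = w + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
      if (sc == M[i][j]) {
        pt[k] = j + 1;
        pt[j] = k + 1;
        db[k] = '(';
        db[j] = ')';
        if (k > i) st.push(std::make_pair(i, k - 1));
        st.push(std::make_pair(k + 1, j - 1));
        break;                           // first k: deterministic
      }
    }
  }

  double energy = n > 1 ? -((double) M[0][n - 1]) : 0.0;
  return List::create(_["structure"] = db,
                      _["pair"] = pt,
                      _["energy"] = energy);
}

// [[Rcpp::export(name = ".nussinov_energy")]]
double nussinov_energy(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  if (n < min_loop + 2) return 0.0;
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int w = pair_weight(seq[k], seq[j]);
        if (w == 0) continue;
        int sc = w + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
        if (sc > best) best = sc;
      }
      M[i][j] = best;
    }
  }
  return -((double) M[0][n - 1]);
}
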