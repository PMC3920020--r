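#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Built-in nested-structure folder.
//
// Energy model (deliberately simple, fully documented, deterministic):
//   * legal pairs: A:U, G:C, G:U (and T == U)
//   * each base pair costs +PAIR_PENALTY (so isolated pairs never help)
//   * each stack of two adjacent pairs (i,j)/(i+1,j-1) contributes
//     -(s(p1) + s(p2)) / 2 with s(GC) = 3.0, s(AU) = 2.0, s(GU) = 1.0 kcal/mol
//   * hairpin loops need >= MIN_LOOP unpaired bases; no other loop terms.
// The reported "mfe" is the minimised score of this model. It is NOT on the
// Turner scale; regression training and scoring must use the same backend.

static const double PAIR_PENALTY = 0.25;
static const int MIN_LOOP = 3;
static const double INF = 1e12;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1; // N or other: never pairs
  }
}

static inline double pair_strength(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.0; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2.0; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.0; // G:U
  return 0.0;
}

static inline bool can_pair(int a, int b) {
  return a >= 0 && b >= 0 && pair_strength(a, b) > 0.0;
}

static inline double stack_energy(int a1, int b1, int a2, int b2) {
  return -(pair_strength(a1, b1) + pair_strength(a2, b2)) / 2.0;
}

// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(std::string seq) {
  int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = base_code(seq[i]);

  if (n == 0) return List::create(_["partner"] = IntegerVector(0), _["mfe"] = 0.0);

  // V[i][j]: best energy of i..j given i pairs j; W[i][j]: best energy of i..j
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > W(n, std::vector<double>(n, 0.0));

  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (can_pair(s[i], s[j]) && j - i - 1 >= MIN_LOOP) {
        double best = PAIR_PENALTY;              // hairpin closed by (i,j)
        double inner = PAIR_PENALTY + W[i + 1][j - 1];
        if (inner < best) best = inner;          // anything nested inside
        if (can_pair(s[i + 1], s[j - 1]) && V[i + 1][j - 1] < INF / 2) {
          double st = PAIR_PENALTY + V[i + 1][j - 1] +
            stack_energy(s[i], s[j], s[i + 1], s[j - 1]);
          if (st < best) best = st;              // helix continuation
        }
        V[i][j] = best;
      }
      double w = W[i][j - 1];                    // j unpaired
      for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
        if (V[k][j] >= INF / 2) continue;
        double cand = (k > i ? W[i][k - 1] : 0.0) + V[k][j];
        if (cand < w - 1e-12) w = cand;          // strict: prefer j unpaired on ties
      }
      W[i][j] = w;
    }
  }

  // traceback
  IntegerVector partner(n, 0); // 1-based partner, 0 = unpaired
  std::vector<std::pair<std::pair<int,int>, int> > stack; // ((i,j), in_V)
  stack.push_back(std::make_pair(std::make_pair(0, n - 1), 0));
  while (!stack.empty()) {
    int i = stack.back().first.first, j = stack.back().first.second;
    int inV = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    if (!inV) {
      if (W[i][j] >= -1e-12) continue; // nothing pairs in here
      if (j - 1 >= i && std::abs(W[i][j] - W[i][j - 1]) < 1e-9) {
        stack.push_back(std::make_pair(std::make_pair(i, j - 1), 0));
        continue;
      }
      bool done = false;
      for (int k = i; k <= j - MIN_LOOP - 1 && !done; ++k) {
        if (V[k][j] >= INF / 2) continue;
        double cand = (k > i ? W[i][k - 1] : 0.0) + V[k][j];
        if (std::abs(W[i][j] - cand) < 1e-9) {
          if (k > i) stack.push_back(std::make_pair(std::make_pair(i, k - 1), 0));
          stack.push_back(std::make_pair(std::make_pair(k, j), 1));
          done = true;
        }
      }
    } else {
      partner[i] = j + 1;
      partner[j] = i + 1;
      // prefer helix continuation, then nested, then bare hairpin
      if (can_pair(s[i + 1], s[j - 1]) && V[i + 1][j - 1] < INF / 2) {
        double st = PAIR_PENALTY + V[i + 1][j - 1] +
          stack_energy(s[i], s[j], s[i + 1], s[j - 1]);
        if (std::abs(V[i][j] - st) < 1e-9) {
          stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 1));
          continue;
        }
      }
      if (std::abs(V[i][j] - (PAIR_PENALTY + W[i + 1][j - 1])) < 1e-9 &&
          W[i + 1][j - 1] < -1e-12) {
        stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 0));
      }
      // else: hairpin, nothing more to do
    }
  }

  double mfe = W[0][n - 1];
  if (mfe > 0.0) mfe = 0.0; // open chain is always available
  return List::create(_["partner"] = partner, _["mfe"] = mfe);
}

// Score an explicit structure (1-based partner vector) under the same model.
// Used by tests to compare the DP optimum against enumerated structures.
// [[Rcpp::export(name = ".fold_score_cpp")]]
double fold_score_cpp(std::string seq, IntegerVector partner) {
  int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = base_code(seq[i]);
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = partner[i] - 1;
    if (j > i) {
      e += PAIR_PENALTY;
      if (i + 1 < n && partner[i + 1] - 1 == j - 1 && j - 1 > i + 1)
        e += stack_energy(s[i], s[j], s[i + 1], s[j - 1]);
    }
  }
  return e;
}
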