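#include <Rcpp.h>
using namespace Rcpp;

// Weighted Nussinov base-pair maximization with a minimum hairpin loop.
// Bases are encoded 0=A, 1=C, 2=G, 3=U/T. Pair weights: GC, AU, GU.
//
// The maximum-weight pairing is not unique; among equal-weight optima the
// traceback realizes a structure with the maximum number of stacked pair
// adjacencies (pairs (k,j) and (k+1,j-1) both present). This secondary
// objective is computed exactly by a lexicographic dynamic program, so a
// planted near-perfect stem is realized as one helix instead of an
// arbitrary tie-broken rearrangement. The primary score is unaffected.

static inline double pair_weight(int a, int b, double wGC, double wAU,
                                 double wGU) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return wGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
  return -1.0;  // not pairable
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(IntegerVector seq, int min_loop, double wGC, double wAU,
                   double wGU) {
  const int n = seq.size();
  if (n == 0)
    return List::create(_["score"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2));

  const double eps = 1e-9;
  const double NEG = -1e18;
  // W:  best weight of [i,j];            S:  max stacks among weight-optima
  // Wp: best weight with (i,j) paired;   Sp: max stacks among Wp-optima
  std::vector<double> W((size_t)n * n, 0.0), Wp((size_t)n * n, NEG);
  std::vector<int> S((size_t)n * n, 0), Sp((size_t)n * n, 0);
  auto at = [n](int i, int j) { return (size_t)i * n + j; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // pairing (i,j) itself; zero-weight pairs (e.g. GU with weight 0)
      // are treated as unpairable so they never enter a structure just to
      // increase stacking
      double w = pair_weight(seq[i], seq[j], wGC, wAU, wGU);
      if (w > eps) {
        double innerW = (i + 1 <= j - 1) ? W[at(i + 1, j - 1)] : 0.0;
        Wp[at(i, j)] = w + innerW;
        int s = (i + 1 <= j - 1) ? S[at(i + 1, j - 1)] : 0;
        if (i + 1 <= j - 1 &&
            Wp[at(i + 1, j - 1)] >= W[at(i + 1, j - 1)] - eps) {
          int s2 = Sp[at(i + 1, j - 1)] + 1;  // (i+1,j-1) paired: stack
          if (s2 > s) s = s2;
        }
        Sp[at(i, j)] = s;
      }
      // interval optimum: j unpaired, or j paired with some k
      double best = W[at(i, j - 1)];
      int bestS = S[at(i, j - 1)];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (Wp[at(k, j)] <= NEG / 2) continue;
        double tot = Wp[at(k, j)] + ((k > i) ? W[at(i, k - 1)] : 0.0);
        int s = Sp[at(k, j)] + ((k > i) ? S[at(i, k - 1)] : 0);
        if (tot > best + eps || (tot >= best - eps && s > bestS)) {
          if (tot > best) best = tot;
          bestS = s;
        }
      }
      W[at(i, j)] = best;
      S[at(i, j)] = bestS;
    }
  }

  // Traceback of the (weight, stacks)-lexicographic optimum. Stack entries
  // carry a mode: 0 = free interval [i,j]; 1 = interval whose ends are a
  // pair already committed (realize an Sp-optimal structure inside).
  std::vector<int> pi, pj;
  struct Item { int i, j, mode; };
  std::vector<Item> stack;
  stack.push_back(Item{0, n - 1, 0});
  while (!stack.empty()) {
    Item it = stack.back();
    stack.pop_back();
    int i = it.i, j = it.j;
    if (it.mode == 1) {
      // (i,j) is paired (already emitted); decide the inside
      pi.push_back(i);
      pj.push_back(j);
      if (i + 1 > j - 1) continue;
      if (Wp[at(i + 1, j - 1)] >= W[at(i + 1, j - 1)] - eps &&
          Sp[at(i + 1, j - 1)] + 1 == Sp[at(i, j)]) {
        stack.push_back(Item{i + 1, j - 1, 1});
      } else {
        stack.push_back(Item{i + 1, j - 1, 0});
      }
      continue;
    }
    if (i >= j || j - i < min_loop + 1) continue;
    double tw = W[at(i, j)];
    int ts = S[at(i, j)];
    if (tw <= eps) continue;  // nothing pairable in here
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      if (Wp[at(k, j)] <= NEG / 2) continue;
      double tot = Wp[at(k, j)] + ((k > i) ? W[at(i, k - 1)] : 0.0);
      int s = Sp[at(k, j)] + ((k > i) ? S[at(i, k - 1)] : 0);
      if (tot >= tw - eps && s >= ts) {
        if (k > i) stack.push_back(Item{i, k - 1, 0});
        stack.push_back(Item{k, j, 1});
        done = true;
      }
    }
    if (!done) stack.push_back(Item{i, j - 1, 0});
  }

  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  return List::create(_["score"] = W[at(0, n - 1)], _["pairs"] = pairs);
}
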