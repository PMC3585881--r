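#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Watson-Crick plus G.U wobble, RNA alphabet
static inline bool pairable(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing (Nussinov) over nested structures with a minimum
// hairpin loop of `min_loop` unpaired bases. Returns the optimal pair count
// and one optimal structure; the traceback is deterministic: at (i, j) a
// pairing of i is preferred over leaving i unpaired, and i is paired with
// the smallest admissible partner.
// [[Rcpp::export(name = ".nussinov")]]
List nussinov(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  // M[i][j], 1-based, stored in (n+2)^2 flat table; M = 0 when j - i <= min_loop
  std::vector<int> M((size_t)(n + 2) * (n + 2), 0);
  auto at = [&](int i, int j) -> int& { return M[(size_t)i * (n + 2) + j]; };
  auto val = [&](int i, int j) -> int {
    if (i < 1 || j > n || j - i <= min_loop) return 0;
    return M[(size_t)i * (n + 2) + j];
  };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int best = val(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (pairable(seq[i - 1], seq[k - 1])) {
          int v = 1 + val(i + 1, k - 1) + val(k + 1, j);
          if (v > best) best = v;
        }
      }
      at(i, j) = best;
    }
  }

  // traceback (explicit stack)
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int>> todo;
  if (n > 0) todo.push_back(std::make_pair(1, n));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (j - i <= min_loop) continue;
    int target = val(i, j);
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (pairable(seq[i - 1], seq[k - 1]) &&
          1 + val(i + 1, k - 1) + val(k + 1, j) == target) {
        pi.push_back(i);
        pj.push_back(k);
        todo.push_back(std::make_pair(i + 1, k - 1));
        todo.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push_back(std::make_pair(i + 1, j));
  }

  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  return List::create(_["n_pairs"] = (n > 0) ? val(1, n) : 0,
                      _["pairs"] = pairs);
}

// Longest single-stem chain over the full pairable space: a maximal run of
// pairs (i1<i2<..., j1>j2>...) with at most `max_bulge` skipped bases
// between consecutive pairs on either side, at most `max_bulge_total`
// skipped bases over the whole stem, and a terminal loop of at least
// `min_loop` bases. This is the longest bulged inverted repeat — the
// structural definition of a hairpin stem — and is independent of which
// maximum-pairing structure a traceback happens to return. The total
// bulge budget is what makes the statistic discriminative: without it,
// chains grow supercritically even in random sequence.
// Optional anchoring: when anchor windows are given (1-based, 0 =
// unconstrained), only chains whose outermost pair has i in
// [anchor_i_lo, anchor_i_hi] or j in [anchor_j_lo, anchor_j_hi] are
// eligible — used to demand that a stem begins at the outer end of a
// candidate mature read.
// [[Rcpp::export(name = ".stem_chain")]]
IntegerMatrix stem_chain(std::string seq, int min_loop = 3,
                         int max_bulge = 4, int max_bulge_total = 8,
                         int anchor_i_lo = 0, int anchor_i_hi = 0,
                         int anchor_j_lo = 0, int anchor_j_hi = 0) {
  const int n = (int) seq.size();
  const int B = max_bulge_total + 1;  // budget states 0..max_bulge_total
  // L[i][j][b]: best chain with outermost pair (i, j) and exactly <= b
  // skipped bases available below it; 1-based positions
  std::vector<int> L((size_t)(n + 2) * (n + 2) * B, 0);
  std::vector<int> Pi((size_t)(n + 2) * (n + 2) * B, 0);
  std::vector<int> Pj((size_t)(n + 2) * (n + 2) * B, 0);
  auto idx = [&](int i, int j, int b) {
    return ((size_t)i * (n + 2) + j) * B + b;
  };

  int best = 0, bi = 0, bj = 0, bb = 0;
  // iterate outermost pairs from inside out so successors are ready
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      if (!pairable(seq[i - 1], seq[j - 1])) continue;
      for (int b = 0; b < B; ++b) {
        int v = 1, pi = 0, pj = 0;
        for (int di = 1; di <= max_bulge + 1; ++di) {
          for (int dj = 1; dj <= max_bulge + 1; ++dj) {
            int cost = (di - 1) + (dj - 1);
            if (cost > b) continue;
            int ii = i + di, jj = j - dj;
            if (jj - ii < min_loop + 1) continue;
            int w = L[idx(ii, jj, b - cost)];
            if (w > 0 && w + 1 > v) { v = w + 1; pi = ii; pj = jj; }
          }
        }
        L[idx(i, j, b)] = v;
        Pi[idx(i, j, b)] = pi;
        Pj[idx(i, j, b)] = pj;
        bool anchored =
          (anchor_i_hi == 0 && anchor_j_hi == 0) ||
          (anchor_i_hi > 0 && i >= anchor_i_lo && i <= anchor_i_hi) ||
          (anchor_j_hi > 0 && j >= anchor_j_lo && j <= anchor_j_hi);
        if (anchored && v > best) { best = v; bi = i; bj = j; bb = b; }
      }
    }
  }

  IntegerMatrix out(best, 2);
  int i = bi, j = bj, b = bb;
  for (int r = 0; r < best; ++r) {
    out(r, 0) = i;
    out(r, 1) = j;
    int ni = Pi[idx(i, j, b)], nj = Pj[idx(i, j, b)];
    if (ni > 0) b -= (ni - i - 1) + (j - nj - 1);
    i = ni; j = nj;
  }
  return out;
}
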