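#include <Rcpp.h>
using namespace Rcpp;

// Randomized construction of block-balanced Type-1 Index-1 sequences.
//
// A T1I1 sequence over n labels has length n^2 + 1, starts and ends with the
// same label, and contains every ordered pair of labels (self-pairs included)
// exactly once as adjacent elements.  The block-balanced variant additionally
// partitions trials 1..n^2 into n consecutive blocks of n trials, each block a
// permutation of the labels.  Equivalently: the n(n-1) distinct-pair arcs of
// the complete digraph decompose into n Hamiltonian paths; path b+1 starts at
// the label ending path b (consuming that label's self-pair arc), the n block
// ends are pairwise distinct, and the last block ends at the first block's
// start.  The search below builds blocks left to right with randomized DFS for
// each Hamiltonian path and backtracks across blocks.  All randomness comes
// from R's RNG, so results are reproducible under set.seed().

namespace {

struct Searcher {
  int n;
  std::vector<char> used;      // n x n, distinct-pair arcs already consumed
  std::vector<char> end_used;  // labels already used as a block end
  std::vector<int> blocks;     // n * n labels (0-based), filled block by block
  int tries_per_block;
  long budget_per_path;
  long work, max_work;
  int start1;

  bool arc_used(int a, int b) const { return used[a * n + b] != 0; }
  void set_arc(int a, int b, char v) { used[a * n + b] = v; }

  // randomized DFS for one Hamiltonian path over unused distinct-pair arcs
  bool ham_path(int start, int must_end, const std::vector<char> &forbidden_end,
                std::vector<int> &path, long &budget) {
    std::vector<char> visited(n, 0);
    path.assign(n, -1);
    return dfs(start, 0, must_end, forbidden_end, visited, path, budget);
  }

  bool dfs(int v, int depth, int must_end, const std::vector<char> &forbidden_end,
           std::vector<char> &visited, std::vector<int> &path, long &budget) {
    if (budget <= 0) return false;
    path[depth] = v;
    visited[v] = 1;
    if (depth == n - 1) {
      if ((must_end < 0 && !forbidden_end[v]) || (must_end >= 0 && v == must_end))
        return true;
      visited[v] = 0;
      return false;
    }
    std::vector<int> nxt;
    nxt.reserve(n);
    for (int w = 0; w < n; ++w) {
      if (w == v || visited[w] || arc_used(v, w)) continue;
      if (must_end >= 0 && depth < n - 2 && w == must_end) continue;
      nxt.push_back(w);
    }
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = (int)nxt.size() - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(nxt[i], nxt[j]);
    }
    for (int w : nxt) {
      --budget;
      if (dfs(w, depth + 1, must_end, forbidden_end, visited, path, budget))
        return true;
    }
    visited[v] = 0;
    return false;
  }

  bool solve_block(int b, int cur_start) {
    if (b == n) return true;
    for (int k = 0; k < tries_per_block; ++k) {
      if (++work > max_work) return false;
      int must_end = (b == n - 1) ? start1 : -1;
      std::vector<char> forbidden_end(n, 0);
      if (b < n - 1) {
        forbidden_end = end_used;
        forbidden_end[start1] = 1;  // reserved for the final block's wrap
      }
      std::vector<int> path;
      long budget = budget_per_path;
      if (!ham_path(cur_start, must_end, forbidden_end, path, budget)) continue;
      for (int i = 0; i < n - 1; ++i) set_arc(path[i], path[i + 1], 1);
      end_used[path[n - 1]] = 1;
      std::copy(path.begin(), path.end(), blocks.begin() + (size_t)b * n);
      if (solve_block(b + 1, path[n - 1])) return true;
      for (int i = 0; i < n - 1; ++i) set_arc(path[i], path[i + 1], 0);
      end_used[path[n - 1]] = 0;
    }
    return false;
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerVector t1i1_block_search(int n, int tries_per_block = 8,
                                int budget_per_path = 500,
                                double max_work = 2e5) {
  if (n < 2) stop("n must be >= 2");
  Searcher s;
  s.n = n;
  s.used.assign((size_t)n * n, 0);
  s.end_used.assign(n, 0);
  s.blocks.assign((size_t)n * n, -1);
  s.tries_per_block = tries_per_block;
  s.budget_per_path = budget_per_path;
  s.work = 0;
  s.max_work = (long)max_work;
  s.start1 = (int)std::floor(unif_rand() * n);
  if (s.start1 >= n) s.start1 = n - 1;
  if (!s.solve_block(0, s.start1)) return IntegerVector(0);
  IntegerVector out(n * n + 1);
  for (int i = 0; i < n * n; ++i) out[i] = s.blocks[i] + 1;  // 1-based labels
  out[n * n] = s.start1 + 1;
  return out;
}
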