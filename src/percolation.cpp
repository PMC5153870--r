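#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Entry {
  int score, gap, sum, i, j;
};

// priority: maximal score, then minimal degree gap |d1-d2|, then minimal
// degree sum d1+d2 (entries tied on all three are popped consecutively)
struct EntryLess {
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.score != b.score) return a.score < b.score;
    if (a.gap != b.gap) return a.gap > b.gap;
    return a.sum > b.sum;
  }
};

inline long long couple_key(int i, int j, int n2) {
  return static_cast<long long>(i) * n2 + j;
}

}  // namespace

// Percolation matching proper. All indices 0-based; matched slots hold the
// partner index, -1 for unmatched, -2 for nodes consumed by a half-present
// seed couple (never re-matchable, never scoring).
// [[Rcpp::export(name = ".percolate_engine")]]
List percolate_engine(const List& adj1, const List& adj2,
                      const IntegerVector& seed_i, const IntegerVector& seed_j,
                      const IntegerVector& blocked1,
                      const IntegerVector& blocked2, int r) {
  const int n1 = adj1.size(), n2 = adj2.size();
  std::vector<std::vector<int> > a1(n1), a2(n2);
  std::vector<int> d1(n1), d2(n2);
  for (int v = 0; v < n1; ++v) {
    IntegerVector nb = adj1[v];
    a1[v].assign(nb.begin(), nb.end());
    d1[v] = a1[v].size();
  }
  for (int v = 0; v < n2; ++v) {
    IntegerVector nb = adj2[v];
    a2[v].assign(nb.begin(), nb.end());
    d2[v] = a2[v].size();
  }

  std::vector<int> m1(n1, -1), m2(n2, -1);
  for (int k = 0; k < blocked1.size(); ++k) m1[blocked1[k]] = -2;
  for (int k = 0; k < blocked2.size(); ++k) m2[blocked2[k]] = -2;
  for (int k = 0; k < seed_i.size(); ++k) {
    m1[seed_i[k]] = seed_j[k];
    m2[seed_j[k]] = seed_i[k];
  }

  std::unordered_map<long long, int> score;
  std::priority_queue<Entry, std::vector<Entry>, EntryLess> heap;

  // bump the score of every fully-unmatched neighbour couple of (i, j)
  auto spread = [&](int i, int j) {
    for (int ii : a1[i]) {
      if (m1[ii] != -1) continue;
      for (int jj : a2[j]) {
        if (m2[jj] != -1) continue;
        int sc = ++score[couple_key(ii, jj, n2)];
        heap.push(Entry{sc, std::abs(d1[ii] - d2[jj]), d1[ii] + d2[jj], ii, jj});
      }
    }
  };

  // seeds enter pi as a block: candidate scores see the whole seed set
  for (int k = 0; k < seed_i.size(); ++k) spread(seed_i[k], seed_j[k]);

  std::vector<int> out_i, out_j, out_s;
  auto valid = [&](const Entry& e) {
    return m1[e.i] == -1 && m2[e.j] == -1 &&
           score[couple_key(e.i, e.j, n2)] == e.score;
  };

  while (!heap.empty()) {
    Entry top = heap.top();
    if (!valid(top)) {
      heap.pop();
      continue;
    }
    if (top.score < r) break;
    heap.pop();
    std::vector<Entry> tied;
    tied.push_back(top);
    while (!heap.empty()) {
      Entry e = heap.top();
      if (e.score != top.score || e.gap != top.gap || e.sum != top.sum) break;
      heap.pop();
      if (valid(e)) tied.push_back(e);
    }
    std::size_t pick = 0;
    if (tied.size() > 1) {
      // canonical couple order, then one uniform draw from R's RNG stream
      std::sort(tied.begin(), tied.end(), [](const Entry& a, const Entry& b) {
        return a.i < b.i || (a.i == b.i && a.j < b.j);
      });
      double u = unif_rand();
      pick = std::min(static_cast<std::size_t>(u * tied.size()),
                      tied.size() - 1);
    }
    Entry ch = tied[pick];
    for (std::size_t k = 0; k < tied.size(); ++k)
      if (k != pick) heap.push(tied[k]);
    m1[ch.i] = ch.j;
    m2[ch.j] = ch.i;
    out_i.push_back(ch.i);
    out_j.push_back(ch.j);
    out_s.push_back(ch.score);
    spread(ch.i, ch.j);
  }

  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["score"] = wrap(out_s));
}
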