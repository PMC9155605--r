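#include <Rcpp.h>
#include <functional>
#include <array>
#include <set>
#include <string>
#include <vector>
#include <algorithm>

// Exhaustive enumeration of connected edge-induced subgraphs (fragments)
// of a molecular graph, deduplicated by an exact canonical form.  This is
// the desk-scale replacement for an external frequent-subgraph miner:
// supports are molecule-level presence flags, so each molecule only needs
// the *set* of distinct fragments it contains.
//
// Canonical form: among all colour-preserving vertex orderings, the one
// minimising (vertex-colour sequence, sorted coloured edge list) is
// chosen by brute force over per-colour-block permutations.  Atom counts
// are capped (default 8), so the permutation search is tiny in practice.

namespace {

struct Fragment {
  std::vector<int> vcol;                  // local vertex colours
  std::vector<std::array<int, 3>> edges;  // (u, v, colour), local 0-based
};

std::string canonical_key(const Fragment &f) {
  const int n = static_cast<int>(f.vcol.size());
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::sort(perm.begin(), perm.end(), [&](int a, int b) {
    if (f.vcol[a] != f.vcol[b]) return f.vcol[a] < f.vcol[b];
    return a < b;
  });

  std::vector<std::pair<int, int>> blocks;  // [start, end) of equal colour
  int s = 0;
  for (int i = 1; i <= n; ++i) {
    if (i == n || f.vcol[perm[i]] != f.vcol[perm[s]]) {
      blocks.push_back(std::make_pair(s, i));
      s = i;
    }
  }

  std::vector<int> best;
  std::vector<int> pos(n);
  bool first = true;

  auto consider = [&]() {
    for (int i = 0; i < n; ++i) pos[perm[i]] = i;  // old id -> new position
    std::vector<std::array<int, 3>> es;
    es.reserve(f.edges.size());
    for (const auto &e : f.edges) {
      int a = pos[e[0]], b = pos[e[1]];
      if (a > b) std::swap(a, b);
      es.push_back({a, b, e[2]});
    }
    std::sort(es.begin(), es.end());
    std::vector<int> ser;
    ser.reserve(es.size() * 3);
    for (const auto &e : es) {
      ser.push_back(e[0]);
      ser.push_back(e[1]);
      ser.push_back(e[2]);
    }
    if (first || ser < best) {
      best = ser;
      first = false;
    }
  };

  // odometer over per-block permutations
  std::vector<size_t> bi_stack;
  // simple recursion via lambda-free implementation
  struct Rec {
    std::vector<int> &perm;
    const std::vector<std::pair<int, int>> &blocks;
    const std::function<void()> &consider;
    void run(size_t bi) {
      if (bi == blocks.size()) {
        consider();
        return;
      }
      int lo = blocks[bi].first, hi = blocks[bi].second;
      std::sort(perm.begin() + lo, perm.begin() + hi);
      do {
        run(bi + 1);
      } while (std::next_permutation(perm.begin() + lo, perm.begin() + hi));
    }
  };
  std::function<void()> consider_fn = consider;
  Rec rec{perm, blocks, consider_fn};
  rec.run(0);

  std::string key;
  key.reserve(4 * n + 6 * f.edges.size() + 8);
  key += std::to_string(n);
  key += '|';
  std::vector<int> vc(f.vcol);
  std::sort(vc.begin(), vc.end());
  for (int i = 0; i < n; ++i) {
    if (i) key += ',';
    key += std::to_string(vc[i]);
  }
  key += '|';
  for (size_t i = 0; i < best.size(); i += 3) {
    if (i) key += ';';
    key += std::to_string(best[i]);
    key += '-';
    key += std::to_string(best[i + 1]);
    key += '-';
    key += std::to_string(best[i + 2]);
  }
  return key;
}

class Enumerator {
 public:
  Enumerator(int n_atoms, const Rcpp::IntegerMatrix &edges,
             const Rcpp::IntegerVector &vcol, const Rcpp::IntegerVector &ecol,
             int max_atoms, long max_fragments)
      : n_(n_atoms),
        m_(edges.nrow()),
        edges_(edges),
        vcol_(vcol),
        ecol_(ecol),
        max_atoms_(max_atoms),
        max_fragments_(max_fragments),
        inc_(n_atoms),
        in_sub_(edges.nrow(), 0),
        forb_(edges.nrow(), 0),
        vcount_(n_atoms, 0),
        sub_atoms_(0),
        emitted_(0) {
    for (int k = 0; k < m_; ++k) {
      inc_[edges_(k, 0)].push_back(k);
      inc_[edges_(k, 1)].push_back(k);
    }
  }

  std::set<std::string> run() {
    // single-atom fragments
    std::set<int> seen;
    for (int v = 0; v < n_; ++v) {
      if (seen.insert(vcol_[v]).second) {
        keys_.insert("1|" + std::to_string(vcol_[v]) + "|");
      }
    }
    for (int e0 = 0; max_atoms_ >= 2 && e0 < m_; ++e0) {
      root_ = e0;
      add_edge(e0);
      grow();
      remove_edge(e0);
      forb_[e0] = 1;  // later roots may not reuse earlier edges
    }
    for (int e = 0; e < m_; ++e) forb_[e] = 0;
    return keys_;
  }

 private:
  void add_edge(int e) {
    in_sub_[e] = 1;
    sub_edges_.push_back(e);
    if (vcount_[edges_(e, 0)]++ == 0) ++sub_atoms_;
    if (vcount_[edges_(e, 1)]++ == 0) ++sub_atoms_;
  }

  void remove_edge(int e) {
    in_sub_[e] = 0;
    sub_edges_.pop_back();
    if (--vcount_[edges_(e, 0)] == 0) --sub_atoms_;
    if (--vcount_[edges_(e, 1)] == 0) --sub_atoms_;
  }

  int atoms_after(int e) const {
    return sub_atoms_ + (vcount_[edges_(e, 0)] == 0) +
           (vcount_[edges_(e, 1)] == 0);
  }

  void emit() {
    if (++emitted_ > max_fragments_) {
      Rcpp::stop("fragment enumeration exceeded the cap; lower max_atoms");
    }
    Fragment f;
    std::vector<int> local(n_, -1);
    for (int ke : sub_edges_) {
      for (int side = 0; side < 2; ++side) {
        int v = edges_(ke, side);
        if (local[v] < 0) {
          local[v] = static_cast<int>(f.vcol.size());
          f.vcol.push_back(vcol_[v]);
        }
      }
    }
    for (int ke : sub_edges_) {
      f.edges.push_back({local[edges_(ke, 0)], local[edges_(ke, 1)], ecol_[ke]});
    }
    keys_.insert(canonical_key(f));
  }

  // Emit the current set, then branch on each admissible frontier edge;
  // branch i forbids the edges of branches < i throughout its subtree, so
  // every connected edge subset is produced exactly once per root, and
  // roots only use edges with index >= root.
  void grow() {
    emit();
    if (sub_atoms_ >= max_atoms_) {
      // adding any edge with a new vertex would overflow; edges closing a
      // ring among current vertices are still admissible
    }
    std::vector<int> frontier;
    for (int ke : sub_edges_) {
      for (int side = 0; side < 2; ++side) {
        for (int e : inc_[edges_(ke, side)]) {
          if (e <= root_ || in_sub_[e] || forb_[e]) continue;
          if (atoms_after(e) > max_atoms_) continue;
          if (std::find(frontier.begin(), frontier.end(), e) ==
              frontier.end()) {
            frontier.push_back(e);
          }
        }
      }
    }
    std::sort(frontier.begin(), frontier.end());
    std::vector<int> locally_forbidden;
    for (int e : frontier) {
      add_edge(e);
      grow();
      remove_edge(e);
      forb_[e] = 1;
      locally_forbidden.push_back(e);
    }
    for (int e : locally_forbidden) forb_[e] = 0;
  }

  const int n_, m_;
  Rcpp::IntegerMatrix edges_;
  Rcpp::IntegerVector vcol_, ecol_;
  const int max_atoms_;
  const long max_fragments_;
  int root_ = 0;
  std::vector<std::vector<int>> inc_;
  std::vector<char> in_sub_, forb_;
  std::vector<int> vcount_;
  std::vector<int> sub_edges_;
  int sub_atoms_;
  long emitted_;
  std::set<std::string> keys_;
};

}  // namespace

// [[Rcpp::export(name = ".fragment_keys_cpp")]]
Rcpp::CharacterVector fragment_keys_cpp(int n_atoms,
                                        Rcpp::IntegerMatrix edges,
                                        Rcpp::IntegerVector vcol,
                                        Rcpp::IntegerVector ecol,
                                        int max_atoms,
                                        double max_fragments) {
  Enumerator en(n_atoms, edges, vcol, ecol, max_atoms,
                static_cast<long>(max_fragments));
  std::set<std::string> keys = en.run();
  return Rcpp::CharacterVector(keys.begin(), keys.end());
}
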