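#ifndef FRAGCHAIN_RMQ_H
#define FRAGCHAIN_RMQ_H

#include <vector>
#include <map>
#include <algorithm>
#include <stdexcept>
#include <string>

namespace fragchain {

struct Entry {
  double priority;
  int payload;
};

// Dominance staircase over a fixed, sorted key universe.  Keys are
// rank-condensed at insertion; only non-dominated (key, priority) pairs are
// stored, so a range-maximum query reduces to a single predecessor (or
// successor) lookup in the underlying ordered map.
//
// direction max-below:  query(bound) = max priority over keys <  bound,
//   stored priorities strictly increasing in key.
// direction max-above:  query(bound) = max priority over keys >  bound,
//   stored priorities strictly decreasing in key.
class Staircase {
public:
  const std::vector<double>* universe = nullptr;  // borrowed when inside a tree
  std::vector<double> owned;
  bool max_below = true;
  std::map<int, Entry> entries;  // rank -> entry

  Staircase() = default;
  Staircase(std::vector<double> u, bool below) : owned(std::move(u)), max_below(below) {
    universe = &owned;
  }
  void attach(const std::vector<double>* u, bool below) {
    universe = u;
    max_below = below;
  }

  int rankOf(double key) const {
    auto it = std::lower_bound(universe->begin(), universe->end(), key);
    if (it == universe->end() || *it != key)
      throw std::runtime_error("staircase: key outside the fixed key universe");
    return static_cast<int>(it - universe->begin());
  }

  // ranks whose key value is strictly below `bound` are 0 .. belowLimit-1
  int belowLimit(double bound) const {
    return static_cast<int>(
        std::lower_bound(universe->begin(), universe->end(), bound) - universe->begin());
  }
  // first rank whose key value is strictly above `bound`
  int aboveStart(double bound) const {
    return static_cast<int>(
        std::upper_bound(universe->begin(), universe->end(), bound) - universe->begin());
  }

  // Insert with eager removal of dominated entries.  If a dominating entry
  // (more permissive key, priority >= p) exists the structure is unchanged.
  void insertRank(int r, double priority, int payload) {
    if (max_below) {
      // dominating candidate: largest stored rank <= r (max priority among <= r)
      auto it = entries.upper_bound(r);
      if (it != entries.begin()) {
        auto p = std::prev(it);
        if (p->second.priority >= priority) return;
      }
      // remove entries this one dominates: rank >= r, priority <= p
      auto kill = entries.lower_bound(r);
      while (kill != entries.end() && kill->second.priority <= priority)
        kill = entries.erase(kill);
      entries[r] = Entry{priority, payload};
    } else {
      // dominating candidate: smallest stored rank >= r
      auto it = entries.lower_bound(r);
      if (it != entries.end() && it->second.priority >= priority) return;
      // remove dominated: rank <= r, priority <= p
      auto kill = entries.upper_bound(r);
      while (kill != entries.begin()) {
        auto p = std::prev(kill);
        if (p->second.priority <= priority) entries.erase(p);
        else break;
      }
      entries[r] = Entry{priority, payload};
    }
  }

  void insertKey(double key, double priority, int payload) {
    insertRank(rankOf(key), priority, payload);
  }

  bool query(double bound, Entry& out) const {
    if (max_below) {
      int lim = belowLimit(bound);
      if (lim <= 0) return false;
      auto it = entries.lower_bound(lim);  // first rank >= lim
      if (it == entries.begin()) return false;
      out = std::prev(it)->second;
      return true;
    } else {
      int st = aboveStart(bound);
      auto it = entries.lower_bound(st);
      if (it == entries.end()) return false;
      out = it->second;
      return true;
    }
  }
};

// Range tree: implicit balanced primary tree (array segment tree) over the
// rank-condensed first-dimension universe; each node holds a max-below
// staircase over the second dimension for its canonical subset.
// query(b1, b2) = max priority over elements with key1 <= b1 AND key2 < b2,
// answered by decomposing the prefix [0, b1] into O(log U) canonical nodes.
class RangeTree2D {
public:
  std::vector<double> u1, u2;
  int base = 1;
  std::vector<Staircase> nodes;  // 1-based heap layout, size 2*base
  long lastLookups = 0;

  RangeTree2D(std::vector<double> a, std::vector<double> b)
      : u1(std::move(a)), u2(std::move(b)) {
    int U = std::max(static_cast<int>(u1.size()), 1);
    base = 1;
    while (base < U) base <<= 1;
    nodes.resize(2 * static_cast<size_t>(base));
    for (auto& s : nodes) s.attach(&u2, true);
  }

  int rank1(double key) const {
    auto it = std::lower_bound(u1.begin(), u1.end(), key);
    if (it == u1.end() || *it != key)
      throw std::runtime_error("range tree: key1 outside the fixed key universe");
    return static_cast<int>(it - u1.begin());
  }

  void insert(double k1, double k2, double priority, int payload) {
    int r2 = nodes[1].rankOf(k2);  // validates k2 against u2
    int pos = base + rank1(k1);
    while (pos >= 1) {
      nodes[pos].insertRank(r2, priority, payload);
      pos >>= 1;
    }
  }

  bool query(double b1, double b2, Entry& out) {
    lastLookups = 0;
    // last rank with u1 value <= b1 (non-strict bound on dimension 1)
    int r1 = static_cast<int>(
                 std::upper_bound(u1.begin(), u1.end(), b1) - u1.begin()) - 1;
    if (r1 < 0) return false;
    bool found = false;
    Entry best{0.0, -1};
    int lo = 0, hi = base, pos = 1;
    while (true) {
      if (r1 >= hi - 1) {  // node fully inside the prefix
        probe(pos, b2, best, found);
        break;
      }
      int mid = (lo + hi) / 2;
      if (r1 < mid) {
        pos = 2 * pos;
        hi = mid;
      } else {
        probe(2 * pos, b2, best, found);  // left child canonical
        pos = 2 * pos + 1;
        lo = mid;
      }
    }
    if (found) out = best;
    return found;
  }

private:
  void probe(int pos, double b2, Entry& best, bool& found) {
    ++lastLookups;
    Entry e;
    if (nodes[static_cast<size_t>(pos)].query(b2, e)) {
      if (!found || e.priority > best.priority) {
        best = e;
        found = true;
      }
    }
  }
};

}  // namespace fragchain

#endif
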