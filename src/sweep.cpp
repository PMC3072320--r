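// Line-sweep local fragment chaining.
//
// Events are fragment start points (at beg_x) and end points (at end_x - 1,
// the last covered base under half-open coordinates), processed in order of
// database position with starts before ends at equal coordinate.  Hence when
// a start event at X' fires, exactly the fragments with end_x <= X' are
// active -- the database-axis non-overlap constraint is enforced by the
// sweep order and never needs to be part of an RMQ range.
//
// Linear model: one max-below staircase keyed by end_y; priority
//   score + lam*end_x + eps*end_y.
// Sum-of-pair model, octant split at the end diagonal end_x - end_y:
//   octant 1 (d_x >= d_y, diagonal <= beg_x' - beg_y'): range tree keyed by
//     (diagonal, end_y), priority score + lam*end_x + (eps - lam)*end_y;
//   octant 2 (d_x < d_y, diagonal > beg_x' - beg_y'): max-above staircase
//     keyed by the diagonal, priority score + (eps - lam)*end_x + lam*end_y.
// Within each region the priority differs from score - gap by a constant
// depending only on the successor, so the RMQ maximum is the optimal
// predecessor there.  The winning candidate's value is recomputed from the
// retrieved fragment with the exact gap formula before the connect decision.

#include <Rcpp.h>
#include "rmq.h"

using namespace Rcpp;
using fragchain::Entry;
using fragchain::Staircase;
using fragchain::RangeTree2D;

namespace {

struct Event {
  double coord;
  int kind;  // 0 = start, 1 = end
  int frag;
};

inline double gap_linear(double dx, double dy, double lam, double eps) {
  return lam * dx + eps * dy;
}
inline double gap_sop(double dx, double dy, double lam, double eps) {
  return lam * std::fabs(dx - dy) + eps * std::min(dx, dy);
}

}  // namespace

// [[Rcpp::export]]
List cpp_sweep_chain(NumericVector begX, NumericVector endX,
                     NumericVector begY, NumericVector endY,
                     NumericVector score, std::string model,
                     double lam, double eps, int octantMask) {
  const int n = begX.size();
  NumericVector recScore(n);
  IntegerVector pred(n, NA_INTEGER);
  IntegerVector first(n);
  if (n == 0)
    return List::create(_["score"] = recScore, _["pred"] = pred, _["first"] = first);

  std::vector<Event> ev;
  ev.reserve(2 * static_cast<size_t>(n));
  for (int i = 0; i < n; ++i) {
    ev.push_back(Event{begX[i], 0, i});
    ev.push_back(Event{endX[i] - 1.0, 1, i});
  }
  std::stable_sort(ev.begin(), ev.end(), [](const Event& a, const Event& b) {
    if (a.coord != b.coord) return a.coord < b.coord;
    return a.kind < b.kind;
  });

  const bool sop = (model == "sop");
  std::vector<int> firstV(static_cast<size_t>(n));

  if (!sop) {
    std::vector<double> uy;
    uy.reserve(2 * static_cast<size_t>(n));
    for (int i = 0; i < n; ++i) {
      uy.push_back(begY[i]);
      uy.push_back(endY[i]);
    }
    std::sort(uy.begin(), uy.end());
    uy.erase(std::unique(uy.begin(), uy.end()), uy.end());
    Staircase stair(uy, true);

    for (auto& e : ev) {
      const int f = e.frag;
      if (e.kind == 0) {
        recScore[f] = score[f];
        firstV[static_cast<size_t>(f)] = f;
        Entry cand;
        // predecessors need end_y <= beg_y (half-open abutment allowed)
        if (stair.query(begY[f] + 0.5, cand)) {
          const int j = cand.payload;
          const double v = recScore[j] -
              gap_linear(begX[f] - endX[j], begY[f] - endY[j], lam, eps);
          if (v >= 0.0) {
            recScore[f] = score[f] + v;
            pred[f] = j + 1;  // 1-based for R
            firstV[static_cast<size_t>(f)] = firstV[static_cast<size_t>(j)];
          }
        }
      } else {
        stair.insertKey(endY[f], recScore[f] + lam * endX[f] + eps * endY[f], f);
      }
    }
  } else {
    std::vector<double> udiag, uy;
    udiag.reserve(2 * static_cast<size_t>(n));
    uy.reserve(2 * static_cast<size_t>(n));
    for (int i = 0; i < n; ++i) {
      udiag.push_back(begX[i] - begY[i]);
      udiag.push_back(endX[i] - endY[i]);
      uy.push_back(begY[i]);
      uy.push_back(endY[i]);
    }
    std::sort(udiag.begin(), udiag.end());
    udiag.erase(std::unique(udiag.begin(), udiag.end()), udiag.end());
    std::sort(uy.begin(), uy.end());
    uy.erase(std::unique(uy.begin(), uy.end()), uy.end());

    RangeTree2D oct1(udiag, uy);        // d_x >= d_y half-plane
    Staircase oct2(udiag, false);       // d_x <  d_y half-plane, max-above
    const bool use1 = (octantMask & 1) != 0;
    const bool use2 = (octantMask & 2) != 0;

    for (auto& e : ev) {
      const int f = e.frag;
      if (e.kind == 0) {
        recScore[f] = score[f];
        firstV[static_cast<size_t>(f)] = f;
        const double sdiag = begX[f] - begY[f];
        double bestV = -1.0;
        int bestJ = -1;
        Entry cand;
        if (use1 && oct1.query(sdiag, begY[f] + 0.5, cand)) {
          const int j = cand.payload;
          const double v = recScore[j] -
              gap_sop(begX[f] - endX[j], begY[f] - endY[j], lam, eps);
          if (v > bestV) { bestV = v; bestJ = j; }
        }
        if (use2 && oct2.query(sdiag, cand)) {
          const int j = cand.payload;
          const double v = recScore[j] -
              gap_sop(begX[f] - endX[j], begY[f] - endY[j], lam, eps);
          if (v > bestV) { bestV = v; bestJ = j; }
        }
        if (bestJ >= 0 && bestV >= 0.0) {
          recScore[f] = score[f] + bestV;
          pred[f] = bestJ + 1;
          firstV[static_cast<size_t>(f)] = firstV[static_cast<size_t>(bestJ)];
        }
      } else {
        const double ediag = endX[f] - endY[f];
        if (use1)
          oct1.insert(ediag, endY[f],
                      recScore[f] + lam * endX[f] + (eps - lam) * endY[f], f);
        if (use2)
          oct2.insertKey(ediag,
                         recScore[f] + (eps - lam) * endX[f] + lam * endY[f], f);
      }
    }
  }

  for (int i = 0; i < n; ++i) first[i] = firstV[static_cast<size_t>(i)] + 1;
  return List::create(_["score"] = recScore, _["pred"] = pred, _["first"] = first);
}
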