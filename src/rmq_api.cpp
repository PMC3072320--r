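// External-pointer API over the RMQ structures so that the R level (and the
// randomized oracle tests) can drive Staircase and RangeTree2D directly.

#include <Rcpp.h>
#include "rmq.h"

using namespace Rcpp;
using fragchain::Entry;
using fragchain::Staircase;
using fragchain::RangeTree2D;

static std::vector<double> as_sorted_unique(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return v;
}

// [[Rcpp::export]]
SEXP cpp_staircase_new(NumericVector universe, bool maxBelow) {
  XPtr<Staircase> p(new Staircase(as_sorted_unique(universe), maxBelow), true);
  return p;
}

// [[Rcpp::export]]
void cpp_staircase_insert(SEXP xp, double key, double priority, int payload) {
  XPtr<Staircase> p(xp);
  p->insertKey(key, priority, payload);
}

// [[Rcpp::export]]
SEXP cpp_staircase_query(SEXP xp, double bound) {
  XPtr<Staircase> p(xp);
  Entry e;
  if (!p->query(bound, e)) return R_NilValue;
  return List::create(_["priority"] = e.priority, _["payload"] = e.payload);
}

// [[Rcpp::export]]
DataFrame cpp_staircase_entries(SEXP xp) {
  XPtr<Staircase> p(xp);
  int n = static_cast<int>(p->entries.size());
  NumericVector key(n), prio(n);
  IntegerVector pay(n);
  int i = 0;
  for (auto& kv : p->entries) {
    key[i] = (*p->universe)[static_cast<size_t>(kv.first)];
    prio[i] = kv.second.priority;
    pay[i] = kv.second.payload;
    ++i;
  }
  return DataFrame::create(_["key"] = key, _["priority"] = prio, _["payload"] = pay);
}

// [[Rcpp::export]]
SEXP cpp_rangetree_new(NumericVector universe1, NumericVector universe2) {
  XPtr<RangeTree2D> p(
      new RangeTree2D(as_sorted_unique(universe1), as_sorted_unique(universe2)), true);
  return p;
}

// [[Rcpp::export]]
void cpp_rangetree_insert(SEXP xp, double key1, double key2, double priority, int payload) {
  XPtr<RangeTree2D> p(xp);
  p->insert(key1, key2, priority, payload);
}

// [[Rcpp::export]]
SEXP cpp_rangetree_query(SEXP xp, double bound1, double bound2) {
  XPtr<RangeTree2D> p(xp);
  Entry e;
  if (!p->query(bound1, bound2, e)) return R_NilValue;
  return List::create(_["priority"] = e.priority, _["payload"] = e.payload);
}

// [[Rcpp::export]]
double cpp_rangetree_query_count(SEXP xp) {
  XPtr<RangeTree2D> p(xp);
  return static_cast<double>(p->lastLookups);
}

// Structural audit: every node staircase must be strictly monotone in both
// key rank and priority (increasing, max-below direction).
// [[Rcpp::export]]
bool cpp_rangetree_audit(SEXP xp) {
  XPtr<RangeTree2D> p(xp);
  for (auto& node : p->nodes) {
    double last = R_NegInf;
    for (auto& kv : node.entries) {
      if (kv.second.priority <= last) return false;
      last = kv.second.priority;
    }
  }
  return true;
}
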