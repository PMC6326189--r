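#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Per-line boundary rules for the lateral (L/R) segmentation bands.
//
// A line is a vector of intensity-cluster ranks in {1..k}. Internally every
// line is mapped to "scan coordinates": t = 0 at the base end (the vertebra
// side: the last index for the left band, the first index for the right
// band), t increasing toward the far (background) end. In scan space both
// sides share one rule set:
//
//   B    = base point: the index, closest to the base end, of the nearest
//          local-maximum run (the base end itself when it is one).
//   Rref = ceil(y[B]/2).
//   A valley is a run strictly beyond B with both neighboring runs higher.
//   A peak is a run beyond B with both neighbors lower (the terminal run
//   counts when its predecessor is lower).
//   A peak q "qualifies" when some valley v lies between B and q with
//   y[v] < Rref and y[q] >= y[v] + 2 (the "2 cluster stages" margin that
//   operationalizes a *deep* valley).
//
//   Case 1: some qualifying peak has value > Rref. The boundary is the
//           deepest point strictly between the line end at the base side and
//           P, the qualifying peak closest to B (ties toward the base).
//   Case 2: valleys exist but no qualifying peak exceeds Rref.
//   Case 3: no valley at all.
//   Cases 2 and 3: the boundary is M, the point closest to B (searching from
//   B toward the far end) whose value equals ceil(y[B]/3); if no point
//   attains that value the far end is used and flagged as a fallback.

struct LineOut {
  int cs;        // 1, 2 or 3
  int e;         // boundary point, 0-based scan coordinate
  int b;         // base point, 0-based scan coordinate
  int rref;
  bool fallback;
};

// classify a line given in scan order (t=0 is the base end)
static inline LineOut classify_scan(const int *y, int n) {
  LineOut out;
  out.fallback = false;

  // run-length compression
  static std::vector<int> rval, rstart;
  rval.clear(); rstart.clear();
  for (int i = 0; i < n; ) {
    int j = i;
    while (j + 1 < n && y[j + 1] == y[i]) ++j;
    rval.push_back(y[i]);
    rstart.push_back(i);
    i = j + 1;
  }
  const int m = (int)rval.size();

  // base: nearest local-maximum run from t = 0
  int bRun = 0;
  for (int kk = 0; kk < m; ++kk) {
    bool lo_ok = (kk == 0) || (rval[kk - 1] < rval[kk]);
    bool hi_ok = (kk == m - 1) || (rval[kk + 1] < rval[kk]);
    if (lo_ok && hi_ok) { bRun = kk; break; }
  }
  out.b = rstart[bRun];
  const int yB = rval[bRun];
  out.rref = (yB + 1) / 2;           // ceil(yB / 2)
  const int target = (yB + 2) / 3;   // ceil(yB / 3)

  // scan runs beyond B: valleys, peaks, qualifying peaks
  bool has_valley = false;
  bool case1 = false;
  int p_run = -1;                    // closest qualifying peak run
  int min_valley = INT_MAX;
  for (int kk = bRun + 1; kk < m; ++kk) {
    bool is_valley = (kk < m - 1) && rval[kk - 1] > rval[kk] &&
                     rval[kk + 1] > rval[kk];
    if (is_valley) {
      has_valley = true;
      if (rval[kk] < min_valley) min_valley = rval[kk];
    }
    bool is_peak = (kk == m - 1) ? (rval[kk - 1] < rval[kk])
                                 : (rval[kk - 1] < rval[kk] &&
                                    rval[kk + 1] < rval[kk]);
    if (is_peak && min_valley < out.rref && rval[kk] - min_valley >= 2) {
      if (p_run < 0) p_run = kk;
      if (rval[kk] > out.rref) case1 = true;
    }
  }

  if (case1) {
    out.cs = 1;
    // argmin strictly between the base end (t=0 exclusive) and P; ties
    // toward the base (band interior)
    int tP = rstart[p_run];
    int best = -1, bestv = INT_MAX;
    for (int t = 1; t < tP; ++t)
      if (y[t] < bestv) { bestv = y[t]; best = t; }
    if (best < 0) { best = n - 1; out.fallback = true; }  // unreachable guard
    out.e = best;
  } else {
    out.cs = has_valley ? 2 : 3;
    int best = -1;
    for (int t = out.b; t < n; ++t)
      if (y[t] == target) { best = t; break; }
    if (best < 0) { best = n - 1; out.fallback = true; }
    out.e = best;
  }
  return out;
}

// independently evaluated case predicates (for the totality/exclusivity
// property check)
static inline void predicates_scan(const int *y, int n, bool &p1, bool &p2,
                                   bool &p3) {
  static std::vector<int> rval;
  rval.clear();
  for (int i = 0; i < n; ) {
    int j = i;
    while (j + 1 < n && y[j + 1] == y[i]) ++j;
    rval.push_back(y[i]);
    i = j + 1;
  }
  const int m = (int)rval.size();
  int bRun = 0;
  for (int kk = 0; kk < m; ++kk) {
    bool lo_ok = (kk == 0) || (rval[kk - 1] < rval[kk]);
    bool hi_ok = (kk == m - 1) || (rval[kk + 1] < rval[kk]);
    if (lo_ok && hi_ok) { bRun = kk; break; }
  }
  const int rref = (rval[bRun] + 1) / 2;
  bool has_valley = false, qual_above = false;
  int min_valley = INT_MAX;
  for (int kk = bRun + 1; kk < m; ++kk) {
    if (kk < m - 1 && rval[kk - 1] > rval[kk] && rval[kk + 1] > rval[kk]) {
      has_valley = true;
      if (rval[kk] < min_valley) min_valley = rval[kk];
    }
    bool is_peak = (kk == m - 1) ? (rval[kk - 1] < rval[kk])
                                 : (rval[kk - 1] < rval[kk] &&
                                    rval[kk + 1] < rval[kk]);
    if (is_peak && min_valley < rref && rval[kk] - min_valley >= 2 &&
        rval[kk] > rref)
      qual_above = true;
  }
  p1 = qual_above;
  p2 = has_valley && !qual_above;
  p3 = !has_valley;
}

// [[Rcpp::export(name = ".classify_line_cpp")]]
List classify_line_cpp(IntegerVector y, bool left) {
  const int n = y.size();
  if (n < 1) stop("empty line profile");
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = left ? y[n - 1 - i] : y[i];
  LineOut o = classify_scan(s.data(), n);
  // map scan coordinates back to 1-based original indices
  int e = left ? (n - o.e) : (o.e + 1);
  int b = left ? (n - o.b) : (o.b + 1);
  return List::create(_["case"] = o.cs, _["e"] = e, _["b"] = b,
                      _["rref"] = o.rref, _["fallback"] = o.fallback);
}

// Exhaustive sweep over all rank profiles in {1..k}^n for n = 1..nmax,
// verifying on each that (a) exactly one case predicate holds, (b) the
// classifier's case agrees with the predicates, and (c) the boundary and
// base points are valid indices. Profiles are enumerated in scan space,
// which covers both band sides (the left band is the reversal of the right
// band, and the profile set is closed under reversal).
// [[Rcpp::export(name = ".check_line_rules_cpp")]]
List check_line_rules_cpp(int nmax, int k) {
  double n_checked = 0, n_violations = 0;
  double case_counts[3] = {0, 0, 0};
  std::vector<int> y;
  for (int n = 1; n <= nmax; ++n) {
    y.assign(n, 1);
    for (;;) {
      LineOut o = classify_scan(y.data(), n);
      bool p1, p2, p3;
      predicates_scan(y.data(), n, p1, p2, p3);
      int truecount = (int)p1 + (int)p2 + (int)p3;
      bool ok = (truecount == 1) &&
                ((o.cs == 1 && p1) || (o.cs == 2 && p2) || (o.cs == 3 && p3)) &&
                (o.e >= 0 && o.e < n) && (o.b >= 0 && o.b < n) &&
                (o.cs >= 1 && o.cs <= 3);
      if (!ok) n_violations += 1;
      else case_counts[o.cs - 1] += 1;
      n_checked += 1;
      // odometer increment
      int pos = 0;
      while (pos < n && y[pos] == k) { y[pos] = 1; ++pos; }
      if (pos == n) break;
      ++y[pos];
    }
  }
  return List::create(_["n_checked"] = n_checked,
                      _["n_violations"] = n_violations,
                      _["case1"] = case_counts[0],
                      _["case2"] = case_counts[1],
                      _["case3"] = case_counts[2]);
}
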