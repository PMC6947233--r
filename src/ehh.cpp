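#include <Rcpp.h>
using namespace Rcpp;

// Site-EHH (allele-agnostic) decay machinery.
//
// Haplotypes are rows of an integer 0/1 matrix, markers are columns ordered
// by physical position within one chromosome.  EHHS at flank marker x is the
// number of haplotype pairs identical over every marker in [core..x] divided
// by the number of pairs identical at the core site itself.  The decay is
// walked outward until it drops below `cutoff`, an inter-marker gap exceeds
// `max_gap_bp`, or the chromosome end is reached.

static inline double n_pairs(int k) { return (double)k * (k - 1) / 2.0; }

// stop reasons
static const int REASON_CUTOFF = 0;
static const int REASON_GAP = 1;
static const int REASON_CHROM_END = 2;
static const int REASON_EXTEND = 3;

// reusable scratch space so long scans do not allocate per step
struct Workspace {
  std::vector<int> cls, map0, map1, csz, active, keep;
  explicit Workspace(int n)
      : cls(n), map0(2 * n + 2), map1(2 * n + 2), csz(2 * n + 2), active(n),
        keep(n) {}
};

// Walk one flank.  `dir` is +1 (right) or -1 (left).  Appends visited column
// indices (0-based) and EHHS values; returns the stop reason.
static int walk_flank(const IntegerMatrix &H, int core, int dir,
                      double cutoff, double max_gap_bp, double max_extend_bp,
                      const NumericVector &pos, Workspace &ws,
                      std::vector<int> &idx_out,
                      std::vector<double> &ehhs_out) {
  const int n = H.nrow(), m = H.ncol();
  int n_cls = 2;
  for (int i = 0; i < n; ++i) ws.cls[i] = H(i, core);
  int sz0 = 0;
  for (int i = 0; i < n; ++i) sz0 += (H(i, core) == 0);
  double denom = n_pairs(sz0) + n_pairs(n - sz0);
  if (denom <= 0) return REASON_CUTOFF; // degenerate, handled by caller

  // haplotypes in singleton classes can never rejoin a pair; track only the
  // active (non-singleton-class) rows to keep long walks cheap
  int n_active = n;
  for (int i = 0; i < n; ++i) ws.active[i] = i;

  const int *hp = H.begin();
  int j = core;
  while (true) {
    int nxt = j + dir;
    if (nxt < 0 || nxt >= m) return REASON_CHROM_END;
    if (std::abs(pos[nxt] - pos[j]) > max_gap_bp) return REASON_GAP;
    if (std::abs(pos[nxt] - pos[core]) > max_extend_bp) return REASON_EXTEND;
    const int *col = hp + (size_t)nxt * n;
    for (int c = 0; c < n_cls; ++c) { ws.map0[c] = -1; ws.map1[c] = -1; }
    int k = 0;
    for (int t = 0; t < n_active; ++t) {
      const int i = ws.active[t];
      const int c = ws.cls[i];
      int *mp = col[i] ? ws.map1.data() : ws.map0.data();
      if (mp[c] < 0) { mp[c] = k; ws.csz[k] = 0; ++k; }
      const int nc = mp[c];
      ws.cls[i] = nc;
      ws.csz[nc]++;
    }
    n_cls = k;
    double num = 0;
    for (int c = 0; c < n_cls; ++c) num += n_pairs(ws.csz[c]);
    double e = num / denom;
    if (e < cutoff) return REASON_CUTOFF;
    idx_out.push_back(nxt);
    ehhs_out.push_back(e);
    j = nxt;
    if (num == 0) return REASON_CUTOFF; // cannot recover once zero
    int kept = 0;
    for (int t = 0; t < n_active; ++t)
      if (ws.csz[ws.cls[ws.active[t]]] > 1) ws.keep[kept++] = ws.active[t];
    std::copy(ws.keep.begin(), ws.keep.begin() + kept, ws.active.begin());
    n_active = kept;
  }
}

// [[Rcpp::export(name = ".ehhs_flank_cpp")]]
List ehhs_flank_cpp(IntegerMatrix H, int core0, int dir, double cutoff,
                    double max_gap_bp, NumericVector pos,
                    double max_extend_bp = 1e18) {
  Workspace ws(H.nrow());
  std::vector<int> idx;
  std::vector<double> ehhs;
  int reason = walk_flank(H, core0, dir, cutoff, max_gap_bp, max_extend_bp,
                          pos, ws, idx, ehhs);
  return List::create(_["idx"] = wrap(idx), _["ehhs"] = wrap(ehhs),
                      _["reason"] = reason);
}

// Trapezoidal integral of a flank decay against bp distance, anchored at
// EHHS = 1 at the core position.
static double flank_integral(const NumericVector &pos, int core,
                             const std::vector<int> &idx,
                             const std::vector<double> &ehhs) {
  double x_prev = pos[core], e_prev = 1.0, area = 0.0;
  for (size_t t = 0; t < idx.size(); ++t) {
    double x = pos[idx[t]];
    area += std::abs(x - x_prev) * (e_prev + ehhs[t]) / 2.0;
    x_prev = x;
    e_prev = ehhs[t];
  }
  return area;
}

// Pair counts of haplotypes identical over [c..block_end] (dir = +1) or
// [block_start..c] (dir = -1) for every marker, where blocks are delimited
// by inter-marker gaps above max_gap_bp.  One refinement sweep per block:
// partitions only get finer, so with singleton dropping the total work is
// close to O(n * m).  `at_end[c]` marks markers whose block boundary in the
// walk direction is the chromosome end (not a gap).
static void span_pairs(const IntegerMatrix &H, const NumericVector &pos,
                       double max_gap_bp, int dir, Workspace &ws,
                       std::vector<double> &pairs, std::vector<bool> &at_end) {
  const int n = H.nrow(), m = H.ncol();
  pairs.assign(m, 0.0);
  at_end.assign(m, false);
  int start = (dir > 0) ? m - 1 : 0;
  bool boundary_is_end = true;
  int c = start;
  int n_cls = 0, n_active = 0;
  auto reset = [&]() {
    n_cls = 1;
    n_active = n;
    for (int i = 0; i < n; ++i) { ws.cls[i] = 0; ws.active[i] = i; }
  };
  reset();
  while (c >= 0 && c < m) {
    int prev = c + (dir > 0 ? 1 : -1);
    bool in_block = (prev >= 0 && prev < m) &&
      std::abs(pos[c] - pos[prev]) <= max_gap_bp;
    if (!in_block && c != start) {
      reset();
      boundary_is_end = false;
    }
    // refine with column c
    for (int k = 0; k < n_cls; ++k) { ws.map0[k] = -1; ws.map1[k] = -1; }
    int k = 0;
    for (int t = 0; t < n_active; ++t) {
      int i = ws.active[t];
      int cl = ws.cls[i];
      if (H(i, c) == 0) {
        if (ws.map0[cl] < 0) ws.map0[cl] = k++;
        ws.cls[i] = ws.map0[cl];
      } else {
        if (ws.map1[cl] < 0) ws.map1[cl] = k++;
        ws.cls[i] = ws.map1[cl];
      }
    }
    n_cls = k;
    for (int q = 0; q < n_cls; ++q) ws.csz[q] = 0;
    for (int t = 0; t < n_active; ++t) ws.csz[ws.cls[ws.active[t]]]++;
    double np = 0;
    for (int q = 0; q < n_cls; ++q) np += n_pairs(ws.csz[q]);
    pairs[c] = np;
    at_end[c] = boundary_is_end;
    int kept = 0;
    for (int t = 0; t < n_active; ++t)
      if (ws.csz[ws.cls[ws.active[t]]] > 1) ws.keep[kept++] = ws.active[t];
    std::copy(ws.keep.begin(), ws.keep.begin() + kept, ws.active.begin());
    n_active = kept;
    c -= dir;
  }
}

// Whole-chromosome iES scan for one population.
// Returns a matrix m x 3: iES, left stop reason, right stop reason.
// Cores with a degenerate pair denominator get iES = NA.  When
// `skip_end_reaching` is true, cores whose decay provably stays at or above
// `cutoff` all the way to a chromosome end (exactly the cores flagged for
// exclusion from standardization) are not walked: they get iES = NA with
// the chromosome-end reason on the reaching flank.
// [[Rcpp::export(name = ".ies_scan_cpp")]]
NumericMatrix ies_scan_cpp(IntegerMatrix H, NumericVector pos, double cutoff,
                           double max_gap_bp, bool skip_end_reaching = true,
                           double max_extend_bp = 1e18) {
  const int n = H.nrow(), m = H.ncol();
  NumericMatrix out(m, 3);
  colnames(out) = CharacterVector::create("ies", "reason_left", "reason_right");
  Workspace ws(n);
  std::vector<int> idx;
  std::vector<double> ehhs;
  idx.reserve(m);
  ehhs.reserve(m);
  std::vector<double> pr_right, pr_left;
  std::vector<bool> end_right, end_left;
  if (skip_end_reaching) {
    span_pairs(H, pos, max_gap_bp, +1, ws, pr_right, end_right);
    span_pairs(H, pos, max_gap_bp, -1, ws, pr_left, end_left);
  }
  for (int c = 0; c < m; ++c) {
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += H(i, c);
    double denom = n_pairs(n1) + n_pairs(n - n1);
    if (denom <= 0) {
      out(c, 0) = NA_REAL;
      out(c, 1) = NA_REAL;
      out(c, 2) = NA_REAL;
      continue;
    }
    if (skip_end_reaching) {
      // EHHS is non-increasing, so the walk reaches the block boundary iff
      // the boundary EHHS (= span pairs / denom) is still >= cutoff
      bool reach_r = end_right[c] && pr_right[c] >= cutoff * denom &&
        pos[m - 1] - pos[c] <= max_extend_bp;
      bool reach_l = end_left[c] && pr_left[c] >= cutoff * denom &&
        pos[c] - pos[0] <= max_extend_bp;
      if (reach_r || reach_l) {
        out(c, 0) = NA_REAL;
        out(c, 1) = reach_l ? REASON_CHROM_END : NA_REAL;
        out(c, 2) = reach_r ? REASON_CHROM_END : NA_REAL;
        continue;
      }
    }
    double ies = 0;
    idx.clear(); ehhs.clear();
    int rl = walk_flank(H, c, -1, cutoff, max_gap_bp, max_extend_bp, pos,
                        ws, idx, ehhs);
    ies += flank_integral(pos, c, idx, ehhs);
    idx.clear(); ehhs.clear();
    int rr = walk_flank(H, c, +1, cutoff, max_gap_bp, max_extend_bp, pos,
                        ws, idx, ehhs);
    ies += flank_integral(pos, c, idx, ehhs);
    out(c, 0) = ies;
    out(c, 1) = rl;
    out(c, 2) = rr;
  }
  return out;
}
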