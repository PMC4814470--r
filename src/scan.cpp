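#include <Rcpp.h>
using namespace Rcpp;

// Sequences are encoded as integers: A=1, C=2, G=3, T=4, anything else 0.
// Code 0 (ambiguous base) never matches, so an N in a target always counts
// as a mismatch against any query base.

// Mismatch count of `query` laid ungapped at every offset of `target`.
// Returns an integer vector of length(target) - length(query) + 1
// (empty when the query is longer than the target).
// [[Rcpp::export]]
IntegerVector mismatch_scan_cpp(IntegerVector target, IntegerVector query) {
  const int L = target.size(), m = query.size();
  const int n = L - m + 1;
  if (n < 1) return IntegerVector(0);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      const int t = target[i + j];
      if (t == 0 || t != query[j]) ++mm;
    }
    out[i] = mm;
  }
  return out;
}

// Hamming distance between every row of `a` and the single sequence `centre`.
// [[Rcpp::export]]
IntegerVector hamming_to_centre_cpp(IntegerMatrix a, IntegerVector centre) {
  const int n = a.nrow(), L = a.ncol();
  if (centre.size() != L) stop("centre length does not match sequence length");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int d = 0;
    for (int j = 0; j < L; ++j) if (a(i, j) != centre[j]) ++d;
    out[i] = d;
  }
  return out;
}

// All pairwise Hamming distances between rows of `a` and rows of `b`
// (sequences of equal length, one row per sequence).
// [[Rcpp::export]]
IntegerMatrix hamming_cross_cpp(IntegerMatrix a, IntegerMatrix b) {
  const int n = a.nrow(), m = b.nrow(), L = a.ncol();
  if (b.ncol() != L) stop("sequence lengths differ");
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int d = 0;
      for (int k = 0; k < L; ++k) if (a(i, k) != b(j, k)) ++d;
      out(i, j) = d;
    }
  }
  return out;
}

namespace {
struct Cand { int start, end, strand, mm, full; };
}

// Locate direct-repeat occurrences on one read: all full-length windows on
// both strands with Hamming distance <= max_mm, plus (optionally) the best
// primer-truncated terminal match at each read end (>= min_part bases of a
// repeat suffix at the read start / repeat prefix at the read end, on either
// strand). Overlaps are resolved greedily by fewest mismatches, full matches
// before partial, then leftmost. Columns: start, end (0-based half-open),
// strand (0 = '+', 1 = '-'), mismatches, full (0/1); rows sorted by start.
// [[Rcpp::export]]
IntegerMatrix repeat_match_cpp(IntegerVector read, IntegerVector cons,
                               IntegerVector cons_rc, int max_mm,
                               int min_part, bool terminals) {
  const int L = read.size(), r = cons.size();
  std::vector<Cand> cands;
  for (int strand = 0; strand < 2; ++strand) {
    const IntegerVector &q = strand ? cons_rc : cons;
    for (int i = 0; i + r <= L; ++i) {
      int mm = 0;
      for (int j = 0; j < r && mm <= max_mm; ++j) {
        const int t = read[i + j];
        if (t == 0 || t != q[j]) ++mm;
      }
      if (mm <= max_mm) cands.push_back({i, i + r, strand, mm, 1});
    }
    if (!terminals) continue;
    const int maxLp = std::min(r - 1, L);
    // read start vs repeat suffix (in this strand's orientation)
    int bestLp = -1, bestmm = max_mm + 1;
    for (int Lp = min_part; Lp <= maxLp; ++Lp) {
      int mm = 0;
      for (int j = 0; j < Lp; ++j) {
        const int t = read[j];
        if (t == 0 || t != q[r - Lp + j]) ++mm;
      }
      if (mm < bestmm || (mm == bestmm && Lp > bestLp)) { bestmm = mm; bestLp = Lp; }
    }
    if (bestLp >= min_part && bestmm <= max_mm)
      cands.push_back({0, bestLp, strand, bestmm, 0});
    // read end vs repeat prefix
    bestLp = -1; bestmm = max_mm + 1;
    for (int Lp = min_part; Lp <= maxLp; ++Lp) {
      int mm = 0;
      for (int j = 0; j < Lp; ++j) {
        const int t = read[L - Lp + j];
        if (t == 0 || t != q[j]) ++mm;
      }
      if (mm < bestmm || (mm == bestmm && Lp > bestLp)) { bestmm = mm; bestLp = Lp; }
    }
    if (bestLp >= min_part && bestmm <= max_mm)
      cands.push_back({L - bestLp, L, strand, bestmm, 0});
  }
  std::stable_sort(cands.begin(), cands.end(),
                   [](const Cand &a, const Cand &b) {
    if (a.mm != b.mm) return a.mm < b.mm;
    if (a.full != b.full) return a.full > b.full;
    return a.start < b.start;
  });
  std::vector<Cand> sel;
  for (const auto &c : cands) {
    bool ok = true;
    for (const auto &s : sel)
      if (c.start < s.end && s.start < c.end) { ok = false; break; }
    if (ok) sel.push_back(c);
  }
  std::sort(sel.begin(), sel.end(),
            [](const Cand &a, const Cand &b) { return a.start < b.start; });
  IntegerMatrix out(sel.size(), 5);
  for (size_t i = 0; i < sel.size(); ++i) {
    out(i, 0) = sel[i].start; out(i, 1) = sel[i].end;
    out(i, 2) = sel[i].strand; out(i, 3) = sel[i].mm; out(i, 4) = sel[i].full;
  }
  return out;
}
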