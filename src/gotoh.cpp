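#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Semi-global affine-gap pairwise alignment (Gotoh three-state recurrence).
// The pattern (an exon, or a read) is aligned end-to-end; the subject (a
// genomic window) has cost-free overhangs on both sides.
//
// Scoring: match/mismatch per base; any column involving an N contributes 0
// (neither match nor mismatch) so assembly gaps can neither create nor mask
// mutations. A gap of length L costs gap_open + (L-1) * gap_extend, both
// parameters negative, gap_open <= gap_extend.
//
// Determinism: traceback prefers diagonal > up (gap in subject, i.e. a
// pattern base with no subject partner) > left (gap in pattern); within a
// gap run, extension is preferred over re-opening; the alignment endpoint is
// the leftmost subject position achieving the optimal score.

static const int NEG = INT_MIN / 4;

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N' || a == 'n' || b == 'n') return 0;
  return (a == b) ? match : mismatch;
}

// free_begin / free_end control the subject end-gap policy: TRUE leaves the
// corresponding subject overhang uncharged (semi-global); FALSE forces the
// alignment to start at the first / end at the last subject base (used for
// constrained segments of a seed-anchored chain).
// [[Rcpp::export(name = ".gotoh_semiglobal")]]
List gotoh_semiglobal(std::string pattern, std::string subject,
                      int match, int mismatch, int gap_open, int gap_extend,
                      bool free_begin = true, bool free_end = true) {
  const int n = pattern.size();
  const int m = subject.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // H = best, X = gap-in-subject (consumes pattern), Y = gap-in-pattern
  IntegerMatrix H(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  H(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    X(0, j) = NEG;
    Y(0, j) = free_begin ? NEG : gap_open + (j - 1) * gap_extend;
    H(0, j) = free_begin ? 0 : Y(0, j);
  }
  for (int i = 1; i <= n; ++i) {
    X(i, 0) = gap_open + (i - 1) * gap_extend;
    H(i, 0) = X(i, 0);
    Y(i, 0) = NEG;
  }

  for (int i = 1; i <= n; ++i) {
    const char pi = pattern[i - 1];
    for (int j = 1; j <= m; ++j) {
      int sc = subst(pi, subject[j - 1], match, mismatch);
      int mm = H(i - 1, j - 1) + sc;
      int xo = H(i - 1, j) + gap_open;
      int xe = X(i - 1, j) + gap_extend;
      X(i, j) = (xe >= xo) ? xe : xo;     // prefer extension on ties
      int yo = H(i, j - 1) + gap_open;
      int ye = Y(i, j - 1) + gap_extend;
      Y(i, j) = (ye >= yo) ? ye : yo;
      int h = mm;                          // diagonal > up > left on ties
      if (X(i, j) > h) h = X(i, j);
      if (Y(i, j) > h) h = Y(i, j);
      H(i, j) = h;
    }
  }

  // endpoint: leftmost j with maximal H(n, j); trailing overhang free
  int best = NEG, jend = m;
  if (free_end) {
    for (int j = 0; j <= m; ++j) {
      if (H(n, j) > best) { best = H(n, j); jend = j; }
    }
  } else {
    best = H(n, m);
  }

  // traceback
  std::vector<int> ref_idx, tgt_idx;      // 1-based, NA_INTEGER for gaps
  int i = n, j = jend;
  // state: 0 = H-dispatch, 1 = X, 2 = Y
  int state = 0;
  while (i > 0) {
    if (state == 0) {
      int sc = (j > 0) ? subst(pattern[i - 1], subject[j - 1], match, mismatch) : 0;
      if (j > 0 && H(i, j) == H(i - 1, j - 1) + sc) {
        ref_idx.push_back(i); tgt_idx.push_back(j);
        --i; --j;
      } else if (H(i, j) == X(i, j)) {
        state = 1;
      } else {
        state = 2;
      }
      continue;
    }
    if (state == 1) {                      // pattern base vs gap
      ref_idx.push_back(i); tgt_idx.push_back(NA_INTEGER);
      bool ext = (X(i, j) == X(i - 1, j) + gap_extend);
      --i;
      state = ext ? 1 : 0;
      continue;
    }
    // state == 2: subject base vs gap
    ref_idx.push_back(NA_INTEGER); tgt_idx.push_back(j);
    bool ext = (Y(i, j) == Y(i, j - 1) + gap_extend);
    --j;
    state = ext ? 2 : 0;
  }
  if (!free_begin) {                       // charge + emit leading subject
    while (j > 0) {
      ref_idx.push_back(NA_INTEGER); tgt_idx.push_back(j);
      --j;
    }
  }
  int jstart = j;                          // subject prefix [1..jstart] skipped

  std::reverse(ref_idx.begin(), ref_idx.end());
  std::reverse(tgt_idx.begin(), tgt_idx.end());

  return List::create(
    _["score"] = best,
    _["ref_idx"] = IntegerVector(ref_idx.begin(), ref_idx.end()),
    _["tgt_idx"] = IntegerVector(tgt_idx.begin(), tgt_idx.end()),
    _["subject_start"] = jstart,           // 0-based half-open interval
    _["subject_end"] = jend);
}
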