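// Affine-gap pairwise DP used by every stage of the pipeline.
//
// Two entry points:
//   cpp_align       - general local / semi-global alignment with traceback
//                     (spans, match count, CIGAR, aligned column pairs)
//   cpp_grid_scores - score-only scorer for the (m, n) repeat template grid;
//                     templates share the prefix left_flank + motif1^m, so DP
//                     rows are checkpointed at repeat-unit boundaries instead
//                     of re-aligning every template from scratch.
//
// Scoring convention: a gap of length L costs gap_open + L * gap_extend
// (both negative). N matches nothing, scored as a mismatch against any base.
// Semi-global mode consumes the query end to end; target ends are free.

#include <Rcpp.h>
#include <climits>
#include <cstring>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int sub_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

static inline int max2(int a, int b) { return a > b ? a : b; }
static inline int max3(int a, int b, int c) { return max2(max2(a, b), c); }

// [[Rcpp::export]]
List cpp_align(std::string query, std::string target, std::string mode,
               int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int) query.size();
  const int m = (int) target.size();
  const bool local = (mode == "local");
  const size_t sz = (size_t)(n + 1) * (size_t)(m + 1);

  std::vector<int> H(sz), X(sz), Y(sz);
  // direction codes; for H: 0 from M(diag), 1 from X, 2 from Y, 3 start
  std::vector<unsigned char> dH(sz), dX(sz), dY(sz);

  #define IDX(i, j) ((size_t)(i) * (size_t)(m + 1) + (size_t)(j))

  H[IDX(0, 0)] = 0; X[IDX(0, 0)] = NEG; Y[IDX(0, 0)] = NEG; dH[IDX(0, 0)] = 3;
  for (int j = 1; j <= m; ++j) {         // leading target bases free in both modes
    H[IDX(0, j)] = 0; X[IDX(0, j)] = NEG; Y[IDX(0, j)] = NEG; dH[IDX(0, j)] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    if (local) {
      H[IDX(i, 0)] = 0; X[IDX(i, 0)] = NEG; dH[IDX(i, 0)] = 3;
    } else {                             // query start must be consumed
      X[IDX(i, 0)] = gap_open + i * gap_ext;
      H[IDX(i, 0)] = X[IDX(i, 0)];
      dH[IDX(i, 0)] = 1; dX[IDX(i, 0)] = 1;
    }
    Y[IDX(i, 0)] = NEG;
  }

  int best = local ? 0 : NEG;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t u = IDX(i, j), up = IDX(i - 1, j), lf = IDX(i, j - 1),
                   dg = IDX(i - 1, j - 1);
      const int M = H[dg] + sub_score(qc, target[j - 1], match, mismatch);
      const int xo = H[up] + gap_open + gap_ext, xe = X[up] + gap_ext;
      X[u] = max2(xo, xe); dX[u] = (xe > xo) ? 1 : 0;
      const int yo = H[lf] + gap_open + gap_ext, ye = Y[lf] + gap_ext;
      Y[u] = max2(yo, ye); dY[u] = (ye > yo) ? 1 : 0;
      int h = max3(M, X[u], Y[u]);
      unsigned char d = (h == M) ? 0 : ((h == X[u]) ? 1 : 2);
      if (local && h < 0) { h = 0; d = 3; }
      H[u] = h; dH[u] = d;
      if (local) {
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
  }
  if (!local) {
    for (int j = 0; j <= m; ++j)
      if (H[IDX(n, j)] > best) { best = H[IDX(n, j)]; bi = n; bj = j; }
  }

  // traceback
  int i = bi, j = bj, nmatch = 0;
  std::vector<int> qpos, tpos;          // aligned (query, target) columns, 1-based
  std::string ops;                      // reversed op chars
  int state = 0;                        // 0 H, 1 X, 2 Y
  while (i > 0 || j > 0) {
    const size_t u = IDX(i, j);
    if (state == 0) {
      const unsigned char d = dH[u];
      if (d == 3) break;                // local start / free leading target
      if (d == 0) {
        if (i == 0 || j == 0) break;
        if (query[i - 1] == target[j - 1] && query[i - 1] != 'N') nmatch++;
        qpos.push_back(i); tpos.push_back(j);
        ops.push_back('M'); --i; --j;
      } else state = (int) d;
    } else if (state == 1) {            // gap in target: consume query base
      if (i == 0) break;
      ops.push_back('I');
      const unsigned char d = dX[u];
      --i;
      if (d == 0) state = 0;            // came from H(i-1, j)
    } else {                            // gap in query: consume target base
      if (j == 0) break;
      ops.push_back('D');
      const unsigned char d = dY[u];
      --j;
      if (d == 0) state = 0;
    }
  }
  const int qstart = i, tstart = j;     // 0-based starts

  // compress ops (reversed) into CIGAR
  std::string cigar;
  for (size_t k = ops.size(); k > 0;) {
    const char op = ops[k - 1];
    size_t run = 0;
    while (k > 0 && ops[k - 1] == op) { --k; ++run; }
    cigar += std::to_string(run); cigar += op;
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(tpos.begin(), tpos.end());

  return List::create(
    _["score"] = best,
    _["query_span"] = IntegerVector::create(qstart, bi),
    _["target_span"] = IntegerVector::create(tstart, bj),
    _["n_matches"] = nmatch,
    _["cigar"] = cigar,
    _["qpos"] = wrap(qpos),
    _["tpos"] = wrap(tpos));
  #undef IDX
}

// --- grid scorer -----------------------------------------------------------

struct DpRow {
  std::vector<int> H, X;                // Y never crosses rows
};

static void init_row(DpRow &r, int m) {
  r.H.assign(m + 1, 0);
  r.X.assign(m + 1, NEG);
}

// advance the DP by one template character (template global, read ends free)
static inline void advance_row(DpRow &r, char qc, const std::string &t,
                               int match, int mismatch, int go, int ge) {
  const int m = (int) t.size();
  int prev_diag = r.H[0];               // H(i-1, j-1) as j runs
  int x0 = max2(r.H[0] + go + ge, r.X[0] + ge);
  r.X[0] = x0; r.H[0] = x0;
  int y = NEG;
  for (int j = 1; j <= m; ++j) {
    const int M = prev_diag + sub_score(qc, t[j - 1], match, mismatch);
    r.X[j] = max2(r.H[j] + go + ge, r.X[j] + ge);
    y = max2(r.H[j - 1] + go + ge, y + ge);   // H[j-1] already current row
    prev_diag = r.H[j];
    r.H[j] = max3(M, r.X[j], y);
  }
}

static inline void advance_seq(DpRow &r, const std::string &q,
                               const std::string &t,
                               int match, int mismatch, int go, int ge) {
  for (size_t i = 0; i < q.size(); ++i)
    advance_row(r, q[i], t, match, mismatch, go, ge);
}

static inline int row_best(const DpRow &r) {
  int best = NEG;
  for (size_t j = 0; j < r.H.size(); ++j) best = max2(best, r.H[j]);
  return best;
}

// [[Rcpp::export]]
IntegerMatrix cpp_grid_scores(std::string read, std::string left,
                              std::string motif1, std::string inter,
                              std::string motif2, std::string right,
                              int L1, int U1, int L2, int U2,
                              int match, int mismatch, int gap_open,
                              int gap_ext) {
  const int m = (int) read.size();
  IntegerMatrix out(U1 - L1 + 1, U2 - L2 + 1);

  DpRow spine; init_row(spine, m);
  advance_seq(spine, left, read, match, mismatch, gap_open, gap_ext);

  for (int c1 = 0; c1 <= U1; ++c1) {
    if (c1 > 0)
      advance_seq(spine, motif1, read, match, mismatch, gap_open, gap_ext);
    if (c1 < L1) continue;
    DpRow mid = spine;                  // branch for this m
    advance_seq(mid, inter, read, match, mismatch, gap_open, gap_ext);
    for (int c2 = 0; c2 <= U2; ++c2) {
      if (c2 > 0)
        advance_seq(mid, motif2, read, match, mismatch, gap_open, gap_ext);
      if (c2 < L2) continue;
      DpRow tail = mid;                 // branch for this (m, n)
      advance_seq(tail, right, read, match, mismatch, gap_open, gap_ext);
      out(c1 - L1, c2 - L2) = row_best(tail);
    }
  }
  return out;
}

// --- small sequence utilities ---------------------------------------------

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    std::string s = as<std::string>(x[k]);
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) r[i] = comp(s[s.size() - 1 - i]);
    out[k] = r;
  }
  return out;
}

// longest run of exact consecutive motif copies, any phase
// [[Rcpp::export]]
int cpp_longest_exact_run(std::string seq, std::string motif) {
  const int n = (int) seq.size(), k = (int) motif.size();
  if (k == 0 || n < k) return 0;
  std::vector<int> reps(n, 0);
  int best = 0;
  for (int p = n - k; p >= 0; --p) {
    if (std::memcmp(seq.data() + p, motif.data(), k) == 0) {
      reps[p] = 1 + ((p + k <= n - k) ? reps[p + k] : 0);
      if (reps[p] > best) best = reps[p];
    }
  }
  return best;
}

// per-base error process: substitution, insertion-after, deletion.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
std::string cpp_mutate_seq(std::string seq, double sub_rate, double ins_rate,
                           double del_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  out.reserve(seq.size() + 16);
  for (size_t i = 0; i < seq.size(); ++i) {
    char b = seq[i];
    if (unif_rand() < del_rate) {
      // base dropped
    } else {
      if (unif_rand() < sub_rate) {
        char nb = b;
        while (nb == b) nb = bases[(int)(unif_rand() * 4) & 3];
        b = nb;
      }
      out.push_back(b);
    }
    if (unif_rand() < ins_rate)
      out.push_back(bases[(int)(unif_rand() * 4) & 3]);
  }
  return out;
}
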