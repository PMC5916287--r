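// End-to-end (global-in-read, local-in-reference) gapped alignment with a
// quality-scaled scoring scheme: score <= 0, 0 = perfect. Candidate
// placements come from exact-seed anchoring into a k-mer index of the
// reference; each candidate cluster is resolved by affine-gap DP over a
// reference window around the seed diagonal. References short enough for
// full DP skip the seeding step entirely.
//
// Alignment columns: M (match), X (mismatch or N), I (read base, no ref
// base), D (ref base, no read base). The first and last columns of an
// alignment must consume reference (no terminal insertions), mirroring
// end-to-end mappers where reads overhanging a contig end are unmapped.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG = -1000000000;

struct Scheme {
  int mm_min, mm_max, n_pen, gap_open, gap_extend;
};

struct Cell {
  int score;
  int start;  // window index (0-based column j of first alignment column)
  int gaps;   // number of I+D columns so far
  signed char bp; // predecessor state: -1 none/fresh, 0=M, 1=I, 2=D
};

// lexicographic preference: higher score, then smaller start, then fewer gaps
static inline bool better(int s1, int st1, int g1, int s2, int st2, int g2) {
  if (s1 != s2) return s1 > s2;
  if (st1 != st2) return st1 < st2;
  return g1 < g2;
}

struct AlnResult {
  bool valid = false;
  int score = NEG;
  int ref_start = -1, ref_end = -1;
  int gaps = 0;
  std::string ops;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Substitution penalty (>= 0) for read base r (quality q) vs ref base c.
static inline int sub_pen(char r, char c, int q, const Scheme& sc,
                          bool& is_match) {
  if (r == 'N' || c == 'N') { is_match = false; return sc.n_pen; }
  if (r == c) { is_match = true; return 0; }
  is_match = false;
  int qq = q < 40 ? q : 40;
  return sc.mm_min + ((sc.mm_max - sc.mm_min) * qq) / 40;
}

// Fit-alignment DP of the whole read against ref[win_lo, win_hi).
static AlnResult dp_window(const std::string& read,
                           const std::vector<int>& qual,
                           const std::string& ref,
                           int win_lo, int win_hi, const Scheme& sc) {
  AlnResult res;
  int n = (int)read.size();
  int m = win_hi - win_lo;
  if (m < 1) return res;
  // state layout: [state][ (i)*(m+1) + j ], states 0=M,1=I,2=D
  std::vector<Cell> M((size_t)(n + 1) * (m + 1), {NEG, 0, 0, -1});
  std::vector<Cell> I((size_t)(n + 1) * (m + 1), {NEG, 0, 0, -1});
  std::vector<Cell> D((size_t)(n + 1) * (m + 1), {NEG, 0, 0, -1});
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  for (int i = 1; i <= n; ++i) {
    char rb = read[i - 1];
    int q = qual[i - 1];
    for (int j = 1; j <= m; ++j) {
      char cb = ref[win_lo + j - 1];
      bool is_match;
      int sp = sub_pen(rb, cb, q, sc, is_match);
      // --- M state ---
      {
        int bs = NEG, bst = 0, bg = 0; signed char bb = -1;
        if (i == 1) { // fresh start: first column at window pos j-1
          bs = -sp; bst = j - 1; bg = 0; bb = -1;
        } else {
          const Cell& pm = M[at(i - 1, j - 1)];
          if (pm.score > NEG) { bs = pm.score - sp; bst = pm.start;
                                bg = pm.gaps; bb = 0; }
          const Cell& pi = I[at(i - 1, j - 1)];
          if (pi.score > NEG &&
              better(pi.score - sp, pi.start, pi.gaps, bs, bst, bg)) {
            bs = pi.score - sp; bst = pi.start; bg = pi.gaps; bb = 1;
          }
          const Cell& pd = D[at(i - 1, j - 1)];
          if (pd.score > NEG &&
              better(pd.score - sp, pd.start, pd.gaps, bs, bst, bg)) {
            bs = pd.score - sp; bst = pd.start; bg = pd.gaps; bb = 2;
          }
        }
        if (bs > NEG) M[at(i, j)] = {bs, bst, bg, bb};
      }
      // --- I state (read base consumed, no ref) --- needs i >= 2 content
      {
        int bs = NEG, bst = 0, bg = 0; signed char bb = -1;
        const Cell& pm = M[at(i - 1, j)];
        if (i >= 2 && pm.score > NEG) {
          bs = pm.score - sc.gap_open - sc.gap_extend;
          bst = pm.start; bg = pm.gaps + 1; bb = 0;
        }
        const Cell& pi = I[at(i - 1, j)];
        if (pi.score > NEG &&
            better(pi.score - sc.gap_extend, pi.start, pi.gaps + 1,
                   bs, bst, bg)) {
          bs = pi.score - sc.gap_extend; bst = pi.start;
          bg = pi.gaps + 1; bb = 1;
        }
        if (bs > NEG) I[at(i, j)] = {bs, bst, bg, bb};
      }
      // --- D state (ref base consumed, no read) ---
      {
        int bs = NEG, bst = 0, bg = 0; signed char bb = -1;
        const Cell& pm = M[at(i, j - 1)];
        if (pm.score > NEG) {
          bs = pm.score - sc.gap_open - sc.gap_extend;
          bst = pm.start; bg = pm.gaps + 1; bb = 0;
        }
        const Cell& pd = D[at(i, j - 1)];
        if (pd.score > NEG &&
            better(pd.score - sc.gap_extend, pd.start, pd.gaps + 1,
                   bs, bst, bg)) {
          bs = pd.score - sc.gap_extend; bst = pd.start;
          bg = pd.gaps + 1; bb = 2;
        }
        if (bs > NEG) D[at(i, j)] = {bs, bst, bg, bb};
      }
    }
  }
  // last column must consume reference: end in M state
  int bj = -1, bs = NEG, bst = 0, bg = 0;
  for (int j = 1; j <= m; ++j) {
    const Cell& c = M[at(n, j)];
    if (c.score > NEG && (bj < 0 || better(c.score, c.start, c.gaps,
                                           bs, bst, bg))) {
      bj = j; bs = c.score; bst = c.start; bg = c.gaps;
    }
  }
  if (bj < 0) return res;
  // traceback
  std::string ops;
  int i = n, j = bj, state = 0;
  while (i > 0) {
    if (state == 0) {
      const Cell& c = M[at(i, j)];
      char rb = read[i - 1], cb = ref[win_lo + j - 1];
      ops.push_back((rb != 'N' && cb != 'N' && rb == cb) ? 'M' : 'X');
      state = c.bp; --i; --j;
      if (state < 0) break; // fresh start reached
    } else if (state == 1) {
      const Cell& c = I[at(i, j)];
      ops.push_back('I');
      state = c.bp; --i;
    } else {
      const Cell& c = D[at(i, j)];
      ops.push_back('D');
      state = c.bp; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  res.valid = true;
  res.score = bs;
  res.ref_start = win_lo + bst;
  res.ref_end = win_lo + bj;
  res.gaps = bg;
  res.ops = ops;
  return res;
}

// Build an exact-seed index of the reference (positions per seed k-mer).
static void build_index(const std::string& ref, int seed_len,
                        std::unordered_map<uint64_t,
                                           std::vector<int> >& idx) {
  int L = (int)ref.size();
  if (seed_len > L || seed_len > 31) return;
  uint64_t mask = (seed_len == 32) ? ~0ULL
                                   : ((1ULL << (2 * seed_len)) - 1);
  uint64_t h = 0;
  int valid = 0;
  for (int i = 0; i < L; ++i) {
    int c = base_code(ref[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= seed_len)
      idx[h].push_back(i - seed_len + 1);
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return out;
}

// best placement of one read orientation against the reference
static AlnResult align_one(const std::string& read,
                           const std::vector<int>& qual,
                           const std::string& reference,
                           const std::unordered_map<uint64_t,
                                                    std::vector<int> >& idx,
                           bool use_seeds, int seed_length, int band,
                           const Scheme& sc) {
  AlnResult best;
  int n = (int)read.size();
  int L = (int)reference.size();
  if (!use_seeds)
    return dp_window(read, qual, reference, 0, L, sc);
  // seed offsets: every seed_length bases plus the final window
  std::vector<int> diags;
  if (n >= seed_length) {
    std::vector<int> offs;
    for (int o = 0; o + seed_length <= n; o += seed_length)
      offs.push_back(o);
    if (offs.empty() || offs.back() != n - seed_length)
      offs.push_back(n - seed_length);
    for (int o : offs) {
      uint64_t h = 0; bool ok = true;
      for (int t = 0; t < seed_length; ++t) {
        int c = base_code(read[o + t]);
        if (c < 0) { ok = false; break; }
        h = (h << 2) | (uint64_t)c;
      }
      if (!ok) continue;
      auto it = idx.find(h);
      if (it == idx.end()) continue;
      for (int p : it->second) diags.push_back(p - o);
    }
  }
  if (diags.empty()) return best; // no anchor: unmapped
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  // cluster nearby diagonals into one window each
  size_t c0 = 0;
  for (size_t t = 1; t <= diags.size(); ++t) {
    if (t == diags.size() || diags[t] - diags[t - 1] > band) {
      int lo = std::max(0, diags[c0] - band);
      int hi = std::min(L, diags[t - 1] + n + band);
      AlnResult a = dp_window(read, qual, reference, lo, hi, sc);
      if (a.valid && (!best.valid ||
                      better(a.score, a.ref_start, a.gaps,
                             best.score, best.ref_start, best.gaps)))
        best = a;
      c0 = t;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_align_batch")]]
DataFrame cpp_align_batch(CharacterVector reads, List quals,
                          std::string reference,
                          IntegerVector min_score,
                          int mismatch_min, int mismatch_max, int n_penalty,
                          int gap_open, int gap_extend,
                          int seed_length, int band, int full_dp_max_ref) {
  Scheme sc{mismatch_min, mismatch_max, n_penalty, gap_open, gap_extend};
  int nr = reads.size();
  int L = (int)reference.size();
  std::unordered_map<uint64_t, std::vector<int> > idx;
  bool use_seeds = L > full_dp_max_ref;
  if (use_seeds) build_index(reference, seed_length, idx);

  IntegerVector out_start(nr, NA_INTEGER), out_end(nr, NA_INTEGER);
  NumericVector out_score(nr, NA_REAL);
  LogicalVector out_mapped(nr);
  CharacterVector out_ops(nr, NA_STRING), out_strand(nr, NA_STRING);

  for (int r = 0; r < nr; ++r) {
    std::string read = as<std::string>(reads[r]);
    std::vector<int> qual = as<std::vector<int> >(quals[r]);
    int n = (int)read.size();
    if (n == 0) stop("align: empty read at index %d", r + 1);
    if ((int)qual.size() != n)
      stop("align: quality length mismatch at index %d", r + 1);
    out_mapped[r] = false;
    if (n > L) continue; // longer than reference: unmapped by definition

    // both orientations; forward wins ties
    AlnResult fwd = align_one(read, qual, reference, idx, use_seeds,
                              seed_length, band, sc);
    std::string rc = revcomp(read);
    std::vector<int> rq(qual.rbegin(), qual.rend());
    AlnResult rev = align_one(rc, rq, reference, idx, use_seeds,
                              seed_length, band, sc);
    bool use_rev = rev.valid &&
      (!fwd.valid || better(rev.score, rev.ref_start, rev.gaps,
                            fwd.score, fwd.ref_start, fwd.gaps));
    AlnResult& best = use_rev ? rev : fwd;
    if (!best.valid || best.score < min_score[r]) continue;
    out_mapped[r] = true;
    out_start[r] = best.ref_start;
    out_end[r] = best.ref_end;
    out_score[r] = best.score;
    out_ops[r] = best.ops;
    out_strand[r] = use_rev ? "-" : "+";
  }
  return DataFrame::create(_["ref_start"] = out_start,
                           _["ref_end"] = out_end,
                           _["score"] = out_score,
                           _["mapped"] = out_mapped,
                           _["ops"] = out_ops,
                           _["strand"] = out_strand,
                           _["stringsAsFactors"] = false);
}

// Per-position coverage and connectivity plus match/mismatch column tallies.
// Coverage: positions receiving a read base (M/X column). Connectivity:
// positions whose adjacency to BOTH neighbours is supported by read bases
// consecutive in the read (interior of a maximal gap-free M/X run).
// [[Rcpp::export(name = ".cpp_profiles")]]
List cpp_profiles(CharacterVector ops, IntegerVector ref_start,
                  LogicalVector mapped, int length) {
  IntegerVector cov(length), conn(length);
  double match_cols = 0, mismatch_cols = 0;
  int n = ops.size();
  for (int r = 0; r < n; ++r) {
    if (!mapped[r] || CharacterVector::is_na(ops[r])) continue;
    std::string o = as<std::string>(ops[r]);
    int pos = ref_start[r];
    if (pos < 0) stop("profiles: negative ref_start");
    int run_start = -1;
    for (size_t t = 0; t <= o.size(); ++t) {
      char c = t < o.size() ? o[t] : 0;
      if (c == 'M' || c == 'X') {
        if (pos >= length)
          stop("profiles: alignment extends past reference length");
        if (run_start < 0) run_start = pos;
        cov[pos] += 1;
        if (c == 'M') match_cols += 1; else mismatch_cols += 1;
        ++pos;
      } else {
        if (run_start >= 0) {
          for (int p = run_start + 1; p < pos - 1; ++p) conn[p] += 1;
          run_start = -1;
        }
        if (c == 'D') ++pos;
      }
    }
  }
  return List::create(_["coverage"] = cov, _["connectivity"] = conn,
                      _["match_cols"] = match_cols,
                      _["mismatch_cols"] = mismatch_cols);
}
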