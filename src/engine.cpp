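// Core sequence engine: 2-bit k-mer index, seed-chain-extend local alignment
// with affine gaps (+1 match, -4 mismatch, -6 gap open, -1 gap extend),
// ungapped short-read mapping, bottom-s MinHash sketching, and pileup
// evidence over intervals. Coordinates are 0-based half-open throughout.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

static const int MATCH = 1, MISMATCH = -4, GAP_OPEN = -6, GAP_EXT = -1;
static const double NEG_INF = -1e18;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}
static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(std::string(seqs[i]));
  out.names() = seqs.names();
  return out;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// ---------------------------------------------------------------- k-mer index

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<uint64_t> keys;     // sorted distinct canonical k-mers
  std::vector<uint64_t> starts;   // keys.size()+1 offsets into occs
  std::vector<uint64_t> occs;     // (tid<<40) | (pos<<1) | fwd_is_canonical
};

// Enumerate canonical k-mers of s; cb(pos, canonical_key, fwd_is_canonical).
template <typename F>
static void scan_kmers(const std::string& s, int k, F cb) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2code(s[i]);
    if (b > 3) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | (((uint64_t)(3 - b)) << shift);
    if (++valid >= k) {
      bool f = fwd <= rc;
      cb((long)(i + 1 - k), f ? fwd : rc, f);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 11 || k > 31) stop("k must be in [11, 31]");
  XPtr<KmerIndex> ptr(new KmerIndex(), true);
  KmerIndex& idx = *ptr;
  idx.k = k;
  std::vector<std::pair<uint64_t, uint64_t>> all;
  for (R_xlen_t t = 0; t < seqs.size(); ++t) {
    idx.names.push_back(std::string(names[t]));
    idx.seqs.push_back(std::string(seqs[t]));
    const std::string& s = idx.seqs.back();
    scan_kmers(s, k, [&](long pos, uint64_t key, bool f) {
      all.emplace_back(key, ((uint64_t)t << 40) | ((uint64_t)pos << 1) | (f ? 1 : 0));
    });
  }
  std::sort(all.begin(), all.end());
  idx.occs.reserve(all.size());
  for (size_t i = 0; i < all.size(); ++i) {
    if (i == 0 || all[i].first != all[i - 1].first) {
      idx.keys.push_back(all[i].first);
      idx.starts.push_back(i);
    }
    idx.occs.push_back(all[i].second);
  }
  idx.starts.push_back(all.size());
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP idx_ptr) {
  XPtr<KmerIndex> ptr(idx_ptr);
  IntegerVector lens(ptr->seqs.size());
  for (size_t i = 0; i < ptr->seqs.size(); ++i) lens[i] = (int)ptr->seqs[i].size();
  return List::create(_["k"] = ptr->k,
                      _["names"] = wrap(ptr->names),
                      _["lengths"] = lens,
                      _["n_keys"] = (double)ptr->keys.size(),
                      _["n_positions"] = (double)ptr->occs.size());
}

// [[Rcpp::export]]
CharacterVector cpp_index_seqs(SEXP idx_ptr) {
  XPtr<KmerIndex> ptr(idx_ptr);
  CharacterVector out(ptr->seqs.size());
  for (size_t i = 0; i < ptr->seqs.size(); ++i) out[i] = ptr->seqs[i];
  out.names() = wrap(ptr->names);
  return out;
}

// ------------------------------------------------------------------ alignment

struct AlnPiece { long score, matches, cols, qlen, tlen; };

// Global affine alignment of q vs t, both ends anchored. Tracks matches and
// alignment columns along the optimal path. Sizes here are inter-seed gaps,
// normally tiny; above the cap a straight diagonal + indel approximation is
// used (never reached on generated data).
static AlnPiece align_segment(const char* q, long ql, const char* t, long tl) {
  AlnPiece r{0, 0, 0, ql, tl};
  if (ql == 0 && tl == 0) return r;
  if (ql == 0 || tl == 0) {
    long g = ql + tl;
    r.score = GAP_OPEN + GAP_EXT * (g - 1);
    r.cols = g;
    return r;
  }
  if ((double)ql * (double)tl > 4e6) {
    long m = std::min(ql, tl), g = std::max(ql, tl) - m, match = 0;
    for (long i = 0; i < m; ++i) if (q[i] == t[i]) ++match;
    r.matches = match;
    r.cols = m + g;
    r.score = match * MATCH + (m - match) * MISMATCH +
              (g > 0 ? GAP_OPEN + GAP_EXT * (g - 1) : 0);
    return r;
  }
  long W = tl + 1;
  std::vector<double> M(W), X(W), Y(W), Mp(W), Xp(W), Yp(W);
  std::vector<long> mM(W), mX(W), mY(W), mMp(W), mXp(W), mYp(W);
  std::vector<long> cM(W), cX(W), cY(W), cMp(W), cXp(W), cYp(W);
  // row 0
  Mp[0] = 0; Xp[0] = NEG_INF; Yp[0] = NEG_INF; mMp[0] = cMp[0] = 0;
  for (long j = 1; j < W; ++j) {
    Mp[j] = NEG_INF; Yp[j] = NEG_INF;
    Xp[j] = GAP_OPEN + GAP_EXT * (j - 1);
    mXp[j] = 0; cXp[j] = j;
  }
  for (long i = 1; i <= ql; ++i) {
    M[0] = NEG_INF; X[0] = NEG_INF;
    Y[0] = GAP_OPEN + GAP_EXT * (i - 1); mY[0] = 0; cY[0] = i;
    for (long j = 1; j < W; ++j) {
      bool eq = (q[i - 1] == t[j - 1]) && q[i - 1] != 'N';
      double s = eq ? MATCH : MISMATCH;
      // M from diag
      double best = Mp[j - 1]; long bm = mMp[j - 1], bc = cMp[j - 1];
      if (Xp[j - 1] > best) { best = Xp[j - 1]; bm = mXp[j - 1]; bc = cXp[j - 1]; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; bm = mYp[j - 1]; bc = cYp[j - 1]; }
      M[j] = best + s; mM[j] = bm + (eq ? 1 : 0); cM[j] = bc + 1;
      // X: gap consuming t (left cell)
      double xo = M[j - 1] + GAP_OPEN, xe = X[j - 1] + GAP_EXT, yo = Y[j - 1] + GAP_OPEN;
      if (xo >= xe && xo >= yo) { X[j] = xo; mX[j] = mM[j - 1]; cX[j] = cM[j - 1] + 1; }
      else if (xe >= yo) { X[j] = xe; mX[j] = mX[j - 1]; cX[j] = cX[j - 1] + 1; }
      else { X[j] = yo; mX[j] = mY[j - 1]; cX[j] = cY[j - 1] + 1; }
      // Y: gap consuming q (upper cell)
      double yo2 = Mp[j] + GAP_OPEN, ye = Yp[j] + GAP_EXT, xo2 = Xp[j] + GAP_OPEN;
      if (yo2 >= ye && yo2 >= xo2) { Y[j] = yo2; mY[j] = mMp[j]; cY[j] = cMp[j] + 1; }
      else if (ye >= xo2) { Y[j] = ye; mY[j] = mYp[j]; cY[j] = cYp[j] + 1; }
      else { Y[j] = xo2; mY[j] = mXp[j]; cY[j] = cXp[j] + 1; }
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    std::swap(mM, mMp); std::swap(mX, mXp); std::swap(mY, mYp);
    std::swap(cM, cMp); std::swap(cX, cXp); std::swap(cY, cYp);
  }
  double best = Mp[tl]; long bm = mMp[tl], bc = cMp[tl];
  if (Xp[tl] > best) { best = Xp[tl]; bm = mXp[tl]; bc = cXp[tl]; }
  if (Yp[tl] > best) { best = Yp[tl]; bm = mYp[tl]; bc = cYp[tl]; }
  r.score = (long)best; r.matches = bm; r.cols = bc;
  return r;
}

// Banded X-drop extension from an anchored start into q[0..ql) / t[0..tl).
// Returns the best-scoring prefix pair. Band half-width bw around diagonal 0:
// net indels beyond bw are not followed (chains are split at such events).
static AlnPiece extend_xdrop(const char* q, long ql, const char* t, long tl,
                             int bw, int xdrop) {
  AlnPiece best{0, 0, 0, 0, 0};
  if (ql == 0 || tl == 0) return best;
  int W = 2 * bw + 1;
  std::vector<double> M(W), X(W), Y(W), Mp(W), Xp(W), Yp(W);
  std::vector<long> mM(W), mX(W), mY(W), mMp(W), mXp(W), mYp(W);
  std::vector<long> cM(W), cX(W), cY(W), cMp(W), cXp(W), cYp(W);
  // row i = query bases consumed; offset d -> j = i + d - bw
  for (int d = 0; d < W; ++d) { Mp[d] = NEG_INF; Xp[d] = NEG_INF; Yp[d] = NEG_INF; }
  long j0 = 0; // row 0, j == d - bw must be >= 0
  Mp[bw] = 0; mMp[bw] = 0; cMp[bw] = 0;
  for (int d = bw + 1; d < W; ++d) {
    long j = d - bw;
    if (j > tl) break;
    Xp[d] = GAP_OPEN + GAP_EXT * (j - 1); mXp[d] = 0; cXp[d] = j;
    if (Xp[d] > best.score) { best = {(long)Xp[d], mXp[d], cXp[d], 0, j}; }
  }
  (void)j0;
  double global_best = 0;
  for (long i = 1; i <= ql; ++i) {
    double row_best = NEG_INF;
    for (int d = 0; d < W; ++d) { M[d] = NEG_INF; X[d] = NEG_INF; Y[d] = NEG_INF; }
    for (int d = 0; d < W; ++d) {
      long j = i + d - bw;
      if (j < 0 || j > tl) continue;
      if (j >= 1) {
        // diagonal predecessor at row i-1 has same offset d
        double pb = Mp[d]; long bm = mMp[d], bc = cMp[d];
        if (Xp[d] > pb) { pb = Xp[d]; bm = mXp[d]; bc = cXp[d]; }
        if (Yp[d] > pb) { pb = Yp[d]; bm = mYp[d]; bc = cYp[d]; }
        if (pb > NEG_INF / 2) {
          bool eq = (q[i - 1] == t[j - 1]) && q[i - 1] != 'N';
          M[d] = pb + (eq ? MATCH : MISMATCH);
          mM[d] = bm + (eq ? 1 : 0); cM[d] = bc + 1;
        }
      }
      if (d >= 1 && j >= 1) {
        // left cell: same row, offset d-1
        double xo = M[d - 1] + GAP_OPEN, xe = X[d - 1] + GAP_EXT;
        if (M[d - 1] <= NEG_INF / 2) xo = NEG_INF;
        if (X[d - 1] <= NEG_INF / 2) xe = NEG_INF;
        if (xo >= xe && xo > NEG_INF / 2) { X[d] = xo; mX[d] = mM[d - 1]; cX[d] = cM[d - 1] + 1; }
        else if (xe > NEG_INF / 2) { X[d] = xe; mX[d] = mX[d - 1]; cX[d] = cX[d - 1] + 1; }
      }
      if (d + 1 < W) {
        // upper cell: row i-1, offset d+1
        double yo = Mp[d + 1] + GAP_OPEN, ye = Yp[d + 1] + GAP_EXT;
        if (Mp[d + 1] <= NEG_INF / 2) yo = NEG_INF;
        if (Yp[d + 1] <= NEG_INF / 2) ye = NEG_INF;
        if (yo >= ye && yo > NEG_INF / 2) { Y[d] = yo; mY[d] = mMp[d + 1]; cY[d] = cMp[d + 1] + 1; }
        else if (ye > NEG_INF / 2) { Y[d] = ye; mY[d] = mYp[d + 1]; cY[d] = cYp[d + 1] + 1; }
      }
      double cell = std::max(M[d], std::max(X[d], Y[d]));
      if (cell > row_best) row_best = cell;
      if (cell > best.score && cell > NEG_INF / 2) {
        long bm, bc;
        if (M[d] >= X[d] && M[d] >= Y[d]) { bm = mM[d]; bc = cM[d]; }
        else if (X[d] >= Y[d]) { bm = mX[d]; bc = cX[d]; }
        else { bm = mY[d]; bc = cY[d]; }
        best = {(long)cell, bm, bc, i, j};
      }
    }
    if (row_best > global_best) global_best = row_best;
    if (row_best < global_best - xdrop) break;
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    std::swap(mM, mMp); std::swap(mX, mXp); std::swap(mY, mYp);
    std::swap(cM, cMp); std::swap(cX, cXp); std::swap(cY, cYp);
  }
  return best;
}

struct Seed { int tid; long diag, qpos, tpos; };
struct Hit {
  int tid; long ts, te, qs, qe; bool rev;
  long score, matches, cols;
};

// Align one orientation of the query against the index. Coordinates in the
// returned hits refer to the oriented query.
static void align_one(const std::string& q, const KmerIndex& idx, bool rev,
                      int seed_step, int max_occ, int diag_band, int max_bridge,
                      int bw, int xdrop, long min_score, long min_chain_bp,
                      std::vector<Hit>& out) {
  const int k = idx.k;
  if ((long)q.size() < k) return;
  std::vector<Seed> seeds;
  scan_kmers(q, k, [&](long pos, uint64_t key, bool fq) {
    if (seed_step > 1 && (pos % seed_step) != 0) return;
    auto it = std::lower_bound(idx.keys.begin(), idx.keys.end(), key);
    if (it == idx.keys.end() || *it != key) return;
    size_t ki = it - idx.keys.begin();
    uint64_t a = idx.starts[ki], b = idx.starts[ki + 1];
    if ((long)(b - a) > max_occ) return;
    for (uint64_t o = a; o < b; ++o) {
      uint64_t v = idx.occs[o];
      bool ft = v & 1;
      if (ft != fq) continue;
      int tid = (int)(v >> 40);
      long tpos = (long)((v >> 1) & ((1ULL << 39) - 1));
      seeds.push_back({tid, tpos - pos, pos, tpos});
    }
  });
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    if (a.tid != b.tid) return a.tid < b.tid;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qpos < b.qpos;
  });
  // bucket by diagonal adjacency, then emit chains split at large indels
  size_t i = 0;
  std::vector<Seed> bucket;
  auto flush_bucket = [&]() {
    if (bucket.empty()) return;
    std::sort(bucket.begin(), bucket.end(), [](const Seed& a, const Seed& b) {
      if (a.qpos != b.qpos) return a.qpos < b.qpos;
      return a.tpos < b.tpos;
    });
    // monotone filter + exact-run merging; split where net indel > max_bridge
    struct Run { long q0, t0, len; };
    std::vector<std::vector<Run>> chains(1);
    Run cur{-1, -1, 0};
    long pq = -1, pt = -1;
    for (const Seed& s : bucket) {
      if (s.qpos <= pq || s.tpos <= pt) continue;
      if (cur.len == 0) {
        cur = {s.qpos, s.tpos, (long)k};
      } else {
        long dq = s.qpos - (cur.q0 + cur.len - k), dt = s.tpos - (cur.t0 + cur.len - k);
        if (dq == dt && dq <= k) {
          cur.len += dq;
        } else {
          long qgap = s.qpos - (cur.q0 + cur.len), tgap = s.tpos - (cur.t0 + cur.len);
          // a seed just past an indel can overlap the run end; trim the run
          long over = std::max(-std::min(qgap, tgap), 0L);
          if (over > 0 && cur.len - over >= k) {
            cur.len -= over; qgap += over; tgap += over;
          }
          chains.back().push_back(cur);
          if (qgap < 0 || tgap < 0 || std::labs(qgap - tgap) > max_bridge ||
              qgap > 8000 || tgap > 8000) {
            chains.emplace_back();
          }
          cur = {s.qpos, s.tpos, (long)k};
        }
      }
      pq = s.qpos; pt = s.tpos;
    }
    if (cur.len > 0) chains.back().push_back(cur);
    int tid = bucket[0].tid;
    const std::string& t = idx.seqs[tid];
    for (auto& runs : chains) {
      if (runs.empty()) continue;
      if (min_chain_bp > 0) {
        long seed_bp = 0;
        for (const Run& r : runs) seed_bp += r.len;
        if (seed_bp < min_chain_bp) continue;
      }
      long score = 0, matches = 0, cols = 0;
      for (size_t r = 0; r < runs.size(); ++r) {
        score += runs[r].len * MATCH; matches += runs[r].len; cols += runs[r].len;
        if (r + 1 < runs.size()) {
          long qa = runs[r].q0 + runs[r].len, qb = runs[r + 1].q0;
          long ta = runs[r].t0 + runs[r].len, tb = runs[r + 1].t0;
          AlnPiece p = align_segment(q.data() + qa, qb - qa, t.data() + ta, tb - ta);
          score += p.score; matches += p.matches; cols += p.cols;
        }
      }
      long qs = runs.front().q0, ts = runs.front().t0;
      long qe = runs.back().q0 + runs.back().len, te = runs.back().t0 + runs.back().len;
      // left extension (reversed strings); extensions longer than 20 kb of
      // clean band alignment would already be covered by seeds, so cap copies
      {
        const long CAP = 20000;
        long ql_ext = std::min(qs, CAP);
        long tl_ext = std::min(ts, ql_ext + (long)bw);
        std::string qr(q.begin() + (qs - ql_ext), q.begin() + qs);
        std::reverse(qr.begin(), qr.end());
        std::string tr(t.begin() + (ts - tl_ext), t.begin() + ts);
        std::reverse(tr.begin(), tr.end());
        AlnPiece e = extend_xdrop(qr.data(), ql_ext, tr.data(), tl_ext, bw, xdrop);
        qs -= e.qlen; ts -= e.tlen;
        score += e.score; matches += e.matches; cols += e.cols;
      }
      // right extension
      {
        const long CAP = 20000;
        long ql_ext = std::min((long)q.size() - qe, CAP);
        long tl_ext = std::min((long)t.size() - te, ql_ext + (long)bw);
        AlnPiece e = extend_xdrop(q.data() + qe, ql_ext, t.data() + te, tl_ext, bw, xdrop);
        qe += e.qlen; te += e.tlen;
        score += e.score; matches += e.matches; cols += e.cols;
      }
      if (score >= min_score && te > ts && qe > qs)
        out.push_back({tid, ts, te, qs, qe, rev, score, matches, cols});
    }
    bucket.clear();
  };
  for (i = 0; i < seeds.size(); ++i) {
    if (!bucket.empty() &&
        (seeds[i].tid != bucket.back().tid ||
         seeds[i].diag - bucket.back().diag > diag_band))
      flush_bucket();
    bucket.push_back(seeds[i]);
  }
  flush_bucket();
}

// [[Rcpp::export]]
DataFrame cpp_align(SEXP idx_ptr, std::string query, double min_score = 20,
                    int seed_step = 1, int max_occ = 200, int diag_band = 30,
                    int max_bridge = 30, int bw = 16, int xdrop = 50,
                    double min_chain_bp = 0) {
  XPtr<KmerIndex> ptr(idx_ptr);
  const KmerIndex& idx = *ptr;
  long qlen = (long)query.size();
  std::vector<Hit> hits;
  align_one(query, idx, false, seed_step, max_occ, diag_band, max_bridge, bw,
            xdrop, (long)min_score, (long)min_chain_bp, hits);
  std::string rcq = revcomp_str(query);
  align_one(rcq, idx, true, seed_step, max_occ, diag_band, max_bridge, bw,
            xdrop, (long)min_score, (long)min_chain_bp, hits);
  // map reverse-orientation query coords back to the forward query
  for (auto& h : hits) {
    if (h.rev) {
      long qs = qlen - h.qe, qe = qlen - h.qs;
      h.qs = qs; h.qe = qe;
    }
  }
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.tid != b.tid) return a.tid < b.tid;
    return a.ts < b.ts;
  });
  hits.erase(std::unique(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    return a.tid == b.tid && a.ts == b.ts && a.te == b.te &&
           a.qs == b.qs && a.qe == b.qe && a.rev == b.rev;
  }), hits.end());
  R_xlen_t n = hits.size();
  IntegerVector tid(n); CharacterVector tname(n), strand(n);
  NumericVector ts(n), te(n), qs(n), qe(n), score(n), matches(n), cols(n),
      identity(n), qcov(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const Hit& h = hits[i];
    tid[i] = h.tid + 1; tname[i] = idx.names[h.tid];
    ts[i] = h.ts; te[i] = h.te; qs[i] = h.qs; qe[i] = h.qe;
    strand[i] = h.rev ? "-" : "+";
    score[i] = h.score; matches[i] = h.matches; cols[i] = h.cols;
    identity[i] = h.cols > 0 ? (double)h.matches / h.cols : 0.0;
    qcov[i] = qlen > 0 ? (double)(h.qe - h.qs) / qlen : 0.0;
  }
  return DataFrame::create(
      _["tid"] = tid, _["tname"] = tname, _["tstart"] = ts, _["tend"] = te,
      _["qstart"] = qs, _["qend"] = qe, _["strand"] = strand,
      _["score"] = score, _["matches"] = matches, _["columns"] = cols,
      _["identity"] = identity, _["qcov"] = qcov,
      _["stringsAsFactors"] = false);
}

// --------------------------------------------------------- short-read mapping

// Ungapped best-diagonal placement; mapped iff score >= min_frac * read length.
// [[Rcpp::export]]
List cpp_map_reads(SEXP idx_ptr, CharacterVector reads, double min_frac = 0.6,
                   int seed_step = 5, int max_occ = 200) {
  XPtr<KmerIndex> ptr(idx_ptr);
  const KmerIndex& idx = *ptr;
  const int k = idx.k;
  R_xlen_t n = reads.size();
  IntegerVector tid(n), pos(n), score(n);
  LogicalVector mapped(n), rev(n);
  struct Cand { int tid; long diag; bool rev; int votes; };
  std::vector<Cand> cands;
  for (R_xlen_t ri = 0; ri < n; ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    long L = (long)rd.size();
    cands.clear();
    if (L >= k) {
      scan_kmers(rd, k, [&](long p, uint64_t key, bool fq) {
        if (seed_step > 1 && (p % seed_step) != 0) return;
        auto it = std::lower_bound(idx.keys.begin(), idx.keys.end(), key);
        if (it == idx.keys.end() || *it != key) return;
        size_t ki = it - idx.keys.begin();
        uint64_t a = idx.starts[ki], b = idx.starts[ki + 1];
        if ((long)(b - a) > max_occ) return;
        for (uint64_t o = a; o < b; ++o) {
          uint64_t v = idx.occs[o];
          bool ft = v & 1;
          int t = (int)(v >> 40);
          long tp = (long)((v >> 1) & ((1ULL << 39) - 1));
          bool rv = (ft != fq);
          long diag = rv ? tp - (L - k - p) : tp - p;
          bool found = false;
          for (auto& c : cands)
            if (c.tid == t && c.rev == rv && c.diag == diag) { c.votes++; found = true; break; }
          if (!found) cands.push_back({t, diag, rv, 1});
        }
      });
    }
    int best_score = INT_MIN, best_tid = -1; long best_pos = 0; bool best_rev = false;
    if (!cands.empty()) {
      std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
        if (a.votes != b.votes) return a.votes > b.votes;
        if (a.tid != b.tid) return a.tid < b.tid;
        return a.diag < b.diag;
      });
      std::string rcrd;
      size_t ncand = std::min((size_t)4, cands.size());
      for (size_t c = 0; c < ncand; ++c) {
        const Cand& cd = cands[c];
        const std::string& t = idx.seqs[cd.tid];
        const std::string* rp = &rd;
        if (cd.rev) { if (rcrd.empty()) rcrd = revcomp_str(rd); rp = &rcrd; }
        long m = 0, cmp = 0;
        for (long p = 0; p < L; ++p) {
          long tp = cd.diag + p;
          if (tp < 0 || tp >= (long)t.size()) continue;
          ++cmp;
          if ((*rp)[p] == t[tp] && (*rp)[p] != 'N') ++m;
        }
        int sc = (int)(m * MATCH + (cmp - m) * MISMATCH);
        if (sc > best_score ||
            (sc == best_score && (cd.tid < best_tid ||
              (cd.tid == best_tid && cd.diag < best_pos)))) {
          best_score = sc; best_tid = cd.tid; best_pos = cd.diag; best_rev = cd.rev;
        }
      }
    }
    bool ok = best_tid >= 0 && best_score >= min_frac * (double)L;
    mapped[ri] = ok;
    if (ok) {
      tid[ri] = best_tid + 1; pos[ri] = (int)best_pos;
      score[ri] = best_score; rev[ri] = best_rev;
    } else {
      tid[ri] = NA_INTEGER; pos[ri] = NA_INTEGER; score[ri] = NA_INTEGER; rev[ri] = NA_LOGICAL;
    }
  }
  return List::create(_["tid"] = tid, _["pos"] = pos, _["rev"] = rev,
                      _["score"] = score, _["mapped"] = mapped);
}

// ---------------------------------------------------------------- MinHash

// [[Rcpp::export]]
NumericVector cpp_minhash(std::string seq, int k, int s) {
  const uint64_t M53 = (1ULL << 53) - 1;
  std::vector<uint64_t> hs;
  scan_kmers(seq, k, [&](long, uint64_t key, bool) {
    hs.push_back(splitmix64(key) & M53);
  });
  std::sort(hs.begin(), hs.end());
  hs.erase(std::unique(hs.begin(), hs.end()), hs.end());
  size_t keep = std::min((size_t)s, hs.size());
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = (double)hs[i];
  return out;
}

// ---------------------------------------------------------------- pileup

// Per-interval read evidence on one target: fraction of positions covered and
// majority-consensus identity (ties resolved toward the target base).
// [[Rcpp::export]]
NumericMatrix cpp_interval_evidence(std::string target, IntegerVector starts,
                                    IntegerVector ends, CharacterVector reads,
                                    IntegerVector pos, LogicalVector rev) {
  long L = (long)target.size();
  std::vector<uint32_t> counts(4 * (size_t)L, 0);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    if (rev[i]) rd = revcomp_str(rd);
    long p0 = pos[i];
    for (long p = 0; p < (long)rd.size(); ++p) {
      long tp = p0 + p;
      if (tp < 0 || tp >= L) continue;
      int b = base2code(rd[p]);
      if (b > 3) continue;
      counts[4 * tp + b]++;
    }
  }
  R_xlen_t n = starts.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("covered_fraction", "consensus_identity", "mean_depth");
  for (R_xlen_t i = 0; i < n; ++i) {
    long a = starts[i], b = ends[i];
    long covered = 0, match = 0; double depth = 0;
    for (long tp = a; tp < b; ++tp) {
      uint32_t* c = &counts[4 * tp];
      uint32_t tot = c[0] + c[1] + c[2] + c[3];
      depth += tot;
      if (tot == 0) continue;
      ++covered;
      uint32_t mx = std::max(std::max(c[0], c[1]), std::max(c[2], c[3]));
      int tb = base2code(target[tp]);
      int cons;
      if (tb <= 3 && c[tb] == mx) cons = tb;  // tie (or win) -> target base
      else { cons = 0; for (int x = 0; x < 4; ++x) if (c[x] == mx) { cons = x; break; } }
      if (cons == tb) ++match;
    }
    long len = b - a;
    out(i, 0) = len > 0 ? (double)covered / len : 0.0;
    out(i, 1) = covered > 0 ? (double)match / covered : 0.0;
    out(i, 2) = len > 0 ? depth / len : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------- SDUST

// Symmetric DUST. Score of an interval of w bases with triplet counts c_t:
// S = sum c_t (c_t - 1) / 2 / (w - 2). Perfect intervals (score > thr and
// score >= every proper subinterval's score, lengths 3..W) are reported as
// maximal intervals, merged when overlapping.
// [[Rcpp::export]]
IntegerMatrix cpp_sdust(std::string seq, int W = 64, double thr = 2.0) {
  long n = (long)seq.size();
  std::vector<int> tri(n, -1);  // triplet code starting at i, -1 if any N
  for (long i = 0; i + 2 < n; ++i) {
    int a = base2code(seq[i]), b = base2code(seq[i + 1]), c = base2code(seq[i + 2]);
    tri[i] = (a > 3 || b > 3 || c > 3) ? -1 : (a << 4) | (b << 2) | c;
  }
  if (n < 3) return IntegerMatrix(0, 2);
  int maxlen = std::min((long)W, n);
  // S[i*(W+1) + len] for len in 3..maxlen
  std::vector<float> S((size_t)n * (maxlen + 1), 0.0f);
  std::vector<int> cnt(64);
  for (long i = 0; i < n; ++i) {
    std::fill(cnt.begin(), cnt.end(), 0);
    double raw = 0;
    long lim = std::min((long)maxlen, n - i);
    for (long len = 3; len <= lim; ++len) {
      int t = tri[i + len - 3];
      if (t >= 0) { raw += cnt[t]; cnt[t]++; }
      S[(size_t)i * (maxlen + 1) + len] = (float)(raw / (double)(len - 2));
    }
  }
  // Msub(i,len) = max score over proper subintervals; rolling over len
  std::vector<float> Mprev(n, 0.0f), Mcur(n, 0.0f);  // M includes self
  struct Iv { long s, e; };
  std::vector<Iv> perfect;
  for (int len = 3; len <= maxlen; ++len) {
    for (long i = 0; i + len <= n; ++i) {
      float s = S[(size_t)i * (maxlen + 1) + len];
      float msub = 0.0f;
      if (len > 3) msub = std::max(Mprev[i], Mprev[i + 1]);
      if (s > thr && s >= msub) perfect.push_back({i, i + len});
      Mcur[i] = std::max(s, msub);
    }
    std::swap(Mprev, Mcur);
  }
  if (perfect.empty()) return IntegerMatrix(0, 2);
  // maximal: drop intervals contained in another perfect interval
  std::sort(perfect.begin(), perfect.end(), [](const Iv& a, const Iv& b) {
    if (a.s != b.s) return a.s < b.s;
    return a.e > b.e;
  });
  std::vector<Iv> maximal;
  long max_e = -1;
  for (const Iv& v : perfect) {
    if (v.e > max_e) { maximal.push_back(v); max_e = v.e; }
  }
  // merge overlapping
  std::vector<Iv> merged;
  for (const Iv& v : maximal) {
    if (!merged.empty() && v.s < merged.back().e)
      merged.back().e = std::max(merged.back().e, v.e);
    else merged.push_back(v);
  }
  IntegerMatrix out(merged.size(), 2);
  for (size_t i = 0; i < merged.size(); ++i) {
    out(i, 0) = (int)merged[i].s;
    out(i, 1) = (int)merged[i].e;
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
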