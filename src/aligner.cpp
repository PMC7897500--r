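// Minimizer seed-and-chain long-read aligner.
//
// Desk-scale stand-in for a production long-read mapper: canonical-k-mer
// minimizer index, O(n^2) colinear chaining with a lookback cap, and
// piecewise banded dynamic-programming refinement (gap segments between
// anchors plus x-drop end extension).  Coordinates are 0-based half-open;
// minus-strand chains are aligned on the reverse complement of the read and
// converted back at the end.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>
#include <cstdint>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char RC_TAB[4] = {'T', 'G', 'C', 'A'};

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[s.size() - 1 - i]);
    r[i] = (b < 0) ? 'N' : RC_TAB[b];
  }
  return r;
}

// Invertible 64-bit mixer (Wang hash) restricted to `mask` bits; keeps hash
// values below 2^(2k) so they survive a round trip through an R double.
static inline uint64_t hash64(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = ((key + (key << 3)) + (key << 8)) & mask;
  key = key ^ (key >> 14);
  key = ((key + (key << 2)) + (key << 4)) & mask;
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

struct Kmer {
  uint64_t hash;   // canonical hash, UINT64_MAX if invalid
  int8_t strand;   // +1 forward canonical, -1 reverse canonical, 0 invalid
};

// Canonical hashed k-mers at every start position of `seq`.
static std::vector<Kmer> kmer_scan(const std::string& seq, int k) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  size_t n = seq.size();
  std::vector<Kmer> out;
  if ((int)n < k) return out;
  out.resize(n - k + 1, Kmer{UINT64_MAX, 0});
  uint64_t fwd = 0, rev = 0;
  int valid = 0;  // run length of valid bases ending at i
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    ++valid;
    if (valid >= k) {
      size_t pos = i + 1 - k;
      if (fwd == rev) continue;  // strand-symmetric k-mer: skip
      uint64_t canon = std::min(fwd, rev);
      out[pos].hash = hash64(canon, mask);
      out[pos].strand = (fwd < rev) ? 1 : -1;
    }
  }
  return out;
}

struct Minimizer {
  uint64_t hash;
  int32_t pos;
  int8_t strand;
};

// (w,k)-minimizers: every position whose hash attains the minimum of some
// window of w consecutive k-mer starts.
static std::vector<Minimizer> minimizers(const std::string& seq, int k, int w) {
  std::vector<Kmer> km = kmer_scan(seq, k);
  std::vector<Minimizer> out;
  if (km.empty()) return out;
  int n = (int)km.size();
  std::vector<char> selected(n, 0);
  if (n < w) w = n;  // short sequence: one window over everything
  for (int start = 0; start + w <= n; ++start) {
    uint64_t mn = UINT64_MAX;
    for (int j = start; j < start + w; ++j) mn = std::min(mn, km[j].hash);
    if (mn == UINT64_MAX) continue;
    for (int j = start; j < start + w; ++j)
      if (km[j].hash == mn) selected[j] = 1;
  }
  for (int i = 0; i < n; ++i)
    if (selected[i])
      out.push_back(Minimizer{km[i].hash, i, km[i].strand});
  return out;
}

struct MzIndex {
  int k, w;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // hash -> packed hits (target << 33 | pos << 1 | strand_bit)
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
};

// [[Rcpp::export(name = ".mz_kmer_table")]]
DataFrame mz_kmer_table(std::string seq, int k) {
  std::vector<Kmer> km = kmer_scan(seq, k);
  int n = (int)km.size();
  NumericVector hash(n);
  IntegerVector pos(n), strand(n);
  for (int i = 0; i < n; ++i) {
    pos[i] = i;
    if (km[i].strand == 0) {
      hash[i] = NA_REAL; strand[i] = NA_INTEGER;
    } else {
      hash[i] = (double)km[i].hash;
      strand[i] = km[i].strand;
    }
  }
  return DataFrame::create(_["pos"] = pos, _["hash"] = hash,
                           _["strand"] = strand);
}

// [[Rcpp::export(name = ".mz_index_build")]]
SEXP mz_index_build(CharacterVector seqs, CharacterVector names, int k, int w) {
  if (k < 4 || k > 26) stop("k must be in [4, 26]");
  if (w < 1) stop("w must be >= 1");
  MzIndex* idx = new MzIndex();
  idx->k = k; idx->w = w;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) { delete idx; stop("k exceeds sequence length"); }
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(s);
    std::vector<Minimizer> mz = minimizers(s, k, w);
    for (const Minimizer& m : mz) {
      uint64_t packed = ((uint64_t)i << 33) | ((uint64_t)m.pos << 1) |
                        (m.strand > 0 ? 1ULL : 0ULL);
      idx->table[m.hash].push_back(packed);
    }
  }
  XPtr<MzIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".mz_index_stats")]]
List mz_index_stats(SEXP xp) {
  XPtr<MzIndex> idx(xp);
  size_t npos = 0;
  for (auto& kv : idx->table) npos += kv.second.size();
  return List::create(_["n_distinct_kmers"] = (double)idx->table.size(),
                      _["n_positions"] = (double)npos,
                      _["k"] = idx->k, _["w"] = idx->w);
}

// [[Rcpp::export(name = ".mz_index_minimizers")]]
DataFrame mz_index_minimizers(SEXP xp) {
  XPtr<MzIndex> idx(xp);
  std::vector<double> hash;
  std::vector<int> target, pos, strand, nhits;
  for (auto& kv : idx->table) {
    for (uint64_t p : kv.second) {
      hash.push_back((double)kv.first);
      target.push_back((int)(p >> 33) + 1);  // 1-based index into names
      pos.push_back((int)((p >> 1) & 0xFFFFFFFFULL));
      strand.push_back((p & 1ULL) ? 1 : -1);
      nhits.push_back((int)kv.second.size());
    }
  }
  return DataFrame::create(_["target"] = target, _["pos"] = pos,
                           _["strand"] = strand, _["hash"] = hash,
                           _["n_hits"] = nhits);
}

// ---------------------------------------------------------------------------
// Banded DP pieces.  Linear gap model: match +1, mismatch -2, gap -2.

static const int MATCH = 1, MISMATCH = -2, GAP = -2;
static const int NEG_INF = -(1 << 28);

struct AlnStats { int score, matches, blocklen, qadv, tadv; };

// Global banded alignment of q[0..ql) vs t[0..tl); band centred on the
// (0,0)-(ql,tl) diagonal corridor.
static AlnStats aln_global(const char* q, int ql, const char* t, int tl,
                           int band) {
  AlnStats st{0, 0, 0, ql, tl};
  if (ql == 0 || tl == 0) {
    st.score = GAP * (ql + tl);
    st.blocklen = ql + tl;
    return st;
  }
  if (ql == tl && memcmp(q, t, ql) == 0) {  // fast path
    st.score = MATCH * ql; st.matches = ql; st.blocklen = ql;
    return st;
  }
  band = std::max(band, std::abs(ql - tl) + 8);
  int width = 2 * band + 1;
  std::vector<int> prev(width, NEG_INF), cur(width, NEG_INF);
  std::vector<int8_t> trace((size_t)(ql + 1) * width, 0);  // 1 diag 2 up(q gap) 3 left(t gap)
  // row i: target offset j stored at column j - (i - band)
  auto col = [&](int i, int j) { return j - i + band; };
  for (int j = 0; j <= std::min(tl, band); ++j) {
    prev[col(0, j)] = GAP * j;
    trace[col(0, j)] = 3;
  }
  trace[col(0, 0)] = 0;
  for (int i = 1; i <= ql; ++i) {
    std::fill(cur.begin(), cur.end(), NEG_INF);
    int jlo = std::max(0, i - band), jhi = std::min(tl, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int c = col(i, j);
      int best = NEG_INF; int8_t tb = 0;
      if (j > 0) {  // diagonal
        int pc = col(i - 1, j - 1);
        if (pc >= 0 && pc < width && prev[pc] > NEG_INF) {
          int s = prev[pc] + (q[i - 1] == t[j - 1] ? MATCH : MISMATCH);
          if (s > best) { best = s; tb = 1; }
        }
      }
      {  // up: consume q base (gap in target)
        int pc = col(i - 1, j);
        if (pc >= 0 && pc < width && prev[pc] > NEG_INF) {
          int s = prev[pc] + GAP;
          if (s > best) { best = s; tb = 2; }
        }
      }
      if (j > jlo) {  // left: consume t base
        int pc = col(i, j - 1);
        if (cur[pc] > NEG_INF) {
          int s = cur[pc] + GAP;
          if (s > best) { best = s; tb = 3; }
        }
      }
      cur[c] = best;
      trace[(size_t)i * width + c] = tb;
    }
    std::swap(prev, cur);
  }
  int endc = col(ql, tl);
  st.score = prev[endc];
  // traceback for match count
  int i = ql, j = tl;
  while (i > 0 || j > 0) {
    int8_t tb = trace[(size_t)i * width + col(i, j)];
    if (tb == 1) {
      if (q[i - 1] == t[j - 1]) st.matches++;
      --i; --j;
    } else if (tb == 2) { --i; }
    else if (tb == 3) { --j; }
    else break;
    st.blocklen++;
  }
  return st;
}

// Extension: align a prefix of q against a prefix of t, semi-global, keeping
// the best-scoring cell; stops early when the running best drops by > xdrop.
static AlnStats aln_extend(const char* q, int ql, const char* t, int tl,
                           int band, int xdrop) {
  AlnStats st{0, 0, 0, 0, 0};
  if (ql == 0 || tl == 0) return st;
  // greedy exact-match fast path
  int e = 0, lim = std::min(ql, tl);
  while (e < lim && q[e] == t[e]) ++e;
  if (e == lim) {
    st.score = MATCH * e; st.matches = e; st.blocklen = e;
    st.qadv = e; st.tadv = e;
    return st;
  }
  int width = 2 * band + 1;
  std::vector<int> prev(width, NEG_INF), cur(width, NEG_INF);
  std::vector<int8_t> trace((size_t)(ql + 1) * width, 0);
  auto col = [&](int i, int j) { return j - i + band; };
  int best = 0, bi = 0, bj = 0;
  for (int j = 0; j <= std::min(tl, band); ++j) {
    prev[col(0, j)] = GAP * j;
    trace[col(0, j)] = 3;
  }
  trace[col(0, 0)] = 0;
  bool stopped = false;
  int ifinal = 0;
  for (int i = 1; i <= ql && !stopped; ++i) {
    std::fill(cur.begin(), cur.end(), NEG_INF);
    int jlo = std::max(0, i - band), jhi = std::min(tl, i + band);
    if (jlo > jhi) break;
    int rowbest = NEG_INF;
    for (int j = jlo; j <= jhi; ++j) {
      int c = col(i, j);
      int bestc = NEG_INF; int8_t tb = 0;
      if (j > 0) {
        int pc = col(i - 1, j - 1);
        if (pc >= 0 && pc < width && prev[pc] > NEG_INF) {
          int s = prev[pc] + (q[i - 1] == t[j - 1] ? MATCH : MISMATCH);
          if (s > bestc) { bestc = s; tb = 1; }
        }
      }
      {
        int pc = col(i - 1, j);
        if (pc >= 0 && pc < width && prev[pc] > NEG_INF) {
          int s = prev[pc] + GAP;
          if (s > bestc) { bestc = s; tb = 2; }
        }
      }
      if (j > jlo && cur[col(i, j - 1)] > NEG_INF) {
        int s = cur[col(i, j - 1)] + GAP;
        if (s > bestc) { bestc = s; tb = 3; }
      }
      cur[c] = bestc;
      trace[(size_t)i * width + c] = tb;
      if (bestc > rowbest) rowbest = bestc;
      if (bestc > best) { best = bestc; bi = i; bj = j; }
    }
    ifinal = i;
    if (rowbest < best - xdrop) stopped = true;
    std::swap(prev, cur);
  }
  (void)ifinal;
  if (best <= 0) return st;  // no positive-scoring extension
  st.score = best; st.qadv = bi; st.tadv = bj;
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    int8_t tb = trace[(size_t)i * width + col(i, j)];
    if (tb == 1) {
      if (q[i - 1] == t[j - 1]) st.matches++;
      --i; --j;
    } else if (tb == 2) { --i; }
    else if (tb == 3) { --j; }
    else break;
    st.blocklen++;
  }
  return st;
}

// ---------------------------------------------------------------------------
// Chaining

struct Anchor { int32_t q, t; };

struct Chain {
  std::vector<int> idx;  // anchor indices
  double score;
};

static std::vector<Chain> chain_anchors(std::vector<Anchor>& a, int k,
                                        int min_anchors, int max_chains,
                                        int max_gap) {
  std::vector<Chain> chains;
  int n = (int)a.size();
  if (n == 0) return chains;
  std::sort(a.begin(), a.end(), [](const Anchor& x, const Anchor& y) {
    return x.t != y.t ? x.t < y.t : x.q < y.q;
  });
  std::vector<char> used(n, 0);
  const int LOOKBACK = 64;
  std::vector<double> f(n);
  std::vector<int> pre(n);
  for (int round = 0; round < max_chains; ++round) {
    double bestf = -1; int besti = -1;
    for (int i = 0; i < n; ++i) {
      if (used[i]) { f[i] = -1e18; pre[i] = -1; continue; }
      f[i] = k; pre[i] = -1;
      int seen = 0;
      for (int j = i - 1; j >= 0 && seen < LOOKBACK; --j) {
        if (used[j]) continue;
        ++seen;
        int dq = a[i].q - a[j].q, dt = a[i].t - a[j].t;
        if (dq <= 0 || dt <= 0) continue;
        if (dq > max_gap || dt > max_gap) continue;
        int gap = std::abs(dq - dt);
        double add = std::min(std::min(dq, dt), k) -
                     (gap > 0 ? 0.05 * gap + std::log2(gap + 1.0) : 0.0);
        if (f[j] + add > f[i]) { f[i] = f[j] + add; pre[i] = j; }
      }
      if (f[i] > bestf) { bestf = f[i]; besti = i; }
    }
    if (besti < 0) break;
    Chain ch; ch.score = bestf;
    for (int i = besti; i >= 0; i = pre[i]) ch.idx.push_back(i);
    std::reverse(ch.idx.begin(), ch.idx.end());
    if ((int)ch.idx.size() < min_anchors) break;  // best remaining too weak
    for (int i : ch.idx) used[i] = 1;
    chains.push_back(std::move(ch));
  }
  return chains;
}

// ---------------------------------------------------------------------------

struct Span {
  int target;            // 0-based index into index targets
  int qs, qe, ts, te;    // 0-based half-open
  int strand;            // +1 / -1
  int matches, blocklen, score, n_anchors;
};

// Refine one chain into a base-level span by piecewise DP.
static bool refine_chain(const std::string& q, const std::string& t,
                         const std::vector<Anchor>& anchors,
                         const Chain& ch, int k, int band, int xdrop,
                         Span& out) {
  int score = 0, matches = 0, blocklen = 0;
  const Anchor& a0 = anchors[ch.idx[0]];
  int cq = a0.q, ct = a0.t;  // consumed up to (exclusive)
  // first anchor
  score += MATCH * k; matches += k; blocklen += k;
  int q_end = a0.q + k, t_end = a0.t + k;
  for (size_t m = 1; m < ch.idx.size(); ++m) {
    const Anchor& an = anchors[ch.idx[m]];
    int dq = an.q - q_end, dt = an.t - t_end;
    if (dq < 0 || dt < 0) {
      // overlapping anchors: same diagonal extends the match run
      if (an.q - q_end == an.t - t_end) {
        int adv = an.q + k - q_end;
        if (adv > 0) { score += MATCH * adv; matches += adv; blocklen += adv; }
        q_end = std::max(q_end, an.q + k); t_end = std::max(t_end, an.t + k);
      }
      continue;  // off-diagonal overlap: drop anchor
    }
    if (dq > 0 || dt > 0) {
      AlnStats st = aln_global(q.c_str() + q_end, dq, t.c_str() + t_end, dt,
                               band);
      score += st.score; matches += st.matches; blocklen += st.blocklen;
    }
    score += MATCH * k; matches += k; blocklen += k;
    q_end = an.q + k; t_end = an.t + k;
  }
  // right extension
  {
    AlnStats st = aln_extend(q.c_str() + q_end, (int)q.size() - q_end,
                             t.c_str() + t_end, (int)t.size() - t_end,
                             band, xdrop);
    score += st.score; matches += st.matches; blocklen += st.blocklen;
    q_end += st.qadv; t_end += st.tadv;
  }
  // left extension on reversed strings
  int q_start = cq, t_start = ct;
  {
    std::string qr(q.rend() - cq, q.rend());      // reverse of q[0..cq)
    std::string tr(t.rend() - ct, t.rend());
    AlnStats st = aln_extend(qr.c_str(), cq, tr.c_str(), ct, band, xdrop);
    score += st.score; matches += st.matches; blocklen += st.blocklen;
    q_start -= st.qadv; t_start -= st.tadv;
  }
  if (blocklen <= 0 || q_end <= q_start || t_end <= t_start) return false;
  out.qs = q_start; out.qe = q_end; out.ts = t_start; out.te = t_end;
  out.matches = matches; out.blocklen = blocklen; out.score = score;
  out.n_anchors = (int)ch.idx.size();
  return true;
}

// [[Rcpp::export(name = ".mz_align")]]
DataFrame mz_align(SEXP xp, std::string read, int min_chain_anchors,
                   double min_identity, int max_chains, int band, int xdrop,
                   int max_gap, int max_occ) {
  XPtr<MzIndex> idx(xp);
  const int k = idx->k;
  std::vector<Span> spans;
  if ((int)read.size() >= k) {
    std::vector<Minimizer> mz = minimizers(read, k, idx->w);
    std::string rc = revcomp(read);
    int qlen = (int)read.size();
    // group anchors by (target, strand)
    std::unordered_map<uint64_t, std::vector<Anchor>> groups;
    for (const Minimizer& m : mz) {
      auto it = idx->table.find(m.hash);
      if (it == idx->table.end()) continue;
      if ((int)it->second.size() > max_occ) continue;  // repeat filter
      for (uint64_t p : it->second) {
        int target = (int)(p >> 33);
        int tpos = (int)((p >> 1) & 0xFFFFFFFFULL);
        int tstrand = (p & 1ULL) ? 1 : -1;
        int rel = (m.strand == tstrand) ? 1 : -1;
        int qq = (rel == 1) ? m.pos : (qlen - k - m.pos);  // rc-frame coord
        uint64_t key = ((uint64_t)target << 1) | (rel == 1 ? 1ULL : 0ULL);
        groups[key].push_back(Anchor{qq, tpos});
      }
    }
    for (auto& kv : groups) {
      int target = (int)(kv.first >> 1);
      int rel = (kv.first & 1ULL) ? 1 : -1;
      std::vector<Chain> chains = chain_anchors(kv.second, k,
                                                min_chain_anchors, max_chains,
                                                max_gap);
      const std::string& qseq = (rel == 1) ? read : rc;
      for (const Chain& ch : chains) {
        Span sp; sp.target = target; sp.strand = rel;
        if (!refine_chain(qseq, idx->seqs[target], kv.second, ch, k, band,
                          xdrop, sp))
          continue;
        if ((double)sp.matches / sp.blocklen < min_identity) continue;
        if (rel == -1) {  // convert rc-frame query coords to read frame
          int qs = qlen - sp.qe, qe = qlen - sp.qs;
          sp.qs = qs; sp.qe = qe;
        }
        spans.push_back(sp);
      }
    }
  }
  // deterministic order: score desc, then target_start asc, then target idx
  std::sort(spans.begin(), spans.end(), [&](const Span& a, const Span& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ts != b.ts) return a.ts < b.ts;
    if (idx->names[a.target] != idx->names[b.target])
      return idx->names[a.target] < idx->names[b.target];
    return a.strand > b.strand;
  });
  int n = (int)spans.size();
  IntegerVector target(n), qs(n), qe(n), ts(n), te(n), matches(n),
      blocklen(n), score(n), nanch(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    const Span& s = spans[i];
    target[i] = s.target + 1;
    qs[i] = s.qs; qe[i] = s.qe; ts[i] = s.ts; te[i] = s.te;
    matches[i] = s.matches; blocklen[i] = s.blocklen; score[i] = s.score;
    nanch[i] = s.n_anchors;
    strand[i] = (s.strand == 1) ? "+" : "-";
  }
  return DataFrame::create(_["target"] = target, _["query_start"] = qs,
                           _["query_end"] = qe, _["target_start"] = ts,
                           _["target_end"] = te, _["strand"] = strand,
                           _["matches"] = matches, _["block_length"] = blocklen,
                           _["score"] = score, _["n_anchors"] = nanch,
                           _["stringsAsFactors"] = false);
}
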