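#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// 2-bit encoding; anything outside ACGT (IUPAC, N) becomes -1 and never
// matches, neither in seeds nor as an aligned identity.
static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)enc(s[i]);
  return v;
}

static inline bool eq(int8_t a, int8_t b) { return a >= 0 && a == b; }

// ---------------------------------------------------------------------------
// Seeding: maximal exact matches of length >= word_size between query and
// subject (single orientation; the caller handles strand by reverse
// complementing the subject).  Each maximal run is reported exactly once,
// anchored at its start.
// ---------------------------------------------------------------------------

struct Seed { int qpos, spos, len; };

// (code, pos) pairs sorted by code: binary-search word index of the subject.
static void subject_word_index(const std::vector<int8_t>& s, int w,
                               std::vector<std::pair<uint64_t, int> >& idx) {
  idx.clear();
  if ((int)s.size() < w) return;
  uint64_t code = 0, mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;  // valid chars accumulated
  for (int i = 0; i < (int)s.size(); ++i) {
    if (s[i] < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)s[i]) & mask;
    if (++run >= w) idx.push_back(std::make_pair(code, i - w + 1));
  }
  std::sort(idx.begin(), idx.end());
}

static void collect_seeds(const std::vector<int8_t>& q,
                          const std::vector<int8_t>& s, int w,
                          const std::vector<std::pair<uint64_t, int> >& idx,
                          std::vector<Seed>& out) {
  out.clear();
  if ((int)q.size() < w || idx.empty()) return;
  uint64_t code = 0, mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;
  for (int i = 0; i < (int)q.size(); ++i) {
    if (q[i] < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)q[i]) & mask;
    if (++run < w) continue;
    int qpos = i - w + 1;
    std::pair<uint64_t, int> key(code, -1);
    size_t lo = std::lower_bound(idx.begin(), idx.end(), key) - idx.begin();
    for (size_t t = lo; t < idx.size() && idx[t].first == code; ++t) {
      int spos = idx[t].second;
      // only the start of a maximal run spawns a seed
      if (qpos > 0 && spos > 0 && eq(q[qpos - 1], s[spos - 1])) continue;
      int len = w;
      while (qpos + len < (int)q.size() && spos + len < (int)s.size() &&
             eq(q[qpos + len], s[spos + len]))
        ++len;
      Seed sd; sd.qpos = qpos; sd.spos = spos; sd.len = len;
      out.push_back(sd);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_seed_hits(std::string query, std::string subject, int word_size) {
  std::vector<int8_t> q = encode(query), s = encode(subject);
  std::vector<std::pair<uint64_t, int> > idx;
  subject_word_index(s, word_size, idx);
  std::vector<Seed> seeds;
  collect_seeds(q, s, word_size, idx, seeds);
  int n = seeds.size();
  IntegerVector qp(n), sp(n), ln(n);
  for (int i = 0; i < n; ++i) {
    qp[i] = seeds[i].qpos; sp[i] = seeds[i].spos; ln[i] = seeds[i].len;
  }
  return DataFrame::create(_["qstart"] = qp, _["sstart"] = sp,
                           _["length"] = ln);
}

// ---------------------------------------------------------------------------
// X-drop Gotoh extension.  Extends an alignment of the first i query chars
// against the first j subject chars starting from an anchor at (0,0); cells
// whose best state falls more than xdrop below the running optimum are
// abandoned.  Sequences are addressed through (origin, dir) so the same code
// extends rightwards and leftwards.
// ---------------------------------------------------------------------------

static const int NEG = INT_MIN / 4;

struct Ext { int score, qlen, slen, matches, cols, gapcols; };

struct TraceRow {
  int lo, hi;                    // inclusive column window
  std::vector<int8_t> tM, tIq, tIs;
};

static Ext xdrop_extend(const std::vector<int8_t>& qseq, int q0, int qdir,
                        int qlen, const std::vector<int8_t>& sseq, int s0,
                        int sdir, int slen, int reward, int penalty,
                        int gopen, int gext, int xdrop) {
  Ext res; res.score = 0; res.qlen = 0; res.slen = 0;
  res.matches = 0; res.cols = 0; res.gapcols = 0;
  if (qlen <= 0 && slen <= 0) return res;

  int gfirst = gopen + gext;
  int best = 0, bi = 0, bj = 0, bstate = 0;  // 0=M 1=Iq 2=Is

  // previous row buffers over window [plo, phi]
  std::vector<int> pM, pIq, pIs, cM, cIq, cIs;
  int plo = 0, phi = 0;
  std::vector<TraceRow> trace(1);

  // row 0: origin plus horizontal (subject-only) gap chain
  {
    TraceRow& tr = trace[0];
    tr.lo = 0;
    pM.clear(); pIq.clear(); pIs.clear();
    pM.push_back(0); pIq.push_back(NEG); pIs.push_back(NEG);
    tr.tM.push_back(0); tr.tIq.push_back(0); tr.tIs.push_back(0);
    int j = 1;
    while (j <= slen) {
      int is = (j == 1) ? -gfirst : pIs[j - 1] - gext;
      if (is < best - xdrop) break;
      pM.push_back(NEG); pIq.push_back(NEG); pIs.push_back(is);
      tr.tM.push_back(0); tr.tIq.push_back(0);
      tr.tIs.push_back(j == 1 ? 0 : 1);
      ++j;
    }
    phi = (int)pM.size() - 1;
    tr.hi = phi;
  }

  for (int i = 1; i <= qlen; ++i) {
    int clo = plo, j = clo;
    cM.clear(); cIq.clear(); cIs.clear();
    TraceRow tr; tr.lo = clo;
    bool any_alive = false;
    int rowbest_j = -1;
    for (;; ++j) {
      if (j > slen) break;
      int diagM = NEG, diagIq = NEG, diagIs = NEG;  // prev row, col j-1
      int upM = NEG, upIq = NEG;                    // prev row, col j
      if (j - 1 >= plo && j - 1 <= phi) {
        diagM = pM[j - 1 - plo]; diagIq = pIq[j - 1 - plo];
        diagIs = pIs[j - 1 - plo];
      }
      if (j >= plo && j <= phi) { upM = pM[j - plo]; upIq = pIq[j - plo]; }
      int leftM = NEG, leftIs = NEG;                // current row, col j-1
      if (j - 1 >= clo && (int)cM.size() > 0) {
        leftM = cM[j - 1 - clo]; leftIs = cIs[j - 1 - clo];
      }

      int m = NEG; int8_t tm = 0;
      if (j >= 1) {
        int dbest = diagM; tm = 0;
        if (diagIq > dbest) { dbest = diagIq; tm = 1; }
        if (diagIs > dbest) { dbest = diagIs; tm = 2; }
        if (dbest > NEG) {
          int8_t qc = qseq[q0 + qdir * (i - 1)];
          int8_t sc = sseq[s0 + sdir * (j - 1)];
          m = dbest + (eq(qc, sc) ? reward : penalty);
        }
      }
      int iq = NEG; int8_t tiq = 0;
      if (upM > NEG && upM - gfirst > iq) { iq = upM - gfirst; tiq = 0; }
      if (upIq > NEG && upIq - gext > iq) { iq = upIq - gext; tiq = 1; }
      int is = NEG; int8_t tis = 0;
      if (leftM > NEG && leftM - gfirst > is) { is = leftM - gfirst; tis = 0; }
      if (leftIs > NEG && leftIs - gext > is) { is = leftIs - gext; tis = 1; }

      int cellbest = std::max(m, std::max(iq, is));
      bool alive = cellbest >= best - xdrop && cellbest > NEG;
      if (!alive) { m = iq = is = NEG; }
      if (!any_alive && !alive) {
        // window has not started yet: slide clo forward
        if (j >= phi + 1) break;  // nothing downstream can revive
        clo = j + 1; tr.lo = clo;
        continue;
      }
      cM.push_back(m); cIq.push_back(iq); cIs.push_back(is);
      tr.tM.push_back(tm); tr.tIq.push_back(tiq); tr.tIs.push_back(tis);
      if (alive) {
        any_alive = true; rowbest_j = j;
        if (cellbest > best) {
          best = cellbest; bi = i; bj = j;
          bstate = (cellbest == m) ? 0 : (cellbest == iq ? 1 : 2);
        }
      }
      if (!alive && j > phi) break;
    }
    if (!any_alive) break;
    // trim dead tail
    while (!cM.empty() && cM.back() == NEG && cIq.back() == NEG &&
           cIs.back() == NEG) {
      cM.pop_back(); cIq.pop_back(); cIs.pop_back();
      tr.tM.pop_back(); tr.tIq.pop_back(); tr.tIs.pop_back();
    }
    (void)rowbest_j;
    tr.hi = tr.lo + (int)cM.size() - 1;
    trace.push_back(tr);
    pM.swap(cM); pIq.swap(cIq); pIs.swap(cIs);
    plo = tr.lo; phi = tr.hi;
  }

  // traceback from the best cell
  res.score = best; res.qlen = bi; res.slen = bj;
  int i = bi, j = bj, st = bstate;
  while (i > 0 || j > 0) {
    const TraceRow& tr = trace[i];
    int off = j - tr.lo;
    if (st == 0) {
      res.cols++;
      if (eq(qseq[q0 + qdir * (i - 1)], sseq[s0 + sdir * (j - 1)]))
        res.matches++;
      st = tr.tM[off]; --i; --j;
    } else if (st == 1) {
      res.cols++; res.gapcols++;
      st = (tr.tIq[off] == 0) ? 0 : 1; --i;
    } else {
      res.cols++; res.gapcols++;
      st = (tr.tIs[off] == 0) ? 0 : 2; --j;
    }
  }
  return res;
}

// Extend a single seed in both directions; returns one row.
struct Hit {
  int qstart, qend, sstart, send;  // 0-based half-open
  int score, matches, cols, gapcols;
};

static Hit extend_seed(const std::vector<int8_t>& q,
                       const std::vector<int8_t>& s, const Seed& sd,
                       int reward, int penalty, int gopen, int gext,
                       int xdrop) {
  Ext right = xdrop_extend(q, sd.qpos + sd.len, +1,
                           (int)q.size() - sd.qpos - sd.len, s,
                           sd.spos + sd.len, +1,
                           (int)s.size() - sd.spos - sd.len, reward, penalty,
                           gopen, gext, xdrop);
  Ext left = xdrop_extend(q, sd.qpos - 1, -1, sd.qpos, s, sd.spos - 1, -1,
                          sd.spos, reward, penalty, gopen, gext, xdrop);
  Hit h;
  h.qstart = sd.qpos - left.qlen;
  h.qend = sd.qpos + sd.len + right.qlen;
  h.sstart = sd.spos - left.slen;
  h.send = sd.spos + sd.len + right.slen;
  h.score = sd.len * reward + left.score + right.score;
  h.matches = sd.len + left.matches + right.matches;
  h.cols = sd.len + left.cols + right.cols;
  h.gapcols = left.gapcols + right.gapcols;
  return h;
}

// [[Rcpp::export]]
List cpp_extend_one(std::string query, std::string subject, int qpos, int spos,
                    int seed_len, int reward, int penalty, int gap_open,
                    int gap_extend, int xdrop) {
  std::vector<int8_t> q = encode(query), s = encode(subject);
  Seed sd; sd.qpos = qpos; sd.spos = spos; sd.len = seed_len;
  Hit h = extend_seed(q, s, sd, reward, penalty, gap_open, gap_extend, xdrop);
  return List::create(_["qstart"] = h.qstart, _["qend"] = h.qend,
                      _["sstart"] = h.sstart, _["send"] = h.send,
                      _["score"] = h.score, _["matches"] = h.matches,
                      _["aligned_cols"] = h.cols, _["gaps"] = h.gapcols);
}

// ---------------------------------------------------------------------------
// Whole search, one subject orientation, many queries.  Seeds are processed
// longest first; a seed whose midpoint already lies inside an accepted hit of
// the same query is redundant and skipped.
// ---------------------------------------------------------------------------

static bool seed_longer(const Seed& a, const Seed& b) { return a.len > b.len; }

// [[Rcpp::export]]
DataFrame cpp_search(std::string subject, CharacterVector queries,
                     int word_size, int reward, int penalty, int gap_open,
                     int gap_extend, int xdrop) {
  std::vector<int8_t> s = encode(subject);
  std::vector<std::pair<uint64_t, int> > idx;
  subject_word_index(s, word_size, idx);

  std::vector<int> o_q, o_qs, o_qe, o_ss, o_se, o_sc, o_mt, o_cl, o_gp;
  std::vector<Seed> seeds;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qs = as<std::string>(queries[qi]);
    std::vector<int8_t> q = encode(qs);
    collect_seeds(q, s, word_size, idx, seeds);
    std::sort(seeds.begin(), seeds.end(), seed_longer);
    std::vector<Hit> hits;
    for (size_t k = 0; k < seeds.size(); ++k) {
      const Seed& sd = seeds[k];
      int qm = sd.qpos + sd.len / 2, sm = sd.spos + sd.len / 2;
      bool covered = false;
      for (size_t h = 0; h < hits.size(); ++h) {
        if (qm >= hits[h].qstart && qm < hits[h].qend && sm >= hits[h].sstart &&
            sm < hits[h].send) { covered = true; break; }
      }
      if (covered) continue;
      hits.push_back(extend_seed(q, s, sd, reward, penalty, gap_open,
                                 gap_extend, xdrop));
    }
    // drop exact duplicates
    for (size_t h = 0; h < hits.size(); ++h) {
      bool dup = false;
      for (size_t g = 0; g < h; ++g) {
        if (hits[g].qstart == hits[h].qstart && hits[g].qend == hits[h].qend &&
            hits[g].sstart == hits[h].sstart && hits[g].send == hits[h].send) {
          dup = true; break;
        }
      }
      if (dup) continue;
      o_q.push_back(qi + 1);
      o_qs.push_back(hits[h].qstart); o_qe.push_back(hits[h].qend);
      o_ss.push_back(hits[h].sstart); o_se.push_back(hits[h].send);
      o_sc.push_back(hits[h].score); o_mt.push_back(hits[h].matches);
      o_cl.push_back(hits[h].cols); o_gp.push_back(hits[h].gapcols);
    }
  }
  return DataFrame::create(
      _["query"] = wrap(o_q), _["qstart"] = wrap(o_qs), _["qend"] = wrap(o_qe),
      _["sstart"] = wrap(o_ss), _["send"] = wrap(o_se),
      _["score"] = wrap(o_sc), _["matches"] = wrap(o_mt),
      _["aligned_cols"] = wrap(o_cl), _["gaps"] = wrap(o_gp));
}
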