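#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Seed-and-extend read mapper: flat-hash k-mer index over the reference
// (open addressing + CSR position lists), merged seed diagonals verified
// by banded semi-global edit distance.  With non-overlapping seeds of
// size k and floor(L/k) >= max_edit + 1 seeds, the pigeonhole principle
// guarantees every alignment with <= max_edit differences is seeded.
// Deterministic throughout (no RNG).

struct GenomeIndex {
  int k;
  uint64_t mask;      // 2k-bit kmer mask
  uint64_t hmask;     // hash table size - 1 (power of two)
  std::vector<std::string> seqs;
  std::vector<uint64_t> keys;   // kmer + 1 (0 = empty slot)
  std::vector<uint64_t> range;  // (start << 24) | count into pos[]
  std::vector<uint64_t> pos;    // (refid << 40) | position
};

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0; case 'C': case 'c': return 1;
  case 'G': case 'g': return 2; case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k = 14) {
  GenomeIndex* gi = new GenomeIndex();
  gi->k = k;
  gi->mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  size_t total = 0;
  for (int r = 0; r < seqs.size(); ++r) {
    gi->seqs.push_back(as<std::string>(seqs[r]));
    total += gi->seqs.back().size();
  }
  // collect (kmer, packed position)
  std::vector<std::pair<uint64_t, uint64_t>> kp;
  kp.reserve(total);
  for (size_t r = 0; r < gi->seqs.size(); ++r) {
    const std::string& s = gi->seqs[r];
    uint64_t h = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = baseCode(s[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & gi->mask;
      if (++run >= k)
        kp.push_back(std::make_pair(h, ((uint64_t)r << 40) | (i + 1 - k)));
    }
  }
  std::sort(kp.begin(), kp.end());
  gi->pos.resize(kp.size());
  for (size_t i = 0; i < kp.size(); ++i) gi->pos[i] = kp[i].second;
  // open-addressing table at load factor <= 0.5
  uint64_t tabsize = 64;
  while (tabsize < 2 * kp.size() + 1) tabsize <<= 1;
  gi->hmask = tabsize - 1;
  gi->keys.assign(tabsize, 0);
  gi->range.assign(tabsize, 0);
  size_t i = 0;
  while (i < kp.size()) {
    size_t j = i;
    while (j < kp.size() && kp[j].first == kp[i].first) ++j;
    uint64_t key = kp[i].first + 1;
    uint64_t slot = mix64(kp[i].first) & gi->hmask;
    while (gi->keys[slot]) slot = (slot + 1) & gi->hmask;
    gi->keys[slot] = key;
    gi->range[slot] = ((uint64_t)i << 24) | (uint64_t)(j - i);
    i = j;
  }
  XPtr<GenomeIndex> p(gi, true);
  return p;
}

// [[Rcpp::export]]
IntegerVector cpp_index_info(SEXP idx) {
  XPtr<GenomeIndex> gi(idx);
  return IntegerVector::create(_["k"] = gi->k,
                               _["n_seq"] = (int)gi->seqs.size(),
                               _["n_pos"] = (int)gi->pos.size());
}

static inline bool lookup(const GenomeIndex* gi, uint64_t kmer,
                          uint32_t& start, uint32_t& count) {
  uint64_t slot = mix64(kmer) & gi->hmask;
  uint64_t key = kmer + 1;
  while (true) {
    uint64_t k = gi->keys[slot];
    if (k == 0) return false;
    if (k == key) {
      start = (uint32_t)(gi->range[slot] >> 24);
      count = (uint32_t)(gi->range[slot] & 0xffffff);
      return true;
    }
    slot = (slot + 1) & gi->hmask;
  }
}

struct Hit { int refid; int pos; int alen; int strand; int ed; };

struct Workspace {
  std::vector<std::pair<int, int>> cand; // (refid, diag)
  std::vector<int> Dprev, Dcur, Sprev, Scur;
  std::vector<Hit> hits;
  std::string rev;
};

// banded semi-global: full read against ref window, free ref ends.
static bool bandedAlign(const std::string& read, const std::string& ref,
                        int wstart, int wend, int dlo, int dhi, int max_edit,
                        Workspace& ws, int& ed, int& astart, int& aend) {
  int m = read.size(), n = wend - wstart;
  if (n <= 0) return false;
  dlo = dlo - wstart - max_edit;
  dhi = dhi - wstart + max_edit;
  if (dlo < -m) dlo = -m;
  if (dhi > n) dhi = n;
  if (dlo > dhi) return false;
  int W = dhi - dlo + 1;
  const int INF = 1 << 28;
  ws.Dprev.assign(W, INF); ws.Dcur.assign(W, INF);
  ws.Sprev.assign(W, 0); ws.Scur.assign(W, 0);
  int* Dp = ws.Dprev.data(); int* Dc = ws.Dcur.data();
  int* Sp = ws.Sprev.data(); int* Sc = ws.Scur.data();
  for (int b = 0; b < W; ++b) {
    int j = dlo + b;
    if (j >= 0 && j <= n) { Dp[b] = 0; Sp[b] = j; }
  }
  const char* rf = ref.data() + wstart;
  for (int i = 1; i <= m; ++i) {
    char rc = read[i - 1];
    int blo = std::max(0, 1 - (i + dlo));      // ensure j >= 1
    int bhi = std::min(W - 1, n - (i + dlo));  // ensure j <= n
    for (int b = 0; b < W; ++b) Dc[b] = INF;
    for (int b = blo; b <= bhi; ++b) {
      int j = i + dlo + b;
      int bestv = INF, bests = 0;
      int dv = Dp[b]; // (i-1, j-1), same band offset
      if (dv < INF) {
        char tc = rf[j - 1];
        int v = dv + ((rc == tc && rc != 'N') ? 0 : 1);
        if (v < bestv) { bestv = v; bests = Sp[b]; }
      }
      if (b + 1 < W) {
        int v = Dp[b + 1]; // (i-1, j): consume read
        if (v < INF && v + 1 < bestv) { bestv = v + 1; bests = Sp[b + 1]; }
      }
      if (b - 1 >= 0) {
        int v = Dc[b - 1]; // (i, j-1): consume ref
        if (v < INF && v + 1 < bestv) { bestv = v + 1; bests = Sc[b - 1]; }
      }
      Dc[b] = bestv; Sc[b] = bests;
    }
    std::swap(Dp, Dc); std::swap(Sp, Sc);
  }
  int bestv = INF, bestj = -1, bests = 0;
  for (int b = 0; b < W; ++b) {
    int j = m + dlo + b;
    if (j < 0 || j > n) continue;
    if (Dp[b] < bestv || (Dp[b] == bestv && Sp[b] < bests)) {
      bestv = Dp[b]; bestj = j; bests = Sp[b];
    }
  }
  if (bestv > max_edit || bestj < 0) return false;
  ed = bestv; astart = wstart + bests; aend = wstart + bestj;
  return true;
}

static void mapOne(const GenomeIndex* gi, const std::string& fwd,
                   int max_edit, Workspace& ws) {
  int k = gi->k;
  int m = fwd.size();
  ws.hits.clear();
  ws.rev.assign(fwd.rbegin(), fwd.rend());
  for (size_t i = 0; i < ws.rev.size(); ++i) {
    switch (ws.rev[i]) {
    case 'A': ws.rev[i] = 'T'; break; case 'C': ws.rev[i] = 'G'; break;
    case 'G': ws.rev[i] = 'C'; break; case 'T': ws.rev[i] = 'A'; break;
    default: break;
    }
  }
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& s = strand == 0 ? fwd : ws.rev;
    if (m < k) continue;
    ws.cand.clear();
    int nseed = m / k;
    for (int si = 0; si <= nseed; ++si) {
      int o = si < nseed ? si * k : m - k;
      if (si == nseed && o == (nseed - 1) * k) break; // tail == last seed
      uint64_t h = 0; bool okseed = true;
      for (int x = 0; x < k; ++x) {
        int c = baseCode(s[o + x]);
        if (c < 0) { okseed = false; break; }
        h = (h << 2) | (uint64_t)c;
      }
      if (!okseed) continue;
      h &= gi->mask;
      uint32_t start, count;
      if (!lookup(gi, h, start, count)) continue;
      if (count > 5000) continue; // overly promiscuous seed
      for (uint32_t x = 0; x < count; ++x) {
        uint64_t v = gi->pos[start + x];
        int refid = (int)(v >> 40);
        int p = (int)(v & ((1ULL << 40) - 1));
        ws.cand.push_back(std::make_pair(refid, p - o));
      }
    }
    if (ws.cand.empty()) continue;
    std::sort(ws.cand.begin(), ws.cand.end());
    ws.cand.erase(std::unique(ws.cand.begin(), ws.cand.end()), ws.cand.end());
    size_t i0 = 0;
    while (i0 < ws.cand.size()) {
      size_t i1 = i0;
      while (i1 + 1 < ws.cand.size() &&
             ws.cand[i1 + 1].first == ws.cand[i0].first &&
             ws.cand[i1 + 1].second - ws.cand[i1].second <= max_edit)
        ++i1;
      int refid = ws.cand[i0].first;
      int dlo = ws.cand[i0].second, dhi = ws.cand[i1].second;
      const std::string& ref = gi->seqs[refid];
      int n = ref.size();
      int wstart = std::max(0, dlo - max_edit);
      int wend = std::min(n, dhi + m + max_edit);
      int ed, as, ae;
      if (bandedAlign(s, ref, wstart, wend, dlo, dhi, max_edit, ws, ed, as,
                      ae)) {
        Hit h; h.refid = refid; h.pos = as; h.alen = ae - as;
        h.strand = strand; h.ed = ed;
        ws.hits.push_back(h);
      }
      i0 = i1 + 1;
    }
  }
  // dedupe overlapping placements on the same strand: keep best
  std::vector<Hit>& hits = ws.hits;
  if (hits.size() > 1) {
    std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.refid != b.refid) return a.refid < b.refid;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.ed < b.ed;
    });
    size_t out = 0;
    for (size_t i = 0; i < hits.size(); ++i) {
      if (out > 0 && hits[out - 1].refid == hits[i].refid &&
          hits[out - 1].strand == hits[i].strand &&
          hits[i].pos - hits[out - 1].pos < m / 2) {
        if (hits[i].ed < hits[out - 1].ed) hits[out - 1] = hits[i];
      } else hits[out++] = hits[i];
    }
    hits.resize(out);
  }
}

// mode 0: best-hit summary, one row per read.
// mode 1: all hits (match sets), one row per hit.
// [[Rcpp::export]]
List cpp_map_reads(SEXP idx, CharacterVector reads, int max_edit = 6,
                   int mode = 0) {
  XPtr<GenomeIndex> gi(idx);
  int n = reads.size();
  Workspace ws;
  if (mode == 0) {
    IntegerVector refid(n, NA_INTEGER), pos(n, NA_INTEGER),
        alen(n, NA_INTEGER), ed(n, NA_INTEGER), nbest(n, 0),
        second(n, NA_INTEGER), strand(n, NA_INTEGER);
    LogicalVector mapped(n, false);
    for (int i = 0; i < n; ++i) {
      mapOne(gi, as<std::string>(reads[i]), max_edit, ws);
      std::vector<Hit>& hits = ws.hits;
      if (hits.empty()) continue;
      std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
        if (a.ed != b.ed) return a.ed < b.ed;
        if (a.refid != b.refid) return a.refid < b.refid;
        if (a.pos != b.pos) return a.pos < b.pos;
        return a.strand < b.strand;
      });
      int emin = hits[0].ed, nb = 0, sec = -1;
      for (size_t x = 0; x < hits.size(); ++x) {
        if (hits[x].ed == emin) ++nb;
        else { sec = hits[x].ed; break; }
      }
      mapped[i] = true; refid[i] = hits[0].refid + 1; pos[i] = hits[0].pos;
      alen[i] = hits[0].alen; strand[i] = hits[0].strand; ed[i] = emin;
      nbest[i] = nb;
      if (sec >= 0) second[i] = sec;
    }
    return List::create(_["mapped"] = mapped, _["refid"] = refid,
                        _["pos"] = pos, _["alen"] = alen,
                        _["strand"] = strand, _["ed"] = ed,
                        _["n_best"] = nbest, _["second_ed"] = second);
  } else {
    std::vector<int> rrow, rrefid, rpos, ralen, rstrand, red;
    for (int i = 0; i < n; ++i) {
      mapOne(gi, as<std::string>(reads[i]), max_edit, ws);
      for (size_t x = 0; x < ws.hits.size(); ++x) {
        rrow.push_back(i + 1); rrefid.push_back(ws.hits[x].refid + 1);
        rpos.push_back(ws.hits[x].pos); ralen.push_back(ws.hits[x].alen);
        rstrand.push_back(ws.hits[x].strand); red.push_back(ws.hits[x].ed);
      }
    }
    return List::create(_["read"] = wrap(rrow), _["refid"] = wrap(rrefid),
                        _["pos"] = wrap(rpos), _["alen"] = wrap(ralen),
                        _["strand"] = wrap(rstrand), _["ed"] = wrap(red));
  }
}
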