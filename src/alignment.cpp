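#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const int NEG = -1000000000;

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) {
      switch (r[j]) {
      case 'A': r[j] = 'T'; break; case 'C': r[j] = 'G'; break;
      case 'G': r[j] = 'C'; break; case 'T': r[j] = 'A'; break;
      case 'a': r[j] = 't'; break; case 'c': r[j] = 'g'; break;
      case 'g': r[j] = 'c'; break; case 't': r[j] = 'a'; break;
      default: break; // N and IUPAC codes stay as-is
      }
    }
    out[i] = r;
  }
  return out;
}

// Affine-gap Smith-Waterman with traceback.  Intended for reads vs regions
// up to a few tens of kb (full matrices).  Coordinates 0-based half-open.
// [[Rcpp::export]]
List cpp_sw(std::string q, std::string t, int match = 2, int mismatch = -3,
            int gap_open = -5, int gap_extend = -2) {
  int m = q.size(), n = t.size();
  size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<int> H(sz, 0), E(sz, NEG), F(sz, NEG);
  std::vector<unsigned char> tbH(sz, 0), tbE(sz, 0), tbF(sz, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t)i * (n + 1) + j;
      size_t up = idx - (n + 1), left = idx - 1, dg = up - 1;
      int eo = H[left] + gap_open + gap_extend, ee = E[left] + gap_extend;
      E[idx] = eo >= ee ? eo : ee; tbE[idx] = eo >= ee ? 1 : 0;
      int fo = H[up] + gap_open + gap_extend, fe = F[up] + gap_extend;
      F[idx] = fo >= fe ? fo : fe; tbF[idx] = fo >= fe ? 1 : 0;
      int sc = (q[i - 1] == t[j - 1] && q[i - 1] != 'N') ? match : mismatch;
      int diag = H[dg] + sc;
      int h = 0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (F[idx] > h) { h = F[idx]; tb = 2; }
      if (E[idx] > h) { h = E[idx]; tb = 3; }
      H[idx] = h; tbH[idx] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, matches = 0, cols = 0, state = 0;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        ++cols; if (q[i - 1] == t[j - 1] && q[i - 1] != 'N') ++matches;
        --i; --j;
      } else if (tb == 2) state = 2; else state = 3;
    } else if (state == 2) { // gap in target, consume query
      ++cols; if (tbF[idx] == 1) state = 0; --i;
    } else {                 // gap in query, consume target
      ++cols; if (tbE[idx] == 1) state = 0; --j;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = i, _["qend"] = bi,
                      _["tstart"] = j, _["tend"] = bj,
                      _["matches"] = matches, _["cols"] = cols);
}

// Global alignment with free end gaps (overlap/glocal), affine gaps, banded.
// Band restricts diagonal d = j - i to [dlo, dhi]; dlo > dhi disables band.
// Mismatch/gap accounting excludes the free end gaps; `cols` counts aligned
// core columns only.
// [[Rcpp::export]]
List cpp_align_endfree(std::string q, std::string t, int match = 2,
                       int mismatch = -3, int gap_open = -5, int gap_extend = -2,
                       int dlo = 1, int dhi = 0) {
  int m = q.size(), n = t.size();
  bool banded = dlo <= dhi;
  if (!banded) { dlo = -m; dhi = n; }
  int W = dhi - dlo + 1;
  size_t sz = (size_t)(m + 1) * W;
  std::vector<int> H(sz, NEG), E(sz, NEG), F(sz, NEG);
  std::vector<unsigned char> tbH(sz, 255), tbE(sz, 0), tbF(sz, 0);
  auto IDX = [&](int i, int j) { return (size_t)i * W + (size_t)(j - i - dlo); };
  auto inband = [&](int i, int j) {
    int d = j - i; return d >= dlo && d <= dhi && j >= 0 && j <= n;
  };
  for (int j = 0; j <= n; ++j) if (inband(0, j)) { H[IDX(0, j)] = 0; tbH[IDX(0, j)] = 0; }
  for (int i = 0; i <= m; ++i) if (inband(i, 0)) { H[IDX(i, 0)] = 0; tbH[IDX(i, 0)] = 0; }
  for (int i = 1; i <= m; ++i) {
    int jmin = std::max(1, i + dlo), jmax = std::min(n, i + dhi);
    for (int j = jmin; j <= jmax; ++j) {
      size_t idx = IDX(i, j);
      int e = NEG, f = NEG; unsigned char te = 0, tf = 0;
      if (inband(i, j - 1)) {
        int eo = H[IDX(i, j - 1)], ee = E[IDX(i, j - 1)];
        eo = eo > NEG / 2 ? eo + gap_open + gap_extend : NEG;
        ee = ee > NEG / 2 ? ee + gap_extend : NEG;
        e = eo >= ee ? eo : ee; te = eo >= ee ? 1 : 0;
      }
      if (inband(i - 1, j)) {
        int fo = H[IDX(i - 1, j)], fe = F[IDX(i - 1, j)];
        fo = fo > NEG / 2 ? fo + gap_open + gap_extend : NEG;
        fe = fe > NEG / 2 ? fe + gap_extend : NEG;
        f = fo >= fe ? fo : fe; tf = fo >= fe ? 1 : 0;
      }
      E[idx] = e; tbE[idx] = te;
      F[idx] = f; tbF[idx] = tf;
      int h = NEG; unsigned char tb = 255;
      if (inband(i - 1, j - 1) && H[IDX(i - 1, j - 1)] > NEG / 2) {
        int sc = (q[i - 1] == t[j - 1] && q[i - 1] != 'N') ? match : mismatch;
        h = H[IDX(i - 1, j - 1)] + sc; tb = 1;
      }
      if (f > h) { h = f; tb = 2; }
      if (e > h) { h = e; tb = 3; }
      H[idx] = h; tbH[idx] = tb;
    }
  }
  int best = NEG, bi = -1, bj = -1;
  for (int j = 0; j <= n; ++j)
    if (inband(m, j) && H[IDX(m, j)] > best) { best = H[IDX(m, j)]; bi = m; bj = j; }
  for (int i = 0; i <= m; ++i)
    if (inband(i, n) && H[IDX(i, n)] > best) { best = H[IDX(i, n)]; bi = i; bj = n; }
  if (bi < 0) return List::create(_["score"] = NA_INTEGER);
  int i = bi, j = bj, matches = 0, mism = 0, gapcols = 0, cols = 0, state = 0;
  while (i > 0 && j > 0) {
    size_t idx = IDX(i, j);
    if (state == 0) {
      unsigned char tb = tbH[idx];
      if (tb == 0 || tb == 255) break;
      if (tb == 1) {
        ++cols;
        if (q[i - 1] == t[j - 1] && q[i - 1] != 'N') ++matches; else ++mism;
        --i; --j;
      } else if (tb == 2) state = 2; else state = 3;
    } else if (state == 2) {
      ++cols; ++gapcols; if (tbF[idx] == 1) state = 0; --i;
    } else {
      ++cols; ++gapcols; if (tbE[idx] == 1) state = 0; --j;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["mismatches"] = mism, _["gapcols"] = gapcols,
                      _["cols"] = cols, _["qstart"] = i, _["qend"] = bi,
                      _["tstart"] = j, _["tend"] = bj);
}

// [[Rcpp::export]]
CharacterVector cpp_revstr(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::reverse(s.begin(), s.end());
    out[i] = s;
  }
  return out;
}
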