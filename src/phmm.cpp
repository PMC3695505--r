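#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>
#include <cmath>
using namespace Rcpp;

// Anchored Viterbi decoding of reads against a profile HMM.
//
// Model layout: match columns 1..K; insert states I_0..I_K (I_j follows
// column j); delete states D_1..D_K.  logTr is a (K+1) x 7 matrix, row j
// (0-based j = from-column 0..K) with columns
//   0 M_j->M_{j+1}, 1 M_j->I_j, 2 M_j->D_{j+1},
//   3 I_j->M_{j+1}, 4 I_j->I_j, 5 D_j->M_{j+1}, 6 D_j->D_{j+1}.
// Entry is free (local in the model) at any match/insert state whose
// column lies within [anchor - window, anchor + window]; exit is free
// after the last read base, so scores are comparable across models.
// Emission of 'N' (or any non-ACGT code) scores 1/4.

static inline int bcode(char c) {
  switch (c) {
  case 'A': case 'a': return 0; case 'C': case 'c': return 1;
  case 'G': case 'g': return 2; case 'T': case 't': return 3;
  default: return -1;
  }
}

struct VitResult {
  double logp;
  // path as parallel vectors, in forward order
  std::vector<int> state, col, readpos;
};

static const double VNEG = -1e30;

// core decoder; paths built only when want_path
static bool viterbi_core(const std::string& s, const NumericMatrix& logEm,
                         const NumericMatrix& logTr, double logEins,
                         int anchor, int window, bool want_path,
                         VitResult& res) {
  int m = s.size(), K = logEm.nrow();
  if (m < 1 || anchor < 1 || anchor > K) return false;
  int elo = std::max(1, anchor - window), ehi = std::min(K, anchor + window);
  int clo = std::max(0, elo - 2), chi = std::min(K, ehi + m + 16);
  int W = chi - clo + 1;
  size_t sz = (size_t)(m + 1) * W;
  static thread_local std::vector<double> VM, VI, VD;
  static thread_local std::vector<unsigned char> TM, TI, TD;
  VM.assign(sz, VNEG); VI.assign(sz, VNEG); VD.assign(sz, VNEG);
  TM.assign(sz, 0); TI.assign(sz, 0); TD.assign(sz, 0);
  std::vector<int> sc(m);
  for (int i = 0; i < m; ++i) sc[i] = bcode(s[i]);
  const double lquarter = std::log(0.25);
  auto IX = [&](int i, int j) { return (size_t)i * W + (j - clo); };
  auto em = [&](int j, int i) {
    return sc[i] >= 0 ? logEm(j - 1, sc[i]) : lquarter;
  };
  for (int j = std::max(clo, elo); j <= ehi; ++j) {
    if (j >= 1) VM[IX(1, j)] = em(j, 0);
  }
  for (int j = std::max(clo, elo - 1); j <= ehi; ++j)
    VI[IX(1, j)] = logEins;
  for (int j = std::max(clo, 1); j <= chi; ++j) {
    double fm = (j - 1 >= clo && j - 1 >= 1) ?
        VM[IX(1, j - 1)] + logTr(j - 1, 2) : VNEG;
    double fd = (j - 1 >= clo && j - 1 >= 1) ?
        VD[IX(1, j - 1)] + logTr(j - 1, 6) : VNEG;
    if (fm >= fd) { if (fm > VNEG / 2) { VD[IX(1, j)] = fm; TD[IX(1, j)] = 1; } }
    else if (fd > VNEG / 2) { VD[IX(1, j)] = fd; TD[IX(1, j)] = 3; }
  }
  for (int i = 2; i <= m; ++i) {
    int ei = sc[i - 1];
    for (int j = clo; j <= chi; ++j) {
      size_t ix = IX(i, j);
      if (j >= 1 && j - 1 >= clo) {
        double a = VM[IX(i - 1, j - 1)] + logTr(j - 1, 0);
        double b = VI[IX(i - 1, j - 1)] + logTr(j - 1, 3);
        double c = (j - 1 >= 1) ? VD[IX(i - 1, j - 1)] + logTr(j - 1, 5) : VNEG;
        double bm = a; unsigned char tb = 1;
        if (b > bm) { bm = b; tb = 2; }
        if (c > bm) { bm = c; tb = 3; }
        if (bm > VNEG / 2) {
          VM[ix] = (ei >= 0 ? logEm(j - 1, ei) : lquarter) + bm;
          TM[ix] = tb;
        }
      }
      {
        double a = VM[IX(i - 1, j)] + logTr(j, 1);
        double b = VI[IX(i - 1, j)] + logTr(j, 4);
        if (a >= b) {
          if (a > VNEG / 2) { VI[ix] = (ei >= 0 ? lquarter : lquarter) + a; TI[ix] = 1; }
        } else if (b > VNEG / 2) { VI[ix] = lquarter + b; TI[ix] = 2; }
      }
      if (j >= 1 && j - 1 >= clo) {
        double fm = VM[IX(i, j - 1)] + logTr(j - 1, 2);
        double fd = (j - 1 >= 1) ? VD[IX(i, j - 1)] + logTr(j - 1, 6) : VNEG;
        if (fm >= fd) { if (fm > VNEG / 2) { VD[ix] = fm; TD[ix] = 1; } }
        else if (fd > VNEG / 2) { VD[ix] = fd; TD[ix] = 3; }
      }
    }
  }
  double best = VNEG; int bj = -1, bstate = -1;
  for (int j = clo; j <= chi; ++j) {
    if (j >= 1 && VM[IX(m, j)] > best) { best = VM[IX(m, j)]; bj = j; bstate = 0; }
    if (VI[IX(m, j)] > best) { best = VI[IX(m, j)]; bj = j; bstate = 1; }
  }
  if (bj < 0 || best < VNEG / 2) return false;
  res.logp = best;
  if (!want_path) return true;
  res.state.clear(); res.col.clear(); res.readpos.clear();
  int i = m, j = bj, st = bstate;
  while (true) {
    res.state.push_back(st); res.col.push_back(j);
    res.readpos.push_back(st == 2 ? 0 : i);
    unsigned char tb;
    if (st == 0) tb = TM[IX(i, j)];
    else if (st == 1) tb = TI[IX(i, j)];
    else tb = TD[IX(i, j)];
    if (st == 0) {
      if (i == 1 || tb == 0) break;
      --i; --j; st = tb == 1 ? 0 : (tb == 2 ? 1 : 2);
    } else if (st == 1) {
      if (i == 1 || tb == 0) break;
      --i; st = tb == 1 ? 0 : 1;
    } else {
      --j; st = tb == 1 ? 0 : 2;
    }
  }
  std::reverse(res.state.begin(), res.state.end());
  std::reverse(res.col.begin(), res.col.end());
  std::reverse(res.readpos.begin(), res.readpos.end());
  return true;
}

// [[Rcpp::export]]
List cpp_viterbi(std::string s, NumericMatrix logEm, NumericMatrix logTr,
                 double logEins, int anchor, int window) {
  if (anchor < 1 || anchor > logEm.nrow()) stop("anchor outside template");
  VitResult res;
  if (!viterbi_core(s, logEm, logTr, logEins, anchor, window, true, res))
    return List::create(_["logp"] = R_NegInf, _["path"] = R_NilValue);
  int np = res.state.size();
  IntegerMatrix path(np, 3);
  for (int x = 0; x < np; ++x) {
    path(x, 0) = res.state[x]; path(x, 1) = res.col[x];
    path(x, 2) = res.readpos[x];
  }
  colnames(path) = CharacterVector::create("state", "col", "readpos");
  return List::create(_["logp"] = res.logp, _["path"] = path);
}

// batched log-probabilities only (recruiting)
// [[Rcpp::export]]
NumericVector cpp_phmm_score(CharacterVector seqs, NumericMatrix logEm,
                             NumericMatrix logTr, double logEins,
                             IntegerVector anchors, int window) {
  int n = seqs.size();
  NumericVector out(n, R_NegInf);
  VitResult res;
  for (int i = 0; i < n; ++i) {
    if (anchors[i] == NA_INTEGER) continue;
    if (viterbi_core(as<std::string>(seqs[i]), logEm, logTr, logEins,
                     anchors[i], window, false, res))
      out[i] = res.logp;
  }
  return out;
}

// batched align-and-accumulate (retraining): returns emission counts,
// transition counts, per-column read depth / match / delete usage,
// junction spanning counts and insert events
// [[Rcpp::export]]
List cpp_phmm_train(CharacterVector seqs, NumericMatrix logEm,
                    NumericMatrix logTr, double logEins,
                    IntegerVector anchors, int window) {
  int n = seqs.size(), K = logEm.nrow();
  NumericMatrix counts_em(K, 4), counts_tr(K + 1, 7);
  IntegerVector depth(K), matchc(K), delc(K), junction(K + 1);
  std::vector<int> ins_col; std::vector<std::string> ins_str;
  NumericVector logps(n, R_NegInf);
  VitResult res;
  for (int i = 0; i < n; ++i) {
    if (anchors[i] == NA_INTEGER) continue;
    std::string s = as<std::string>(seqs[i]);
    if (!viterbi_core(s, logEm, logTr, logEins, anchors[i], window, true,
                      res)) continue;
    logps[i] = res.logp;
    int np = res.state.size();
    int cmin = K + 1, cmax = 0;
    for (int x = 0; x < np; ++x) {
      int st = res.state[x], j = res.col[x], rp = res.readpos[x];
      if (st == 0 && j >= 1 && j <= K) {
        int b = bcode(s[rp - 1]);
        if (b >= 0) counts_em(j - 1, b) += 1;
        matchc[j - 1] += 1;
        if (j < cmin) cmin = j; if (j > cmax) cmax = j;
      } else if (st == 2 && j >= 1 && j <= K) {
        delc[j - 1] += 1;
        if (j < cmin) cmin = j; if (j > cmax) cmax = j;
      }
      if (x + 1 < np) {
        int st2 = res.state[x + 1];
        int tc = -1;
        if (st == 0 && st2 == 0) tc = 0;
        else if (st == 0 && st2 == 1) tc = 1;
        else if (st == 0 && st2 == 2) tc = 2;
        else if (st == 1 && st2 == 0) tc = 3;
        else if (st == 1 && st2 == 1) tc = 4;
        else if (st == 2 && st2 == 0) tc = 5;
        else if (st == 2 && st2 == 2) tc = 6;
        if (tc >= 0 && j >= 0 && j <= K) counts_tr(j, tc) += 1;
      }
    }
    if (cmax >= cmin) {
      for (int j = cmin; j <= cmax; ++j) depth[j - 1] += 1;
      for (int j = cmin; j < cmax; ++j) junction[j] += 1; // j -> j+1
    }
    // insert runs
    int x = 0;
    while (x < np) {
      if (res.state[x] == 1) {
        int j = res.col[x];
        std::string run;
        while (x < np && res.state[x] == 1 && res.col[x] == j) {
          int rp = res.readpos[x];
          char c = s[rp - 1];
          run.push_back(bcode(c) >= 0 ? c : 'A');
          ++x;
        }
        ins_col.push_back(j); ins_str.push_back(run);
      } else ++x;
    }
  }
  return List::create(_["counts_em"] = counts_em, _["counts_tr"] = counts_tr,
                      _["depth"] = depth, _["matchc"] = matchc,
                      _["delc"] = delc, _["junction"] = junction,
                      _["ins_col"] = wrap(ins_col),
                      _["ins_str"] = wrap(ins_str),
                      _["logps"] = logps);
}
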