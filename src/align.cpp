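#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap (Gotoh) global alignment of a read against a reference.
//
// Scoring convention: a gap of length L costs gap_open + (L - 1) * gap_extend.
// States: M = diagonal (match/mismatch), X = gap in read (ref base deleted),
// Y = gap in ref (read base inserted).  Tie-breaking is deterministic:
// M > X > Y both when choosing the cell state and the predecessor state,
// so the traceback prefers diagonal over deletion over insertion.
//
// With free_ends = true, leading and trailing gaps in either sequence are
// unpenalized (overlap alignment); ops are only emitted for the aligned span.

static const double NEG_INF = -1e18;

static inline int argmax3(double m, double x, double y) {
  // priority M(0) > X(1) > Y(2) on ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".ampedit_align_cpp")]]
List ampedit_align_cpp(std::string ref, std::string read,
                       double match, double mismatch,
                       double gap_open, double gap_extend,
                       bool free_ends) {
  const int m = ref.size(), n = read.size();
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF), X((m + 1) * W, NEG_INF),
      Y((m + 1) * W, NEG_INF);
  // predecessor state of each cell, per matrix
  std::vector<signed char> pM((m + 1) * W, -1), pX((m + 1) * W, -1),
      pY((m + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    double s = free_ends ? 0.0 : gap_open + (i - 1) * gap_extend;
    X[i * W] = s;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    double s = free_ends ? 0.0 : gap_open + (j - 1) * gap_extend;
    Y[j] = s;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: diagonal step
      double sub = (ref[i - 1] == read[j - 1]) ? match : mismatch;
      int bp = argmax3(M[d], X[d], Y[d]);
      double bd = (bp == 0) ? M[d] : (bp == 1 ? X[d] : Y[d]);
      if (bd > NEG_INF / 2) {
        M[c] = bd + sub;
        pM[c] = bp;
      }
      // X: consume ref base (deletion from read's perspective)
      {
        double fromM = M[u] > NEG_INF / 2 ? M[u] + gap_open : NEG_INF;
        double fromX = X[u] > NEG_INF / 2 ? X[u] + gap_extend : NEG_INF;
        double fromY = Y[u] > NEG_INF / 2 ? Y[u] + gap_open : NEG_INF;
        int b = argmax3(fromM, fromX, fromY);
        double v = (b == 0) ? fromM : (b == 1 ? fromX : fromY);
        if (v > NEG_INF / 2) {
          X[c] = v;
          pX[c] = b;
        }
      }
      // Y: consume read base (insertion relative to ref)
      {
        double fromM = M[l] > NEG_INF / 2 ? M[l] + gap_open : NEG_INF;
        double fromX = X[l] > NEG_INF / 2 ? X[l] + gap_open : NEG_INF;
        double fromY = Y[l] > NEG_INF / 2 ? Y[l] + gap_extend : NEG_INF;
        int b = argmax3(fromM, fromX, fromY);
        double v = (b == 0) ? fromM : (b == 1 ? fromX : fromY);
        if (v > NEG_INF / 2) {
          Y[c] = v;
          pY[c] = b;
        }
      }
    }
  }

  const int end = m * W + n;
  int state = argmax3(M[end], X[end], Y[end]);
  double score = (state == 0) ? M[end] : (state == 1 ? X[end] : Y[end]);
  if (m == 0 && n == 0) {
    state = 0;
    score = 0.0;
  }

  // traceback
  std::vector<std::string> kind;
  std::vector<int> ref_start, ref_len;
  std::vector<std::string> alt;
  int i = m, j = n;
  int span_lo = m, span_hi = 0;
  // pending gap runs (built right-to-left)
  int del_end = -1, del_len = 0;
  std::string ins_buf;
  int ins_pos = -1;

  auto flush_del = [&]() {
    if (del_len > 0) {
      kind.push_back("del");
      ref_start.push_back(del_end - del_len);
      ref_len.push_back(del_len);
      alt.push_back("");
      del_len = 0;
      del_end = -1;
    }
  };
  auto flush_ins = [&]() {
    if (!ins_buf.empty()) {
      kind.push_back("ins");
      ref_start.push_back(ins_pos);
      ref_len.push_back(0);
      alt.push_back(ins_buf);
      ins_buf.clear();
      ins_pos = -1;
    }
  };

  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      // diagonal
      flush_del();
      flush_ins();
      if (ref[i - 1] != read[j - 1]) {
        kind.push_back("sub");
        ref_start.push_back(i - 1);
        ref_len.push_back(1);
        alt.push_back(std::string(1, read[j - 1]));
      }
      if (i - 1 < span_lo) span_lo = i - 1;
      if (i > span_hi) span_hi = i;
      state = pM[c];
      --i;
      --j;
    } else if (state == 1) {
      // ref base consumed, no read base: deletion
      bool free_gap = free_ends && (j == 0 || j == n);
      if (!free_gap) {
        flush_ins();
        if (del_len == 0) del_end = i;
        ++del_len;
        if (i - 1 < span_lo) span_lo = i - 1;
        if (i > span_hi) span_hi = i;
      }
      state = pX[c];
      --i;
    } else {
      bool free_gap = free_ends && (i == 0 || i == m);
      if (!free_gap) {
        flush_del();
        // insertion before ref position i
        ins_buf.insert(ins_buf.begin(), read[j - 1]);
        ins_pos = i;
      }
      state = pY[c];
      --j;
    }
  }
  flush_del();
  flush_ins();

  // ops were collected back-to-front
  const int k = kind.size();
  CharacterVector okind(k), oalt(k);
  IntegerVector ostart(k), olen(k);
  for (int t = 0; t < k; ++t) {
    okind[t] = kind[k - 1 - t];
    ostart[t] = ref_start[k - 1 - t];
    olen[t] = ref_len[k - 1 - t];
    oalt[t] = alt[k - 1 - t];
  }
  if (span_lo > span_hi) {
    span_lo = 0;
    span_hi = 0;
  }
  return List::create(_["score"] = score, _["kind"] = okind,
                      _["ref_start"] = ostart, _["ref_len"] = olen,
                      _["alt"] = oalt,
                      _["span"] = IntegerVector::create(span_lo, span_hi));
}
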