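// Smith-Waterman local alignment under the minimization convention:
// match m < 0, mismatch n >= 0, affine gap charged `open` on the first gap
// base and `extend` on each subsequent base.  Internally the scheme is
// negated and a standard maximizing Gotoh recurrence is run; the returned
// v* is the negated maximum, i.e. the minimum total score.
//
// Tie policy (exercised when several cells reach the optimum): smallest
// fragment begin offset, then smallest fragment end, then smallest read end.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

static const double EPS = 1e-9;

// Score-only scan of one read against many fragments; returns minimum scores.
// [[Rcpp::export]]
NumericVector sw_score_batch_cpp(std::string read, CharacterVector frags,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend) {
  const double sm = -match, sx = -mismatch, go = gap_open, ge = gap_extend;
  const int Q = (int)read.size();
  NumericVector out(frags.size());
  std::vector<double> H0, H1, E0, E1;
  for (R_xlen_t f = 0; f < frags.size(); ++f) {
    const char *frag = CHAR(STRING_ELT(frags, f));
    const int L = (int)strlen(frag);
    H0.assign(L + 1, 0.0); H1.assign(L + 1, 0.0);
    E0.assign(L + 1, -1e30); E1.assign(L + 1, -1e30);
    std::vector<double> Fv(L + 1, -1e30);
    double best = 0.0;
    for (int i = 1; i <= Q; ++i) {
      H1[0] = 0.0; E1[0] = -1e30;
      const char rc = read[i - 1];
      for (int j = 1; j <= L; ++j) {
        double e = std::max(H1[j - 1] - go, E1[j - 1] - ge);
        double fv = std::max(H0[j] - go, Fv[j] - ge);
        double diag = H0[j - 1] + (rc == frag[j - 1] ? sm : sx);
        double h = diag;
        if (e > h) h = e;
        if (fv > h) h = fv;
        if (h < 0.0) h = 0.0;
        E1[j] = e; Fv[j] = fv; H1[j] = h;
        if (h > best) best = h;
      }
      H0.swap(H1); E0.swap(E1);
    }
    out[f] = -best;
  }
  return out;
}

struct Cell { double h; int b; };  // value + begin column (0-based frag offset)

// Full alignment of one read against one fragment: optimal score, fragment
// begin/end offsets, read begin/end, and a SAM CIGAR with soft clips.
// [[Rcpp::export]]
List sw_align_cpp(std::string read, std::string frag, double match,
                  double mismatch, double gap_open, double gap_extend) {
  const double sm = -match, sx = -mismatch, go = gap_open, ge = gap_extend;
  const int Q = (int)read.size(), L = (int)frag.size();
  if (Q == 0 || L == 0) stop("empty sequence");
  // Full matrices: H, E (gap consuming fragment), F (gap consuming read),
  // each with a propagated begin column for deterministic tie-breaking.
  std::vector<double> H((Q + 1) * (L + 1), 0.0), E((Q + 1) * (L + 1), -1e30),
      Fm((Q + 1) * (L + 1), -1e30);
  std::vector<int> bH((Q + 1) * (L + 1), 0), bE((Q + 1) * (L + 1), 0),
      bF((Q + 1) * (L + 1), 0);
  auto at = [L](int i, int j) { return i * (L + 1) + j; };
  for (int j = 0; j <= L; ++j) bH[at(0, j)] = j;
  double best = 0.0;
  int bi = 0, bj = 0, bbeg = 0;
  for (int i = 1; i <= Q; ++i) {
    bH[at(i, 0)] = 0;
    const char rc = read[i - 1];
    for (int j = 1; j <= L; ++j) {
      // E: gap consuming fragment chars.
      double e_open = H[at(i, j - 1)] - go, e_ext = E[at(i, j - 1)] - ge;
      if (e_open > e_ext + EPS ||
          (e_open > e_ext - EPS && bH[at(i, j - 1)] <= bE[at(i, j - 1)])) {
        E[at(i, j)] = e_open; bE[at(i, j)] = bH[at(i, j - 1)];
      } else {
        E[at(i, j)] = e_ext; bE[at(i, j)] = bE[at(i, j - 1)];
      }
      // F: gap consuming read chars.
      double f_open = H[at(i - 1, j)] - go, f_ext = Fm[at(i - 1, j)] - ge;
      if (f_open > f_ext + EPS ||
          (f_open > f_ext - EPS && bH[at(i - 1, j)] <= bF[at(i - 1, j)])) {
        Fm[at(i, j)] = f_open; bF[at(i, j)] = bH[at(i - 1, j)];
      } else {
        Fm[at(i, j)] = f_ext; bF[at(i, j)] = bF[at(i - 1, j)];
      }
      // H: best of fresh start, diagonal, E, F; ties -> smallest begin.
      double diag = H[at(i - 1, j - 1)] + (rc == frag[j - 1] ? sm : sx);
      int bdiag = H[at(i - 1, j - 1)] > EPS ? bH[at(i - 1, j - 1)] : j - 1;
      double h = 0.0; int b = j;
      if (diag > h + EPS || (diag > h - EPS && bdiag < b)) { h = diag; b = bdiag; }
      if (E[at(i, j)] > h + EPS ||
          (E[at(i, j)] > h - EPS && bE[at(i, j)] < b)) {
        h = E[at(i, j)]; b = bE[at(i, j)];
      }
      if (Fm[at(i, j)] > h + EPS ||
          (Fm[at(i, j)] > h - EPS && bF[at(i, j)] < b)) {
        h = Fm[at(i, j)]; b = bF[at(i, j)];
      }
      if (h < 0.0) { h = 0.0; b = j; }
      H[at(i, j)] = h; bH[at(i, j)] = b;
      if (h > best + EPS ||
          (h > best - EPS && h > EPS &&
           (b < bbeg || (b == bbeg && (j < bj || (j == bj && i < bi)))))) {
        if (h > best) best = h;
        bi = i; bj = j; bbeg = b;
      }
    }
  }
  if (best <= EPS) {
    // No positive-scoring local alignment (cannot happen for match < 0
    // schemes with at least one shared base, but keep a defined result).
    return List::create(_["v"] = 0.0, _["offset"] = 0, _["frag_end"] = 0,
                        _["read_begin"] = 0, _["read_end"] = 0,
                        _["cigar"] = NA_STRING);
  }
  // Traceback from (bi, bj), preferring predecessors consistent with the
  // recorded begin column, then diagonal > E > F.
  std::string ops;
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      double h = H[at(i, j)];
      if (h <= EPS) break;
      double diag = H[at(i - 1, j - 1)] + (read[i - 1] == frag[j - 1] ? sm : sx);
      int bdiag = H[at(i - 1, j - 1)] > EPS ? bH[at(i - 1, j - 1)] : j - 1;
      if (std::abs(diag - h) < EPS && bdiag == bH[at(i, j)]) {
        ops.push_back('M'); --i; --j;
      } else if (std::abs(E[at(i, j)] - h) < EPS && bE[at(i, j)] == bH[at(i, j)]) {
        state = 'E';
      } else if (std::abs(Fm[at(i, j)] - h) < EPS && bF[at(i, j)] == bH[at(i, j)]) {
        state = 'F';
      } else {  // fall back on value-only match (begin bookkeeping exhausted)
        if (std::abs(diag - h) < EPS) { ops.push_back('M'); --i; --j; }
        else if (std::abs(E[at(i, j)] - h) < EPS) state = 'E';
        else state = 'F';
      }
    } else if (state == 'E') {
      ops.push_back('D');
      double e = E[at(i, j)];
      int beg = bE[at(i, j)];
      --j;
      bool from_open = std::abs(H[at(i, j)] - go - e) < EPS && bH[at(i, j)] == beg;
      bool from_ext = std::abs(E[at(i, j)] - ge - e) < EPS && bE[at(i, j)] == beg;
      if (from_open) state = 'H';
      else if (from_ext) state = 'E';
      else state = std::abs(H[at(i, j)] - go - e) < EPS ? 'H' : 'E';
    } else {  // F
      ops.push_back('I');
      double fv = Fm[at(i, j)];
      int beg = bF[at(i, j)];
      --i;
      bool from_open = std::abs(H[at(i, j)] - go - fv) < EPS && bH[at(i, j)] == beg;
      bool from_ext = std::abs(Fm[at(i, j)] - ge - fv) < EPS && bF[at(i, j)] == beg;
      if (from_open) state = 'H';
      else if (from_ext) state = 'F';
      else state = std::abs(H[at(i, j)] - go - fv) < EPS ? 'H' : 'F';
    }
  }
  const int read_begin = i, frag_begin = j;
  // Build CIGAR: leading/trailing soft clips around run-length encoded ops.
  std::string cigar;
  if (read_begin > 0) cigar += std::to_string(read_begin) + "S";
  int run = 0; char cur = 0;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    if (*it == cur) { ++run; }
    else {
      if (run > 0) cigar += std::to_string(run) + cur;
      cur = *it; run = 1;
    }
  }
  if (run > 0) cigar += std::to_string(run) + cur;
  if (Q - bi > 0) cigar += std::to_string(Q - bi) + "S";
  return List::create(_["v"] = -best, _["offset"] = frag_begin,
                      _["frag_end"] = bj, _["read_begin"] = read_begin,
                      _["read_end"] = bi, _["cigar"] = cigar);
}
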