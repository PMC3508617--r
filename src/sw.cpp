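// Affine-gap Smith-Waterman local alignment (Gotoh three-state recursion)
// with full traceback.  A gap of length L costs gap_open + L * gap_extend,
// i.e. opening a gap already pays one extension.  Scores are floored at
// zero (local alignment); the reported alignment is the traceback from the
// global maximum cell, stopping at the first zero.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  CharacterVector alphabet, double gap_open,
                  double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < alphabet.size(); ++i) {
    std::string s = Rcpp::as<std::string>(alphabet[i]);
    if (!s.empty()) idx[(unsigned char)s[0]] = i;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' not in substitution alphabet",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%s' not in substitution alphabet",
                        std::string(1, b[j]));
  }

  const double open_cost = gap_open + gap_extend;
  const size_t W = (size_t)m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, NEG_INF),
      F((n + 1) * W, NEG_INF);
  // traceback: H from {0 stop, 1 diag, 2 E, 3 F}; E from {1 H, 2 E}; F likewise
  std::vector<signed char> tH((n + 1) * W, 0), tE((n + 1) * W, 0),
      tF((n + 1) * W, 0);

  double best = 0.0;
  int bi_row = 0, bi_col = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, up = c - W, left = c - 1, diag = up - 1;
      // E: gap in sequence a (consume b[j])
      double e_open = H[left] - open_cost, e_ext = E[left] - gap_extend;
      if (e_open >= e_ext) { E[c] = e_open; tE[c] = 1; }
      else { E[c] = e_ext; tE[c] = 2; }
      // F: gap in sequence b (consume a[i])
      double f_open = H[up] - open_cost, f_ext = F[up] - gap_extend;
      if (f_open >= f_ext) { F[c] = f_open; tF[c] = 1; }
      else { F[c] = f_ext; tF[c] = 3; }
      double d = H[diag] + sub(ai[i - 1], bi[j - 1]);
      double h = 0.0; signed char t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[c] > h) { h = E[c]; t = 2; }
      if (F[c] > h) { h = F[c]; t = 3; }
      H[c] = h; tH[c] = t;
      if (h > best) { best = h; bi_row = i; bi_col = j; }
    }
  }

  // traceback from the maximum cell
  int length = 0, identities = 0, positives = 0;
  std::string aln_a, aln_b;
  if (best > 0.0) {
    int i = bi_row, j = bi_col;
    int state = 0;  // 0 = H, 2 = E, 3 = F
    while (i > 0 && j > 0) {
      size_t c = (size_t)i * W + j;
      if (state == 0) {
        signed char t = tH[c];
        if (t == 0) break;
        if (t == 1) {
          double s = sub(ai[i - 1], bi[j - 1]);
          ++length;
          if (a[i - 1] == b[j - 1]) ++identities;
          if (s > 0) ++positives;
          aln_a.push_back(a[i - 1]);
          aln_b.push_back(b[j - 1]);
          --i; --j;
        } else {
          state = t;
        }
      } else if (state == 2) {  // gap in a, consume b[j]
        ++length;
        aln_a.push_back('-');
        aln_b.push_back(b[j - 1]);
        state = (tE[c] == 1) ? 0 : 2;
        --j;
      } else {  // state == 3: gap in b, consume a[i]
        ++length;
        aln_a.push_back(a[i - 1]);
        aln_b.push_back('-');
        state = (tF[c] == 1) ? 0 : 3;
        --i;
      }
    }
    std::reverse(aln_a.begin(), aln_a.end());
    std::reverse(aln_b.begin(), aln_b.end());
  }

  return List::create(
      _["score"] = best, _["alignment_length"] = length,
      _["identities"] = identities, _["positives"] = positives,
      _["aligned_a"] = aln_a, _["aligned_b"] = aln_b);
}
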