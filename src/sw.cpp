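#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
#include <cctype>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps under the convention that
// a gap of length L costs open + L * extend.  Two gap classes are
// distinguished so that read-mapping style costs (insertion in the read vs
// deletion from the read) can differ:
//   * "ins" gaps consume query residues (subject shows '-'): extra bases in
//     the read relative to the reference.
//   * "del" gaps consume subject residues (query shows '-'): bases missing
//     from the read.

static const int NEG_INF = INT_MIN / 4;

static std::vector<int> make_lookup(const std::vector<std::string> &alphabet,
                                    int fallback) {
  std::vector<int> lut(256, fallback);
  for (size_t k = 0; k < alphabet.size(); ++k) {
    if (alphabet[k].size() == 1) {
      unsigned char c = (unsigned char)alphabet[k][0];
      lut[c] = (int)k;
      lut[(unsigned char)std::tolower(c)] = (int)k;
    }
  }
  return lut;
}

static void encode_seq(const char *s, const std::vector<int> &lut,
                       std::vector<int> &out) {
  size_t n = std::strlen(s);
  out.resize(n);
  for (size_t i = 0; i < n; ++i) out[i] = lut[(unsigned char)s[i]];
}

// row-major copy of an R matrix: sm[a * A + b]
static std::vector<int> flatten_rowmajor(const IntegerMatrix &m) {
  int A = m.nrow(), B = m.ncol();
  std::vector<int> out((size_t)A * B);
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < B; ++j) out[(size_t)i * B + j] = m(i, j);
  return out;
}

static int sw_score_one(const std::vector<int> &q, const std::vector<int> &s,
                        const int *sm, int A, int oi, int ei, int od, int ed,
                        std::vector<int> &H, std::vector<int> &E) {
  int m = (int)q.size(), n = (int)s.size();
  if (m == 0 || n == 0) return 0;
  H.assign(n + 1, 0);
  E.assign(n + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int *row = sm + (size_t)q[i - 1] * A;
    int hdiag = 0;      // H[i-1][j-1]
    int f = NEG_INF;    // F[i][j-1] running along the row
    int hprev = 0;      // H[i][j-1]
    for (int j = 1; j <= n; ++j) {
      int e = E[j] - ei;                    // extend vertical gap
      int eo = H[j] - oi - ei;              // open vertical gap (H[i-1][j])
      if (eo > e) e = eo;
      E[j] = e;
      int fo = hprev - od - ed;             // open horizontal gap
      f = f - ed;
      if (fo > f) f = fo;
      int h = hdiag + row[s[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      hdiag = H[j];
      H[j] = h;
      hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerMatrix sw_scores_cpp(CharacterVector qs, CharacterVector ss,
                            IntegerMatrix submat, CharacterVector alphabet,
                            int fallback, int open_ins, int ext_ins,
                            int open_del, int ext_del) {
  int A = submat.nrow();
  if (submat.ncol() != A) stop("substitution matrix must be square");
  std::vector<std::string> alph = as<std::vector<std::string> >(alphabet);
  if ((int)alph.size() != A) stop("alphabet length must match matrix size");
  std::vector<int> lut = make_lookup(alph, fallback - 1);
  std::vector<int> sm = flatten_rowmajor(submat);

  int nq = qs.size(), ns = ss.size();
  std::vector<std::vector<int> > senc(ns);
  for (int j = 0; j < ns; ++j) encode_seq(CHAR(STRING_ELT(ss, j)), lut, senc[j]);

  IntegerMatrix out(nq, ns);
  std::vector<int> qenc, H, E;
  for (int i = 0; i < nq; ++i) {
    encode_seq(CHAR(STRING_ELT(qs, i)), lut, qenc);
    for (int j = 0; j < ns; ++j)
      out(i, j) = sw_score_one(qenc, senc[j], sm.data(), A, open_ins, ext_ins,
                               open_del, ext_del, H, E);
  }
  return out;
}

// Full traceback for one pair.  Tie-break among predecessors of an H cell:
// diagonal, then vertical (gap in subject, consumes query), then horizontal.
// The best cell is the maximal H with the smallest i, then smallest j.
// [[Rcpp::export]]
List sw_traceback_cpp(std::string q, std::string s, IntegerMatrix submat,
                      CharacterVector alphabet, int fallback, int open_ins,
                      int ext_ins, int open_del, int ext_del) {
  int A = submat.nrow();
  std::vector<std::string> alph = as<std::vector<std::string> >(alphabet);
  std::vector<int> lut = make_lookup(alph, fallback - 1);
  std::vector<int> sm = flatten_rowmajor(submat);

  std::vector<int> qe, se;
  encode_seq(q.c_str(), lut, qe);
  encode_seq(s.c_str(), lut, se);
  int m = (int)qe.size(), n = (int)se.size();

  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG_INF);
  size_t W = (size_t)n + 1;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int *row = sm.data() + (size_t)qe[i - 1] * A;
    for (int j = 1; j <= n; ++j) {
      size_t c = i * W + j, up = (i - 1) * W + j, lf = i * W + (j - 1);
      int e = std::max(E[up] - ext_ins, H[up] - open_ins - ext_ins);
      int f = std::max(F[lf] - ext_del, H[lf] - open_del - ext_del);
      E[c] = e;
      F[c] = f;
      int h = H[(i - 1) * W + (j - 1)] + row[se[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["aligned_cols"] = 0,
                        _["matches"] = 0, _["mismatches"] = 0,
                        _["gap_opens"] = 0, _["gap_cols"] = 0,
                        _["q_aln"] = "", _["s_aln"] = "");
  }

  std::string qa, sa;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (vertical), 2 = F (horizontal)
  int matches = 0, mismatches = 0, gap_opens = 0, gap_cols = 0;
  int qend = bi, send = bj;
  while (i > 0 && j > 0) {
    size_t c = i * W + j;
    if (state == 0) {
      if (H[c] == 0) break;
      const int *row = sm.data() + (size_t)qe[i - 1] * A;
      int diag = H[(i - 1) * W + (j - 1)] + row[se[j - 1]];
      if (H[c] == diag) {
        qa.push_back(q[i - 1]);
        sa.push_back(s[j - 1]);
        if (qe[i - 1] == se[j - 1]) ++matches; else ++mismatches;
        --i; --j;
      } else if (H[c] == E[c]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // vertical gap: query residue vs subject '-'
      size_t up = (i - 1) * W + j;
      qa.push_back(q[i - 1]);
      sa.push_back('-');
      ++gap_cols;
      if (E[i * W + j] == H[up] - open_ins - ext_ins) {
        ++gap_opens;
        state = 0;
      }
      --i;
    } else {
      size_t lf = i * W + (j - 1);
      qa.push_back('-');
      sa.push_back(s[j - 1]);
      ++gap_cols;
      if (F[i * W + j] == H[lf] - open_del - ext_del) {
        ++gap_opens;
        state = 0;
      }
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(
      _["score"] = best, _["q_start"] = i + 1, _["q_end"] = qend,
      _["s_start"] = j + 1, _["s_end"] = send,
      _["aligned_cols"] = (int)qa.size(), _["matches"] = matches,
      _["mismatches"] = mismatches, _["gap_opens"] = gap_opens,
      _["gap_cols"] = gap_cols, _["q_aln"] = qa, _["s_aln"] = sa);
}
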