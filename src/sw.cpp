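#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// Gap of length L costs gap_open + L * gap_ext (first gap residue pays both).
// Scores are looked up in a substitution matrix over `alphabet`; characters
// absent from the alphabet fall back to 'X' when available.
// DP buffers are reused across pairs in a batch; only the borders need
// initialization because every interior cell is written before it is read.

struct SWBuffers {
  std::vector<double> M, X, Y;
  std::vector<unsigned char> tbM, tbX, tbY;
  void ensure(size_t cells) {
    if (M.size() < cells) {
      M.resize(cells); X.resize(cells); Y.resize(cells);
      tbM.resize(cells); tbX.resize(cells); tbY.resize(cells);
    }
  }
};

static void sw_pair(const std::vector<int>& a, const std::vector<int>& b,
                    const std::vector<double>& S, int nalpha,
                    double go, double ge, SWBuffers& buf, double* out) {
  const int n = (int)a.size(), m = (int)b.size();
  out[0] = 0.0; out[1] = 0.0; out[2] = 0.0;
  if (n == 0 || m == 0) return;
  const double NEG = -1e30;
  const double open_cost = go + ge;
  const size_t W = (size_t)m + 1;
  buf.ensure((size_t)(n + 1) * W);
  double* M = buf.M.data();
  double* X = buf.X.data();
  double* Y = buf.Y.data();
  unsigned char* tbM = buf.tbM.data();
  unsigned char* tbX = buf.tbX.data();
  unsigned char* tbY = buf.tbY.data();
  for (size_t j = 0; j < W; ++j) { M[j] = 0.0; X[j] = NEG; Y[j] = NEG; }
  for (int i = 1; i <= n; ++i) {
    M[(size_t)i * W] = 0.0; X[(size_t)i * W] = NEG; Y[(size_t)i * W] = NEG;
  }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const double* Srow = S.data() + (size_t)a[i - 1] * nalpha;
    const size_t base = (size_t)i * W;
    for (int j = 1; j <= m; ++j) {
      const size_t ij = base + j;
      const size_t up = ij - W, left = ij - 1, diag = ij - W - 1;
      double x_open = M[up] - open_cost, x_ext = X[up] - ge;
      if (x_open >= x_ext) { X[ij] = x_open; tbX[ij] = 1; }
      else                 { X[ij] = x_ext;  tbX[ij] = 2; }
      double y_open = M[left] - open_cost, y_ext = Y[left] - ge;
      if (y_open >= y_ext) { Y[ij] = y_open; tbY[ij] = 1; }
      else                 { Y[ij] = y_ext;  tbY[ij] = 2; }
      double sc = Srow[b[j - 1]];
      double prev = 0.0; unsigned char tb = 0;
      if (M[diag] > prev) { prev = M[diag]; tb = 1; }
      if (X[diag] > prev) { prev = X[diag]; tb = 2; }
      if (Y[diag] > prev) { prev = Y[diag]; tb = 3; }
      double v = prev + sc;
      if (v < 0.0) { v = 0.0; tb = 0; }
      M[ij] = v; tbM[ij] = tb;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return;

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 0;  // 0=M, 1=X, 2=Y
  double matches = 0.0, cols = 0.0;
  while (i > 0 && j > 0) {
    const size_t ij = (size_t)i * W + j;
    if (state == 0) {
      if (tbM[ij] == 0 && M[ij] <= 0.0) break;
      cols += 1.0;
      if (a[i - 1] == b[j - 1]) matches += 1.0;
      unsigned char tb = tbM[ij];
      --i; --j;
      if (tb == 0) break;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
    } else if (state == 1) {
      cols += 1.0;
      unsigned char tb = tbX[ij];
      --i;
      state = (tb == 1) ? 0 : 1;
    } else {
      cols += 1.0;
      unsigned char tb = tbY[ij];
      --j;
      state = (tb == 1) ? 0 : 2;
    }
  }
  out[0] = best; out[1] = matches; out[2] = cols;
}

static std::vector<int> encode_seq(const char* s, const int* map256) {
  size_t L = std::strlen(s);
  std::vector<int> v(L);
  for (size_t i = 0; i < L; ++i) v[i] = map256[(unsigned char)s[i]];
  return v;
}

// [[Rcpp::export]]
NumericMatrix sw_batch_cpp(CharacterVector a, CharacterVector b,
                           NumericMatrix subst, CharacterVector alphabet,
                           double gap_open, double gap_ext) {
  const int np = a.size();
  if (b.size() != np) stop("a and b must have equal length");
  const int nalpha = alphabet.size();
  if (subst.nrow() != nalpha || subst.ncol() != nalpha)
    stop("substitution matrix does not match alphabet");
  int map256[256];
  int xidx = -1;
  for (int i = 0; i < 256; ++i) map256[i] = -1;
  for (int i = 0; i < nalpha; ++i) {
    const char* c = CHAR(STRING_ELT(alphabet, i));
    map256[(unsigned char)c[0]] = i;
    if (c[0] == 'X') xidx = i;
  }
  if (xidx < 0) xidx = 0;
  for (int i = 0; i < 256; ++i) if (map256[i] < 0) map256[i] = xidx;
  std::vector<double> S((size_t)nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j) S[(size_t)i * nalpha + j] = subst(i, j);

  SWBuffers buf;
  NumericMatrix out(np, 3);
  colnames(out) = CharacterVector::create("score", "matches", "columns");
  for (int p = 0; p < np; ++p) {
    std::vector<int> ea = encode_seq(CHAR(STRING_ELT(a, p)), map256);
    std::vector<int> eb = encode_seq(CHAR(STRING_ELT(b, p)), map256);
    double res[3];
    sw_pair(ea, eb, S, nalpha, gap_open, gap_ext, buf, res);
    out(p, 0) = res[0]; out(p, 1) = res[1]; out(p, 2) = res[2];
  }
  return out;
}
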