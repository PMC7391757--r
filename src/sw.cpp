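#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap local alignment.
// A gap of length k costs gap_open + k * gap_extend (BLAST-style existence
// plus per-residue cost). Traceback ties resolve diagonal > up > left; the
// best cell is the first maximum in row-major order, so results are fully
// deterministic.
//
// submat: integer matrix with single-letter dimnames covering every residue
// that can occur in either sequence.

static const int NEG = -1000000000;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix submat,
                  int gap_open, int gap_extend) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // char -> matrix row index
  std::vector<int> idx(256, -1);
  CharacterVector rn = rownames(submat);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) idx[(unsigned char)s[0]] = i;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' not in substitution matrix",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%s' not in substitution matrix",
                        std::string(1, b[j]));
  }

  int open1 = gap_open + gap_extend;  // cost of first gapped position

  // M: a[i] aligned to b[j]; E: gap in a (consume b); F: gap in b (consume a)
  std::vector<std::vector<int>> M(n + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int>> E(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int>> F(n + 1, std::vector<int>(m + 1, NEG));
  // traceback: which predecessor produced M (0 none, 1 diag-M, 2 diag-F(up), 3 diag-E(left))
  // and whether E/F opened (1) or extended (2)
  std::vector<std::vector<unsigned char>> tM(n + 1, std::vector<unsigned char>(m + 1, 0));
  std::vector<std::vector<unsigned char>> tE(n + 1, std::vector<unsigned char>(m + 1, 0));
  std::vector<std::vector<unsigned char>> tF(n + 1, std::vector<unsigned char>(m + 1, 0));

  int best = 0, bi_ = 0, bj_ = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in a, coming from the left
      int eo = M[i][j - 1] - open1;
      int ee = E[i][j - 1] - gap_extend;
      if (eo >= ee) { E[i][j] = eo; tE[i][j] = 1; }
      else          { E[i][j] = ee; tE[i][j] = 2; }
      // F: gap in b, coming from above
      int fo = M[i - 1][j] - open1;
      int fe = F[i - 1][j] - gap_extend;
      if (fo >= fe) { F[i][j] = fo; tF[i][j] = 1; }
      else          { F[i][j] = fe; tF[i][j] = 2; }
      // M: diagonal from best of {M, F, E} at (i-1, j-1); ties diag > up > left
      int s = submat(ai[i - 1], bi[j - 1]);
      int pm = M[i - 1][j - 1], pf = F[i - 1][j - 1], pe = E[i - 1][j - 1];
      int prev = pm; unsigned char tb = 1;
      if (pf > prev) { prev = pf; tb = 2; }
      if (pe > prev) { prev = pe; tb = 3; }
      int v = prev + s;
      if (v <= 0) { M[i][j] = 0; tM[i][j] = 0; }
      else        { M[i][j] = v; tM[i][j] = tb; }
      if (M[i][j] > best) { best = M[i][j]; bi_ = i; bj_ = j; }
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["a_aln"] = "",
                        _["b_aln"] = "");
  }

  // traceback from (bi_, bj_) in state M; a state-M cell with score 0 is the
  // local start
  std::string aa, bb;
  int i = bi_, j = bj_;
  int state = 0;  // 0 = M, 1 = E (left), 2 = F (up)
  while (true) {
    if (state == 0) {
      if (M[i][j] == 0) break;
      unsigned char tb = tM[i][j];
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      --i; --j;
      state = (tb == 1) ? 0 : (tb == 2 ? 2 : 1);
    } else if (state == 1) {  // E: gap in a
      unsigned char tb = tE[i][j];
      aa.push_back('-'); bb.push_back(b[j - 1]);
      --j;
      if (tb == 1) state = 0;
    } else {  // F: gap in b
      unsigned char tb = tF[i][j];
      aa.push_back(a[i - 1]); bb.push_back('-');
      --i;
      if (tb == 1) state = 0;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["score"] = best, _["a_start"] = i + 1,
                      _["a_end"] = bi_, _["b_start"] = j + 1,
                      _["b_end"] = bj_, _["a_aln"] = aa, _["b_aln"] = bb);
}
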