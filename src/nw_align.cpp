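#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment (Needleman-Wunsch with affine gaps, Gotoh
// recursion). Gap of length k costs gap_open + k * gap_extend. Traceback is
// deterministic: on ties prefer diagonal, then up (gap in b), then left
// (gap in a), so identical inputs give identical alignments on any platform.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // residue -> substitution-matrix row index
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(submat);
  for (int i = 0; i < rn.size(); i++) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; i++) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' not in substitution matrix",
                        std::string(1, a[i]).c_str());
  }
  for (int j = 0; j < m; j++) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%s' not in substitution matrix",
                        std::string(1, b[j]).c_str());
  }

  double go = gap_open, ge = gap_extend;
  int W = m + 1;
  // state 0 = M (diagonal), 1 = X (gap in b, consume a), 2 = Y (gap in a)
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: which state fed each cell
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W),
      tbY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; i++) {
    X[i * W] = -(go + i * ge);
    tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; j++) {
    Y[j] = -(go + j * ge);
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
          l = i * W + (j - 1);
      double s = submat(ai[i - 1], bi[j - 1]);
      // M: tie preference M > X > Y
      double best = M[d];
      unsigned char st = 0;
      if (X[d] > best) { best = X[d]; st = 1; }
      if (Y[d] > best) { best = Y[d]; st = 2; }
      M[c] = best + s;
      tbM[c] = st;
      // X (up): open from M preferred over extend on ties
      double xo = M[u] - (go + ge), xe = X[u] - ge;
      if (xo >= xe) { X[c] = xo; tbX[c] = 0; } else { X[c] = xe; tbX[c] = 1; }
      // Y (left)
      double yo = M[l] - (go + ge), ye = Y[l] - ge;
      if (yo >= ye) { Y[c] = yo; tbY[c] = 0; } else { Y[c] = ye; tbY[c] = 2; }
    }
  }

  int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int c = i * W + j;
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      state = tbM[c];
      i--; j--;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      state = tbX[c];
      i--;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      state = tbY[c];
      j--;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0, len = ra.size();
  for (int k = 0; k < len; k++)
    if (ra[k] == rb[k] && ra[k] != '-') matches++;

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score,
                      _["identity_pct"] = 100.0 * matches / len);
}
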