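#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state DP.
// Gap of length L costs gap_open + L * gap_extend (penalties given positive).
// End gaps are penalized. Tie-breaking in the traceback is fixed as
// diagonal (M) > up (gap in b, consumes a) > left (gap in a, consumes b),
// and within each gap state extension is preferred over opening on ties,
// so results are deterministic.
//
// a, b: 1-based integer codes indexing `submat` rows/cols.
// Returns list(score, path_a, path_b) where path vectors hold 1-based
// positions or 0 for a gap.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List cpp_affine_align(IntegerVector a, IntegerVector b, NumericMatrix submat,
                      double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;  // cost of a length-1 gap
  const double ge = gap_extend;

  // score rows (rolling), traceback kept in full (2 bits/state packed in a byte)
  std::vector<double> M0(m + 1), X0(m + 1), Y0(m + 1);
  std::vector<double> M1(m + 1), X1(m + 1), Y1(m + 1);
  // tb[s][idx]: predecessor state (0=M,1=X,2=Y) for state s at cell idx
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  auto pack = [](int pm, int px, int py) -> unsigned char {
    return (unsigned char)(pm | (px << 2) | (py << 4));
  };

  M0[0] = 0.0; X0[0] = NEG_INF; Y0[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG_INF;
    X0[j] = NEG_INF;
    Y0[j] = -(go + ge * (j - 1));
    tb[j] = pack(0, 0, j == 1 ? 0 : 2);
  }

  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG_INF;
    X1[0] = -(go + ge * (i - 1));
    Y1[0] = NEG_INF;
    tb[(size_t)i * (m + 1)] = pack(0, i == 1 ? 0 : 1, 0);
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const double s = submat(ai, b[j - 1] - 1);
      // M: diagonal from best of previous states; prefer M > X > Y on ties
      int pm = 0;
      double best = M0[j - 1];
      if (X0[j - 1] > best) { best = X0[j - 1]; pm = 1; }
      if (Y0[j - 1] > best) { best = Y0[j - 1]; pm = 2; }
      M1[j] = best + s;
      // X: gap in b (move down); prefer extension (from X) on ties
      int px = 1;
      double xext = X0[j] - ge;
      double xbest = xext;
      if (M0[j] - go > xbest) { xbest = M0[j] - go; px = 0; }
      if (Y0[j] - go > xbest) { xbest = Y0[j] - go; px = 2; }
      X1[j] = xbest;
      // Y: gap in a (move right); prefer extension (from Y) on ties
      int py = 2;
      double yext = Y1[j - 1] - ge;
      double ybest = yext;
      if (M1[j - 1] - go > ybest) { ybest = M1[j - 1] - go; py = 0; }
      if (X1[j - 1] - go > ybest) { ybest = X1[j - 1] - go; py = 1; }
      Y1[j] = ybest;
      tb[(size_t)i * (m + 1) + j] = pack(pm, px, py);
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }

  // final state: prefer M > X > Y on ties
  int state = 0;
  double score = M0[m];
  if (X0[m] > score) { score = X0[m]; state = 1; }
  if (Y0[m] > score) { score = Y0[m]; state = 2; }

  // traceback
  std::vector<int> pa, pb;
  pa.reserve(n + m); pb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    int prev;
    if (state == 0) {        // M consumed a[i], b[j]
      prev = t & 3;
      pa.push_back(i); pb.push_back(j);
      --i; --j;
    } else if (state == 1) { // X consumed a[i], gap in b
      prev = (t >> 2) & 3;
      pa.push_back(i); pb.push_back(0);
      --i;
    } else {                 // Y consumed b[j], gap in a
      prev = (t >> 4) & 3;
      pa.push_back(0); pb.push_back(j);
      --j;
    }
    state = prev;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
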