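#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman), three-state DP.
// Gap of length k costs gap_open + k * gap_extend (BLAST convention).
// Deterministic tie-breaking in the traceback: prefer the diagonal (match)
// state, then the up (gap-in-subject) state, then the left (gap-in-query)
// state; the start cell is the first maximum in row-major scan order.
//
// q, s: 0-based integer codes into the substitution matrix `sub`.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector s, IntegerMatrix sub,
              double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  const double NEG = -1e30;
  const double go_ge = gap_open + gap_extend, ge = gap_extend;
  // DP matrices, (n+1) x (m+1); M ends in a match column, X consumes query
  // (gap in subject, "up"), Y consumes subject (gap in query, "left").
  std::vector<double> M((n + 1) * (m + 1), 0.0), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  // flat copies for the hot loop
  const int na = sub.nrow();
  std::vector<double> subtab(na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) subtab[a * na + b] = sub(a, b);
  std::vector<int> qc(q.begin(), q.end()), sc_(s.begin(), s.end());

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    const double *Mp = &M[(i - 1) * (m + 1)], *Xp = &X[(i - 1) * (m + 1)],
                 *Yp = &Y[(i - 1) * (m + 1)];
    double *Mc = &M[i * (m + 1)], *Xc = &X[i * (m + 1)],
           *Yc = &Y[i * (m + 1)];
    const double *qrow = &subtab[qc[i - 1] * na];
    for (int j = 1; j <= m; ++j) {
      double xo = Mp[j] - go_ge;
      double xe = Xp[j] - ge;
      Xc[j] = xo >= xe ? xo : xe;  // prefer opening from M on ties
      double yo = Mc[j - 1] - go_ge;
      double ye = Yc[j - 1] - ge;
      Yc[j] = yo >= ye ? yo : ye;
      double prev = Mp[j - 1];
      if (Xp[j - 1] > prev) prev = Xp[j - 1];
      if (Yp[j - 1] > prev) prev = Yp[j - 1];
      double scv = prev + qrow[sc_[j - 1]];
      Mc[j] = scv > 0.0 ? scv : 0.0;
      if (Mc[j] > best) {  // strict >: first maximum wins
        best = Mc[j];
        bi = i; bj = j;
      }
    }
  }

  if (best <= 0.0 || bi < 0) {
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = -1,
                        _["s_start"] = 0, _["s_end"] = -1,
                        _["q_aln"] = IntegerVector(0),
                        _["s_aln"] = IntegerVector(0));
  }

  // Traceback: states 0 = M, 1 = X (up), 2 = Y (left).
  std::vector<int> qa, sa;  // -1 encodes a gap
  int i = bi, j = bj, state = 0;
  while (true) {
    if (state == 0) {
      qa.push_back(q[i - 1]);
      sa.push_back(s[j - 1]);
      double pm = M[at(i - 1, j - 1)], px = X[at(i - 1, j - 1)],
             py = Y[at(i - 1, j - 1)];
      double mx = pm;  // preference M > X > Y on ties
      int nstate = 0;
      if (px > mx) { mx = px; nstate = 1; }
      if (py > mx) { mx = py; nstate = 2; }
      --i; --j;
      if (mx <= 0.0) break;  // local alignment starts here
      state = nstate;
    } else if (state == 1) {
      qa.push_back(q[i - 1]);
      sa.push_back(-1);
      double open = M[at(i - 1, j)] - gap_open - gap_extend;
      state = (open >= X[at(i - 1, j)] - gap_extend) ? 0 : 1;
      --i;
    } else {
      qa.push_back(-1);
      sa.push_back(s[j - 1]);
      double open = M[at(i, j - 1)] - gap_open - gap_extend;
      state = (open >= Y[at(i, j - 1)] - gap_extend) ? 0 : 2;
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  return List::create(_["score"] = best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["s_start"] = j + 1, _["s_end"] = bj,
                      _["q_aln"] = IntegerVector(qa.begin(), qa.end()),
                      _["s_aln"] = IntegerVector(sa.begin(), sa.end()));
}
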