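#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Gotoh).
// S: precomputed column-pair score matrix (la x lb).
// Returns ops: 1 = align column of A with column of B,
//              2 = column of A against a gap, 3 = gap against column of B.
// [[Rcpp::export(name = ".profile_align_cpp")]]
IntegerVector profile_align_cpp(NumericMatrix S, double gap_open,
                                double gap_ext) {
  const int la = S.nrow(), lb = S.ncol();
  const double NEG = -1e30;
  // layered DP matrices, (la+1) x (lb+1)
  std::vector<double> M((la + 1) * (lb + 1), NEG);
  std::vector<double> X((la + 1) * (lb + 1), NEG); // gap in B (consume A)
  std::vector<double> Y((la + 1) * (lb + 1), NEG); // gap in A (consume B)
  std::vector<unsigned char> tM(M.size()), tX(M.size()), tY(M.size());
  auto at = [lb](int i, int j) { return i * (lb + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[at(i, 0)] = -gap_open - (i - 1) * gap_ext;
    tX[at(i, 0)] = 1; // came from X (extension), except i==1 from M
  }
  if (la >= 1) tX[at(1, 0)] = 0;
  for (int j = 1; j <= lb; ++j) {
    Y[at(0, j)] = -gap_open - (j - 1) * gap_ext;
    tY[at(0, j)] = 1;
  }
  if (lb >= 1) tY[at(0, 1)] = 0;

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      // M: diagonal move
      double m0 = M[at(i - 1, j - 1)], m1 = X[at(i - 1, j - 1)],
             m2 = Y[at(i - 1, j - 1)];
      double best = m0; unsigned char tb = 0;
      if (m1 > best) { best = m1; tb = 1; }
      if (m2 > best) { best = m2; tb = 2; }
      M[at(i, j)] = best + S(i - 1, j - 1);
      tM[at(i, j)] = tb;
      // X: consume A column i against gap
      double x0 = M[at(i - 1, j)] - gap_open,
             x1 = X[at(i - 1, j)] - gap_ext,
             x2 = Y[at(i - 1, j)] - gap_open;
      best = x0; tb = 0;
      if (x1 > best) { best = x1; tb = 1; }
      if (x2 > best) { best = x2; tb = 2; }
      X[at(i, j)] = best; tX[at(i, j)] = tb;
      // Y: consume B column j against gap
      double y0 = M[at(i, j - 1)] - gap_open,
             y1 = X[at(i, j - 1)] - gap_open,
             y2 = Y[at(i, j - 1)] - gap_ext;
      best = y0; tb = 0;
      if (y1 > best) { best = y1; tb = 1; }
      if (y2 > best) { best = y2; tb = 2; }
      Y[at(i, j)] = best; tY[at(i, j)] = tb;
    }
  }

  // traceback from the best terminal layer
  int i = la, j = lb, layer = 0;
  double endM = M[at(la, lb)], endX = X[at(la, lb)], endY = Y[at(la, lb)];
  if (endX > endM && endX >= endY) layer = 1;
  else if (endY > endM && endY > endX) layer = 2;
  std::vector<int> ops;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      ops.push_back(1);
      layer = tM[at(i, j)];
      --i; --j;
    } else if (layer == 1) {
      ops.push_back(2);
      layer = tX[at(i, j)];
      --i;
    } else {
      ops.push_back(3);
      layer = tY[at(i, j)];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}
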