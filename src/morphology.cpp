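#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat ball structuring element,
// the morphology underlying rolling-ball background estimation: the
// background is the opening of the intensity surface by a ball of the
// given radius (erosion then dilation with heights
// h(dx,dy) = sqrt(r^2 - dx^2 - dy^2)).
//
// Out-of-frame neighbours are skipped, which corresponds to padding with
// +Inf for erosion and -Inf for dilation; with a symmetric element this
// keeps opening(img) <= img everywhere, so the residual is non-negative.

static void ball_offsets(double radius,
                         std::vector<int>& dx, std::vector<int>& dy,
                         std::vector<double>& h) {
  int r = (int)std::floor(radius);
  for (int j = -r; j <= r; ++j) {
    for (int i = -r; i <= r; ++i) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= radius * radius) {
        dx.push_back(i);
        dy.push_back(j);
        h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_ball_open")]]
NumericMatrix cpp_ball_open(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dx, dy;
  std::vector<double> h;
  ball_offsets(radius, dx, dy, h);
  size_t m = h.size();

  NumericMatrix ero(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = R_PosInf;
      for (size_t k = 0; k < m; ++k) {
        int rr = r + dy[k], cc = c + dx[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double cand = img(rr, cc) - h[k];
        if (cand < v) v = cand;
      }
      ero(r, c) = v;
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = R_NegInf;
      for (size_t k = 0; k < m; ++k) {
        int rr = r + dy[k], cc = c + dx[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double cand = ero(rr, cc) + h[k];
        if (cand > v) v = cand;
      }
      out(r, c) = v;
    }
  }
  return out;
}
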