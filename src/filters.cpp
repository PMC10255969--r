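#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Round half up, clamp to [0, 255]. Matches the package-wide 8-bit convention.
static inline double clamp8(double v) {
  double r = std::floor(v + 0.5);
  if (r < 0.0) r = 0.0;
  if (r > 255.0) r = 255.0;
  return r;
}

static inline int reflect_edge(int i, int n) {
  // edge replication: clamp index into [0, n-1]
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Sliding-window spatial filter with edge replication.
// type: 0 = median, 1 = mean, 2 = gaussian (with supplied sigma)
// [[Rcpp::export(name = ".spatial_filter_cpp")]]
NumericMatrix spatial_filter_cpp(const NumericMatrix& img, int window,
                                 int type, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  const int k = window / 2;
  NumericMatrix out(H, W);

  std::vector<double> buf(window * window);
  std::vector<double> kern;
  if (type == 2) {
    kern.resize(window * window);
    double s2 = 2.0 * sigma * sigma, tot = 0.0;
    for (int di = -k; di <= k; ++di)
      for (int dj = -k; dj <= k; ++dj) {
        double w = std::exp(-(di * di + dj * dj) / s2);
        kern[(di + k) * window + (dj + k)] = w;
        tot += w;
      }
    for (double& w : kern) w /= tot;
  }

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (type == 0) {
        int n = 0;
        for (int di = -k; di <= k; ++di)
          for (int dj = -k; dj <= k; ++dj)
            buf[n++] = img(reflect_edge(i + di, H), reflect_edge(j + dj, W));
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
        out(i, j) = buf[n / 2];
      } else if (type == 1) {
        double s = 0.0;
        for (int di = -k; di <= k; ++di)
          for (int dj = -k; dj <= k; ++dj)
            s += img(reflect_edge(i + di, H), reflect_edge(j + dj, W));
        out(i, j) = clamp8(s / (window * window));
      } else {
        double s = 0.0;
        for (int di = -k; di <= k; ++di)
          for (int dj = -k; dj <= k; ++dj)
            s += kern[(di + k) * window + (dj + k)] *
                 img(reflect_edge(i + di, H), reflect_edge(j + dj, W));
        out(i, j) = clamp8(s);
      }
    }
  }
  return out;
}
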