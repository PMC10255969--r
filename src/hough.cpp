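#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Two-stage Hough gradient circle detector.
//
// Stage 1 (centers): Sobel gradients; pixels with gradient magnitude at or
// above `grad_thresh` are edge pixels. Each edge pixel votes along its
// gradient line (both signs, so bright-on-dark and dark-on-bright discs are
// both found) for offsets in [r_min, r_max], collapsing the classical 3-D
// (cx, cy, r) accumulator onto a 2-D center plane. Candidate centers are
// local maxima of the 3x3-smoothed accumulator with at least `param2` raw
// votes, kept greedily by descending support with `min_dist` separation.
//
// Stage 2 (radius + refinement): for each kept center the radius is the
// mode of the integer histogram of edge-pixel distances in [r_min, r_max];
// center and radius are then refined by an algebraic least-squares circle
// fit (Kasa fit) to the edge pixels supporting that radius whose gradient
// direction is consistent with a circle about the center. The fit is
// iterated, which gives sub-pixel accuracy even though individual votes
// are smeared by gradient-direction noise at large radii.
//
// Coordinates returned are 1-based pixel centers (x = col, y = row).
// Circles are sorted by descending votes.
// [[Rcpp::export(name = ".hough_circles_cpp")]]
DataFrame hough_circles_cpp(const NumericMatrix& img, double min_dist,
                            int param2, double grad_thresh,
                            int r_min, int r_max, int max_circles) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<double> ex, ey, egx, egy;  // edge pixels + unit gradients
  std::vector<int> acc(H * W, 0);

  for (int i = 1; i < H - 1; ++i) {
    for (int j = 1; j < W - 1; ++j) {
      double gx =
        (img(i - 1, j + 1) + 2 * img(i, j + 1) + img(i + 1, j + 1)) -
        (img(i - 1, j - 1) + 2 * img(i, j - 1) + img(i + 1, j - 1));
      double gy =
        (img(i + 1, j - 1) + 2 * img(i + 1, j) + img(i + 1, j + 1)) -
        (img(i - 1, j - 1) + 2 * img(i - 1, j) + img(i - 1, j + 1));
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag < grad_thresh) continue;
      double ux = gx / mag, uy = gy / mag;
      ex.push_back(j); ey.push_back(i); egx.push_back(ux); egy.push_back(uy);
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        for (int t = r_min; t <= r_max; ++t) {
          int cx = (int) std::lround(j + sgn * t * ux);
          int cy = (int) std::lround(i + sgn * t * uy);
          if (cx < 0 || cx >= W || cy < 0 || cy >= H) break;
          acc[cy * W + cx]++;
        }
      }
    }
  }
  const int ne = (int) ex.size();

  // 3x3 box-smoothed accumulator for stable peaks
  std::vector<int> sm(H * W, 0);
  for (int i = 1; i < H - 1; ++i)
    for (int j = 1; j < W - 1; ++j) {
      int s = 0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) s += acc[(i + di) * W + (j + dj)];
      sm[i * W + j] = s;
    }

  struct Cand { double x, y; int votes, support; };
  std::vector<Cand> cands;
  for (int i = 1; i < H - 1; ++i) {
    for (int j = 1; j < W - 1; ++j) {
      if (acc[i * W + j] < param2) continue;
      int s = sm[i * W + j];
      bool peak = true;
      for (int di = -1; di <= 1 && peak; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          if (di == 0 && dj == 0) continue;
          int s2 = sm[(i + di) * W + (j + dj)];
          if (s2 > s || (s2 == s && (di < 0 || (di == 0 && dj < 0)))) {
            peak = false; break;
          }
        }
      if (peak) cands.push_back({(double) j, (double) i, acc[i * W + j], s});
    }
  }
  std::sort(cands.begin(), cands.end(),
            [](const Cand& a, const Cand& b) { return a.support > b.support; });

  std::vector<double> out_x, out_y, out_r;
  std::vector<int> out_v;
  const int nr = r_max - r_min + 1;
  std::vector<int> hist(nr);
  for (const Cand& c : cands) {
    if ((int) out_x.size() >= max_circles) break;
    double cx = c.x, cy = c.y, rad = -1.0;

    // iterate: radius histogram -> inlier selection -> Kasa circle fit
    for (int it = 0; it < 3; ++it) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int p = 0; p < ne; ++p) {
        double dx = ex[p] - cx, dy = ey[p] - cy;
        int b = (int) std::lround(std::sqrt(dx * dx + dy * dy)) - r_min;
        if (b >= 0 && b < nr) hist[b]++;
      }
      int bb = 0, bsup = -1;
      for (int b = 0; b < nr; ++b) {
        int sup = hist[b] + (b > 0 ? hist[b - 1] : 0) +
                  (b < nr - 1 ? hist[b + 1] : 0);
        if (sup > bsup) { bsup = sup; bb = b; }
      }
      if (hist[bb] == 0) { rad = -1.0; break; }
      double rmode = bb + r_min;
      // inliers: near the modal radius, gradient nearly radial
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0, sxz = 0, syz = 0,
             sz = 0;
      int n = 0;
      for (int p = 0; p < ne; ++p) {
        double dx = ex[p] - cx, dy = ey[p] - cy;
        double d = std::sqrt(dx * dx + dy * dy);
        if (std::fabs(d - rmode) > 3.0 || d < 1e-9) continue;
        double dot = (dx * egx[p] + dy * egy[p]) / d;
        if (std::fabs(dot) < 0.8) continue;
        double x = ex[p], y = ey[p], z = x * x + y * y;
        sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
        sxz += x * z; syz += y * z; sz += z;
        n++;
      }
      if (n < 6) { rad = rmode; break; }
      // solve the 3x3 normal equations of z + A x + B y + C = 0
      double a11 = sxx, a12 = sxy, a13 = sx;
      double a21 = sxy, a22 = syy, a23 = sy;
      double a31 = sx,  a32 = sy,  a33 = n;
      double b1 = -sxz, b2 = -syz, b3 = -sz;
      double det = a11 * (a22 * a33 - a23 * a32) -
                   a12 * (a21 * a33 - a23 * a31) +
                   a13 * (a21 * a32 - a22 * a31);
      if (std::fabs(det) < 1e-9) { rad = rmode; break; }
      double A = (b1 * (a22 * a33 - a23 * a32) -
                  a12 * (b2 * a33 - a23 * b3) +
                  a13 * (b2 * a32 - a22 * b3)) / det;
      double B = (a11 * (b2 * a33 - a23 * b3) -
                  b1 * (a21 * a33 - a23 * a31) +
                  a13 * (a21 * b3 - b2 * a31)) / det;
      double C = (a11 * (a22 * b3 - b2 * a32) -
                  a12 * (a21 * b3 - b2 * a31) +
                  b1 * (a21 * a32 - a22 * a31)) / det;
      double ncx = -A / 2.0, ncy = -B / 2.0;
      double r2 = ncx * ncx + ncy * ncy - C;
      if (r2 <= 0) { rad = rmode; break; }
      cx = ncx; cy = ncy; rad = std::sqrt(r2);
    }
    if (rad <= 0 || rad < r_min - 2.0 || rad > r_max + 2.0) continue;
    bool close = false;
    for (size_t q = 0; q < out_x.size(); ++q) {
      double dx = cx + 1.0 - out_x[q], dy = cy + 1.0 - out_y[q];
      if (std::sqrt(dx * dx + dy * dy) < min_dist) { close = true; break; }
    }
    if (close) continue;
    out_x.push_back(cx + 1.0);   // 0-based index -> 1-based pixel center
    out_y.push_back(cy + 1.0);
    out_r.push_back(rad);
    out_v.push_back(c.votes);
  }
  return DataFrame::create(_["cx"] = out_x, _["cy"] = out_y,
                           _["r"] = out_r, _["votes"] = out_v);
}
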