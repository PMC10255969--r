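#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Best placement of a (possibly masked) template under zero-mean normalized
// cross-correlation. The mask marks template pixels that are valid after
// rotation/scaling (corners introduced by resampling are excluded).
// Returns best max(0, ncc) score and the 1-based top-left placement.
// Windows with (near-)zero intensity variance score 0 by convention so that
// a fixed decision threshold stays meaningful on flat image regions.
// [[Rcpp::export(name = ".ncc_scan_cpp")]]
List ncc_scan_cpp(const NumericMatrix& img, const NumericMatrix& tpl,
                  const LogicalMatrix& mask) {
  const int H = img.nrow(), W = img.ncol();
  const int th = tpl.nrow(), tw = tpl.ncol();
  if (th > H || tw > W) stop("template larger than image");

  // collect valid template pixels, centered
  std::vector<int> mi, mj;
  std::vector<double> tv;
  double tsum = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i)
      if (mask(i, j)) {
        mi.push_back(i); mj.push_back(j); tv.push_back(tpl(i, j));
        tsum += tpl(i, j);
      }
  const int n = (int) tv.size();
  if (n < 2) stop("template mask is empty");
  const double tmean = tsum / n;
  double sst = 0.0;
  for (int p = 0; p < n; ++p) { tv[p] -= tmean; sst += tv[p] * tv[p]; }

  const double eps = 1e-9;
  double best = 0.0;
  int bi = 0, bj = 0;
  const bool flat_tpl = (sst <= eps);

  for (int j0 = 0; j0 + tw <= W; ++j0) {
    for (int i0 = 0; i0 + th <= H; ++i0) {
      if (flat_tpl) continue;
      double sI = 0.0, sII = 0.0, sTI = 0.0;
      for (int p = 0; p < n; ++p) {
        double v = img(i0 + mi[p], j0 + mj[p]);
        sI += v; sII += v * v; sTI += tv[p] * v;
      }
      double ssI = sII - sI * sI / n;
      if (ssI <= eps) continue;       // flat window scores 0
      double ncc = sTI / std::sqrt(sst * ssI);
      if (ncc > best) { best = ncc; bi = i0; bj = j0; }
    }
  }
  return List::create(_["score"] = best, _["row"] = bi + 1, _["col"] = bj + 1);
}
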