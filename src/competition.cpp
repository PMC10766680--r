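#include <Rcpp.h>
using namespace Rcpp;

// Height-asymmetric competition kernel over a fixed neighborhood radius.
// For tree i: comp_i = scale * sum over neighbors j (j != i, d_ij <= R,
// h_j >= h_i) of (h_j / 100) * (1 - d_ij / R), i.e. taller-or-equal
// neighbors contribute their height in meters, linearly down-weighted with
// distance. A bucket grid with cell size R keeps the query exact and fast.
// [[Rcpp::export]]
NumericVector competition_kernel_cpp(NumericVector x, NumericVector y,
                                     NumericVector h, double radius,
                                     double scale) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0 || radius <= 0.0) return out;
  double xmin = x[0], ymin = y[0], xmax = x[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  const int ncx = std::max(1, (int)((xmax - xmin) / radius) + 1);
  const int ncy = std::max(1, (int)((ymax - ymin) / radius) + 1);
  std::vector<int> cell(n), count((size_t)ncx * ncy + 1, 0);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncx - 1, (int)((x[i] - xmin) / radius));
    int cy = std::min(ncy - 1, (int)((y[i] - ymin) / radius));
    cell[i] = cx * ncy + cy;
    ++count[cell[i] + 1];
  }
  for (size_t c = 1; c < count.size(); ++c) count[c] += count[c - 1];
  std::vector<int> order(n), fill(count.begin(), count.end() - 1);
  for (int i = 0; i < n; ++i) order[fill[cell[i]]++] = i;

  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cx = cell[i] / ncy, cy = cell[i] % ncy;
    double acc = 0.0;
    for (int dx = -1; dx <= 1; ++dx) {
      int nx = cx + dx;
      if (nx < 0 || nx >= ncx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int ny = cy + dy;
        if (ny < 0 || ny >= ncy) continue;
        int c = nx * ncy + ny;
        for (int k = count[c]; k < count[c + 1]; ++k) {
          int j = order[k];
          if (j == i || h[j] < h[i]) continue;
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 > r2) continue;
          acc += (h[j] / 100.0) * (1.0 - std::sqrt(d2) / radius);
        }
      }
    }
    out[i] = scale * acc;
  }
  return out;
}
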