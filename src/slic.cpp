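#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// SLIC superpixel segmentation for a single-channel image in [0,1].
//
// Distance between pixel p and cluster j:
//   D^2 = (I_p - I_j)^2 + m^2 * ||x_p - x_j||^2 / S^2
// where S = sqrt(n_pixels / k) is the sampling interval and m the
// compactness. Each cluster only searches a 2S x 2S window around its
// centre, giving the usual O(n_iter * n_pixels) cost.
//
// Connectivity is enforced afterwards: connected components of the raw
// assignment smaller than S^2/4 pixels are merged into the neighbouring
// component encountered first in raster order; labels are returned
// 1-based and contiguous.

// [[Rcpp::export]]
IntegerMatrix slic_cpp(NumericMatrix img, int k, double compactness, int n_iter) {
  const int nr = img.nrow(), nc = img.ncol();
  const double npix = static_cast<double>(nr) * nc;
  const double S = std::sqrt(npix / k);
  const double m2S2 = (compactness * compactness) / (S * S);

  // initial cluster centres on a regular grid
  int grid_r = std::max(1, (int) std::lround(nr / S));
  int grid_c = std::max(1, (int) std::lround(nc / S));
  std::vector<double> cr, cc, ci;
  for (int gi = 0; gi < grid_r; ++gi) {
    for (int gj = 0; gj < grid_c; ++gj) {
      double r = (gi + 0.5) * nr / grid_r;
      double c = (gj + 0.5) * nc / grid_c;
      int ri = std::min(nr - 1, std::max(0, (int) std::lround(r - 0.5)));
      int cj = std::min(nc - 1, std::max(0, (int) std::lround(c - 0.5)));
      // move centre to the lowest-gradient pixel in a 3x3 neighbourhood
      double best = R_PosInf; int br = ri, bc = cj;
      for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
        int rr = ri + dr, cc2 = cj + dc;
        if (rr < 1 || rr >= nr - 1 || cc2 < 1 || cc2 >= nc - 1) continue;
        double gx = img(rr + 1, cc2) - img(rr - 1, cc2);
        double gy = img(rr, cc2 + 1) - img(rr, cc2 - 1);
        double g = gx * gx + gy * gy;
        if (g < best) { best = g; br = rr; bc = cc2; }
      }
      cr.push_back(br); cc.push_back(bc); ci.push_back(img(br, bc));
    }
  }
  const int K = (int) cr.size();

  std::vector<int> label(nr * nc, -1);
  std::vector<double> dist(nr * nc);

  for (int it = 0; it < n_iter; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int j = 0; j < K; ++j) {
      int r0 = std::max(0, (int) std::floor(cr[j] - S));
      int r1 = std::min(nr - 1, (int) std::ceil(cr[j] + S));
      int c0 = std::max(0, (int) std::floor(cc[j] - S));
      int c1 = std::min(nc - 1, (int) std::ceil(cc[j] + S));
      for (int c = c0; c <= c1; ++c) {
        double dc2 = (c - cc[j]) * (c - cc[j]);
        for (int r = r0; r <= r1; ++r) {
          double ds2 = (r - cr[j]) * (r - cr[j]) + dc2;
          double di = img(r, c) - ci[j];
          double D = di * di + m2S2 * ds2;
          int idx = r + nr * c;
          if (D < dist[idx]) { dist[idx] = D; label[idx] = j; }
        }
      }
    }
    // fallback for pixels outside every search window (rare, tiny k)
    for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
      int idx = r + nr * c;
      if (label[idx] >= 0) continue;
      double best = R_PosInf; int bj = 0;
      for (int j = 0; j < K; ++j) {
        double ds2 = (r - cr[j]) * (r - cr[j]) + (c - cc[j]) * (c - cc[j]);
        double di = img(r, c) - ci[j];
        double D = di * di + m2S2 * ds2;
        if (D < best) { best = D; bj = j; }
      }
      label[idx] = bj;
    }
    // update centres
    std::vector<double> sr(K, 0), sc(K, 0), si(K, 0), n(K, 0);
    for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
      int j = label[r + nr * c];
      sr[j] += r; sc[j] += c; si[j] += img(r, c); n[j] += 1;
    }
    for (int j = 0; j < K; ++j) {
      if (n[j] > 0) { cr[j] = sr[j] / n[j]; cc[j] = sc[j] / n[j]; ci[j] = si[j] / n[j]; }
    }
  }

  // enforce connectivity (4-connectivity), merge small fragments
  const int min_size = std::max(1, (int) (S * S / 4.0));
  std::vector<int> out(nr * nc, -1);
  std::vector<int> comp;   // pixel indices of current component
  int next_label = 0;
  const int drs[4] = {-1, 1, 0, 0}, dcs[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    int idx = r + nr * c;
    if (out[idx] >= 0) continue;
    // neighbour label already assigned (raster predecessor), for merging
    int adj = -1;
    if (r > 0 && out[idx - 1] >= 0) adj = out[idx - 1];
    else if (c > 0 && out[idx - nr] >= 0) adj = out[idx - nr];
    comp.clear();
    comp.push_back(idx);
    out[idx] = next_label;
    size_t head = 0;
    while (head < comp.size()) {
      int cur = comp[head++];
      int rr = cur % nr, cc2 = cur / nr;
      for (int d = 0; d < 4; ++d) {
        int r2 = rr + drs[d], c2 = cc2 + dcs[d];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int idx2 = r2 + nr * c2;
        if (out[idx2] < 0 && label[idx2] == label[idx]) {
          out[idx2] = next_label;
          comp.push_back(idx2);
        }
      }
    }
    if ((int) comp.size() < min_size && adj >= 0) {
      for (size_t t = 0; t < comp.size(); ++t) out[comp[t]] = adj;
    } else {
      ++next_label;
    }
  }

  IntegerMatrix res(nr, nc);
  for (int i = 0; i < nr * nc; ++i) res[i] = out[i] + 1;  // 1-based
  return res;
}
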