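#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbor offsets for 6/18/26-connectivity on a 3D lattice.
static void neighbor_offsets(int connectivity,
                             std::vector<int>& dx,
                             std::vector<int>& dy,
                             std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Flood-fill labeling of the voxels where mask[v] != 0.
// Labels are assigned in raster-scan order of each component's first voxel,
// so the labeling is deterministic.
static int label_mask(const std::vector<char>& mask, int nx, int ny, int nz,
                      int connectivity, std::vector<int>& labels,
                      std::vector<int>& sizes) {
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const int ndir = (int) dx.size();
  const size_t n = mask.size();
  labels.assign(n, 0);
  sizes.clear();
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++next;
    int count = 0;
    stack.push_back(s);
    labels[s] = next;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      ++count;
      int k = (int)(v / (size_t)(nx * ny));
      int rem = (int)(v % (size_t)(nx * ny));
      int j = rem / nx;
      int i = rem % nx;
      for (int d = 0; d < ndir; ++d) {
        int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t w = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
        if (mask[w] && !labels[w]) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(count);
  }
  return next;
}

// [[Rcpp::export(name = ".cc3d_label")]]
List cc3d_label(IntegerVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> m(n);
  for (size_t s = 0; s < n; ++s) m[s] = mask[s] != 0;
  std::vector<int> labels, sizes;
  int ncomp = label_mask(m, nx, ny, nz, connectivity, labels, sizes);
  IntegerVector lab(n);
  for (size_t s = 0; s < n; ++s) lab[s] = labels[s];
  lab.attr("dim") = dims;
  return List::create(_["labels"] = lab,
                      _["sizes"] = wrap(sizes),
                      _["n_components"] = ncomp);
}

// Threshold-free cluster enhancement of a non-negative statistic map:
//   TFCE(v) = sum over h = dh, 2dh, ..., <= z(v) of e(h,v)^E * h^H * dh
// where e(h,v) is the voxel extent of the connected component containing v
// in the supra-threshold set {z >= h}.
// [[Rcpp::export(name = ".tfce_transform")]]
NumericVector tfce_transform(NumericVector z, IntegerVector dims,
                             double H, double E, double dh,
                             int connectivity) {
  if (dh <= 0) stop("tfce: dh must be > 0");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  double zmax = 0.0;
  for (size_t s = 0; s < n; ++s) if (z[s] > zmax) zmax = z[s];
  if (zmax <= 0) { out.attr("dim") = dims; return out; }
  int nsteps = (int) std::floor(zmax / dh + 1e-12);
  std::vector<char> mask(n);
  std::vector<int> labels, sizes;
  for (int step = 1; step <= nsteps; ++step) {
    double h = step * dh;
    bool any = false;
    for (size_t s = 0; s < n; ++s) {
      mask[s] = z[s] >= h;
      any = any || mask[s];
    }
    if (!any) break;
    label_mask(mask, nx, ny, nz, connectivity, labels, sizes);
    double hH = std::pow(h, H) * dh;
    for (size_t s = 0; s < n; ++s) {
      if (labels[s]) out[s] += std::pow((double) sizes[labels[s] - 1], E) * hH;
    }
  }
  out.attr("dim") = dims;
  return out;
}
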