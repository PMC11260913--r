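#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Neighbour offsets for 6-, 18- or 26-connectivity on a 3D grid.
static std::vector<int> neighbour_offsets(int connectivity, int dx[][3]) {
  std::vector<int> keep;
  int k = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        int m = std::abs(ox) + std::abs(oy) + std::abs(oz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx[k][0] = ox; dx[k][1] = oy; dx[k][2] = oz;
        keep.push_back(k);
        ++k;
      }
  return keep;
}

// Label connected components of the TRUE phase of `mask` (column-major,
// dims nx,ny,nz). Returns labels (0 for FALSE voxels, 1..K otherwise,
// in discovery order), per-component voxel counts, whether the component
// touches the volume boundary, and the smallest linear index (1-based)
// of each component.
// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  int offs[26][3];
  std::vector<int> idx = neighbour_offsets(connectivity, offs);
  const int noff = (int)idx.size();

  IntegerVector labels(n, 0);
  std::vector<double> counts;
  std::vector<int> touches, minidx;
  std::vector<R_xlen_t> queue;
  int K = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++K;
    double cnt = 0;
    int touch = 0;
    labels[start] = K;
    queue.clear();
    queue.push_back(start);
    minidx.push_back((int)(start + 1));
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      ++cnt;
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 || z == nz - 1)
        touch = 1;
      for (int j = 0; j < noff; ++j) {
        int xx = x + offs[idx[j]][0];
        int yy = y + offs[idx[j]][1];
        int zz = z + offs[idx[j]][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = K;
          queue.push_back(w);
        }
      }
    }
    counts.push_back(cnt);
    touches.push_back(touch);
  }

  return List::create(
    _["labels"] = labels,
    _["n"] = K,
    _["counts"] = wrap(counts),
    _["touches_boundary"] = wrap(touches),
    _["min_index"] = wrap(minidx));
}

static void smooth_axis(std::vector<double> &v, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (double &k : kern) k /= s;

  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> out(n);
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nx : (R_xlen_t)nx * ny;
  int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;

  for (R_xlen_t v0 = 0; v0 < n; ++v0) {
    int pos = (axis == 0) ? (int)(v0 % nx)
            : (axis == 1) ? (int)((v0 / nx) % ny)
                          : (int)(v0 / ((R_xlen_t)nx * ny));
    double acc = 0;
    for (int i = -r; i <= r; ++i) {
      int p = pos + i;
      if (p < 0) p = 0;            // replicate border
      if (p >= len) p = len - 1;
      acc += kern[i + r] * v[v0 + (R_xlen_t)(p - pos) * stride];
    }
    out[v0] = acc;
  }
  v.swap(out);
}

// Separable Gaussian smoothing of a double volume; sigma per axis in voxels.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  smooth_axis(v, nx, ny, nz, 0, sigma[0]);
  smooth_axis(v, nx, ny, nz, 1, sigma[1]);
  smooth_axis(v, nx, ny, nz, 2, sigma[2]);
  return wrap(v);
}

// Surface area (mm^2) of the TRUE phase of `mask` by normal-weighted
// exposed-face summation: each voxel face separating inside from outside
// contributes its physical face area times |n_axis| of the local unit
// surface normal, estimated from the gradient of a Gaussian-smoothed
// copy of the mask. Exact (asymptotically) for planar interfaces of any
// orientation, hence for both spherical eyes and thin planar cracks.
// [[Rcpp::export]]
double cpp_surface_area(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing, double sigma_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];

  std::vector<double> s(n);
  for (R_xlen_t i = 0; i < n; ++i) s[i] = mask[i] ? 1.0 : 0.0;
  smooth_axis(s, nx, ny, nz, 0, sigma_mm / dx);
  smooth_axis(s, nx, ny, nz, 1, sigma_mm / dy);
  smooth_axis(s, nx, ny, nz, 2, sigma_mm / dz);

  // central-difference gradient in physical units
  std::vector<double> gx(n), gy(n), gz(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        int xm = x > 0 ? x - 1 : x, xp = x < nx - 1 ? x + 1 : x;
        int ym = y > 0 ? y - 1 : y, yp = y < ny - 1 ? y + 1 : y;
        int zm = z > 0 ? z - 1 : z, zp = z < nz - 1 ? z + 1 : z;
        gx[v] = (s[v - x + xp] - s[v - x + xm]) / ((xp - xm) * dx);
        gy[v] = (s[v + (R_xlen_t)(yp - y) * nx] - s[v + (R_xlen_t)(ym - y) * nx]) /
                ((yp - ym) * dy);
        gz[v] = (s[v + (R_xlen_t)(zp - z) * nx * ny] - s[v + (R_xlen_t)(zm - z) * nx * ny]) /
                ((zp - zm) * dz);
      }

  const double face[3] = {dy * dz, dx * dz, dx * dy};
  const double w_iso = 1.0 / std::sqrt(3.0);
  double area = 0;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (!mask[v]) continue;
        for (int axis = 0; axis < 3; ++axis) {
          for (int dir = -1; dir <= 1; dir += 2) {
            int xx = x, yy = y, zz = z;
            if (axis == 0) xx += dir; else if (axis == 1) yy += dir; else zz += dir;
            bool outside;
            R_xlen_t w = -1;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
              outside = true;
            } else {
              w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
              outside = !mask[w];
            }
            if (!outside) continue;
            double nxg = gx[v], nyg = gy[v], nzg = gz[v];
            if (w >= 0) {  // average gradient across the face
              nxg = 0.5 * (nxg + gx[w]);
              nyg = 0.5 * (nyg + gy[w]);
              nzg = 0.5 * (nzg + gz[w]);
            }
            double nrm = std::sqrt(nxg * nxg + nyg * nyg + nzg * nzg);
            double wgt;
            if (nrm < 1e-12) {
              wgt = w_iso;
            } else {
              wgt = std::fabs(axis == 0 ? nxg : axis == 1 ? nyg : nzg) / nrm;
            }
            area += face[axis] * wgt;
          }
        }
      }
  return area;
}

// Per-label voxel count, centroid (0-based voxel index coordinates) and
// bounding box for labels 1..K of a labelled volume.
// [[Rcpp::export]]
List cpp_region_props(IntegerVector labels, IntegerVector dim, int K) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector count(K), sx(K), sy(K), sz(K);
  IntegerVector x0(K, nx), x1(K, -1), y0(K, ny), y1(K, -1), z0(K, nz), z1(K, -1);
  for (R_xlen_t v = 0; v < n; ++v) {
    int lab = labels[v];
    if (lab <= 0) continue;
    if (lab > K) stop("label exceeds K");
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    int k = lab - 1;
    count[k] += 1; sx[k] += x; sy[k] += y; sz[k] += z;
    if (x < x0[k]) x0[k] = x; if (x > x1[k]) x1[k] = x;
    if (y < y0[k]) y0[k] = y; if (y > y1[k]) y1[k] = y;
    if (z < z0[k]) z0[k] = z; if (z > z1[k]) z1[k] = z;
  }
  return List::create(
    _["count"] = count, _["sx"] = sx, _["sy"] = sy, _["sz"] = sz,
    _["x0"] = x0, _["x1"] = x1, _["y0"] = y0, _["y1"] = y1,
    _["z0"] = z0, _["z1"] = z1);
}
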