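#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx); linear index
// i = z + nz * (y + ny * x), i.e. the first (z) index varies fastest.

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// Spatial cross-correlation with zero padding ("same" output size).
// Kernel dims must be odd along every axis.
// [[Rcpp::export]]
NumericVector conv3d_same(NumericVector vol, NumericVector kernel) {
  IntegerVector dv = vol.attr("dim");
  IntegerVector dk = kernel.attr("dim");
  int nz = dv[0], ny = dv[1], nx = dv[2];
  int kz = dk[0], ky = dk[1], kx = dk[2];
  if (kz % 2 == 0 || ky % 2 == 0 || kx % 2 == 0)
    stop("kernel extents must be odd");
  int rz = kz / 2, ry = ky / 2, rx = kx / 2;
  NumericVector out(vol.size());
  out.attr("dim") = dv;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        for (int dx = -rx; dx <= rx; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -ry; dy <= ry; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -rz; dz <= rz; ++dz) {
              int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              acc += vol[idx3(zz, yy, xx, nz, ny)] *
                     kernel[idx3(dz + rz, dy + ry, dx + rx, kz, ky)];
            }
          }
        }
        out[idx3(z, y, x, nz, ny)] = acc;
      }
  return out;
}

// One separable pass along a given axis (0=z, 1=y, 2=x) with reflect
// padding when normalize=true (image smoothing) or zero padding when
// normalize=false (unnormalized Gaussian sums for CRF messages).
static void gauss_axis(std::vector<double> &v, int nz, int ny, int nx,
                       int axis, const std::vector<double> &taps,
                       bool reflect) {
  int r = (int)taps.size() / 2;
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(len), outl(len);
  int n_other1 = axis == 0 ? ny : nz;
  int n_other2 = axis == 2 ? ny : nx;
  for (int a = 0; a < n_other1; ++a)
    for (int b = 0; b < n_other2; ++b) {
      for (int i = 0; i < len; ++i) {
        int z, y, x;
        if (axis == 0) { z = i; y = a; x = b; }
        else if (axis == 1) { z = a; y = i; x = b; }
        else { z = a; y = b; x = i; }
        line[i] = v[idx3(z, y, x, nz, ny)];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int j = i + t;
          if (j < 0 || j >= len) {
            if (!reflect) continue;
            j = j < 0 ? -j - 1 : 2 * len - j - 1; // reflect101-free mirror
            if (j < 0) j = 0; if (j >= len) j = len - 1;
          }
          acc += line[j] * taps[t + r];
        }
        outl[i] = acc;
      }
      for (int i = 0; i < len; ++i) {
        int z, y, x;
        if (axis == 0) { z = i; y = a; x = b; }
        else if (axis == 1) { z = a; y = i; x = b; }
        else { z = a; y = b; x = i; }
        v[idx3(z, y, x, nz, ny)] = outl[i];
      }
    }
}

// Separable Gaussian filter. sigma is per axis (z, y, x); sigma <= 0
// skips that axis. normalize=true gives a unit-sum smoothing kernel with
// mirror padding; normalize=false leaves taps exp(-d^2/2s^2) (peak 1)
// with zero padding, as needed for dense-CRF message passing.
// [[Rcpp::export]]
NumericVector gauss3d(NumericVector vol, NumericVector sigma,
                      bool normalize = true, double truncate = 3.0) {
  IntegerVector dv = vol.attr("dim");
  int nz = dv[0], ny = dv[1], nx = dv[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(truncate * s);
    std::vector<double> taps(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      taps[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += taps[t + r];
    }
    if (normalize) for (double &t : taps) t /= sum;
    gauss_axis(v, nz, ny, nx, axis, taps, normalize);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dv;
  return out;
}

// --- exact squared Euclidean distance transform (Felzenszwalb) --------

static void dt1d(std::vector<double> &f, double w, int n) {
  // lower envelope of parabolas f[j] + w^2 (i-j)^2
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
  f = d;
}

// Squared Euclidean distance from every voxel to the nearest voxel of
// the feature set (set != 0), with per-axis spacing (z, y, x).
// Voxels inside the set get 0. If the set is empty, all Inf.
// [[Rcpp::export]]
NumericVector edt3d_sq(IntegerVector set, NumericVector spacing) {
  IntegerVector dv = set.attr("dim");
  int nz = dv[0], ny = dv[1], nx = dv[2];
  // large finite sentinel: the parabola arithmetic in dt1d is undefined
  // for true infinities
  const double INF = 1e20;
  std::vector<double> d(set.size());
  for (int i = 0; i < set.size(); ++i) d[i] = set[i] != 0 ? 0.0 : INF;

  std::vector<double> line;
  // axis z
  line.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      bool any = false;
      for (int z = 0; z < nz; ++z) { line[z] = d[idx3(z, y, x, nz, ny)]; if (line[z] < INF) any = true; }
      if (any) { dt1d(line, spacing[0], nz);
        for (int z = 0; z < nz; ++z) d[idx3(z, y, x, nz, ny)] = line[z]; }
    }
  // axis y
  line.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      bool any = false;
      for (int y = 0; y < ny; ++y) { line[y] = d[idx3(z, y, x, nz, ny)]; if (line[y] < INF) any = true; }
      if (any) { dt1d(line, spacing[1], ny);
        for (int y = 0; y < ny; ++y) d[idx3(z, y, x, nz, ny)] = line[y]; }
    }
  // axis x
  line.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      bool any = false;
      for (int x = 0; x < nx; ++x) { line[x] = d[idx3(z, y, x, nz, ny)]; if (line[x] < INF) any = true; }
      if (any) { dt1d(line, spacing[2], nx);
        for (int x = 0; x < nx; ++x) d[idx3(z, y, x, nz, ny)] = line[x]; }
    }
  for (size_t i = 0; i < d.size(); ++i)
    if (d[i] >= 1e19) d[i] = std::numeric_limits<double>::infinity();
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = dv;
  return out;
}

// --- seeded watershed by priority flooding (Meyer), 6-connectivity ----

// elev: elevation map (flooded from low to high); seeds: 0 = unseeded,
// >0 = region labels. Every voxel receives a label. Ties broken by
// insertion order (FIFO), making the result deterministic.
// [[Rcpp::export]]
IntegerVector watershed3d(NumericVector elev, IntegerVector seeds) {
  IntegerVector dv = elev.attr("dim");
  int nz = dv[0], ny = dv[1], nx = dv[2];
  int n = elev.size();
  std::vector<int> lab(seeds.begin(), seeds.end());

  typedef std::tuple<double, long long, int, int> Entry; // elev, order, idx, label
  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry> > pq;
  long long counter = 0;

  const int dz[6] = { 1, -1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, 1, -1, 0, 0 };
  const int dx[6] = { 0, 0, 0, 0, 1, -1 };

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (lab[i] <= 0) continue;
        for (int k = 0; k < 6; ++k) {
          int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          int j = idx3(zz, yy, xx, nz, ny);
          if (lab[j] == 0)
            pq.push(Entry(elev[j], counter++, j, lab[i]));
        }
      }

  while (!pq.empty()) {
    Entry e = pq.top(); pq.pop();
    int i = std::get<2>(e), l = std::get<3>(e);
    if (lab[i] != 0) continue;
    lab[i] = l;
    int x = i / (nz * ny), y = (i / nz) % ny, z = i % nz;
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = idx3(zz, yy, xx, nz, ny);
      if (lab[j] == 0)
        pq.push(Entry(elev[j], counter++, j, l));
    }
  }

  IntegerVector out(lab.begin(), lab.end());
  out.attr("dim") = dv;
  return out;
}

// Connected component labelling of a binary mask (6- or 26-connectivity).
// [[Rcpp::export]]
IntegerVector label_components(IntegerVector mask, int connectivity = 6) {
  IntegerVector dv = mask.attr("dim");
  int nz = dv[0], ny = dv[1], nx = dv[2];
  std::vector<int> lab(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        int i0 = idx3(z0, y0, x0, nz, ny);
        if (mask[i0] == 0 || lab[i0] != 0) continue;
        ++next;
        lab[i0] = next;
        stack.push_back(i0);
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          int x = i / (nz * ny), y = (i / nz) % ny, z = i % nz;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (ad == 0) continue;
                if (connectivity == 6 && ad != 1) continue;
                int zz = z + dz, yy = y + dy, xx = x + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
                int j = idx3(zz, yy, xx, nz, ny);
                if (mask[j] != 0 && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
              }
        }
      }
  IntegerVector out(lab.begin(), lab.end());
  out.attr("dim") = dv;
  return out;
}
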