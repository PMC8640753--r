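// Low-level 3-D image primitives shared by the phantom, reconstruction,
// segmentation and quantification modules. Arrays are column-major with
// dim = (nz, ny, nx); linear index = z + nz*(y + ny*x). Spacings are
// physical voxel sizes in micrometres, ordered (z, y, x).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;
typedef R_xlen_t xlen;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable convolution along one axis with symmetric (reflect) boundary.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector a, IntegerVector dim, NumericVector k, int axis) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen s[3] = {1, (xlen)ns[0], (xlen)ns[0] * ns[1]};
  int na = ns[axis];
  xlen sa = s[axis];
  int kl = k.size(), kr = kl / 2;
  NumericVector out(a.size());
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(na);
  for (int i2 = 0; i2 < ns[o2]; i2++) {
    for (int i1 = 0; i1 < ns[o1]; i1++) {
      xlen base = (xlen)i1 * s[o1] + (xlen)i2 * s[o2];
      for (int i = 0; i < na; i++) line[i] = a[base + (xlen)i * sa];
      for (int i = 0; i < na; i++) {
        double acc = 0.0;
        for (int t = 0; t < kl; t++) acc += k[t] * line[reflect_idx(i + t - kr, na)];
        out[base + (xlen)i * sa] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing w; skips infinite parabolas so empty lines stay infinite.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  double w2 = w * w;
  int kk = -1;
  for (int q = 0; q < n; q++) {
    if (!std::isfinite(f[q])) continue;
    double fq = f[q] + w2 * (double)q * q;
    if (kk < 0) {
      kk = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[kk];
      s = (fq - (f[p] + w2 * (double)p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[kk]) { kk--; if (kk < 0) break; } else break;
    }
    kk++;
    v[kk] = q; z[kk] = (kk == 0) ? -INF : s; z[kk + 1] = INF;
  }
  if (kk < 0) { for (int q = 0; q < n; q++) d[q] = INF; return; }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < q) j++;
    double dq = w * (double)(q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
}

static void edt_sq_inplace(std::vector<double>& g, const int ns[3], const double sp[3]) {
  xlen s[3] = {1, (xlen)ns[0], (xlen)ns[0] * ns[1]};
  for (int axis = 0; axis < 3; axis++) {
    int na = ns[axis];
    xlen sa = s[axis];
    int o1 = (axis == 0) ? 1 : 0;
    int o2 = (axis == 2) ? 1 : 2;
    std::vector<double> line(na), out(na);
    for (int i2 = 0; i2 < ns[o2]; i2++) {
      for (int i1 = 0; i1 < ns[o1]; i1++) {
        xlen base = (xlen)i1 * s[o1] + (xlen)i2 * s[o2];
        for (int i = 0; i < na; i++) line[i] = g[base + (xlen)i * sa];
        dt1d(line, out, na, sp[axis]);
        for (int i = 0; i < na; i++) g[base + (xlen)i * sa] = out[i];
      }
    }
  }
}

// Exact anisotropic Euclidean distance (um) to the nearest TRUE voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector feature, IntegerVector dim, NumericVector spacing) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(N);
  for (xlen i = 0; i < N; i++) g[i] = feature[i] ? 0.0 : INF;
  edt_sq_inplace(g, ns, sp);
  NumericVector out(N);
  for (xlen i = 0; i < N; i++) out[i] = std::isfinite(g[i]) ? std::sqrt(g[i]) : R_PosInf;
  out.attr("dim") = dim;
  return out;
}

// Local thickness: per pore voxel, diameter (um) of the largest inscribed
// sphere (in the pore phase, grid border counts as solid) containing it.
// Implemented as distance-transform + redundant-sphere pruning + painting;
// identical by construction to a brute-force all-centres search.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector pore, IntegerVector dim, NumericVector spacing) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> r2(N);
  for (xlen i = 0; i < N; i++) r2[i] = pore[i] ? INF : 0.0;
  edt_sq_inplace(r2, ns, sp);
  // cap by distance to the virtual background ring just outside the grid
  for (int x = 0; x < ns[2]; x++) for (int y = 0; y < ns[1]; y++) for (int z = 0; z < ns[0]; z++) {
    xlen i = z + (xlen)ns[0] * (y + (xlen)ns[1] * x);
    if (!pore[i]) { r2[i] = 0.0; continue; }
    double bz = std::min((double)(z + 1), (double)(ns[0] - z)) * sp[0];
    double by = std::min((double)(y + 1), (double)(ns[1] - y)) * sp[1];
    double bx = std::min((double)(x + 1), (double)(ns[2] - x)) * sp[2];
    double b = std::min(bz, std::min(by, bx));
    if (b * b < r2[i]) r2[i] = b * b;
  }
  // candidate centres, largest radius first
  std::vector<xlen> cand;
  cand.reserve(N / 4);
  for (xlen i = 0; i < N; i++) if (pore[i] && r2[i] > 0) cand.push_back(i);
  std::sort(cand.begin(), cand.end(), [&](xlen a, xlen b) { return r2[a] > r2[b]; });
  NumericVector out(N);
  const double eps = 1e-9;
  for (size_t ci = 0; ci < cand.size(); ci++) {
    xlen i = cand[ci];
    int z = (int)(i % ns[0]);
    int y = (int)((i / ns[0]) % ns[1]);
    int x = (int)(i / ((xlen)ns[0] * ns[1]));
    double Ri2 = r2[i];
    double Ri = std::sqrt(Ri2);
    // prune: skip if some neighbour's sphere contains this one
    bool redundant = false;
    for (int dz = -1; dz <= 1 && !redundant; dz++)
      for (int dy = -1; dy <= 1 && !redundant; dy++)
        for (int dx = -1; dx <= 1 && !redundant; dx++) {
          if (!dz && !dy && !dx) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= ns[0] || yy < 0 || yy >= ns[1] || xx < 0 || xx >= ns[2]) continue;
          xlen j = zz + (xlen)ns[0] * (yy + (xlen)ns[1] * xx);
          if (!pore[j]) continue;
          double dd = std::sqrt(dz * dz * sp[0] * sp[0] + dy * dy * sp[1] * sp[1] + dx * dx * sp[2] * sp[2]);
          if (std::sqrt(r2[j]) >= Ri + dd - eps) redundant = true;
        }
    if (redundant) continue;
    double diam = 2.0 * Ri;
    int ez = (int)std::floor(Ri / sp[0]);
    int ey = (int)std::floor(Ri / sp[1]);
    int ex = (int)std::floor(Ri / sp[2]);
    for (int dx = -ex; dx <= ex; dx++) {
      int xx = x + dx; if (xx < 0 || xx >= ns[2]) continue;
      double qx = dx * sp[2] * dx * sp[2];
      for (int dy = -ey; dy <= ey; dy++) {
        int yy = y + dy; if (yy < 0 || yy >= ns[1]) continue;
        double qxy = qx + dy * sp[1] * dy * sp[1];
        if (qxy > Ri2 + eps) continue;
        for (int dz = -ez; dz <= ez; dz++) {
          int zz = z + dz; if (zz < 0 || zz >= ns[0]) continue;
          if (qxy + dz * sp[0] * dz * sp[0] > Ri2 + eps) continue;
          xlen j = zz + (xlen)ns[0] * (yy + (xlen)ns[1] * xx);
          if (pore[j] && out[j] < diam) out[j] = diam;
        }
      }
    }
  }
  // every pore voxel is at least covered by its own sphere
  for (xlen i = 0; i < N; i++) {
    if (pore[i]) { double d = 2.0 * std::sqrt(r2[i]); if (out[i] < d) out[i] = d; }
  }
  out.attr("dim") = dim;
  return out;
}

static void neighbour_offsets(int connectivity, std::vector<int>& dz,
                              std::vector<int>& dy, std::vector<int>& dx) {
  dz.clear(); dy.clear(); dx.clear();
  for (int a = -1; a <= 1; a++) for (int b = -1; b <= 1; b++) for (int c = -1; c <= 1; c++) {
    if (!a && !b && !c) continue;
    int nnz = std::abs(a) + std::abs(b) + std::abs(c);
    if (connectivity == 6 && nnz > 1) continue;
    dz.push_back(a); dy.push_back(b); dx.push_back(c);
  }
}

// Flood fill of voxels >= threshold connected to seed voxels (0-based z,y,x rows).
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim, IntegerMatrix seeds,
                              double threshold, int connectivity) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  LogicalVector out(N);
  std::vector<int> dz, dy, dx;
  neighbour_offsets(connectivity, dz, dy, dx);
  std::queue<xlen> q;
  for (int s = 0; s < seeds.nrow(); s++) {
    xlen i = seeds(s, 0) + (xlen)ns[0] * (seeds(s, 1) + (xlen)ns[1] * seeds(s, 2));
    if (!out[i] && vol[i] >= threshold) { out[i] = true; q.push(i); }
  }
  while (!q.empty()) {
    xlen i = q.front(); q.pop();
    int z = (int)(i % ns[0]);
    int y = (int)((i / ns[0]) % ns[1]);
    int x = (int)(i / ((xlen)ns[0] * ns[1]));
    for (size_t k = 0; k < dz.size(); k++) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= ns[0] || yy < 0 || yy >= ns[1] || xx < 0 || xx >= ns[2]) continue;
      xlen j = zz + (xlen)ns[0] * (yy + (xlen)ns[1] * xx);
      if (!out[j] && vol[j] >= threshold) { out[j] = true; q.push(j); }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Connected-component labels (0 = background), BFS, first-encounter order.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  IntegerVector lab(N);
  std::vector<int> dz, dy, dx;
  neighbour_offsets(connectivity, dz, dy, dx);
  int next = 0;
  std::queue<xlen> q;
  for (xlen start = 0; start < N; start++) {
    if (!mask[start] || lab[start]) continue;
    next++;
    lab[start] = next;
    q.push(start);
    while (!q.empty()) {
      xlen i = q.front(); q.pop();
      int z = (int)(i % ns[0]);
      int y = (int)((i / ns[0]) % ns[1]);
      int x = (int)(i / ((xlen)ns[0] * ns[1]));
      for (size_t k = 0; k < dz.size(); k++) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= ns[0] || yy < 0 || yy >= ns[1] || xx < 0 || xx >= ns[2]) continue;
        xlen j = zz + (xlen)ns[0] * (yy + (xlen)ns[1] * xx);
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Binary dilation/erosion with a digital ball of the given voxel radius.
// Erosion treats out-of-grid voxels as foreground (boundary-neutral closing).
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim, int radius, bool dilate) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  std::vector<int> dz, dy, dx;
  int r2 = radius * radius;
  for (int a = -radius; a <= radius; a++) for (int b = -radius; b <= radius; b++)
    for (int c = -radius; c <= radius; c++)
      if (a * a + b * b + c * c <= r2) { dz.push_back(a); dy.push_back(b); dx.push_back(c); }
  LogicalVector out(N);
  for (int x = 0; x < ns[2]; x++) for (int y = 0; y < ns[1]; y++) for (int z = 0; z < ns[0]; z++) {
    xlen i = z + (xlen)ns[0] * (y + (xlen)ns[1] * x);
    bool val = dilate ? false : true;
    for (size_t k = 0; k < dz.size(); k++) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      bool inside = !(zz < 0 || zz >= ns[0] || yy < 0 || yy >= ns[1] || xx < 0 || xx >= ns[2]);
      bool m = inside ? (bool)mask[zz + (xlen)ns[0] * (yy + (xlen)ns[1] * xx)] : !dilate;
      if (dilate && m) { val = true; break; }
      if (!dilate && !m) { val = false; break; }
    }
    out[i] = val;
  }
  out.attr("dim") = dim;
  return out;
}

static inline double trilinear(const NumericVector& a, const int ns[3],
                               double pz, double py, double px) {
  if (pz < 0 || py < 0 || px < 0 || pz > ns[0] - 1 || py > ns[1] - 1 || px > ns[2] - 1) {
    // outside samples contribute zero signal
    if (pz < -0.5 || py < -0.5 || px < -0.5 ||
        pz > ns[0] - 0.5 || py > ns[1] - 0.5 || px > ns[2] - 0.5) return 0.0;
    pz = std::min(std::max(pz, 0.0), (double)ns[0] - 1);
    py = std::min(std::max(py, 0.0), (double)ns[1] - 1);
    px = std::min(std::max(px, 0.0), (double)ns[2] - 1);
  }
  int z0 = (int)std::floor(pz), y0 = (int)std::floor(py), x0 = (int)std::floor(px);
  int z1 = std::min(z0 + 1, ns[0] - 1), y1 = std::min(y0 + 1, ns[1] - 1), x1 = std::min(x0 + 1, ns[2] - 1);
  double fz = pz - z0, fy = py - y0, fx = px - x0;
  double v = 0.0;
  for (int iz = 0; iz <= 1; iz++) for (int iy = 0; iy <= 1; iy++) for (int ix = 0; ix <= 1; ix++) {
    double w = (iz ? fz : 1 - fz) * (iy ? fy : 1 - fy) * (ix ? fx : 1 - fx);
    if (w == 0) continue;
    int zz = iz ? z1 : z0, yy = iy ? y1 : y0, xx = ix ? x1 : x0;
    v += w * a[zz + (xlen)ns[0] * (yy + (xlen)ns[1] * xx)];
  }
  return v;
}

// Sample K sheared planes from a truth volume: slice k, row v, col u maps to
// truth voxel coordinates (z0 + k*dz, y0 + v + k*shear, x0 + u).
// [[Rcpp::export]]
NumericVector cpp_sample_sheared(NumericVector truth, IntegerVector dim,
                                 int K, int H, int W,
                                 double z0, double y0, double x0,
                                 double dz, double shear) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  NumericVector out((xlen)K * H * W);
  for (int u = 0; u < W; u++) for (int v = 0; v < H; v++) for (int k = 0; k < K; k++) {
    out[k + (xlen)K * (v + (xlen)H * u)] =
      trilinear(truth, ns, z0 + k * dz, y0 + v + k * shear, x0 + u);
  }
  out.attr("dim") = IntegerVector::create(K, H, W);
  return out;
}

// Inverse shear with nearest-neighbour interpolation; NA marks voxels with no data.
// [[Rcpp::export]]
NumericVector cpp_unshear(NumericVector raw, IntegerVector dim, double shear, int Hout) {
  int K = dim[0], H = dim[1], W = dim[2];
  NumericVector out((xlen)K * Hout * W, NA_REAL);
  for (int u = 0; u < W; u++) for (int j = 0; j < Hout; j++) for (int k = 0; k < K; k++) {
    long v = std::lround((double)j - k * shear);
    if (v >= 0 && v < H)
      out[k + (xlen)K * (j + (xlen)Hout * u)] = raw[k + (xlen)K * (v + (xlen)H * u)];
  }
  out.attr("dim") = IntegerVector::create(K, Hout, W);
  return out;
}

// Per-pixel histogram mode over a frame stack (H, W, F) within a square
// neighbourhood of half-width nb; values below exclude_below are ignored.
// [[Rcpp::export]]
NumericMatrix cpp_local_mode(NumericVector frames, IntegerVector dim, int nb,
                             int nbins, double lo, double hi, double exclude_below) {
  int H = dim[0], W = dim[1], F = dim[2];
  double bw = (hi - lo) / nbins;
  NumericMatrix out(H, W);
  std::vector<int> cnt(nbins);
  for (int c = 0; c < W; c++) for (int r = 0; r < H; r++) {
    std::fill(cnt.begin(), cnt.end(), 0);
    int tot = 0;
    for (int f = 0; f < F; f++) for (int dc = -nb; dc <= nb; dc++) {
      int cc = c + dc; if (cc < 0 || cc >= W) continue;
      for (int dr = -nb; dr <= nb; dr++) {
        int rr = r + dr; if (rr < 0 || rr >= H) continue;
        double x = frames[rr + (xlen)H * (cc + (xlen)W * f)];
        if (ISNAN(x) || x < exclude_below) continue;
        int b = (int)((x - lo) / bw);
        if (b < 0) b = 0; if (b >= nbins) b = nbins - 1;
        cnt[b]++; tot++;
      }
    }
    if (tot == 0) { out(r, c) = NA_REAL; continue; }
    int best = 0;
    for (int b = 1; b < nbins; b++) if (cnt[b] > cnt[best]) best = b;
    out(r, c) = lo + (best + 0.5) * bw;
  }
  return out;
}

// Best integer shift s of b relative to a (a[p] vs b[p - s]) by Pearson
// correlation over voxels valid (non-NA) in both. Returns (sz, sy, sx, corr).
// [[Rcpp::export]]
NumericVector cpp_best_shift(NumericVector a, NumericVector b, IntegerVector dim,
                             int ms, int min_n) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  double bestc = -2.0;
  int bs[3] = {0, 0, 0};
  for (int sz = -ms; sz <= ms; sz++) for (int sy = -ms; sy <= ms; sy++)
    for (int sx = -ms; sx <= ms; sx++) {
      double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      long n = 0;
      for (int x = std::max(0, sx); x < std::min(ns[2], ns[2] + sx); x++)
        for (int y = std::max(0, sy); y < std::min(ns[1], ns[1] + sy); y++)
          for (int z = std::max(0, sz); z < std::min(ns[0], ns[0] + sz); z++) {
            double va = a[z + (xlen)ns[0] * (y + (xlen)ns[1] * x)];
            double vb = b[(z - sz) + (xlen)ns[0] * ((y - sy) + (xlen)ns[1] * (x - sx))];
            if (ISNAN(va) || ISNAN(vb)) continue;
            sa += va; sb += vb; saa += va * va; sbb += vb * vb; sab += va * vb; n++;
          }
      if (n < min_n) continue;
      double cova = sab - sa * sb / n;
      double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
      double c;
      if (va <= 0 || vb <= 0) c = (va <= 0 && vb <= 0) ? 1.0 : 0.0;
      else c = cova / std::sqrt(va * vb);
      // deterministic tie-break: prefer smaller shifts
      double pen = 1e-9 * (std::abs(sz) + std::abs(sy) + std::abs(sx));
      if (c - pen > bestc) { bestc = c - pen; bs[0] = sz; bs[1] = sy; bs[2] = sx; }
    }
  return NumericVector::create(bs[0], bs[1], bs[2], bestc);
}

// Rasterize spheres (centres in um, rows (z,y,x)) onto a voxel grid whose
// voxel i centre sits at origin + i*spacing.
// [[Rcpp::export]]
LogicalVector cpp_paint_spheres(NumericMatrix centers, NumericVector radii,
                                IntegerVector dim, NumericVector spacing, NumericVector origin) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  LogicalVector out(N);
  for (int s = 0; s < centers.nrow(); s++) {
    double cz = centers(s, 0), cy = centers(s, 1), cx = centers(s, 2), r = radii[s];
    double r2 = r * r;
    int z0 = std::max(0, (int)std::ceil((cz - r - origin[0]) / spacing[0]));
    int z1 = std::min(ns[0] - 1, (int)std::floor((cz + r - origin[0]) / spacing[0]));
    int y0 = std::max(0, (int)std::ceil((cy - r - origin[1]) / spacing[1]));
    int y1 = std::min(ns[1] - 1, (int)std::floor((cy + r - origin[1]) / spacing[1]));
    int x0 = std::max(0, (int)std::ceil((cx - r - origin[2]) / spacing[2]));
    int x1 = std::min(ns[2] - 1, (int)std::floor((cx + r - origin[2]) / spacing[2]));
    for (int x = x0; x <= x1; x++) {
      double qx = origin[2] + x * spacing[2] - cx; qx *= qx;
      for (int y = y0; y <= y1; y++) {
        double qy = origin[1] + y * spacing[1] - cy; qy *= qy;
        if (qx + qy > r2) continue;
        for (int z = z0; z <= z1; z++) {
          double qz = origin[0] + z * spacing[0] - cz;
          if (qx + qy + qz * qz <= r2)
            out[z + (xlen)ns[0] * (y + (xlen)ns[1] * x)] = true;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Rasterize a tube around a polyline (nodes in um, per-node radii).
// [[Rcpp::export]]
LogicalVector cpp_paint_tube(NumericMatrix nodes, NumericVector radii,
                             IntegerVector dim, NumericVector spacing, NumericVector origin) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  LogicalVector out(N);
  int M = nodes.nrow();
  for (int s = 0; s < std::max(0, M - 1); s++) {
    double p[3] = {nodes(s, 0), nodes(s, 1), nodes(s, 2)};
    double q[3] = {nodes(s + 1, 0), nodes(s + 1, 1), nodes(s + 1, 2)};
    double r0 = radii[s], r1 = radii[s + 1];
    double rmax = std::max(r0, r1);
    double lo[3], hi[3];
    for (int a = 0; a < 3; a++) {
      lo[a] = std::min(p[a], q[a]) - rmax;
      hi[a] = std::max(p[a], q[a]) + rmax;
    }
    int z0 = std::max(0, (int)std::ceil((lo[0] - origin[0]) / spacing[0]));
    int z1 = std::min(ns[0] - 1, (int)std::floor((hi[0] - origin[0]) / spacing[0]));
    int y0 = std::max(0, (int)std::ceil((lo[1] - origin[1]) / spacing[1]));
    int y1 = std::min(ns[1] - 1, (int)std::floor((hi[1] - origin[1]) / spacing[1]));
    int x0 = std::max(0, (int)std::ceil((lo[2] - origin[2]) / spacing[2]));
    int x1 = std::min(ns[2] - 1, (int)std::floor((hi[2] - origin[2]) / spacing[2]));
    double d[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
    double dd = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    for (int x = x0; x <= x1; x++) for (int y = y0; y <= y1; y++) for (int z = z0; z <= z1; z++) {
      double v[3] = {origin[0] + z * spacing[0] - p[0],
                     origin[1] + y * spacing[1] - p[1],
                     origin[2] + x * spacing[2] - p[2]};
      double t = dd > 0 ? (v[0] * d[0] + v[1] * d[1] + v[2] * d[2]) / dd : 0.0;
      t = std::min(1.0, std::max(0.0, t));
      double rz = v[0] - t * d[0], ry = v[1] - t * d[1], rx = v[2] - t * d[2];
      double rr = r0 + t * (r1 - r0);
      if (rz * rz + ry * ry + rx * rx <= rr * rr)
        out[z + (xlen)ns[0] * (y + (xlen)ns[1] * x)] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Dijkstra geodesic distances within a mask (26-neighbour metric, physical
// step lengths). Returns distances (NA off-mask, Inf unreached) and 1-based
// predecessor indices (-1 for none).
// [[Rcpp::export]]
List cpp_geodesic(LogicalVector mask, IntegerVector dim, NumericVector spacing, int source) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(N, INF);
  std::vector<xlen> pred(N, -1);
  std::vector<int> dz, dy, dx;
  neighbour_offsets(26, dz, dy, dx);
  std::vector<double> step(dz.size());
  for (size_t k = 0; k < dz.size(); k++)
    step[k] = std::sqrt(dz[k] * dz[k] * spacing[0] * spacing[0] +
                        dy[k] * dy[k] * spacing[1] * spacing[1] +
                        dx[k] * dx[k] * spacing[2] * spacing[2]);
  typedef std::pair<double, xlen> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  if (mask[source]) { dist[source] = 0.0; pq.push(Node(0.0, source)); }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    xlen i = nd.second;
    if (nd.first > dist[i]) continue;
    int z = (int)(i % ns[0]);
    int y = (int)((i / ns[0]) % ns[1]);
    int x = (int)(i / ((xlen)ns[0] * ns[1]));
    for (size_t k = 0; k < dz.size(); k++) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= ns[0] || yy < 0 || yy >= ns[1] || xx < 0 || xx >= ns[2]) continue;
      xlen j = zz + (xlen)ns[0] * (yy + (xlen)ns[1] * xx);
      if (!mask[j]) continue;
      double nd2 = dist[i] + step[k];
      if (nd2 < dist[j]) { dist[j] = nd2; pred[j] = i; pq.push(Node(nd2, j)); }
    }
  }
  NumericVector dout(N);
  IntegerVector pout(N);
  for (xlen i = 0; i < N; i++) {
    dout[i] = mask[i] ? dist[i] : NA_REAL;
    pout[i] = pred[i] >= 0 ? (int)(pred[i] + 1) : -1;
  }
  dout.attr("dim") = dim;
  return List::create(_["dist"] = dout, _["pred"] = pout);
}

// For every voxel: arc-length value and distance of the nearest polyline node.
// [[Rcpp::export]]
List cpp_nearest_node(NumericMatrix nodes, NumericVector arclen, IntegerVector dim,
                      NumericVector spacing, NumericVector origin) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  int M = nodes.nrow();
  NumericVector arc(N), dmin(N);
  for (int x = 0; x < ns[2]; x++) {
    double px = origin[2] + x * spacing[2];
    for (int y = 0; y < ns[1]; y++) {
      double py = origin[1] + y * spacing[1];
      for (int z = 0; z < ns[0]; z++) {
        double pz = origin[0] + z * spacing[0];
        double best = std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int m = 0; m < M; m++) {
          double a = nodes(m, 0) - pz, b = nodes(m, 1) - py, c = nodes(m, 2) - px;
          double d2 = a * a + b * b + c * c;
          if (d2 < best) { best = d2; bi = m; }
        }
        xlen i = z + (xlen)ns[0] * (y + (xlen)ns[1] * x);
        arc[i] = arclen[bi];
        dmin[i] = std::sqrt(best);
      }
    }
  }
  arc.attr("dim") = dim;
  dmin.attr("dim") = dim;
  return List::create(_["arclength"] = arc, _["dist"] = dmin);
}

// Replace NA voxels by the value of the nearest (BFS, 6-connected) valid voxel.
// [[Rcpp::export]]
NumericVector cpp_fill_nearest(NumericVector vol, IntegerVector dim) {
  int ns[3] = {dim[0], dim[1], dim[2]};
  xlen N = (xlen)ns[0] * ns[1] * ns[2];
  NumericVector out = clone(vol);
  std::vector<int> dz, dy, dx;
  neighbour_offsets(6, dz, dy, dx);
  std::queue<xlen> q;
  for (xlen i = 0; i < N; i++) if (!ISNAN(out[i])) q.push(i);
  if (q.empty()) return out;
  while (!q.empty()) {
    xlen i = q.front(); q.pop();
    int z = (int)(i % ns[0]);
    int y = (int)((i / ns[0]) % ns[1]);
    int x = (int)(i / ((xlen)ns[0] * ns[1]));
    for (size_t k = 0; k < dz.size(); k++) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= ns[0] || yy < 0 || yy >= ns[1] || xx < 0 || xx >= ns[2]) continue;
      xlen j = zz + (xlen)ns[0] * (yy + (xlen)ns[1] * xx);
      if (ISNAN(out[j])) { out[j] = out[i]; q.push(j); }
    }
  }
  out.attr("dim") = dim;
  return out;
}
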