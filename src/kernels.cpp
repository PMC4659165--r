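// Low-level voxel kernels. All volumes are column-major R arrays indexed
// (x, y, z) with x fastest; coordinates passed from R are 0-based voxel
// indices; physical distances are voxel index * spacing (micrometres).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline long IDX(int x, int y, int z, int nx, int ny) {
  return (long)x + (long)nx * ((long)y + (long)ny * (long)z);
}
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Separable 1-D convolution along one axis with reflected borders.
// [[Rcpp::export]]
NumericVector cpp_conv1d(NumericVector vol, IntegerVector dim,
                         NumericVector kern, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kern.size(), half = klen / 2;
  const int n[3] = {nx, ny, nz};
  const int na = n[axis];
  NumericVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          int off = k - half;
          int xx = x, yy = y, zz = z;
          int *c = (axis == 0) ? &xx : (axis == 1) ? &yy : &zz;
          int v = *c + off;
          // reflect (half-sample symmetric enough: mirror at edges)
          if (v < 0) v = -v - 1;
          if (v >= na) v = 2 * na - v - 1;
          *c = clampi(v, 0, na - 1);
          acc += kern[k] * vol[IDX(xx, yy, zz, nx, ny)];
        }
        out[IDX(x, y, z, nx, ny)] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force 3-D median filter with box half-widths (rx, ry, rz), borders
// clamped.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dim,
                           int rx, int ry, int rz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1));
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        for (int dz = -rz; dz <= rz; ++dz)
          for (int dy = -ry; dy <= ry; ++dy)
            for (int dx = -rx; dx <= rx; ++dx)
              buf.push_back(vol[IDX(clampi(x + dx, 0, nx - 1),
                                    clampi(y + dy, 0, ny - 1),
                                    clampi(z + dz, 0, nz - 1), nx, ny)]);
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        out[IDX(x, y, z, nx, ny)] = med;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), squared
// distances, anisotropic spacing. Returns, per voxel, the squared distance
// in micrometres to the nearest TRUE voxel (Inf if none).
// "Unreachable" sources are encoded as a large finite sentinel so the
// parabola arithmetic needs no special-casing; anything >= DT_BIG/10 on
// output means "no source on this line".
static const double DT_BIG = 1e20;

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      // intersection abscissa in index units (zb[0] = -Inf guards k >= 0)
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector d(mask.size());
  for (long i = 0; i < (long)mask.size(); ++i) d[i] = mask[i] ? 0.0 : DT_BIG;
  std::vector<double> f, o;
  f.resize(nx); o.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[IDX(x, y, z, nx, ny)];
      dt1d(f, o, spacing[0]);
      for (int x = 0; x < nx; ++x) d[IDX(x, y, z, nx, ny)] = o[x];
    }
  f.resize(ny); o.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[IDX(x, y, z, nx, ny)];
      dt1d(f, o, spacing[1]);
      for (int y = 0; y < ny; ++y) d[IDX(x, y, z, nx, ny)] = o[y];
    }
  f.resize(nz); o.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[IDX(x, y, z, nx, ny)];
      dt1d(f, o, spacing[2]);
      for (int z = 0; z < nz; ++z) d[IDX(x, y, z, nx, ny)] = o[z];
    }
  for (long i = 0; i < (long)d.size(); ++i)
    if (d[i] >= DT_BIG / 10) d[i] = R_PosInf;
  return d; // squared distances in micrometres^2
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flood (6-connectivity): minima are
// imposed at the seed voxels and the guide is flooded in order of increasing
// value; ties broken by insertion order so the result is deterministic.
struct QItem {
  double v; long order; long idx; int lab;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.v != b.v) return a.v > b.v;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector g, IntegerVector dim,
                            IntegerMatrix seeds, IntegerVector seed_labels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(g.size());
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long counter = 0;
  for (int i = 0; i < seeds.nrow(); ++i) {
    long id = IDX(seeds(i, 0), seeds(i, 1), seeds(i, 2), nx, ny);
    lab[id] = seed_labels[i];
    pq.push({-std::numeric_limits<double>::infinity(), counter++, id, seed_labels[i]});
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    long id = it.idx;
    int z = (int)(id / ((long)nx * ny));
    long rem = id - (long)z * nx * ny;
    int y = (int)(rem / nx), x = (int)(rem % nx);
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      long nid = IDX(xx, yy, zz, nx, ny);
      if (lab[nid] == 0) {
        lab[nid] = it.lab;
        pq.push({g[nid], counter++, nid, it.lab});
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Multi-cell narrow-band level-set evolution with collision blocking.
//
// Each cell evolves its own embedding phi (negative inside) on a cropped
// sub-window. Update rule (inside-negative convention):
//   dphi/dt = -F |grad phi|_godunov + c1 * g * k * |grad phi|_central
//             + c2 * grad g . grad phi   (upwind)
// with F = g (speed image, low at boundaries) and k the mean curvature.
// When a voxel would be claimed by two different cells it is frozen for both
// and ownership stays with the first claimant, so masks never overlap.
struct Cell {
  int x0, y0, z0, mx, my, mz;          // sub-window origin and size
  std::vector<double> phi;
  std::vector<unsigned char> frozen;
};

static void reinit_cell(Cell &c, const double *sp, double band) {
  // signed distance rebuild from the current mask (chamfer-free: 1-D passes)
  const int n = c.mx * c.my * c.mz;
  std::vector<double> din(n), dout(n);
  // dout: distance to mask (phi<0); din: distance to complement
  std::vector<double> f, o;
  auto pass = [&](std::vector<double> &d, bool target_neg) {
    for (int i = 0; i < n; ++i)
      d[i] = (target_neg ? (c.phi[i] < 0) : (c.phi[i] >= 0)) ? 0.0 : DT_BIG;
    int dims[3] = {c.mx, c.my, c.mz};
    for (int axis = 0; axis < 3; ++axis) {
      int na = dims[axis];
      f.resize(na); o.resize(na);
      int nb = (axis == 0) ? c.my : c.mx;
      int nc2 = (axis == 2) ? c.my : c.mz;
      for (int b = 0; b < nb; ++b)
        for (int cc = 0; cc < nc2; ++cc) {
          bool any = false;
          for (int a = 0; a < na; ++a) {
            int x = (axis == 0) ? a : b;
            int y = (axis == 0) ? b : ((axis == 1) ? a : cc);
            int z = (axis == 2) ? a : cc;
            long id = IDX(x, y, z, c.mx, c.my);
            f[a] = d[id];
            if (std::isfinite(f[a])) any = true;
          }
          if (!any) continue;
          dt1d(f, o, sp[axis]);
          for (int a = 0; a < na; ++a) {
            int x = (axis == 0) ? a : b;
            int y = (axis == 0) ? b : ((axis == 1) ? a : cc);
            int z = (axis == 2) ? a : cc;
            d[IDX(x, y, z, c.mx, c.my)] = o[a];
          }
        }
    }
  };
  pass(dout, true);
  pass(din, false);
  for (int i = 0; i < n; ++i) {
    double sd = std::sqrt(dout[i]) - std::sqrt(din[i]);
    if (sd > band) sd = band;
    if (sd < -band) sd = -band;
    c.phi[i] = sd;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_active_contours(NumericVector g, IntegerVector dim,
                                  NumericVector spacing, IntegerMatrix seeds,
                                  double c1, double c2_step1, double c2_step2,
                                  double dt, int n_steps1, int n_steps2,
                                  double band, int reinit_every,
                                  double init_radius, int margin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ncell = seeds.nrow();
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  IntegerVector owner(g.size()); // 0 = background, i+1 = cell i
  // `band` is a tight active band around the zero level set: only voxels
  // with |phi| < band are updated, which keeps far voxels from drifting
  // across g = 0 barriers between reinitialisations. Values are clamped at
  // the wider band_clamp, which reinitialisation refreshes.
  const double band_clamp = 2.5 * band;

  // precompute grad g on the full lattice (central, spacing-aware)
  std::vector<double> gx(g.size()), gy(g.size()), gz(g.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long id = IDX(x, y, z, nx, ny);
        gx[id] = (g[IDX(clampi(x + 1, 0, nx - 1), y, z, nx, ny)] -
                  g[IDX(clampi(x - 1, 0, nx - 1), y, z, nx, ny)]) / (2 * sp[0]);
        gy[id] = (g[IDX(x, clampi(y + 1, 0, ny - 1), z, nx, ny)] -
                  g[IDX(x, clampi(y - 1, 0, ny - 1), z, nx, ny)]) / (2 * sp[1]);
        gz[id] = (g[IDX(x, y, clampi(z + 1, 0, nz - 1), nx, ny)] -
                  g[IDX(x, y, clampi(z - 1, 0, nz - 1), nx, ny)]) / (2 * sp[2]);
      }

  std::vector<Cell> cells(ncell);
  for (int i = 0; i < ncell; ++i) {
    Cell &c = cells[i];
    int sx = seeds(i, 0), sy = seeds(i, 1), sz = seeds(i, 2);
    c.x0 = clampi(sx - margin, 0, nx - 1);
    c.y0 = clampi(sy - margin, 0, ny - 1);
    c.z0 = clampi(sz - margin, 0, nz - 1);
    c.mx = clampi(sx + margin, 0, nx - 1) - c.x0 + 1;
    c.my = clampi(sy + margin, 0, ny - 1) - c.y0 + 1;
    c.mz = clampi(sz + margin, 0, nz - 1) - c.z0 + 1;
    c.phi.resize((size_t)c.mx * c.my * c.mz);
    c.frozen.assign(c.phi.size(), 0);
    for (int z = 0; z < c.mz; ++z)
      for (int y = 0; y < c.my; ++y)
        for (int x = 0; x < c.mx; ++x) {
          double ddx = (x + c.x0 - sx) * sp[0];
          double ddy = (y + c.y0 - sy) * sp[1];
          double ddz = (z + c.z0 - sz) * sp[2];
          double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz) - init_radius;
          if (d > band_clamp) d = band_clamp;
          if (d < -band_clamp) d = -band_clamp;
          c.phi[IDX(x, y, z, c.mx, c.my)] = d;
          if (d < 0) {
            long gid = IDX(x + c.x0, y + c.y0, z + c.z0, nx, ny);
            if (owner[gid] == 0) owner[gid] = i + 1;
          }
        }
  }

  std::vector<double> nphi;
  const int total = n_steps1 + n_steps2;
  for (int step = 0; step < total; ++step) {
    double c2 = (step < n_steps1) ? c2_step1 : c2_step2;
    for (int i = 0; i < ncell; ++i) {
      Cell &c = cells[i];
      nphi.assign(c.phi.begin(), c.phi.end());
      for (int z = 1; z < c.mz - 1; ++z)
        for (int y = 1; y < c.my - 1; ++y)
          for (int x = 1; x < c.mx - 1; ++x) {
            long li = IDX(x, y, z, c.mx, c.my);
            if (c.frozen[li]) continue;
            double p = c.phi[li];
            if (std::fabs(p) >= band) continue;
            long gid = IDX(x + c.x0, y + c.y0, z + c.z0, nx, ny);
            double gv = g[gid];
            // one-sided differences
            double pxm = (p - c.phi[IDX(x - 1, y, z, c.mx, c.my)]) / sp[0];
            double pxp = (c.phi[IDX(x + 1, y, z, c.mx, c.my)] - p) / sp[0];
            double pym = (p - c.phi[IDX(x, y - 1, z, c.mx, c.my)]) / sp[1];
            double pyp = (c.phi[IDX(x, y + 1, z, c.mx, c.my)] - p) / sp[1];
            double pzm = (p - c.phi[IDX(x, y, z - 1, c.mx, c.my)]) / sp[2];
            double pzp = (c.phi[IDX(x, y, z + 1, c.mx, c.my)] - p) / sp[2];
            double cx = 0.5 * (pxm + pxp), cy = 0.5 * (pym + pyp),
                   cz = 0.5 * (pzm + pzp);
            double gc = std::sqrt(cx * cx + cy * cy + cz * cz);
            // mean curvature (central differences)
            double curv = 0.0;
            if (gc > 1e-8) {
              double pxx = (pxp - pxm) / sp[0];
              double pyy = (pyp - pym) / sp[1];
              double pzz = (pzp - pzm) / sp[2];
              auto P = [&](int ax, int ay, int az) {
                return c.phi[IDX(x + ax, y + ay, z + az, c.mx, c.my)];
              };
              double pxy = (P(1, 1, 0) - P(1, -1, 0) - P(-1, 1, 0) + P(-1, -1, 0)) /
                           (4 * sp[0] * sp[1]);
              double pxz = (P(1, 0, 1) - P(1, 0, -1) - P(-1, 0, 1) + P(-1, 0, -1)) /
                           (4 * sp[0] * sp[2]);
              double pyz = (P(0, 1, 1) - P(0, 1, -1) - P(0, -1, 1) + P(0, -1, -1)) /
                           (4 * sp[1] * sp[2]);
              double g2 = gc * gc;
              curv = ((pyy + pzz) * cx * cx + (pxx + pzz) * cy * cy +
                      (pxx + pyy) * cz * cz -
                      2 * (cx * cy * pxy + cx * cz * pxz + cy * cz * pyz)) /
                     (g2 * gc);
            }
            // Godunov gradient magnitude for outward motion (F = g > 0)
            auto sq = [](double v) { return v * v; };
            double gradP = std::sqrt(
                sq(std::max(pxm, 0.0)) + sq(std::min(pxp, 0.0)) +
                sq(std::max(pym, 0.0)) + sq(std::min(pyp, 0.0)) +
                sq(std::max(pzm, 0.0)) + sq(std::min(pzp, 0.0)));
            double dphi = -gv * gradP + c1 * gv * curv * gc;
            // advection c2 * grad g . grad phi, upwind per component, each
            // velocity clamped to the CFL-stable magnitude for dt
            auto cfl = [&](double a, double h) {
              double lim = 0.45 * h / dt;
              return a > lim ? lim : (a < -lim ? -lim : a);
            };
            double ax = cfl(c2 * gx[gid], sp[0]);
            double ay = cfl(c2 * gy[gid], sp[1]);
            double az = cfl(c2 * gz[gid], sp[2]);
            dphi += ax * (ax > 0 ? pxp : pxm);
            dphi += ay * (ay > 0 ? pyp : pym);
            dphi += az * (az > 0 ? pzp : pzm);
            double np = p + dt * dphi;
            if (np > band_clamp) np = band_clamp;
            if (np < -band_clamp) np = -band_clamp;
            nphi[li] = np;
          }
      // commit with collision blocking
      for (int z = 1; z < c.mz - 1; ++z)
        for (int y = 1; y < c.my - 1; ++y)
          for (int x = 1; x < c.mx - 1; ++x) {
            long li = IDX(x, y, z, c.mx, c.my);
            if (c.frozen[li]) continue;
            double oldp = c.phi[li], newp = nphi[li];
            if (oldp >= 0 && newp < 0) {
              long gid = IDX(x + c.x0, y + c.y0, z + c.z0, nx, ny);
              int ow = owner[gid];
              if (ow == 0) {
                owner[gid] = i + 1;
                c.phi[li] = newp;
              } else if (ow == i + 1) {
                c.phi[li] = newp;
              } else {
                // collision: freeze for both cells, first claimant keeps it
                c.frozen[li] = 1;
                c.phi[li] = 1e-3;
                Cell &oc = cells[ow - 1];
                int oxx = x + c.x0 - oc.x0, oyy = y + c.y0 - oc.y0,
                    ozz = z + c.z0 - oc.z0;
                if (oxx >= 0 && oxx < oc.mx && oyy >= 0 && oyy < oc.my &&
                    ozz >= 0 && ozz < oc.mz)
                  oc.frozen[IDX(oxx, oyy, ozz, oc.mx, oc.my)] = 1;
              }
            } else {
              if (oldp < 0 && newp >= 0) {
                long gid = IDX(x + c.x0, y + c.y0, z + c.z0, nx, ny);
                if (owner[gid] == i + 1) owner[gid] = 0;
              }
              c.phi[li] = newp;
            }
          }
    }
    if (reinit_every > 0 && (step + 1) % reinit_every == 0)
      for (int i = 0; i < ncell; ++i) reinit_cell(cells[i], sp, band_clamp);
  }
  return owner;
}

// ---------------------------------------------------------------------------
// HOG window features. A detection window is two 2-D patches (xy and xz
// planes through the centre), each win x win pixels sampled at offsets scaled
// by `scale` (zero-padded outside the stack). Features: [mean xy brightness,
// xy HOG block, xz HOG block]; each block is a grid x grid layout of
// non-overlapping sub-windows, each contributing nbins orientation-histogram
// entries (L2-normalised) plus the normalisation factor.
static void extract_patch(const double *vol, int nx, int ny, int nz,
                          int cx, int cy, int cz, int win, double scale,
                          bool xzplane, bool flip_u, bool flip_v,
                          std::vector<double> &patch) {
  const double h = win / 2; // integer centre: offsets u - win/2
  patch.assign((size_t)win * win, 0.0);
  for (int v = 0; v < win; ++v)
    for (int u = 0; u < win; ++u) {
      double du = scale * ((flip_u ? (win - 1 - u) : u) - h);
      double dv = scale * ((flip_v ? (win - 1 - v) : v) - h);
      int x = cx + (int)std::lround(du);
      int y, z;
      if (xzplane) { y = cy; z = cz + (int)std::lround(dv); }
      else { y = cy + (int)std::lround(dv); z = cz; }
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      patch[(size_t)u + (size_t)win * v] = vol[IDX(x, y, z, nx, ny)];
    }
}

static void hog_block(const std::vector<double> &patch, int win, int grid,
                      int nbins, double *out) {
  const int cellpx = win / grid;
  std::vector<double> hist((size_t)grid * grid * nbins, 0.0);
  for (int v = 0; v < win; ++v)
    for (int u = 0; u < win; ++u) {
      int um = clampi(u - 1, 0, win - 1), up = clampi(u + 1, 0, win - 1);
      int vm = clampi(v - 1, 0, win - 1), vp = clampi(v + 1, 0, win - 1);
      double du = 0.5 * (patch[(size_t)up + (size_t)win * v] -
                         patch[(size_t)um + (size_t)win * v]);
      double dv = 0.5 * (patch[(size_t)u + (size_t)win * vp] -
                         patch[(size_t)u + (size_t)win * vm]);
      double mag = std::sqrt(du * du + dv * dv);
      if (mag <= 0) continue;
      double th = std::atan2(dv, du); // unsigned orientation in [0, pi)
      if (th < 0) th += M_PI;
      if (th >= M_PI) th -= M_PI;
      int bin = (int)(th / M_PI * nbins);
      if (bin >= nbins) bin = nbins - 1;
      int gu = std::min(u / cellpx, grid - 1), gv = std::min(v / cellpx, grid - 1);
      hist[(size_t)bin + (size_t)nbins * (gu + grid * gv)] += mag;
    }
  int o = 0;
  for (int cell = 0; cell < grid * grid; ++cell) {
    double ss = 0.0;
    for (int b = 0; b < nbins; ++b) ss += hist[(size_t)b + (size_t)nbins * cell] *
                                          hist[(size_t)b + (size_t)nbins * cell];
    double nrm = std::sqrt(ss);
    double denom = nrm > 0 ? nrm : 1.0;
    for (int b = 0; b < nbins; ++b)
      out[o++] = hist[(size_t)b + (size_t)nbins * cell] / denom;
    out[o++] = nrm;
  }
}

// [[Rcpp::export]]
NumericVector cpp_window_features(NumericVector vol, IntegerVector dim,
                                  IntegerVector center, int win, int grid,
                                  int nbins, double scale,
                                  bool flip_u = false, bool flip_v = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int blk = grid * grid * (nbins + 1);
  NumericVector out(1 + 2 * blk);
  std::vector<double> patch;
  extract_patch(REAL(vol), nx, ny, nz, center[0], center[1], center[2], win,
                scale, false, flip_u, flip_v, patch);
  double s = 0.0;
  for (double v : patch) s += v;
  out[0] = s / patch.size();
  hog_block(patch, win, grid, nbins, REAL(out) + 1);
  extract_patch(REAL(vol), nx, ny, nz, center[0], center[1], center[2], win,
                scale, true, flip_u, flip_v, patch);
  hog_block(patch, win, grid, nbins, REAL(out) + 1 + blk);
  return out;
}

// Dense scan: dot product of the window feature vector with w at every
// stride-th voxel; unscanned voxels get -Inf.
// [[Rcpp::export]]
NumericVector cpp_scan_scores(NumericVector vol, IntegerVector dim,
                              NumericVector w, int win, int grid, int nbins,
                              double scale, IntegerVector stride) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int blk = grid * grid * (nbins + 1);
  const int flen = 1 + 2 * blk;
  if ((int)w.size() != flen) stop("weight vector length mismatch");
  NumericVector out(vol.size(), R_NegInf);
  std::vector<double> patch, feat(flen);
  for (int z = 0; z < nz; z += stride[2])
    for (int y = 0; y < ny; y += stride[1])
      for (int x = 0; x < nx; x += stride[0]) {
        extract_patch(REAL(vol), nx, ny, nz, x, y, z, win, scale, false,
                      false, false, patch);
        double s = 0.0;
        for (double v : patch) s += v;
        feat[0] = s / patch.size();
        hog_block(patch, win, grid, nbins, feat.data() + 1);
        extract_patch(REAL(vol), nx, ny, nz, x, y, z, win, scale, true,
                      false, false, patch);
        hog_block(patch, win, grid, nbins, feat.data() + 1 + blk);
        double acc = 0.0;
        for (int i = 0; i < flen; ++i) acc += w[i] * feat[i];
        out[IDX(x, y, z, nx, ny)] = acc;
      }
  return out;
}
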