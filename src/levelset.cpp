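// Finite-difference stencils and grid transforms for 3D level-set evolution.
// All grids are column-major (R array layout), unit voxel spacing, with
// one-sided differences at grid faces (no wraparound).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// value with replicated (clamped) boundary
inline double at(const NumericVector &a, int i, int j, int k,
                 int nx, int ny, int nz) {
  return a[idx3(clampi(i, 0, nx - 1), clampi(j, 0, ny - 1),
               clampi(k, 0, nz - 1), nx, ny)];
}

} // namespace

// Godunov upwind |grad phi| per voxel, chosen by the sign of the speed.
// Solves phi_t + F |grad phi| = 0: for F > 0 the forward-characteristic norm
// (max(D-,0), min(D+,0)), for F < 0 the reverse one.
// [[Rcpp::export]]
NumericVector cpp_godunov_norm(NumericVector phi, NumericVector speed,
                               IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(phi.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int id = idx3(i, j, k, nx, ny);
        const double c = phi[id];
        const double dmx = c - at(phi, i - 1, j, k, nx, ny, nz);
        const double dpx = at(phi, i + 1, j, k, nx, ny, nz) - c;
        const double dmy = c - at(phi, i, j - 1, k, nx, ny, nz);
        const double dpy = at(phi, i, j + 1, k, nx, ny, nz) - c;
        const double dmz = c - at(phi, i, j, k - 1, nx, ny, nz);
        const double dpz = at(phi, i, j, k + 1, nx, ny, nz) - c;
        double s;
        if (speed[id] > 0) {
          const double ax = std::max(dmx, 0.0), bx = std::min(dpx, 0.0);
          const double ay = std::max(dmy, 0.0), by = std::min(dpy, 0.0);
          const double az = std::max(dmz, 0.0), bz = std::min(dpz, 0.0);
          s = ax * ax + bx * bx + ay * ay + by * by + az * az + bz * bz;
        } else {
          const double ax = std::min(dmx, 0.0), bx = std::max(dpx, 0.0);
          const double ay = std::min(dmy, 0.0), by = std::max(dpy, 0.0);
          const double az = std::min(dmz, 0.0), bz = std::max(dpz, 0.0);
          s = ax * ax + bx * bx + ay * ay + by * by + az * az + bz * bz;
        }
        out[id] = std::sqrt(s);
      }
  return out;
}

// g * kappa + grad(g) . (grad phi / |grad phi|), i.e. div(g grad phi/|grad phi|)
// expanded, with kappa = div(grad phi/|grad phi|) from the second-derivative
// formula (central differences), eps-regularized and clamped to +/- kclamp
// (the 1/h bound of the grid). g = NULL means g == 1 (plain curvature).
// [[Rcpp::export]]
NumericVector cpp_div_g_norm_grad(NumericVector phi,
                                  Nullable<NumericVector> g_,
                                  IntegerVector dims, double eps,
                                  double kclamp) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const bool hasg = g_.isNotNull();
  NumericVector g;
  if (hasg) g = g_.get();
  NumericVector out(phi.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int id = idx3(i, j, k, nx, ny);
        const double c = phi[id];
        const double pxp = at(phi, i + 1, j, k, nx, ny, nz);
        const double pxm = at(phi, i - 1, j, k, nx, ny, nz);
        const double pyp = at(phi, i, j + 1, k, nx, ny, nz);
        const double pym = at(phi, i, j - 1, k, nx, ny, nz);
        const double pzp = at(phi, i, j, k + 1, nx, ny, nz);
        const double pzm = at(phi, i, j, k - 1, nx, ny, nz);
        const double px = 0.5 * (pxp - pxm);
        const double py = 0.5 * (pyp - pym);
        const double pz = 0.5 * (pzp - pzm);
        const double pxx = pxp - 2.0 * c + pxm;
        const double pyy = pyp - 2.0 * c + pym;
        const double pzz = pzp - 2.0 * c + pzm;
        const double pxy = 0.25 * (at(phi, i + 1, j + 1, k, nx, ny, nz) -
                                   at(phi, i + 1, j - 1, k, nx, ny, nz) -
                                   at(phi, i - 1, j + 1, k, nx, ny, nz) +
                                   at(phi, i - 1, j - 1, k, nx, ny, nz));
        const double pxz = 0.25 * (at(phi, i + 1, j, k + 1, nx, ny, nz) -
                                   at(phi, i + 1, j, k - 1, nx, ny, nz) -
                                   at(phi, i - 1, j, k + 1, nx, ny, nz) +
                                   at(phi, i - 1, j, k - 1, nx, ny, nz));
        const double pyz = 0.25 * (at(phi, i, j + 1, k + 1, nx, ny, nz) -
                                   at(phi, i, j + 1, k - 1, nx, ny, nz) -
                                   at(phi, i, j - 1, k + 1, nx, ny, nz) +
                                   at(phi, i, j - 1, k - 1, nx, ny, nz));
        const double g2 = px * px + py * py + pz * pz;
        const double gm = std::sqrt(g2);
        double kap = 0.0;
        if (gm > eps) {
          kap = (pxx * (py * py + pz * pz) + pyy * (px * px + pz * pz) +
                 pzz * (px * px + py * py) -
                 2.0 * (px * py * pxy + px * pz * pxz + py * pz * pyz)) /
                (g2 * gm + eps);
        }
        if (kap > kclamp) kap = kclamp;
        if (kap < -kclamp) kap = -kclamp;
        if (!hasg) {
          out[id] = kap;
        } else {
          const double gx = 0.5 * (at(g, i + 1, j, k, nx, ny, nz) -
                                   at(g, i - 1, j, k, nx, ny, nz));
          const double gy = 0.5 * (at(g, i, j + 1, k, nx, ny, nz) -
                                   at(g, i, j - 1, k, nx, ny, nz));
          const double gz = 0.5 * (at(g, i, j, k + 1, nx, ny, nz) -
                                   at(g, i, j, k - 1, nx, ny, nz));
          double dot = 0.0;
          if (gm > eps) dot = (gx * px + gy * py + gz * pz) / gm;
          out[id] = g[id] * kap + dot;
        }
      }
  return out;
}

// Central-difference gradient magnitude (first-order one-sided at faces).
// [[Rcpp::export]]
NumericVector cpp_gradmag(NumericVector a, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(a.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double hx = (i == 0 || i == nx - 1) ? 1.0 : 2.0;
        const double hy = (j == 0 || j == ny - 1) ? 1.0 : 2.0;
        const double hz = (k == 0 || k == nz - 1) ? 1.0 : 2.0;
        const double gx = (at(a, i + 1, j, k, nx, ny, nz) -
                           at(a, i - 1, j, k, nx, ny, nz)) / hx;
        const double gy = (at(a, i, j + 1, k, nx, ny, nz) -
                           at(a, i, j - 1, k, nx, ny, nz)) / hy;
        const double gz = (at(a, i, j, k + 1, nx, ny, nz) -
                           at(a, i, j, k - 1, nx, ny, nz)) / hz;
        out[idx3(i, j, k, nx, ny)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}

namespace {

// Felzenszwalb-Huttenlocher 1D squared distance transform.
void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
          std::vector<int> &v, std::vector<double> &z) {
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) {
        --kk;
      } else {
        break;
      }
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = (q - v[kk]) * (q - v[kk]) + f[v[kk]];
  }
}

} // namespace

// Exact Euclidean distance (voxel units) from every voxel to the nearest
// foreground voxel centre. Requires at least one foreground voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e20;
  NumericVector d(fg.size());
  for (int t = 0; t < fg.size(); ++t) d[t] = fg[t] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, dd, nx, v, z);
      for (int i = 0; i < nx; ++i) d[idx3(i, j, k, nx, ny)] = dd[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, dd, ny, v, z);
      for (int j = 0; j < ny; ++j) d[idx3(i, j, k, nx, ny)] = dd[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, dd, nz, v, z);
      for (int k = 0; k < nz; ++k) d[idx3(i, j, k, nx, ny)] = dd[k];
    }
  for (int t = 0; t < d.size(); ++t) d[t] = std::sqrt(d[t]);
  return d;
}

// Reinitialization toward a signed distance function by the Sussman PDE
// phi_t = sign(phi0) (1 - |grad phi|) with the Russo-Smereka subcell fix at
// interface cells, which pins the zero level set to its interpolated position
// in phi0 (no voxel flips, sub-voxel accurate).
// [[Rcpp::export]]
NumericVector cpp_reinit(NumericVector phi0, IntegerVector dims, int iters,
                         double dt) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = phi0.size();
  NumericVector phi = clone(phi0);
  std::vector<char> iface(n, 0);
  std::vector<double> D(n, 0.0);
  // interface cells: sign change with a 6-neighbour in phi0
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int id = idx3(i, j, k, nx, ny);
        const double c = phi0[id];
        bool cut = false;
        const int di[6] = {1, -1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, 1, -1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, 1, -1};
        for (int q = 0; q < 6; ++q) {
          const int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          if (c * phi0[idx3(ii, jj, kk, nx, ny)] < 0.0) { cut = true; break; }
        }
        if (cut) {
          iface[id] = 1;
          const double px = 0.5 * (at(phi0, i + 1, j, k, nx, ny, nz) -
                                   at(phi0, i - 1, j, k, nx, ny, nz));
          const double py = 0.5 * (at(phi0, i, j + 1, k, nx, ny, nz) -
                                   at(phi0, i, j - 1, k, nx, ny, nz));
          const double pz = 0.5 * (at(phi0, i, j, k + 1, nx, ny, nz) -
                                   at(phi0, i, j, k - 1, nx, ny, nz));
          double gm = std::sqrt(px * px + py * py + pz * pz);
          if (gm < 1e-8) gm = 1e-8;
          D[id] = c / gm; // signed interpolated distance to the interface
        }
      }
  for (int it = 0; it < iters; ++it) {
    NumericVector nxt = clone(phi);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int id = idx3(i, j, k, nx, ny);
          const double s0 = phi0[id] > 0 ? 1.0 : (phi0[id] < 0 ? -1.0 : 0.0);
          if (iface[id]) {
            // relax toward the pinned subcell distance
            nxt[id] = phi[id] - dt * (s0 * std::fabs(phi[id]) - D[id]);
            continue;
          }
          const double c = phi[id];
          const double a = c - at(phi, i - 1, j, k, nx, ny, nz);
          const double b = at(phi, i + 1, j, k, nx, ny, nz) - c;
          const double cc = c - at(phi, i, j - 1, k, nx, ny, nz);
          const double dd2 = at(phi, i, j + 1, k, nx, ny, nz) - c;
          const double e = c - at(phi, i, j, k - 1, nx, ny, nz);
          const double ff = at(phi, i, j, k + 1, nx, ny, nz) - c;
          double G;
          if (s0 > 0) {
            const double ap = std::max(a, 0.0), bm = std::min(b, 0.0);
            const double cp = std::max(cc, 0.0), dm = std::min(dd2, 0.0);
            const double ep = std::max(e, 0.0), fm = std::min(ff, 0.0);
            G = std::sqrt(std::max(ap * ap, bm * bm) +
                          std::max(cp * cp, dm * dm) +
                          std::max(ep * ep, fm * fm));
          } else if (s0 < 0) {
            const double am = std::min(a, 0.0), bp = std::max(b, 0.0);
            const double cm = std::min(cc, 0.0), dp = std::max(dd2, 0.0);
            const double em = std::min(e, 0.0), fp = std::max(ff, 0.0);
            G = std::sqrt(std::max(am * am, bp * bp) +
                          std::max(cm * cm, dp * dp) +
                          std::max(em * em, fp * fp));
          } else {
            G = 1.0;
          }
          nxt[id] = c - dt * s0 * (G - 1.0);
        }
    phi = nxt;
  }
  return phi;
}

// Connected component of the in-range set containing the seed (6- or
// 26-connectivity), iterative BFS.
// [[Rcpp::export]]
LogicalVector cpp_flood(LogicalVector inrange, IntegerVector dims,
                        IntegerVector seed0, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(inrange.size());
  const int sid = idx3(seed0[0], seed0[1], seed0[2], nx, ny);
  if (!inrange[sid]) return out;
  std::vector<int> stack;
  stack.push_back(sid);
  out[sid] = true;
  while (!stack.empty()) {
    const int id = stack.back();
    stack.pop_back();
    const int k = id / (nx * ny);
    const int j = (id - k * nx * ny) / nx;
    const int i = id - k * nx * ny - j * nx;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          if (connectivity == 6 &&
              std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
            continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const int nid = idx3(ii, jj, kk, nx, ny);
          if (inrange[nid] && !out[nid]) {
            out[nid] = true;
            stack.push_back(nid);
          }
        }
  }
  return out;
}
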