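#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Grid convention: intensities stored as an R array dim = c(nx, ny, nz),
// x fastest (column-major), voxel centre of [1,1,1] at `origin` (nm).

static inline int vox_index(double p, double origin, double voxel) {
  return (int) std::lround((p - origin) / voxel);
}

// Render a set of weighted points as a sum of isotropic Gaussian kernels on
// the grid: each voxel within `truncate` sigmas receives
// weight * exp(-d^2 / (2 sigma^2)) of the CONTINUOUS distance d between the
// voxel centre and the point, normalised (separably) so each unit weight
// deposits total mass 1. Continuous sampling keeps the rendered map, and
// hence the CCC, smooth in the point coordinates.
// [[Rcpp::export]]
NumericVector cpp_splat_gaussian(NumericMatrix coords, NumericVector weights,
                                 IntegerVector dim, NumericVector origin,
                                 double voxel, double sigma,
                                 double truncate = 4.0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector grid((R_xlen_t) nx * ny * nz);
  const int rad = (int) std::ceil(truncate * sigma / voxel);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> kx(2 * rad + 1), ky(2 * rad + 1), kz(2 * rad + 1);

  for (int n = 0; n < coords.nrow(); ++n) {
    const int cx = vox_index(coords(n, 0), origin[0], voxel);
    const int cy = vox_index(coords(n, 1), origin[1], voxel);
    const int cz = vox_index(coords(n, 2), origin[2], voxel);
    double sx = 0, sy = 0, sz = 0;
    for (int o = -rad; o <= rad; ++o) {
      const double dx = origin[0] + (cx + o) * voxel - coords(n, 0);
      const double dy = origin[1] + (cy + o) * voxel - coords(n, 1);
      const double dz = origin[2] + (cz + o) * voxel - coords(n, 2);
      kx[o + rad] = std::exp(-dx * dx * inv2s2); sx += kx[o + rad];
      ky[o + rad] = std::exp(-dy * dy * inv2s2); sy += ky[o + rad];
      kz[o + rad] = std::exp(-dz * dz * inv2s2); sz += kz[o + rad];
    }
    const double w = weights[n] / (sx * sy * sz);
    for (int oz = -rad; oz <= rad; ++oz) {
      const int iz = cz + oz; if (iz < 0 || iz >= nz) continue;
      for (int oy = -rad; oy <= rad; ++oy) {
        const int iy = cy + oy; if (iy < 0 || iy >= ny) continue;
        const double kyz = w * ky[oy + rad] * kz[oz + rad];
        const R_xlen_t base = (R_xlen_t) iz * nx * ny + (R_xlen_t) iy * nx;
        for (int ox = -rad; ox <= rad; ++ox) {
          const int ix = cx + ox; if (ix < 0 || ix >= nx) continue;
          grid[base + ix] += kx[ox + rad] * kyz;
        }
      }
    }
  }
  return grid;
}

// Pearson correlation between two equal-length intensity vectors.
// [[Rcpp::export]]
double cpp_pearson(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  double ma = 0, mb = 0;
  for (R_xlen_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// CCC between render(coords) and a fixed target map, evaluated in one pass
// (render + correlate); used in the rigid-fit hot loop.
// [[Rcpp::export]]
double cpp_render_ccc(NumericMatrix coords, NumericVector target,
                      IntegerVector dim, NumericVector origin, double voxel,
                      double sigma, double truncate = 4.0) {
  NumericVector w(coords.nrow(), 1.0);
  NumericVector probe = cpp_splat_gaussian(coords, w, dim, origin, voxel,
                                           sigma, truncate);
  return cpp_pearson(probe, target);
}

// Analytic gradient of ccc(render(coords), target) with respect to bead
// coordinates. d ccc / d P_i = (T~_i - (u/vP) P~_i) / sqrt(vP vT) with
// u = sum P~ T~, and d P_i / d x_n = K(d) (x_i - x_n) / sigma^2.
// [[Rcpp::export]]
List cpp_ccc_grad(NumericMatrix coords, NumericVector target,
                  IntegerVector dim, NumericVector origin, double voxel,
                  double sigma, double truncate = 4.0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t m = (R_xlen_t) nx * ny * nz;
  NumericVector w(coords.nrow(), 1.0);
  NumericVector probe = cpp_splat_gaussian(coords, w, dim, origin, voxel,
                                           sigma, truncate);
  double mp = 0, mt = 0;
  for (R_xlen_t i = 0; i < m; ++i) { mp += probe[i]; mt += target[i]; }
  mp /= m; mt /= m;
  double u = 0, vP = 0, vT = 0;
  for (R_xlen_t i = 0; i < m; ++i) {
    const double dp = probe[i] - mp, dt = target[i] - mt;
    u += dp * dt; vP += dp * dp; vT += dt * dt;
  }
  NumericMatrix grad(coords.nrow(), 3);
  if (vP <= 0 || vT <= 0)
    return List::create(_["ccc"] = NA_REAL, _["grad"] = grad);
  const double denom = std::sqrt(vP * vT);
  const double ccc = u / denom;

  // weight field w_i = d ccc / d P_i
  std::vector<double> wf(m);
  for (R_xlen_t i = 0; i < m; ++i)
    wf[i] = ((target[i] - mt) - (u / vP) * (probe[i] - mp)) / denom;

  const int rad = (int) std::ceil(truncate * sigma / voxel);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);
  std::vector<double> kx(2 * rad + 1), ky(2 * rad + 1), kz(2 * rad + 1);

  // continuous-distance kernel, matching cpp_splat_gaussian (the separable
  // normalisation is treated as locally constant, an O(sigma/extent) error)
  for (int n = 0; n < coords.nrow(); ++n) {
    const int cx = vox_index(coords(n, 0), origin[0], voxel);
    const int cy = vox_index(coords(n, 1), origin[1], voxel);
    const int cz = vox_index(coords(n, 2), origin[2], voxel);
    double sx = 0, sy = 0, sz = 0;
    for (int o = -rad; o <= rad; ++o) {
      const double dx = origin[0] + (cx + o) * voxel - coords(n, 0);
      const double dy = origin[1] + (cy + o) * voxel - coords(n, 1);
      const double dz = origin[2] + (cz + o) * voxel - coords(n, 2);
      kx[o + rad] = std::exp(-dx * dx * inv2s2); sx += kx[o + rad];
      ky[o + rad] = std::exp(-dy * dy * inv2s2); sy += ky[o + rad];
      kz[o + rad] = std::exp(-dz * dz * inv2s2); sz += kz[o + rad];
    }
    const double norm = 1.0 / (sx * sy * sz);
    double gx = 0, gy = 0, gz = 0;
    for (int oz = -rad; oz <= rad; ++oz) {
      const int iz = cz + oz; if (iz < 0 || iz >= nz) continue;
      const double pz = origin[2] + iz * voxel;
      for (int oy = -rad; oy <= rad; ++oy) {
        const int iy = cy + oy; if (iy < 0 || iy >= ny) continue;
        const double py = origin[1] + iy * voxel;
        const double kyz = ky[oy + rad] * kz[oz + rad];
        const R_xlen_t base = (R_xlen_t) iz * nx * ny + (R_xlen_t) iy * nx;
        for (int ox = -rad; ox <= rad; ++ox) {
          const int ix = cx + ox; if (ix < 0 || ix >= nx) continue;
          const double kv = norm * kx[ox + rad] * kyz;
          const double ww = wf[base + ix] * kv * invs2;
          gx += ww * (origin[0] + ix * voxel - coords(n, 0));
          gy += ww * (py - coords(n, 1));
          gz += ww * (pz - coords(n, 2));
        }
      }
    }
    grad(n, 0) = gx; grad(n, 1) = gy; grad(n, 2) = gz;
  }
  return List::create(_["ccc"] = ccc, _["grad"] = grad);
}

// CCC of a posed rigid body plus its analytic gradient in the 6 pose
// parameters: translation t (nm) and an incremental axis-angle rotation w
// (rad) about the body centre, evaluated at w = 0 where the Rodrigues
// Jacobian is exact. coords = Xc %*% t(R) + t with Xc centred.
// [[Rcpp::export]]
List cpp_pose_ccc_grad(NumericMatrix Xc, NumericMatrix R, NumericVector t,
                       NumericVector target, IntegerVector dim,
                       NumericVector origin, double voxel, double sigma,
                       double truncate = 4.0) {
  const int n = Xc.nrow();
  NumericMatrix coords(n, 3), y(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      y(i, c) = R(c, 0) * Xc(i, 0) + R(c, 1) * Xc(i, 1) + R(c, 2) * Xc(i, 2);
      coords(i, c) = y(i, c) + t[c];
    }
  List cg = cpp_ccc_grad(coords, target, dim, origin, voxel, sigma,
                         truncate);
  NumericMatrix g = cg["grad"];
  NumericVector pose_grad(6);
  for (int i = 0; i < n; ++i) {
    pose_grad[0] += g(i, 0);
    pose_grad[1] += g(i, 1);
    pose_grad[2] += g(i, 2);
    // d coords_i / d w = w x y_i  =>  grad_w = sum_i y_i x grad_i (sign via
    // triple product: d/dw_k = (e_k x y_i) . g_i = e_k . (y_i x g_i))
    pose_grad[3] += y(i, 1) * g(i, 2) - y(i, 2) * g(i, 1);
    pose_grad[4] += y(i, 2) * g(i, 0) - y(i, 0) * g(i, 2);
    pose_grad[5] += y(i, 0) * g(i, 1) - y(i, 1) * g(i, 0);
  }
  return List::create(_["ccc"] = cg["ccc"], _["grad"] = pose_grad);
}

// Restraint energy components and (optionally) the gradient of the weighted
// sum W_pair*(E_LB+E_UB+E_C) + W_ev*E_EV.
// kind codes: 1 lower-bound harmonic, 2 upper-bound harmonic, 3 connectivity.
// Excluded volume runs over all non-adjacent pairs: k_ev*(2r - d)^2 if d<2r.
// [[Rcpp::export]]
List cpp_restraint_energy(NumericMatrix coords, IntegerVector ri,
                          IntegerVector rj, IntegerVector kind,
                          NumericVector d0, NumericVector k, double r_bead,
                          double k_ev, double w_pair = 1.0, double w_ev = 1.0,
                          bool want_grad = true) {
  const int n = coords.nrow();
  double e_lb = 0, e_ub = 0, e_c = 0, e_ev = 0;
  NumericMatrix grad(want_grad ? n : 1, 3);

  auto add_pair = [&](int a, int b, double coef, double diff, double dist) {
    // energy term coef * diff^2 with diff = (d - d0) sign handled by caller;
    // gradient of coef*(d-d0)^2 wrt x_a is 2*coef*(d-d0)*(x_a-x_b)/d
    if (!want_grad || dist <= 0) return;
    const double f = 2.0 * coef * diff / dist;
    for (int c = 0; c < 3; ++c) {
      const double dx = coords(a, c) - coords(b, c);
      grad(a, c) += f * dx;
      grad(b, c) -= f * dx;
    }
  };

  for (int t = 0; t < ri.size(); ++t) {
    const int a = ri[t] - 1, b = rj[t] - 1;
    double d2 = 0;
    for (int c = 0; c < 3; ++c) {
      const double dx = coords(a, c) - coords(b, c);
      d2 += dx * dx;
    }
    const double d = std::sqrt(d2);
    if (kind[t] == 1) {            // lower bound: penalise d < d0
      if (d < d0[t]) {
        const double diff = d - d0[t];
        e_lb += k[t] * diff * diff;
        add_pair(a, b, w_pair * k[t], diff, d);
      }
    } else if (kind[t] == 2) {     // upper bound: penalise d > d0
      if (d > d0[t]) {
        const double diff = d - d0[t];
        e_ub += k[t] * diff * diff;
        add_pair(a, b, w_pair * k[t], diff, d);
      }
    } else {                       // connectivity bond
      const double diff = d - d0[t];
      e_c += k[t] * diff * diff;
      add_pair(a, b, w_pair * k[t], diff, d);
    }
  }

  const double dmin = 2.0 * r_bead;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 2; b < n; ++b) {  // skip adjacent (bonded) pairs
      double d2 = 0;
      for (int c = 0; c < 3; ++c) {
        const double dx = coords(a, c) - coords(b, c);
        d2 += dx * dx;
      }
      if (d2 < dmin * dmin) {
        const double d = std::sqrt(d2);
        const double diff = d - dmin;
        e_ev += k_ev * diff * diff;
        add_pair(a, b, w_ev * k_ev, diff, d);
      }
    }
  }
  return List::create(_["e_lb"] = e_lb, _["e_ub"] = e_ub, _["e_c"] = e_c,
                      _["e_ev"] = e_ev, _["grad"] = grad);
}

// Gradient-descent minimisation of the restraint energy (no map term);
// adaptive step size. Returns final coordinates and energy.
// [[Rcpp::export]]
List cpp_minimize_restraints(NumericMatrix coords0, IntegerVector ri,
                             IntegerVector rj, IntegerVector kind,
                             NumericVector d0, NumericVector k, double r_bead,
                             double k_ev, int max_iter = 300,
                             double step0 = 5.0, double tol = 1e-6) {
  NumericMatrix x = clone(coords0);
  const int n = x.nrow();
  double step = step0;

  auto energy = [&](NumericMatrix& c) {
    List e = cpp_restraint_energy(c, ri, rj, kind, d0, k, r_bead, k_ev,
                                  1.0, 1.0, false);
    return as<double>(e["e_lb"]) + as<double>(e["e_ub"]) +
           as<double>(e["e_c"]) + as<double>(e["e_ev"]);
  };

  double e_cur = energy(x);
  for (int it = 0; it < max_iter; ++it) {
    List eg = cpp_restraint_energy(x, ri, rj, kind, d0, k, r_bead, k_ev,
                                   1.0, 1.0, true);
    NumericMatrix g = eg["grad"];
    double gmax = 0;
    for (int a = 0; a < n; ++a)
      for (int c = 0; c < 3; ++c) gmax = std::max(gmax, std::fabs(g(a, c)));
    if (gmax < 1e-12) break;
    bool improved = false;
    for (int half = 0; half < 12; ++half) {
      NumericMatrix xt(n, 3);
      const double s = step / gmax;  // cap displacement at `step` nm
      for (int a = 0; a < n; ++a)
        for (int c = 0; c < 3; ++c) xt(a, c) = x(a, c) - s * g(a, c);
      const double e_try = energy(xt);
      if (e_try < e_cur) {
        x = xt;
        if (e_cur - e_try < tol * std::max(1.0, e_cur)) { e_cur = e_try; it = max_iter; }
        else e_cur = e_try;
        step *= 1.2; improved = true; break;
      }
      step *= 0.5;
    }
    if (!improved) break;
  }
  return List::create(_["coords"] = x, _["energy"] = e_cur);
}

// Count non-adjacent bead pairs with d < 2r (serious clashes).
// [[Rcpp::export]]
int cpp_clash_count(NumericMatrix coords, double r_bead) {
  const int n = coords.nrow();
  const double lim2 = 4.0 * r_bead * r_bead;
  int cnt = 0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 2; b < n; ++b) {
      double d2 = 0;
      for (int c = 0; c < 3; ++c) {
        const double dx = coords(a, c) - coords(b, c);
        d2 += dx * dx;
      }
      if (d2 < lim2) ++cnt;
    }
  return cnt;
}

// Grid-accelerated fixed-radius neighbour lists (indices are 1-based,
// include the point itself).
// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix pts, double eps) {
  const int n = pts.nrow();
  double mn[3], mx[3];
  for (int c = 0; c < 3; ++c) { mn[c] = R_PosInf; mx[c] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      mn[c] = std::min(mn[c], pts(i, c));
      mx[c] = std::max(mx[c], pts(i, c));
    }
  const double cell = eps;
  int dims[3];
  for (int c = 0; c < 3; ++c)
    dims[c] = std::max(1, (int) std::floor((mx[c] - mn[c]) / cell) + 1);
  auto cell_id = [&](int i) {
    long id = 0;
    for (int c = 2; c >= 0; --c) {
      int ic = (int) std::floor((pts(i, c) - mn[c]) / cell);
      ic = std::min(std::max(ic, 0), dims[c] - 1);
      id = id * dims[c] + ic;
    }
    return id;
  };
  std::vector<std::vector<int> > buckets((long) dims[0] * dims[1] * dims[2]);
  for (int i = 0; i < n; ++i) buckets[cell_id(i)].push_back(i);

  const double eps2 = eps * eps;
  List out(n);
  for (int i = 0; i < n; ++i) {
    int ic[3];
    for (int c = 0; c < 3; ++c) {
      ic[c] = (int) std::floor((pts(i, c) - mn[c]) / cell);
      ic[c] = std::min(std::max(ic[c], 0), dims[c] - 1);
    }
    std::vector<int> nb;
    for (int dz = -1; dz <= 1; ++dz) {
      const int z = ic[2] + dz; if (z < 0 || z >= dims[2]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int y = ic[1] + dy; if (y < 0 || y >= dims[1]) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int x = ic[0] + dx; if (x < 0 || x >= dims[0]) continue;
          const long b = ((long) z * dims[1] + y) * dims[0] + x;
          for (int j : buckets[b]) {
            double d2 = 0;
            for (int c = 0; c < 3; ++c) {
              const double dd = pts(i, c) - pts(j, c);
              d2 += dd * dd;
            }
            if (d2 <= eps2) nb.push_back(j + 1);
          }
        }
      }
    }
    std::sort(nb.begin(), nb.end());
    out[i] = wrap(nb);
  }
  return out;
}

// Per-row minimum Euclidean distance from each point of A to the set B.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix A, NumericMatrix B) {
  NumericVector out(A.nrow());
  for (int i = 0; i < A.nrow(); ++i) {
    double best = R_PosInf;
    for (int j = 0; j < B.nrow(); ++j) {
      double d2 = 0;
      for (int c = 0; c < 3; ++c) {
        const double dx = A(i, c) - B(j, c);
        d2 += dx * dx;
      }
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
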