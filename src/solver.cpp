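// 3-D velocity-stress elastic finite-difference core.
//
// Collocated grid, 9-component state U = (vx,vy,vz,sxx,syy,szz,sxy,sxz,syz).
// Spatial derivatives use a 5-node one-sided biased (MacCormack-type) stencil
// with offsets -1..3 (forward) and its mirrored-negated counterpart
// (backward); forward/backward operators alternate across RK4 stages and
// axes on a fixed cycle.  Free surface at the top (k = nz-1) by the
// traction-image method: sigma_zz, sigma_xz, sigma_yz vanish on the surface
// and are antisymmetrically mirrored into the stencil's virtual ghost nodes.
// Sides/bottom (optionally top) are exponential-damping sponge layers.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

enum { VX = 0, VY, VZ, SXX, SYY, SZZ, SXY, SXZ, SYZ, NF };

struct Geom {
  int nx, ny, nz;
  size_t n;
  double invdx;           // 1/dx along x and y (uniform horizontal spacing)
  const double *invdz;    // per-column 1/dz(i,j), length nx*ny
};

// 2-point / central fallback where the biased stencil would leave the domain
static inline double edge_d(const double *f, int p, int n, int s, double invh) {
  if (n < 2) return 0.0;
  if (p == 0) return (f[(size_t)s] - f[0]) * invh;
  if (p == n - 1) return (f[(size_t)(n - 1) * s] - f[(size_t)(n - 2) * s]) * invh;
  return 0.5 * (f[(size_t)(p + 1) * s] - f[(size_t)(p - 1) * s]) * invh;
}

// Biased derivative along one line of length n with stride s.
// a = coefficients for offsets -1..3 (forward); backward is mirrored-negated.
// mirror_top: antisymmetric continuation about p = n-1 (traction image).
static void dline(const double *f, double *o, int n, int s, bool fwd,
                  const double *a, double invh, bool mirror_top) {
  if (n < 5) {  // degenerate extent: low-order everywhere
    for (int p = 0; p < n; ++p) o[(size_t)p * s] = edge_d(f, p, n, s, invh);
    return;
  }
#define GET(q) ((mirror_top && (q) > n - 1) ? -f[(size_t)(2 * (n - 1) - (q)) * s] \
                                            : f[(size_t)(q) * s])
  if (fwd) {
    const int hi = mirror_top ? (n - 1) : (n - 4);
    for (int p = 0; p < n; ++p) {
      if (p >= 1 && p <= hi) {
        double v = a[0] * GET(p - 1) + a[1] * GET(p) + a[2] * GET(p + 1) +
                   a[3] * GET(p + 2) + a[4] * GET(p + 3);
        o[(size_t)p * s] = v * invh;
      } else {
        o[(size_t)p * s] = edge_d(f, p, n, s, invh);
      }
    }
  } else {
    const int hi = mirror_top ? (n - 1) : (n - 2);
    for (int p = 0; p < n; ++p) {
      if (p >= 3 && p <= hi) {
        double v = -(a[0] * GET(p + 1) + a[1] * GET(p) + a[2] * GET(p - 1) +
                     a[3] * GET(p - 2) + a[4] * GET(p - 3));
        o[(size_t)p * s] = v * invh;
      } else {
        o[(size_t)p * s] = edge_d(f, p, n, s, invh);
      }
    }
  }
#undef GET
}

static void dfield(const double *f, double *o, const Geom &g, int axis,
                   bool fwd, const double *a, bool mirror_top) {
  if (axis == 0) {
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j) {
        size_t base = (size_t)g.nx * (j + (size_t)g.ny * k);
        dline(f + base, o + base, g.nx, 1, fwd, a, g.invdx, false);
      }
  } else if (axis == 1) {
    for (int k = 0; k < g.nz; ++k)
      for (int i = 0; i < g.nx; ++i) {
        size_t base = (size_t)i + (size_t)g.nx * (size_t)g.ny * k;
        dline(f + base, o + base, g.ny, g.nx, fwd, a, g.invdx, false);
      }
  } else {
    size_t plane = (size_t)g.nx * g.ny;
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        size_t base = (size_t)i + (size_t)g.nx * j;
        dline(f + base, o + base, g.nz, (int)plane, fwd, a, g.invdz[base],
              mirror_top);
      }
  }
}

static inline void zero_tractions(std::vector<std::vector<double> > &U,
                                  const Geom &g) {
  size_t plane = (size_t)g.nx * g.ny, off = plane * (size_t)(g.nz - 1);
  std::memset(&U[SZZ][off], 0, plane * sizeof(double));
  std::memset(&U[SXZ][off], 0, plane * sizeof(double));
  std::memset(&U[SYZ][off], 0, plane * sizeof(double));
}

// Semi-discrete right-hand side of the velocity-stress system.
static void rhs(std::vector<std::vector<double> > &U,
                std::vector<std::vector<double> > &K,
                std::vector<double> &T1, std::vector<double> &T2,
                std::vector<double> &D1, std::vector<double> &D2,
                std::vector<double> &D3, const double *rho_inv,
                const double *lam, const double *mu, const Geom &g,
                const double *a, const bool fwd[3], bool free_surf, int nsrc,
                const int *sidx, const int *stype, const double *mech,
                const double *svolinv, const double *sval) {
  const size_t n = g.n;
  // particle-velocity rates: rho dv_i/dt = d_j sigma_ij
  dfield(U[SXX].data(), K[VX].data(), g, 0, fwd[0], a, false);
  dfield(U[SXY].data(), T1.data(), g, 1, fwd[1], a, false);
  for (size_t q = 0; q < n; ++q) K[VX][q] += T1[q];
  dfield(U[SXZ].data(), T1.data(), g, 2, fwd[2], a, free_surf);
  for (size_t q = 0; q < n; ++q) K[VX][q] = (K[VX][q] + T1[q]) * rho_inv[q];

  dfield(U[SXY].data(), K[VY].data(), g, 0, fwd[0], a, false);
  dfield(U[SYY].data(), T1.data(), g, 1, fwd[1], a, false);
  for (size_t q = 0; q < n; ++q) K[VY][q] += T1[q];
  dfield(U[SYZ].data(), T1.data(), g, 2, fwd[2], a, free_surf);
  for (size_t q = 0; q < n; ++q) K[VY][q] = (K[VY][q] + T1[q]) * rho_inv[q];

  dfield(U[SXZ].data(), K[VZ].data(), g, 0, fwd[0], a, false);
  dfield(U[SYZ].data(), T1.data(), g, 1, fwd[1], a, false);
  for (size_t q = 0; q < n; ++q) K[VZ][q] += T1[q];
  dfield(U[SZZ].data(), T1.data(), g, 2, fwd[2], a, free_surf);
  for (size_t q = 0; q < n; ++q) K[VZ][q] = (K[VZ][q] + T1[q]) * rho_inv[q];

  // stress rates: dsigma/dt = lambda tr(grad v) I + mu (grad v + grad v^T)
  dfield(U[VX].data(), D1.data(), g, 0, fwd[0], a, false);
  dfield(U[VY].data(), D2.data(), g, 1, fwd[1], a, false);
  dfield(U[VZ].data(), D3.data(), g, 2, fwd[2], a, false);
  for (size_t q = 0; q < n; ++q) {
    double div = D1[q] + D2[q] + D3[q];
    double ld = lam[q] * div;
    K[SXX][q] = ld + 2.0 * mu[q] * D1[q];
    K[SYY][q] = ld + 2.0 * mu[q] * D2[q];
    K[SZZ][q] = ld + 2.0 * mu[q] * D3[q];
  }
  dfield(U[VX].data(), T1.data(), g, 1, fwd[1], a, false);
  dfield(U[VY].data(), T2.data(), g, 0, fwd[0], a, false);
  for (size_t q = 0; q < n; ++q) K[SXY][q] = mu[q] * (T1[q] + T2[q]);
  dfield(U[VX].data(), T1.data(), g, 2, fwd[2], a, false);
  dfield(U[VZ].data(), T2.data(), g, 0, fwd[0], a, false);
  for (size_t q = 0; q < n; ++q) K[SXZ][q] = mu[q] * (T1[q] + T2[q]);
  dfield(U[VY].data(), T1.data(), g, 2, fwd[2], a, false);
  dfield(U[VZ].data(), T2.data(), g, 1, fwd[1], a, false);
  for (size_t q = 0; q < n; ++q) K[SYZ][q] = mu[q] * (T1[q] + T2[q]);

  // source injection (moment tensor into stress rates, force into velocity);
  // mech is an nsrc x 6 column-major matrix
  for (int s = 0; s < nsrc; ++s) {
    const double v = sval[s];
    if (v == 0.0) continue;
    const size_t p = (size_t)sidx[s];
#define MECH(c) mech[s + (size_t)nsrc * (c)]
    if (stype[s] == 0) {  // moment tensor, N*m: rate scaled by 1/cell volume
      const double c = v * svolinv[s];
      K[SXX][p] += MECH(0) * c;
      K[SYY][p] += MECH(1) * c;
      K[SZZ][p] += MECH(2) * c;
      K[SXY][p] += MECH(3) * c;
      K[SXZ][p] += MECH(4) * c;
      K[SYZ][p] += MECH(5) * c;
    } else {  // body force, N: velocity rate f/(rho V)
      const double c = v * svolinv[s] * rho_inv[p];
      K[VX][p] += MECH(0) * c;
      K[VY][p] += MECH(1) * c;
      K[VZ][p] += MECH(2) * c;
    }
#undef MECH
  }
}

// [[Rcpp::export]]
List cpp_run_sim(IntegerVector dims, double dx, NumericVector invdz,
                 NumericVector rho, NumericVector lam, NumericVector mu,
                 NumericVector coeff, double dt, int nt, int step0,
                 bool free_surface, IntegerVector sponge_width,
                 double sponge_alpha, IntegerVector src_idx,
                 IntegerVector src_type, NumericMatrix src_mech,
                 NumericVector src_volinv, NumericMatrix stf_half,
                 Nullable<List> init_state, int surface_every,
                 IntegerMatrix receivers, IntegerVector snapshot_steps,
                 bool record_surface, bool return_final) {
  Geom g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.n = (size_t)g.nx * g.ny * g.nz;
  g.invdx = 1.0 / dx;
  g.invdz = invdz.begin();
  const double *a = coeff.begin();
  const int nsrc = src_idx.size();
  const size_t n = g.n;

  if ((size_t)rho.size() != n || (size_t)lam.size() != n ||
      (size_t)mu.size() != n)
    stop("material arrays do not match grid dimensions");
  if (coeff.size() != 5) stop("stencil must have 5 coefficients");
  if (nsrc > 0 && stf_half.nrow() < 2 * nt + 1)
    stop("source time function must be sampled at half-step resolution");

  std::vector<double> rho_inv(n);
  for (size_t q = 0; q < n; ++q) rho_inv[q] = 1.0 / rho[q];

  // state, stage work state, stage rate, RK accumulator + scratch
  std::vector<std::vector<double> > U(NF), W(NF), K(NF), A(NF);
  for (int f = 0; f < NF; ++f) {
    U[f].assign(n, 0.0); W[f].assign(n, 0.0);
    K[f].assign(n, 0.0); A[f].assign(n, 0.0);
  }
  std::vector<double> T1(n), T2(n), D1(n), D2(n), D3(n);

  if (init_state.isNotNull()) {
    List is(init_state);
    if (is.size() != NF) stop("initial state must have 9 fields");
    for (int f = 0; f < NF; ++f) {
      NumericVector v = is[f];
      if ((size_t)v.size() != n) stop("initial state field has wrong size");
      std::copy(v.begin(), v.end(), U[f].begin());
    }
  }
  if (free_surface) zero_tractions(U, g);

  // sponge profiles (Cerjan-style exponential damping)
  std::vector<double> gx(g.nx, 1.0), gy(g.ny, 1.0), gz(g.nz, 1.0);
  {
    int wx = sponge_width[0], wy = sponge_width[1];
    int wzb = sponge_width[2], wzt = sponge_width[3];
    for (int i = 0; i < g.nx; ++i) {
      int d = std::min(i, g.nx - 1 - i);
      if (wx > 0 && d < wx) {
        double u = sponge_alpha * (wx - d);
        gx[i] = std::exp(-u * u);
      }
    }
    for (int j = 0; j < g.ny; ++j) {
      int d = std::min(j, g.ny - 1 - j);
      if (wy > 0 && d < wy) {
        double u = sponge_alpha * (wy - d);
        gy[j] = std::exp(-u * u);
      }
    }
    for (int k = 0; k < g.nz; ++k) {
      double gk = 1.0;
      if (wzb > 0 && k < wzb) {
        double u = sponge_alpha * (wzb - k);
        gk = std::exp(-u * u);
      }
      int dt_ = g.nz - 1 - k;
      if (wzt > 0 && dt_ < wzt) {
        double u = sponge_alpha * (wzt - dt_);
        gk = std::min(gk, std::exp(-u * u));
      }
      gz[k] = gk;
    }
  }
  bool any_sponge = sponge_width[0] > 0 || sponge_width[1] > 0 ||
                    sponge_width[2] > 0 || sponge_width[3] > 0;

  // output buffers
  const size_t plane = (size_t)g.nx * g.ny;
  NumericVector pgv_h(plane), pgv_3d(plane);
  const int nrec = record_surface ? nt / std::max(1, surface_every) + 1 : 0;
  NumericVector surf_vx(record_surface ? plane * nrec : 0),
      surf_vy(record_surface ? plane * nrec : 0),
      surf_vz(record_surface ? plane * nrec : 0);
  NumericVector surf_t(record_surface ? nrec : 0);
  const int nrcv = receivers.nrow();
  NumericVector rcv(nrcv > 0 ? (size_t)(nt + 1) * nrcv * 3 : 0);
  std::vector<size_t> rcvp(nrcv);
  for (int r = 0; r < nrcv; ++r)
    rcvp[r] = (size_t)receivers(r, 0) +
              (size_t)g.nx * (receivers(r, 1) + (size_t)g.ny * receivers(r, 2));
  List snaps;

  const size_t soff = plane * (size_t)(g.nz - 1);
  auto record_step = [&](int m) {  // after step m completed (m = -1: initial)
    // PGV accumulators, every step
    for (size_t q = 0; q < plane; ++q) {
      double vx = U[VX][soff + q], vy = U[VY][soff + q], vz = U[VZ][soff + q];
      double h2 = vx * vx + vy * vy;
      double h = std::sqrt(h2), v3 = std::sqrt(h2 + vz * vz);
      if (h > pgv_h[q]) pgv_h[q] = h;
      if (v3 > pgv_3d[q]) pgv_3d[q] = v3;
    }
    if (record_surface && (m + 1) % surface_every == 0) {
      int slot = (m + 1) / surface_every;
      if (slot < nrec) {
        std::copy(&U[VX][soff], &U[VX][soff] + plane,
                  surf_vx.begin() + (size_t)slot * plane);
        std::copy(&U[VY][soff], &U[VY][soff] + plane,
                  surf_vy.begin() + (size_t)slot * plane);
        std::copy(&U[VZ][soff], &U[VZ][soff] + plane,
                  surf_vz.begin() + (size_t)slot * plane);
        surf_t[slot] = (m + 1) * dt;
      }
    }
    for (int r = 0; r < nrcv; ++r) {
      size_t row = (size_t)(m + 1);
      rcv[row + (size_t)(nt + 1) * (3 * r + 0)] = U[VX][rcvp[r]];
      rcv[row + (size_t)(nt + 1) * (3 * r + 1)] = U[VY][rcvp[r]];
      rcv[row + (size_t)(nt + 1) * (3 * r + 2)] = U[VZ][rcvp[r]];
    }
  };
  auto take_snapshot = [&](int step1) {  // step1 = completed step count
    for (int s = 0; s < snapshot_steps.size(); ++s) {
      if (snapshot_steps[s] == step1) {
        List st(NF);
        for (int f = 0; f < NF; ++f) {
          NumericVector v(n);
          std::copy(U[f].begin(), U[f].end(), v.begin());
          st[f] = v;
        }
        st.attr("names") = CharacterVector::create(
            "vx", "vy", "vz", "sxx", "syy", "szz", "sxy", "sxz", "syz");
        st.attr("step") = step1;
        snaps.push_back(st);
      }
    }
  };

  record_step(-1);
  take_snapshot(0);

  const double bcoef[4] = {1.0, 2.0, 2.0, 1.0};
  const double ccoef[4] = {0.0, 0.5, 0.5, 1.0};
  const int stfrow[4] = {0, 1, 1, 2};

  for (int m = 0; m < nt; ++m) {
    for (int f = 0; f < NF; ++f) std::fill(A[f].begin(), A[f].end(), 0.0);
    for (int stage = 0; stage < 4; ++stage) {
      bool fwd[3];
      for (int ax = 0; ax < 3; ++ax)
        fwd[ax] = (((step0 + m) + stage + ax) % 2) == 0;
      std::vector<std::vector<double> > &S = (stage == 0) ? U : W;
      std::vector<double> sval(nsrc > 0 ? nsrc : 1, 0.0);
      if (nsrc > 0) {
        int row = 2 * m + stfrow[stage];
        for (int s = 0; s < nsrc; ++s) sval[s] = stf_half(row, s);
      }
      rhs(S, K, T1, T2, D1, D2, D3, rho_inv.data(), lam.begin(), mu.begin(),
          g, a, fwd, free_surface, nsrc, src_idx.begin(), src_type.begin(),
          src_mech.begin(), src_volinv.begin(), sval.data());
      for (int f = 0; f < NF; ++f) {
        double *Af = A[f].data();
        const double *Kf = K[f].data();
        const double b = bcoef[stage];
        for (size_t q = 0; q < n; ++q) Af[q] += b * Kf[q];
      }
      if (stage < 3) {  // prepare next stage state
        const double c = ccoef[stage + 1] * dt;
        for (int f = 0; f < NF; ++f) {
          double *Wf = W[f].data();
          const double *Uf = U[f].data(), *Kf = K[f].data();
          for (size_t q = 0; q < n; ++q) Wf[q] = Uf[q] + c * Kf[q];
        }
        if (free_surface) zero_tractions(W, g);
      }
    }
    const double c = dt / 6.0;
    for (int f = 0; f < NF; ++f) {
      double *Uf = U[f].data();
      const double *Af = A[f].data();
      for (size_t q = 0; q < n; ++q) Uf[q] += c * Af[q];
    }
    if (free_surface) zero_tractions(U, g);
    if (any_sponge) {
      for (int k = 0; k < g.nz; ++k)
        for (int j = 0; j < g.ny; ++j) {
          const double gkj = gz[k] * gy[j];
          size_t base = (size_t)g.nx * (j + (size_t)g.ny * k);
          for (int f = 0; f < NF; ++f) {
            double *Uf = U[f].data() + base;
            for (int i = 0; i < g.nx; ++i) Uf[i] *= gkj * gx[i];
          }
        }
    }
    record_step(m);
    take_snapshot(m + 1);
    if ((m + 1) % 25 == 0 || m == nt - 1) {
      double mx = 0.0;
      for (size_t q = 0; q < n; ++q) {
        double v = std::fabs(U[VX][q]);
        if (v > mx) mx = v;
      }
      if (!std::isfinite(mx) || mx > 1e15)
        stop("numerical instability detected at step %d", m + 1);
      Rcpp::checkUserInterrupt();
    }
  }

  List fin;
  if (return_final) {
    fin = List(NF);
    for (int f = 0; f < NF; ++f) {
      NumericVector v(n);
      std::copy(U[f].begin(), U[f].end(), v.begin());
      fin[f] = v;
    }
    fin.attr("names") = CharacterVector::create(
        "vx", "vy", "vz", "sxx", "syy", "szz", "sxy", "sxz", "syz");
  }

  List out = List::create(
      _["pgv_h"] = pgv_h, _["pgv_3d"] = pgv_3d, _["surf_vx"] = surf_vx,
      _["surf_vy"] = surf_vy, _["surf_vz"] = surf_vz, _["surf_t"] = surf_t,
      _["nrec"] = nrec, _["rcv"] = rcv, _["snapshots"] = snaps,
      _["final"] = fin);
  return out;
}

// One-sided biased spatial derivative of a 3-D array (exposed for testing
// and for operator-level use from R).  axis is 1..3, h the grid spacing.
// [[Rcpp::export]]
NumericVector cpp_deriv(NumericVector field, IntegerVector dims, int axis,
                        bool forward, NumericVector coeff, double h) {
  Geom g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.n = (size_t)g.nx * g.ny * g.nz;
  g.invdx = 1.0 / h;
  std::vector<double> invdz((size_t)g.nx * g.ny, 1.0 / h);
  g.invdz = invdz.data();
  if ((size_t)field.size() != g.n) stop("field does not match dims");
  if (axis < 1 || axis > 3) stop("axis must be 1, 2 or 3");
  NumericVector out(g.n);
  dfield(field.begin(), out.begin(), g, axis - 1, forward, coeff.begin(),
         false);
  return out;
}
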