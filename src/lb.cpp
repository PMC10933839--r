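#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hybrid lattice-Boltzmann solver for 2-D active nematic hydrodynamics:
// D2Q9 BGK momentum solver with Guo forcing, coupled to a finite-difference
// Beris-Edwards update of the nematic order parameter.
//
// Q is the 3-D traceless tensor restricted to in-plane directors
// (Q_xz = Q_yz = 0 is an invariant subspace of in-plane flow); the stored
// components are Qxx, Qxy, Qyy with Qzz = -(Qxx + Qyy).  Bulk free energy
//   f = (A0/2)(1 - U/3) Tr Q^2 - (A0 U/3) Tr Q^3 + (A0 U/4) (Tr Q^2)^2
// whose ordered minimum is q* = 1/4 + (3/4) sqrt(1 - 8/(3U)) for
// Q = q (nn - I/3).  One-constant elasticity (K/2)|grad Q|^2, rotational
// mobility Gamma, flow alignment xi, active stress -alpha Q.
//
// Lattice units throughout: dx = dt = 1, viscosity eta = (tau - 1/2)/3.

static const int ex[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int ey[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const double w9[9] = {4.0 / 9,  1.0 / 9,  1.0 / 9, 1.0 / 9, 1.0 / 9,
                             1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36};

struct Lat {
  int nx, ny, N;
  inline int idx(int xx, int yy) const { return yy + ny * xx; }
  inline int xp(int xx) const { return (xx + 1) % nx; }
  inline int xm(int xx) const { return (xx + nx - 1) % nx; }
  inline int yp(int yy) const { return (yy + 1) % ny; }
  inline int ym(int yy) const { return (yy + ny - 1) % ny; }
};

// [[Rcpp::export]]
List lb_core(NumericMatrix f_in, NumericVector rho_in,
             NumericVector ux_in, NumericVector uy_in,
             NumericVector qxx_in, NumericVector qxy_in, NumericVector qyy_in,
             int nx, int ny, double tau, double xi, double gamma_rot,
             double a0, double u_lc, double k_elastic, double alpha,
             int n_steps, int sample_every) {
  Lat L; L.nx = nx; L.ny = ny; L.N = nx * ny;
  const int N = L.N;
  std::vector<double> f(9 * N), fpost(9 * N);
  for (int i = 0; i < 9; ++i)
    for (int k = 0; k < N; ++k) f[i * N + k] = f_in(k, i);
  std::vector<double> rho(rho_in.begin(), rho_in.end());
  std::vector<double> ux(ux_in.begin(), ux_in.end());
  std::vector<double> uy(uy_in.begin(), uy_in.end());
  std::vector<double> Qxx(qxx_in.begin(), qxx_in.end());
  std::vector<double> Qxy(qxy_in.begin(), qxy_in.end());
  std::vector<double> Qyy(qyy_in.begin(), qyy_in.end());

  std::vector<double> Hxx(N), Hxy(N), Hyy(N);
  std::vector<double> Fx(N), Fy(N);
  std::vector<double> Qxx_n(N), Qxy_n(N), Qyy_n(N);
  std::vector<double> Sxx(N), Sxy(N), Syx(N), Syy(N);  // stress tensor

  std::vector<int> nb_xp(N), nb_xm(N), nb_yp(N), nb_ym(N);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int k = L.idx(x, y);
      nb_xp[k] = L.idx(L.xp(x), y); nb_xm[k] = L.idx(L.xm(x), y);
      nb_yp[k] = L.idx(x, L.yp(y)); nb_ym[k] = L.idx(x, L.ym(y));
    }

  int n_samp = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector samp_t(n_samp), samp_ke(n_samp), samp_sp(n_samp), samp_q(n_samp);
  int isamp = 0;

  const double U = u_lc;

  for (int step = 1; step <= n_steps; ++step) {
    // --- molecular field H = -dF_bulk/dQ + K lap Q (traceless) ---
    for (int k = 0; k < N; ++k) {
      {
        double qxx = Qxx[k], qxy = Qxy[k], qyy = Qyy[k];
        double qzz = -(qxx + qyy);
        double tr2 = qxx * qxx + qyy * qyy + qzz * qzz + 2.0 * qxy * qxy;
        double m2xx = qxx * qxx + qxy * qxy;
        double m2xy = qxy * (qxx + qyy);
        double m2yy = qyy * qyy + qxy * qxy;
        double lin = a0 * (1.0 - U / 3.0);
        double hxx = -(lin * qxx - a0 * U * (m2xx - tr2 / 3.0) + a0 * U * qxx * tr2);
        double hxy = -(lin * qxy - a0 * U * m2xy + a0 * U * qxy * tr2);
        double hyy = -(lin * qyy - a0 * U * (m2yy - tr2 / 3.0) + a0 * U * qyy * tr2);
        int kxp = nb_xp[k], kxm = nb_xm[k], kyp = nb_yp[k], kym = nb_ym[k];
        hxx += k_elastic * (Qxx[kxp] + Qxx[kxm] + Qxx[kyp] + Qxx[kym] - 4.0 * qxx);
        hxy += k_elastic * (Qxy[kxp] + Qxy[kxm] + Qxy[kyp] + Qxy[kym] - 4.0 * qxy);
        hyy += k_elastic * (Qyy[kxp] + Qyy[kxm] + Qyy[kyp] + Qyy[kym] - 4.0 * qyy);
        Hxx[k] = hxx; Hxy[k] = hxy; Hyy[k] = hyy;
      }
    }

    // --- stress tensor (passive + elastic + active) ---
    for (int k = 0; k < N; ++k) {
      {
        double qxx = Qxx[k], qxy = Qxy[k], qyy = Qyy[k];
        double qzz = -(qxx + qyy);
        double hxx = Hxx[k], hxy = Hxy[k], hyy = Hyy[k];
        double hzz = -(hxx + hyy);
        double trQH = qxx * hxx + qyy * hyy + qzz * hzz + 2.0 * qxy * hxy;
        // A = Q + I/3 (in-plane block)
        double axx = qxx + 1.0 / 3.0, ayy = qyy + 1.0 / 3.0, axy = qxy;
        // HA + AH (symmetric, in-plane block)
        double haxx = 2.0 * (hxx * axx + hxy * axy);
        double haxy = hxx * axy + hxy * ayy + axx * hxy + axy * hyy;
        double hayy = 2.0 * (hxy * axy + hyy * ayy);
        // QH - HQ (antisymmetric): xy component
        double anti = qxx * hxy + qxy * hyy - hxx * qxy - hxy * qyy;
        // elastic (Ericksen) stress -K dQ:dQ over the 3x3 tensor
        int kxp = nb_xp[k], kxm = nb_xm[k], kyp = nb_yp[k], kym = nb_ym[k];
        double dxQxx = 0.5 * (Qxx[kxp] - Qxx[kxm]);
        double dyQxx = 0.5 * (Qxx[kyp] - Qxx[kym]);
        double dxQxy = 0.5 * (Qxy[kxp] - Qxy[kxm]);
        double dyQxy = 0.5 * (Qxy[kyp] - Qxy[kym]);
        double dxQyy = 0.5 * (Qyy[kxp] - Qyy[kxm]);
        double dyQyy = 0.5 * (Qyy[kyp] - Qyy[kym]);
        double dxQzz = -(dxQxx + dxQyy), dyQzz = -(dyQxx + dyQyy);
        double gxx = dxQxx * dxQxx + dxQyy * dxQyy + dxQzz * dxQzz + 2.0 * dxQxy * dxQxy;
        double gxy = dxQxx * dyQxx + dxQyy * dyQyy + dxQzz * dyQzz + 2.0 * dxQxy * dyQxy;
        double gyy = dyQxx * dyQxx + dyQyy * dyQyy + dyQzz * dyQzz + 2.0 * dyQxy * dyQxy;

        Sxx[k] = 2.0 * xi * axx * trQH - xi * haxx - k_elastic * gxx - alpha * qxx;
        Syy[k] = 2.0 * xi * ayy * trQH - xi * hayy - k_elastic * gyy - alpha * qyy;
        double sym_xy = 2.0 * xi * axy * trQH - xi * haxy - k_elastic * gxy - alpha * qxy;
        Sxy[k] = sym_xy + anti;   // sigma_xy (row x, col y)
        Syx[k] = sym_xy - anti;   // sigma_yx
      }
    }

    // --- body force F_a = d_b sigma_ab, and Beris-Edwards update of Q ---
    for (int k = 0; k < N; ++k) {
      {
        int kxp = nb_xp[k], kxm = nb_xm[k], kyp = nb_yp[k], kym = nb_ym[k];
        Fx[k] = 0.5 * (Sxx[kxp] - Sxx[kxm]) + 0.5 * (Sxy[kyp] - Sxy[kym]);
        Fy[k] = 0.5 * (Syx[kxp] - Syx[kxm]) + 0.5 * (Syy[kyp] - Syy[kym]);

        // velocity gradient W_ab = d_b u_a
        double wxx = 0.5 * (ux[kxp] - ux[kxm]);
        double wxy = 0.5 * (ux[kyp] - ux[kym]);
        double wyx = 0.5 * (uy[kxp] - uy[kxm]);
        double wyy = 0.5 * (uy[kyp] - uy[kym]);
        double dxx = wxx, dyy = wyy, dxy = 0.5 * (wxy + wyx);
        double oxy = 0.5 * (wxy - wyx);            // Omega_xy
        double trQW = Qxx[k] * wxx + Qxy[k] * (wxy + wyx) + Qyy[k] * wyy;

        double axx = Qxx[k] + 1.0 / 3.0, ayy = Qyy[k] + 1.0 / 3.0, axy = Qxy[k];
        double azz = -(Qxx[k] + Qyy[k]) + 1.0 / 3.0;
        // B = xi*D + Omega ; C = xi*D - Omega (in-plane blocks)
        double bxx = xi * dxx, byy = xi * dyy;
        double bxy = xi * dxy + oxy, byx = xi * dxy - oxy;
        double cxx = bxx, cyy = byy;
        double cxy = xi * dxy - oxy, cyx = xi * dxy + oxy;
        // S = B A + A C - 2 xi A tr(QW)
        double sxx = bxx * axx + bxy * axy + axx * cxx + axy * cyx - 2.0 * xi * axx * trQW;
        double sxy = bxx * axy + bxy * ayy + axx * cxy + axy * cyy - 2.0 * xi * axy * trQW;
        double syy = byx * axy + byy * ayy + axy * cxy + ayy * cyy - 2.0 * xi * ayy * trQW;
        double szz = -2.0 * xi * azz * trQW;
        double trS = sxx + syy + szz;              // remove trace leak (div u != 0)
        sxx -= trS / 3.0; syy -= trS / 3.0;

        // advection -u . grad Q (central differences)
        double adxx = -(ux[k] * 0.5 * (Qxx[kxp] - Qxx[kxm]) + uy[k] * 0.5 * (Qxx[kyp] - Qxx[kym]));
        double adxy = -(ux[k] * 0.5 * (Qxy[kxp] - Qxy[kxm]) + uy[k] * 0.5 * (Qxy[kyp] - Qxy[kym]));
        double adyy = -(ux[k] * 0.5 * (Qyy[kxp] - Qyy[kxm]) + uy[k] * 0.5 * (Qyy[kyp] - Qyy[kym]));

        Qxx_n[k] = Qxx[k] + adxx + sxx + gamma_rot * Hxx[k];
        Qxy_n[k] = Qxy[k] + adxy + sxy + gamma_rot * Hxy[k];
        Qyy_n[k] = Qyy[k] + adyy + syy + gamma_rot * Hyy[k];
      }
    }

    // --- D2Q9 BGK collision with Guo forcing, then streaming (pull) ---
    const double omega = 1.0 / tau;
    const double gpre = 1.0 - 0.5 * omega;
    for (int k = 0; k < N; ++k) {
      double r = rho[k], vx = ux[k], vy = uy[k];
      double usq = vx * vx + vy * vy;
      for (int i = 0; i < 9; ++i) {
        double eu = ex[i] * vx + ey[i] * vy;
        double feq = w9[i] * r * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * usq);
        double gi = gpre * w9[i] *
          ((3.0 * (ex[i] - vx) + 9.0 * eu * ex[i]) * Fx[k] +
           (3.0 * (ey[i] - vy) + 9.0 * eu * ey[i]) * Fy[k]);
        fpost[i * N + k] = f[i * N + k] - omega * (f[i * N + k] - feq) + gi;
      }
    }
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        int k = L.idx(x, y);
        for (int i = 0; i < 9; ++i) {
          int xs = (x - ex[i] + nx) % nx;
          int ys = (y - ey[i] + ny) % ny;
          f[i * N + k] = fpost[i * N + L.idx(xs, ys)];
        }
      }
    }

    // --- macroscopic moments (with half-force velocity correction) ---
    for (int k = 0; k < N; ++k) {
      double r = 0.0, mx = 0.0, my = 0.0;
      for (int i = 0; i < 9; ++i) {
        double fi = f[i * N + k];
        r += fi; mx += fi * ex[i]; my += fi * ey[i];
      }
      rho[k] = r;
      ux[k] = (mx + 0.5 * Fx[k]) / r;
      uy[k] = (my + 0.5 * Fy[k]) / r;
      Qxx[k] = Qxx_n[k]; Qxy[k] = Qxy_n[k]; Qyy[k] = Qyy_n[k];
      if (!std::isfinite(rho[k]) || !std::isfinite(ux[k]) || !std::isfinite(Qxx[k]))
        stop("lattice-Boltzmann fields became non-finite at step %d", step);
    }

    if (sample_every > 0 && step % sample_every == 0 && isamp < n_samp) {
      double ke = 0.0, sp = 0.0, mq = 0.0;
      for (int k = 0; k < N; ++k) {
        double u2 = ux[k] * ux[k] + uy[k] * uy[k];
        ke += 0.5 * rho[k] * u2;
        sp += std::sqrt(u2);
        double mean = 0.5 * (Qxx[k] + Qyy[k]);
        double dev = std::sqrt(0.25 * (Qxx[k] - Qyy[k]) * (Qxx[k] - Qyy[k]) +
                               Qxy[k] * Qxy[k]);
        mq += 1.5 * (mean + dev);      // q from largest in-plane eigenvalue
      }
      samp_t[isamp] = step; samp_ke[isamp] = ke / N;
      samp_sp[isamp] = sp / N; samp_q[isamp] = mq / N;
      ++isamp;
    }
  }

  NumericMatrix f_out(N, 9);
  for (int i = 0; i < 9; ++i)
    for (int k = 0; k < N; ++k) f_out(k, i) = f[i * N + k];
  return List::create(
    _["f"] = f_out, _["rho"] = wrap(rho),
    _["ux"] = wrap(ux), _["uy"] = wrap(uy),
    _["Qxx"] = wrap(Qxx), _["Qxy"] = wrap(Qxy), _["Qyy"] = wrap(Qyy),
    _["samples"] = DataFrame::create(
      _["step"] = samp_t, _["kinetic_energy"] = samp_ke,
      _["mean_speed"] = samp_sp, _["mean_q"] = samp_q));
}
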