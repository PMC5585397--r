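// 1D-periodic Coulomb pair interaction (Lekner-type resummation) and the
// reduced-unit configuration energy
//
//   beta H = xi * sum_{i<j} v(rho_ij, zeta_ij) + 2 xi * sum_i ln(r_i / R)
//
// with lengths in units of a = q/tau and energies in k_B T.
//
// The image-summed 1/r interaction is conditionally divergent; v is defined as
// the regularized limit  v = lim_M [ sum_{|n|<=M} 1/d_n - (2/H) ln(2M) ],
// so only differences of v are physical (additive constant convention C0 = 0).
// Two evaluation branches share that regularization exactly:
//   * rho >= rho_switch*H : Poisson-resummed form
//       v = (4/H) sum_{k>=1} K0(2 pi k rho/H) cos(2 pi k zeta/H) - (2/H) ln(rho/H)
//   * rho <  rho_switch*H : 13 explicit images plus a digamma tail expanded in
//       powers of (rho/H)^2 (the K0 series converges too slowly near the axis).
// Both are accurate to ~1e-12 at the default settings; the brute-force image
// sum oracle in R cross-checks the differences.

#include "cylcond.h"
#include <Rmath.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

LkPar as_lkpar(List lek) {
  LkPar p;
  p.n_fourier  = as<int>(lek["n_fourier"]);
  p.rho_switch = as<double>(lek["rho_switch"]);
  p.tol        = as<double>(lek["tol"]);
  if (p.n_fourier < 1 || p.rho_switch <= 0 || p.tol <= 0)
    stop("invalid Lekner parameters");
  return p;
}

// ---- cached ln K0 Hermite table on a log-spaced grid -----------------------

namespace {

const double K0_TMIN = 0.045, K0_TMAX = 30.0;
const int    K0_N    = 4096;
std::vector<double> k0_f, k0_g;  // ln K0 and d(ln K0)/d(ln t) at the nodes
double k0_smin, k0_ds;
bool   k0_ready = false;

void k0_init() {
  k0_f.resize(K0_N);
  k0_g.resize(K0_N);
  k0_smin = std::log(K0_TMIN);
  k0_ds   = (std::log(K0_TMAX) - k0_smin) / (K0_N - 1);
  for (int i = 0; i < K0_N; ++i) {
    double t  = std::exp(k0_smin + i * k0_ds);
    double v0 = ::Rf_bessel_k(t, 0.0, 2.0);  // e^t K0(t), avoids underflow
    double v1 = ::Rf_bessel_k(t, 1.0, 2.0);
    k0_f[i] = std::log(v0) - t;
    k0_g[i] = -t * v1 / v0;                  // d ln K0/d ln t = -t K1/K0
  }
  k0_ready = true;
}

// K0(t) for t in [K0_TMIN, K0_TMAX]; cubic Hermite in s = ln t on ln K0.
inline double k0_fast(double t) {
  if (!k0_ready) k0_init();
  if (t >= K0_TMAX) return 0.0;
  if (t < K0_TMIN) return ::Rf_bessel_k(t, 0.0, 1.0);
  double s = std::log(t);
  double u = (s - k0_smin) / k0_ds;
  int    i = (int)u;
  if (i >= K0_N - 1) i = K0_N - 2;
  double x  = u - i;
  double h00 = (1 + 2 * x) * (1 - x) * (1 - x);
  double h10 = x * (1 - x) * (1 - x);
  double h01 = x * x * (3 - 2 * x);
  double h11 = x * x * (x - 1);
  double f = h00 * k0_f[i] + h10 * k0_ds * k0_g[i]
           + h01 * k0_f[i + 1] + h11 * k0_ds * k0_g[i + 1];
  return std::exp(f);
}

// ---- Chebyshev fits of the digamma-tail coefficient functions --------------
//
// With m = 6 explicit image pairs and c = zeta/H in [0, 1/2]:
//   G0(c) = psi(7+c) + psi(7-c)
//   G2(c) = sum_{n>=7} (n+c)^-3 + (n-c)^-3 = -[psi''(7+c) + psi''(7-c)]/2
//   G4(c) = sum (n+-c)^-5 = -[psi''''(7+c) + psi''''(7-c)]/24
//   G6(c) = sum (n+-c)^-7 = -[psi^(6)(7+c) + psi^(6)(7-c)]/720

const int NEAR_M   = 6;      // explicit images n = -6..6
const int CHEB_DEG = 16;
double chebG[4][CHEB_DEG];
bool   cheb_ready = false;

double g_exact(int which, double c) {
  double xp = NEAR_M + 1 + c, xm = NEAR_M + 1 - c;
  switch (which) {
    case 0: return ::Rf_digamma(xp) + ::Rf_digamma(xm);
    case 1: return -(::Rf_psigamma(xp, 2) + ::Rf_psigamma(xm, 2)) / 2.0;
    case 2: return -(::Rf_psigamma(xp, 4) + ::Rf_psigamma(xm, 4)) / 24.0;
    default: return -(::Rf_psigamma(xp, 6) + ::Rf_psigamma(xm, 6)) / 720.0;
  }
}

void cheb_init() {
  // fit on c in [0, 1/2] via Chebyshev nodes
  for (int w = 0; w < 4; ++w) {
    double fv[CHEB_DEG];
    for (int j = 0; j < CHEB_DEG; ++j) {
      double y = std::cos(M_PI * (j + 0.5) / CHEB_DEG);   // node in [-1,1]
      double c = 0.25 * (y + 1.0);                        // map to [0, 1/2]
      fv[j] = g_exact(w, c);
    }
    for (int k = 0; k < CHEB_DEG; ++k) {
      double s = 0;
      for (int j = 0; j < CHEB_DEG; ++j)
        s += fv[j] * std::cos(M_PI * k * (j + 0.5) / CHEB_DEG);
      chebG[w][k] = 2.0 * s / CHEB_DEG;
    }
  }
  cheb_ready = true;
}

inline double cheb_eval(const double* a, double c) {
  double y = 4.0 * c - 1.0;  // [0, 1/2] -> [-1, 1]
  double y2 = 2.0 * y, b0 = 0.0, b1 = 0.0;
  for (int k = CHEB_DEG - 1; k >= 1; --k) {
    double t = a[k] + y2 * b0 - b1;
    b1 = b0; b0 = t;
  }
  return 0.5 * a[0] + y * b0 - b1;
}

}  // namespace

// ---- the pair potential ----------------------------------------------------

double lk_pair(double rho, double zeta, double H, const LkPar& p) {
  // fold zeta into [0, H/2] (v is even and H-periodic in zeta)
  double z = zeta - H * std::floor(zeta / H);
  if (z > 0.5 * H) z = H - z;

  if (rho == 0.0 && z == 0.0)
    stop("ion self-overlap: rho = 0 with zeta on an image plane");

  if (rho >= p.rho_switch * H) {
    // Poisson-resummed (Fourier) branch
    double q = 2.0 * M_PI * rho / H;
    double phi = 2.0 * M_PI * z / H;
    double cut = 0.1 * p.tol * H;   // stop when the term bound (4/H) K0 << tol
    double cphi = std::cos(phi);
    double ckm1 = 1.0, ck = cphi;   // cos(0), cos(phi)
    double s = 0.0;
    for (int k = 1; k <= p.n_fourier; ++k) {
      double K = k0_fast(q * k);
      s += K * ck;
      if (K < cut) break;
      double cnext = 2.0 * cphi * ck - ckm1;
      ckm1 = ck; ck = cnext;
    }
    return (4.0 * s - 2.0 * std::log(rho / H)) / H;
  }

  // near-axis branch: explicit images plus digamma tail in powers of (rho/H)^2
  if (!cheb_ready) cheb_init();
  double x = rho / H, c = z / H;
  double direct = 0.0;
  for (int n = -NEAR_M; n <= NEAR_M; ++n) {
    double u = c + n;
    direct += 1.0 / std::sqrt(x * x + u * u);
  }
  double x2 = x * x;
  double tail = -cheb_eval(chebG[0], c) - 2.0 * M_LN2
              - 0.5 * x2 * cheb_eval(chebG[1], c)
              + 0.375 * x2 * x2 * cheb_eval(chebG[2], c)
              - 0.3125 * x2 * x2 * x2 * cheb_eval(chebG[3], c);
  return (direct + tail) / H;
}

// ---- configuration energies ------------------------------------------------

static inline double pair_geom(double ri, double thi, double zi,
                               double rj, double thj, double zj,
                               double H, const LkPar& p) {
  double rho2 = ri * ri + rj * rj - 2.0 * ri * rj * std::cos(thi - thj);
  double rho  = rho2 > 0 ? std::sqrt(rho2) : 0.0;
  return lk_pair(rho, zi - zj, H, p);
}

double lk_total_energy(const double* r, const double* th, const double* z,
                       int N, double xi, double Rcyl, double H, const LkPar& p) {
  double e = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j)
      e += pair_geom(r[i], th[i], z[i], r[j], th[j], z[j], H, p);
  }
  e *= xi;
  for (int i = 0; i < N; ++i) e += 2.0 * xi * std::log(r[i] / Rcyl);
  return e;
}

double lk_delta_one(const double* r, const double* th, const double* z,
                    int N, int i, double rn, double thn, double zn,
                    double xi, double Rcyl, double H, const LkPar& p) {
  double d = 0.0;
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    d += pair_geom(rn, thn, zn, r[j], th[j], z[j], H, p)
       - pair_geom(r[i], th[i], z[i], r[j], th[j], z[j], H, p);
  }
  return xi * d + 2.0 * xi * std::log(rn / r[i]);
}

// ---- R-facing wrappers -----------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_pair_potential(NumericVector rho, NumericVector zeta,
                                 double H, List lek) {
  LkPar p = as_lkpar(lek);
  if (H <= 0) stop("H must be positive");
  R_xlen_t n = rho.size();
  if (zeta.size() != n) stop("rho and zeta must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (rho[i] < 0) stop("rho must be nonnegative");
    out[i] = lk_pair(rho[i], zeta[i], H, p);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_total_energy(NumericVector r, NumericVector th, NumericVector z,
                        double xi, double Rcyl, double H, List lek) {
  LkPar p = as_lkpar(lek);
  return lk_total_energy(r.begin(), th.begin(), z.begin(), r.size(),
                         xi, Rcyl, H, p);
}

// [[Rcpp::export]]
double cpp_energy_delta(NumericVector r, NumericVector th, NumericVector z,
                        int i, double rn, double thn, double zn,
                        double xi, double Rcyl, double H, List lek) {
  LkPar p = as_lkpar(lek);
  if (i < 1 || i > r.size()) stop("ion index out of range");
  return lk_delta_one(r.begin(), th.begin(), z.begin(), r.size(), i - 1,
                      rn, thn, zn, xi, Rcyl, H, p);
}
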