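// Metropolis Monte Carlo chain for counterions in the cylindrical cell.
//
// Move set (probabilities from move_mix):
//   local       uniform displacement in a Cartesian cube of half-width
//               step_local; plain Metropolis (the Cartesian measure is flat).
//   centrifugal r' = R exp(u * Delta), u ~ U(0,1) (log-uniform over the cell),
//               theta and z redrawn uniformly; the acceptance carries the
//               proposal/measure factor (r'/r)^2: one power of r'/r from the
//               cylindrical volume element, one from the 1/r proposal density.
//   swap        exchange the radii of one condensed (ln(r/R) <= Delta/2) and
//               one unbound ion; symmetric proposal, plain Metropolis.
//
// Uses R's RNG (seed via set.seed in the calling R code); one sweep is N
// attempted moves regardless of type.

#include "cylcond.h"
#include <Rmath.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Cand { double r, th, z; bool valid; };

inline double wrap(double z, double H) {
  double w = z - H * std::floor(z / H);
  return w >= H ? 0.0 : w;  // guard the rounding edge so z stays in [0, H)
}

Cand prop_local(double r, double th, double z, double step,
                double Rcyl, double D, double H) {
  double x = r * std::cos(th) + (2.0 * unif_rand() - 1.0) * step;
  double y = r * std::sin(th) + (2.0 * unif_rand() - 1.0) * step;
  double zn = wrap(z + (2.0 * unif_rand() - 1.0) * step, H);
  Cand c;
  c.r = std::sqrt(x * x + y * y);
  c.th = std::atan2(y, x);
  if (c.th < 0) c.th += 2.0 * M_PI;
  c.z = zn;
  c.valid = (c.r >= Rcyl && c.r <= D);
  return c;
}

Cand prop_centrifugal(double Rcyl, double delta, double H) {
  Cand c;
  c.r = Rcyl * std::exp(unif_rand() * delta);
  c.th = 2.0 * M_PI * unif_rand();
  c.z = H * unif_rand();
  c.valid = true;
  return c;
}

}  // namespace

// Single-proposal wrappers so tests exercise the exact kernels the chain uses.

// [[Rcpp::export]]
NumericVector cpp_propose_local(double r, double th, double z, double step,
                                double Rcyl, double D, double H) {
  RNGScope scope;
  Cand c = prop_local(r, th, z, step, Rcyl, D, H);
  return NumericVector::create(c.r, c.th, c.z, c.valid ? 1.0 : 0.0);
}

// [[Rcpp::export]]
NumericVector cpp_propose_centrifugal(double Rcyl, double delta, double H) {
  RNGScope scope;
  Cand c = prop_centrifugal(Rcyl, delta, H);
  return NumericVector::create(c.r, c.th, c.z, 1.0);
}

// Pick a (condensed, unbound) pair for the swap move; returns 1-based indices
// or c(0, 0) when one side is empty.
// [[Rcpp::export]]
IntegerVector cpp_propose_swap_pair(NumericVector r, double Rcyl, double delta) {
  RNGScope scope;
  int N = r.size();
  double rstar = Rcyl * std::exp(0.5 * delta);
  std::vector<int> cond, unb;
  for (int i = 0; i < N; ++i) (r[i] <= rstar ? cond : unb).push_back(i);
  if (cond.empty() || unb.empty()) return IntegerVector::create(0, 0);
  int i = cond[(int)(unif_rand() * cond.size()) % cond.size()];
  int j = unb[(int)(unif_rand() * unb.size()) % unb.size()];
  return IntegerVector::create(i + 1, j + 1);
}

// [[Rcpp::export]]
List cpp_run_chain(NumericVector r0, NumericVector th0, NumericVector z0,
                   double xi, double Rcyl, double D, double H, double delta,
                   List lek, int n_equil, int n_prod, int stride,
                   NumericVector pmix, double step_local, bool tune) {
  LkPar p = as_lkpar(lek);
  RNGScope scope;
  const int N = r0.size();
  std::vector<double> r(r0.begin(), r0.end()),
                      th(th0.begin(), th0.end()),
                      z(z0.begin(), z0.end());
  const double rstar = Rcyl * std::exp(0.5 * delta);
  double step = step_local;
  double E = lk_total_energy(r.data(), th.data(), z.data(), N, xi, Rcyl, H, p);

  const int n_samp = n_prod / stride;
  NumericVector energies(n_samp);
  NumericMatrix rsamp(n_samp, N);
  // acceptance bookkeeping: rows local/centrifugal/swap, cols attempted/accepted
  IntegerMatrix acc(3, 2);
  int tune_att = 0, tune_acc = 0;
  int isamp = 0;

  std::vector<int> cond, unb;
  cond.reserve(N); unb.reserve(N);

  for (int sweep = 0; sweep < n_equil + n_prod; ++sweep) {
    bool equil = sweep < n_equil;
    for (int mv = 0; mv < N; ++mv) {
      double u = unif_rand();
      int type = u < pmix[0] ? 0 : (u < pmix[0] + pmix[1] ? 1 : 2);
      acc(type, 0)++;
      if (type == 2) {
        // global condensed <-> unbound radius exchange
        cond.clear(); unb.clear();
        for (int k = 0; k < N; ++k) (r[k] <= rstar ? cond : unb).push_back(k);
        if (cond.empty() || unb.empty()) continue;  // counted as rejected
        int i = cond[(int)(unif_rand() * cond.size()) % cond.size()];
        int j = unb[(int)(unif_rand() * unb.size()) % unb.size()];
        // pair (i,j) term and the one-body log terms are invariant under the
        // radius exchange; only pairs with third ions change
        double dE = 0.0;
        for (int k = 0; k < N; ++k) {
          if (k == i || k == j) continue;
          double rho2n, rho2o, ck;
          ck = std::cos(th[i] - th[k]);
          rho2n = r[j]*r[j] + r[k]*r[k] - 2.0*r[j]*r[k]*ck;
          rho2o = r[i]*r[i] + r[k]*r[k] - 2.0*r[i]*r[k]*ck;
          dE += lk_pair(std::sqrt(rho2n > 0 ? rho2n : 0), z[i]-z[k], H, p)
              - lk_pair(std::sqrt(rho2o > 0 ? rho2o : 0), z[i]-z[k], H, p);
          ck = std::cos(th[j] - th[k]);
          rho2n = r[i]*r[i] + r[k]*r[k] - 2.0*r[i]*r[k]*ck;
          rho2o = r[j]*r[j] + r[k]*r[k] - 2.0*r[j]*r[k]*ck;
          dE += lk_pair(std::sqrt(rho2n > 0 ? rho2n : 0), z[j]-z[k], H, p)
              - lk_pair(std::sqrt(rho2o > 0 ? rho2o : 0), z[j]-z[k], H, p);
        }
        dE *= xi;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
          double tmp = r[i]; r[i] = r[j]; r[j] = tmp;
          E += dE;
          acc(type, 1)++;
        }
        continue;
      }

      int i = (int)(unif_rand() * N) % N;
      Cand c = type == 0 ? prop_local(r[i], th[i], z[i], step, Rcyl, D, H)
                         : prop_centrifugal(Rcyl, delta, H);
      if (type == 0 && tune && equil) tune_att++;
      if (!c.valid) continue;
      double dE = lk_delta_one(r.data(), th.data(), z.data(), N, i,
                               c.r, c.th, c.z, xi, Rcyl, H, p);
      double logacc = -dE;
      if (type == 1) logacc += 2.0 * std::log(c.r / r[i]);  // measure/proposal factor
      if (logacc >= 0.0 || unif_rand() < std::exp(logacc)) {
        r[i] = c.r; th[i] = c.th; z[i] = c.z;
        E += dE;
        acc(type, 1)++;
        if (type == 0 && tune && equil) tune_acc++;
      }
      if (!R_finite(E)) stop("non-finite energy at sweep %d", sweep);
    }

    // auto-tune the local step toward ~40% acceptance during equilibration
    if (tune && equil && (sweep + 1) % 100 == 0 && tune_att > 0) {
      double rate = (double)tune_acc / tune_att;
      if (rate > 0.45)      step = std::min(step * 1.25, 2.0 * D);
      else if (rate < 0.35) step = std::max(step / 1.25, 1e-8);
      tune_att = tune_acc = 0;
    }

    if (!equil && (sweep - n_equil + 1) % stride == 0 && isamp < n_samp) {
      energies[isamp] = E;
      for (int k = 0; k < N; ++k) rsamp(isamp, k) = r[k];
      isamp++;
    }
  }

  double E_re = lk_total_energy(r.data(), th.data(), z.data(), N, xi, Rcyl, H, p);
  return List::create(
    _["energies"] = energies,
    _["r_samples"] = rsamp,
    _["acceptance"] = acc,
    _["final_r"] = NumericVector(r.begin(), r.end()),
    _["final_theta"] = NumericVector(th.begin(), th.end()),
    _["final_z"] = NumericVector(z.begin(), z.end()),
    _["step_local_final"] = step,
    _["energy_cached"] = E,
    _["energy_recomputed"] = E_re);
}
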