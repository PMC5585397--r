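#pragma once
#include <Rcpp.h>

// Parameters of the resummed 1D-periodic Coulomb pair potential.
struct LkPar {
  int    n_fourier;   // cap on K0-series terms
  double rho_switch;  // below rho_switch * H use the near-axis evaluation
  double tol;         // target absolute accuracy of the pair potential
};

LkPar as_lkpar(Rcpp::List lek);

double lk_pair(double rho, double zeta, double H, const LkPar& p);

double lk_total_energy(const double* r, const double* th, const double* z,
                       int N, double xi, double Rcyl, double H, const LkPar& p);

double lk_delta_one(const double* r, const double* th, const double* z,
                    int N, int i, double rn, double thn, double zn,
                    double xi, double Rcyl, double H, const LkPar& p);
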