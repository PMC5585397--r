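#' Blocking (Flyvbjerg-Petersen) standard error of a correlated series
#'
#' Repeatedly averages neighbouring pairs; at each level the naive standard
#' error of the mean is computed, and the estimate is taken at the first
#' plateau (the first level whose successor does not increase by more than
#' its own uncertainty), falling back to the maximum over levels with at
#' least 16 blocks.
#'
#' @param x Numeric series.
#' @return A list with `se` (standard error of the mean), `se_naive`, and
#'   `tau` (integrated autocorrelation-time estimate from the ratio).
#' @export
blocking_error <- function(x) {
  n <- length(x)
  if (n < 2) return(list(se = NA_real_, se_naive = NA_real_, tau = NA_real_))
  se_naive <- sd(x) / sqrt(n)
  se <- c(); dse <- c()
  y <- x
  while (length(y) >= 16) {
    m <- length(y)
    s <- sd(y) / sqrt(m)
    se <- c(se, s)
    dse <- c(dse, s / sqrt(2 * (m - 1)))
    if (m %% 2 == 1) y <- y[-m]
    y <- (y[seq(1, length(y), 2)] + y[seq(2, length(y), 2)]) / 2
  }
  if (length(se) == 0) return(list(se = se_naive, se_naive = se_naive, tau = 0))
  est <- se[length(se)]
  for (k in seq_len(length(se) - 1)) {
    if (se[k + 1] <= se[k] + dse[k]) { est <- max(se[k], se[k + 1]); break }
  }
  est <- max(est, se_naive)
  tau <- max(0, ((est / se_naive)^2 - 1) / 2)
  list(se = est, se_naive = se_naive, tau = tau)
}

#' Condensed fraction
#'
#' The order parameter of the Manning transition: the mean fraction of
#' counterions inside the cut radius `r_*`, with the inflection-point
#' criterion approximated by the logarithmic midpoint `ln(r_*/R) = Delta/2`.
#' Computed by ion counting (which equals the integral of the empirical
#' density up to `r_*`), not by integrating the binned profile, to avoid
#' binning bias; the two are cross-checked in the tests. The error bar comes
#' from a blocking analysis of the per-sample fractions.
#'
#' @param chain A [run_chain()] result.
#' @param model The cell model (defaults to the chain's).
#' @return A tibble with `f`, `f_err`, `n_samples`, `tau_f`.
#' @export
condensed_fraction <- function(chain, model = chain$model) {
  stopifnot(nrow(chain$samples) > 0)
  frac <- chain$samples$n_condensed / model$N
  b <- blocking_error(frac)
  tibble::tibble(f = mean(frac), f_err = b$se,
                 n_samples = length(frac), tau_f = b$tau)
}

#' Dimensionless heat capacity per particle
#'
#' `C_tilde = <(delta H)^2> / N` with `delta H = H - <H>`, computed from the
#' sampled reduced energies with the 1/n variance normalization (fixed, for
#' bit-reproducibility; immaterial at production sample counts). The error
#' bar is a blocking analysis of the centered squared fluctuations.
#'
#' @param energies Numeric vector of sampled reduced energies (k_B T), or a
#'   `cylcond_chain`.
#' @param N Number of counterions (taken from the chain if one is given).
#' @return A tibble with `C_tilde`, `C_err`, `n_samples`.
#' @export
heat_capacity <- function(energies, N) {
  if (inherits(energies, "cylcond_chain")) {
    N <- energies$model$N
    energies <- energies$samples$energy
  }
  n <- length(energies)
  stopifnot(n >= 2, N >= 1)
  d2 <- (energies - mean(energies))^2
  b <- blocking_error(d2)
  tibble::tibble(C_tilde = mean(d2) / N,
                 C_err = b$se / N,
                 n_samples = n)
}

#' Rescaled radial density profile
#'
#' Histograms the sampled radial coordinates in bins uniform in `ln(r/R)`
#' over `[0, Delta]`, converts counts to a number density (dividing by the
#' exact cylindrical shell volume per bin and by the number of samples) and
#' rescales to \eqn{\tilde\rho(r) = \rho(r) / (2\pi \ell_B \sigma^2)}, which
#' in reduced units is \eqn{\tilde\rho = \rho \cdot 2\pi R^2/\xi}. Per-bin
#' standard errors come from blocking on the per-sample bin counts. The
#' neutrality invariant (the profile integrates to `N/H` ions per unit
#' length) is checked to 1e-6.
#'
#' @param chain A [run_chain()] result.
#' @param model The cell model (defaults to the chain's).
#' @param n_bins Number of bins (default 100).
#' @return A tibble of class `radial_profile` with columns
#'   `ln_r_over_R_lo/hi/mid`, `r_mid`, `count`, `rho`, `rho_tilde`, `stderr`.
#' @export
radial_profile <- function(chain, model = chain$model, n_bins = 100L) {
  stopifnot(n_bins >= 2, nrow(chain$samples) > 0)
  h <- bin_log_radii(chain$r_samples, model, as.integer(n_bins))
  n_samp <- nrow(h$counts)
  r_lo <- model$R * exp(h$lo); r_hi <- model$R * exp(h$hi)
  vol <- pi * (r_hi^2 - r_lo^2) * model$H
  mean_counts <- colMeans(h$counts)
  rho <- mean_counts / vol
  scale <- 2 * pi * model$R^2 / model$xi
  err <- vapply(seq_len(ncol(h$counts)),
                function(j) blocking_error(h$counts[, j])$se, numeric(1))
  # neutrality: integral of 2 pi r rho dr per unit length equals N/H
  line_density <- sum(rho * vol) / model$H
  if (abs(line_density - model$N / model$H) > 1e-6 * model$N / model$H)
    warning("profile neutrality violated: ", format(line_density))
  out <- tibble::tibble(
    ln_r_over_R_lo = h$lo, ln_r_over_R_hi = h$hi,
    ln_r_over_R_mid = (h$lo + h$hi) / 2,
    r_mid = sqrt(r_lo * r_hi),
    count = h$total,
    rho = rho,
    rho_tilde = rho * scale,
    stderr = err / vol * scale)
  structure(out, model = model, n_samples = n_samp,
            class = c("radial_profile", class(out)))
}

#' Summary observables of a chain
#'
#' @param chain A [run_chain()] result.
#' @return A one-row tibble: `f`, `f_err`, `C_tilde`, `C_err`, `n_samples`,
#'   `tau_energy` (integrated autocorrelation estimate of the energy series,
#'   in samples).
#' @export
summarize_chain <- function(chain) {
  cf <- condensed_fraction(chain)
  hc <- heat_capacity(chain)
  be <- blocking_error(chain$samples$energy)
  tibble::tibble(f = cf$f, f_err = cf$f_err,
                 C_tilde = hc$C_tilde, C_err = hc$C_err,
                 n_samples = cf$n_samples,
                 tau_energy = be$tau)
}
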