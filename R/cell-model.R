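#' Cylindrical cell model in reduced units
#'
#' Defines the geometry and couplings of the cell model: a charged cylinder of
#' radius `R` on the axis of an outer confining cylinder of radius `D`, with
#' `N` neutralizing pointlike counterions in between. Lengths are measured in
#' units of `a = q/tau` (the axial spacing of counterions of valency `q` on a
#' line charge density `tau`), energies in units of `k_B T`; the dimensional
#' symbols `q`, `l_B` (Bjerrum length), `tau`, `sigma` (surface charge
#' density) are absorbed by this reduction. Charge neutrality fixes the
#' periodic box height `H = N`.
#'
#' The couplings are the Manning parameter `xi = q l_B tau` (rescaled line
#' charge density, equivalently inverse temperature) and the coupling
#' parameter `Xi = 2 pi q^3 l_B^2 sigma`, related through `Xi = xi^2 / R`
#' (with `R` in units of `a`). The Gouy-Chapman length is `mu = R / xi`.
#'
#' The cylinder radius can be given directly (`R`), through the outer radius
#' (`R` and `D` with `delta` implied), or through the radius-shrinking
#' exponent `alpha` of the parameterization `ln(R/a) = -alpha * Delta /
#' (alpha + 1)`, which approaches the line-charge limit (`R -> 0`) and the
#' infinite-dilution limit (`D -> infinity`) at relative rates set by
#' `alpha` (see [radius_from_alpha()]).
#'
#' @param N Number of counterions (positive integer).
#' @param xi Manning parameter, positive.
#' @param delta Lateral extension `Delta = ln(D/R)`; required unless both `R`
#'   and `D` are given.
#' @param R Cylinder radius in units of `a`. Exactly one of `R`, `alpha`, or
#'   (`R`,`D`) must determine the geometry together with `delta`.
#' @param D Outer cell radius in units of `a`.
#' @param alpha Radius-shrinking exponent (nonnegative, may be `Inf`).
#'
#' @return An object of class `cell_model`: a list with fields `N`, `xi`,
#'   `R`, `D`, `delta`, `H`, `Xi`, `mu` (and `alpha` when supplied).
#' @examples
#' cell_model(N = 30, xi = 2, delta = 10, alpha = 1)
#' cell_model(N = 10, xi = 1.5, R = 1, D = exp(3))
#' @export
cell_model <- function(N, xi, delta = NULL, R = NULL, D = NULL, alpha = NULL) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 1, N == round(N),
            is.numeric(xi), length(xi) == 1, xi > 0)
  if (!is.null(alpha)) {
    if (is.null(delta)) stop("`delta` is required when using `alpha`")
    if (!is.null(R) || !is.null(D)) stop("give either `alpha` or radii, not both")
    stopifnot(alpha >= 0)
    R <- exp(radius_from_alpha(alpha, delta))
    D <- R * exp(delta)
  } else if (!is.null(R) && !is.null(D)) {
    if (!is.null(delta) && abs(delta - log(D / R)) > 1e-8)
      stop("`delta` inconsistent with ln(D/R)")
    delta <- log(D / R)
  } else if (!is.null(R) && !is.null(delta)) {
    D <- R * exp(delta)
  } else if (!is.null(D) && !is.null(delta)) {
    R <- D * exp(-delta)
  } else {
    stop("geometry underdetermined: give (delta, alpha), (R, D), (R, delta) or (D, delta)")
  }
  stopifnot(R > 0, D > R, delta > 0)
  out <- list(
    N = as.integer(N), xi = xi, R = R, D = D, delta = delta,
    H = as.numeric(N),        # charge neutrality: H = N in units of a
    Xi = xi^2 / R,            # Xi = xi^2 * (a / R)
    mu = R / xi,              # Gouy-Chapman length
    alpha = if (is.null(alpha)) NA_real_ else alpha
  )
  structure(out, class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model> N =", x$N, " xi =", format(x$xi), "\n")
  cat("  R =", format(x$R), " D =", format(x$D), " Delta =", format(x$delta),
      " H =", format(x$H), "\n")
  cat("  Xi =", format(x$Xi), " mu =", format(x$mu),
      if (!is.na(x$alpha)) paste(" alpha =", format(x$alpha)) else "", "\n")
  invisible(x)
}

#' Parameters of the resummed periodic pair potential
#'
#' Controls the evaluation of the 1D-periodic Coulomb pair potential: the cap
#' on retained Bessel-K0 series terms, the transverse separation (in units of
#' the box height `H`) below which the series is replaced by a near-axis
#' evaluation (explicit nearby images plus a digamma tail), and the target
#' absolute accuracy.
#'
#' @param n_fourier Maximum number of K0-series terms (the series is truncated
#'   adaptively once terms fall well below `tol`).
#' @param rho_switch Near-axis switch, in units of `H`.
#' @param tol Target absolute accuracy of the pair potential.
#' @return A list of class `lekner_params`.
#' @export
lekner_params <- function(n_fourier = 2000L, rho_switch = 0.25, tol = 1e-10) {
  stopifnot(n_fourier >= 1, rho_switch > 0, rho_switch <= 0.35, tol > 0)
  structure(list(n_fourier = as.integer(n_fourier),
                 rho_switch = rho_switch, tol = tol),
            class = "lekner_params")
}

#' Counterion configuration
#'
#' A set of `N` counterion positions in cylindrical coordinates, carried as a
#' tibble with columns `r` (radial, units of `a`), `theta` (azimuth, radians)
#' and `z` (axial, units of `a`, periodic in `H`), with the total reduced
#' energy cached as an attribute.
#'
#' @param model A [cell_model()].
#' @param r,theta,z Coordinate vectors of length `model$N`. `r` must lie in
#'   `[R, D]`; `z` is wrapped into `[0, H)`.
#' @param lekner A [lekner_params()].
#' @return A tibble of class `ion_config` with attributes `energy` and
#'   `model`.
#' @export
ion_configuration <- function(model, r, theta, z, lekner = lekner_params()) {
  stopifnot(inherits(model, "cell_model"),
            length(r) == model$N, length(theta) == model$N, length(z) == model$N)
  if (any(r < model$R - 1e-12) || any(r > model$D + 1e-12))
    stop("radial coordinates outside [R, D]")
  z <- z %% model$H
  cfg <- tibble::tibble(r = as.numeric(r), theta = as.numeric(theta), z = z)
  e <- cpp_total_energy(cfg$r, cfg$theta, cfg$z, model$xi, model$R, model$H,
                        unclass(lekner))
  structure(cfg, energy = e, model = model, lekner = lekner,
            class = c("ion_config", class(cfg)))
}
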