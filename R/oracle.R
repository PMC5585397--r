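#' Brute-force image-sum difference (independent oracle)
#'
#' Difference of the 1D-periodic Coulomb interaction between two pair
#' geometries `p1` and `p0`, computed by direct summation over periodic
#' images,
#' \deqn{\sum_{n=-M}^{M}\Big[\frac{1}{d(p_1,n)} - \frac{1}{d(p_0,n)}\Big],
#'  \quad d(p, n) = \sqrt{\rho^2 + (\zeta + nH)^2}.}
#' Each sum alone diverges logarithmically with `M`; the difference
#' converges like `1/M^2` and is accelerated by one Richardson step
#' (comparing cutoffs `M` and `2M`). This is the central correctness
#' subtlety of the periodic electrostatics: only differences of the
#' image-summed potential are physical, and the resummed
#' [pair_potential()] must reproduce exactly these differences.
#'
#' @param p1,p0 Numeric `c(rho, zeta)` pair geometries.
#' @param H Periodic box height.
#' @param M Image cutoff (the extrapolation also uses `2M`).
#' @return The extrapolated difference, with attributes `error_estimate`
#'   (the magnitude of the Richardson correction, an upper bound on the
#'   remaining truncation error) and `M`.
#' @export
brute_force_periodic_sum_diff <- function(p1, p0, H, M = 20000L) {
  stopifnot(M >= 1, H > 0, length(p1) == 2, length(p0) == 2)
  partial <- function(MM) {
    n <- -MM:MM
    d1 <- sqrt(p1[1]^2 + (p1[2] + n * H)^2)
    d0 <- sqrt(p0[1]^2 + (p0[2] + n * H)^2)
    if (any(d1 == 0) || any(d0 == 0)) stop("singular image distance")
    sum(1 / d1 - 1 / d0)
  }
  s1 <- partial(M)
  s2 <- partial(2L * M)
  # error ~ c / M^2: Richardson extrapolation S = S(2M) + (S(2M) - S(M)) / 3
  corr <- (s2 - s1) / 3
  structure(s2 + corr, error_estimate = abs(corr), M = M)
}

#' Synthetic finite-size scaling data with known exponents
#'
#' Parameter-recovery fixture for the collapse machinery: generates
#' `m = clip(Delta^(-beta/nu) g(Delta^(1/nu) zeta) (1 + eps), 0, 1)` with a
#' logistic scaling function `g(s) = 1/(1 + exp(-s))`, reduced Manning
#' parameter `zeta = 1 - xi_c/xi` and multiplicative Gaussian noise
#' `eps ~ N(0, noise_sd^2)`. Reported errors are `m_err = max(noise_sd,
#' 1e-3) * m_clean` (the floor keeps errors positive for noiseless
#' fixtures). Deterministic for a fixed seed.
#'
#' When `u_grid` is supplied, the `xi` values for each `Delta` are chosen so
#' the scaling variable `u = Delta^(1/nu) zeta` takes exactly those values
#' for every size (`xi = xi_c / (1 - u Delta^(-1/nu))`); the noiseless
#' dataset then contains exactly coincident master-curve points, a useful
#' degenerate case for the collapse objective.
#'
#' @param beta,nu True exponents, positive.
#' @param xi_c Critical point used to form `zeta`.
#' @param deltas Lateral extensions.
#' @param xi_grid Manning parameters shared by all sizes (ignored when
#'   `u_grid` is given).
#' @param noise_sd Relative noise level (>= 0).
#' @param seed Integer seed.
#' @param u_grid Optional grid of the scaling variable (see above).
#' @return A [scaling_dataset()].
#' @export
synthetic_collapse_data <- function(beta, nu, xi_c, deltas,
                                    xi_grid = NULL, noise_sd = 0, seed = 1L,
                                    u_grid = NULL) {
  stopifnot(beta > 0, nu > 0, noise_sd >= 0)
  set.seed(seed)
  g <- function(s) 1 / (1 + exp(-s))
  rows <- purrr::map(deltas, function(d) {
    if (!is.null(u_grid)) {
      den <- 1 - u_grid * d^(-1 / nu)
      xi <- xi_c / den
      keep <- den > 0 & xi > 0
      tibble::tibble(delta = d, xi = xi[keep])
    } else {
      stopifnot(!is.null(xi_grid))
      tibble::tibble(delta = d, xi = xi_grid)
    }
  }) |> purrr::list_rbind()
  zeta <- 1 - xi_c / rows$xi
  m_clean <- rows$delta^(-beta / nu) * g(rows$delta^(1 / nu) * zeta)
  eps <- rnorm(nrow(rows), 0, noise_sd)
  rows$m <- pmin(pmax(m_clean * (1 + eps), 0), 1)
  rows$m_err <- pmax(noise_sd, 1e-3) * m_clean
  scaling_dataset(rows, xi_c = xi_c)
}

#' Deterministic small fixture configurations
#'
#' Named small ion configurations with hand-checkable energies, shared by
#' the module tests: a single ion at contact (energy 0), a single ion at
#' `r = R e` (energy `2 xi`), an antipodal pair, and a ring of five ions.
#'
#' @param xi Manning parameter of the fixture models.
#' @param delta Lateral extension of the fixture models.
#' @return A named list; each element is a list with `model` and `config`.
#' @export
fixture_configurations <- function(xi = 1, delta = 3) {
  lk <- lekner_params()
  m1 <- cell_model(N = 1, xi = xi, delta = delta, R = 1)
  m2 <- cell_model(N = 2, xi = xi, delta = delta, R = 1)
  m5 <- cell_model(N = 5, xi = xi, delta = delta, R = 1)
  list(
    single_at_R = list(
      model = m1,
      config = ion_configuration(m1, r = 1, theta = 0, z = 0, lekner = lk)),
    single_at_eR = list(
      model = m1,
      config = ion_configuration(m1, r = exp(1), theta = 0, z = 0, lekner = lk)),
    pair_antipodal = list(
      model = m2,
      config = ion_configuration(m2, r = c(1, 1), theta = c(0, pi),
                                 z = c(0, 1), lekner = lk)),
    ring_of_5 = list(
      model = m5,
      config = ion_configuration(m5, r = rep(2, 5),
                                 theta = 2 * pi * (0:4) / 5,
                                 z = (0:4), lekner = lk))
  )
}
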