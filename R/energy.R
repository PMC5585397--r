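#' Periodic Coulomb pair potential
#'
#' The image-summed 1/r interaction between two unit charges at transverse
#' separation `rho` and axial separation `zeta` in a box of height `H`,
#' replicated periodically along the axis. Evaluated by the rapidly convergent
#' resummation
#' \deqn{v(\rho,\zeta) = \frac{2}{H}\Big[2\sum_{n\ge1} K_0(2\pi n\rho/H)
#'   \cos(2\pi n\zeta/H) - \ln(\rho/H)\Big],}
#' switching to a near-axis evaluation (explicit nearby images plus a digamma
#' tail) below `rho_switch * H`, where the K0 series converges slowly.
#'
#' The bare image sum is conditionally divergent; `v` is its regularized
#' limit with the additive constant fixed by the convention `C0 = 0`, so only
#' differences of `v` are physical. Differences match brute-force image-sum
#' differences (see [brute_force_periodic_sum_diff()]). `v` is even and
#' `H`-periodic in `zeta`.
#'
#' @param rho Transverse separation(s), units of `a`, nonnegative.
#' @param zeta Axial separation(s), units of `a`.
#' @param H Periodic box height, units of `a`.
#' @param lekner A [lekner_params()].
#' @return Numeric vector of dimensionless potential values (multiply by `xi`
#'   for the reduced pair energy of unit-valency ions).
#' @examples
#' lp <- lekner_params()
#' pair_potential(0.3, 0.2, H = 1, lekner = lp)
#' @export
pair_potential <- function(rho, zeta, H, lekner = lekner_params()) {
  n <- max(length(rho), length(zeta))
  rho <- rep_len(rho, n); zeta <- rep_len(zeta, n)
  cpp_pair_potential(rho, zeta, H, unclass(lekner))
}

#' Tabulate the pair potential (for inspection/debugging)
#'
#' @param rho,zeta Vectors of separations; the full grid is evaluated.
#' @inheritParams pair_potential
#' @param file Optional path; when given, the table is written as CSV.
#' @return A tibble with columns `rho`, `zeta`, `v` (invisibly when writing).
#' @export
pair_potential_table <- function(rho, zeta, H, lekner = lekner_params(),
                                 file = NULL) {
  grid <- tidyr::expand_grid(rho = rho, zeta = zeta)
  grid$v <- pair_potential(grid$rho, grid$zeta, H, lekner)
  if (!is.null(file)) {
    write.csv(grid, file, row.names = FALSE)
    return(invisible(grid))
  }
  grid
}

#' Total reduced configuration energy
#'
#' The reduced Hamiltonian in units of `k_B T`,
#' \deqn{\beta H = \xi \sum_{i<j} v(\rho_{ij},\zeta_{ij})
#'   + 2\xi\sum_i \ln(r_i/R),}
#' i.e. the image-summed ion-ion repulsion plus the one-body logarithmic
#' attraction to the cylinder (which already accounts for the periodic images
#' of the cylinder's line charge). The position-independent self-image
#' constant is dropped: it cancels in all energy differences and variances.
#'
#' @param config An [ion_configuration()] (its cached energy is ignored).
#' @param model A [cell_model()]; defaults to the one attached to `config`.
#' @param lekner A [lekner_params()].
#' @return Reduced energy, a single number (units `k_B T`).
#' @export
total_energy <- function(config, model = attr(config, "model"),
                         lekner = lekner_params()) {
  cpp_total_energy(config$r, config$theta, config$z,
                   model$xi, model$R, model$H, unclass(lekner))
}

#' Incremental energy of a single-ion move
#'
#' Energy change `betaH(new) - betaH(old)` when ion `i` moves to
#' `new_position`, from the `2(N-1)` affected pair terms plus the one changed
#' log term.
#'
#' @inheritParams total_energy
#' @param i Ion index (1-based).
#' @param new_position Numeric `c(r, theta, z)` inside the cell.
#' @return The energy difference (units `k_B T`).
#' @export
energy_delta <- function(config, i, new_position,
                         model = attr(config, "model"),
                         lekner = lekner_params()) {
  stopifnot(length(new_position) == 3)
  r <- new_position[[1]]; th <- new_position[[2]]; z <- new_position[[3]]
  if (r < model$R || r > model$D) stop("new position outside [R, D]")
  if (z < 0 || z >= model$H) stop("new z outside [0, H)")
  cpp_energy_delta(config$r, config$theta, config$z, as.integer(i),
                   r, th, z, model$xi, model$R, model$H, unclass(lekner))
}
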