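#' Monte Carlo run configuration
#'
#' @param n_equil Equilibration sweeps (one sweep = `N` attempted moves).
#' @param n_prod Production sweeps.
#' @param sample_stride Sweeps between recorded samples.
#' @param move_mix Probabilities of (local, centrifugal, global-swap) moves;
#'   must be nonnegative and sum to 1.
#' @param step_local Initial half-width of the local displacement cube, units
#'   of `a`. When `tune_step = TRUE` it is adjusted toward ~40% acceptance
#'   during equilibration and then frozen for production (tuning during
#'   production would violate detailed balance).
#' @param seed Integer PRNG seed; recorded in all outputs.
#' @param tune_step Auto-tune `step_local` during equilibration?
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_equil = 2000L, n_prod = 10000L, sample_stride = 10L,
                       move_mix = c(local = 0.6, centrifugal = 0.3, swap = 0.1),
                       step_local = 1, seed = 1L, tune_step = TRUE) {
  stopifnot(n_equil >= 0, n_prod >= 1, sample_stride >= 1,
            length(move_mix) == 3, all(move_mix >= 0),
            abs(sum(move_mix) - 1) < 1e-12, step_local >= 0)
  structure(list(n_equil = as.integer(n_equil), n_prod = as.integer(n_prod),
                 sample_stride = as.integer(sample_stride),
                 move_mix = as.numeric(move_mix), step_local = step_local,
                 seed = as.integer(seed), tune_step = isTRUE(tune_step)),
            class = "run_config")
}

#' Initial counterion configuration
#'
#' `"log_uniform"` draws `ln(r/R)` uniformly over `[0, Delta]` (a mixed
#' state, the default); `"condensed"` confines all ions to
#' `ln(r/R) < Delta/20` and `"unbound"` to `ln(r/R) > 19 Delta/20` (the two
#' ordered starts used to test equilibration independence).
#'
#' @param model A [cell_model()].
#' @param init One of `"log_uniform"`, `"condensed"`, `"unbound"`.
#' @return A tibble with columns `r`, `theta`, `z`.
#' @export
initial_configuration <- function(model,
                                  init = c("log_uniform", "condensed", "unbound")) {
  init <- match.arg(init)
  N <- model$N
  band <- switch(init,
    log_uniform = c(0, 1),
    condensed   = c(0, 0.05),
    unbound     = c(0.95, 1))
  u <- runif(N, band[1], band[2])
  tibble::tibble(
    r = model$R * exp(u * model$delta),
    theta = runif(N, 0, 2 * pi),
    z = runif(N, 0, model$H))
}

#' Propose a local displacement
#'
#' Uniform displacement in a Cartesian cube of half-width `step_local`,
#' mapped back to cylindrical coordinates with `z` wrapped mod `H`. Proposals
#' with `r` outside `[R, D]` are flagged invalid (they count as attempted and
#' are rejected by the chain).
#'
#' @param config An [ion_configuration()] or tibble with `r`, `theta`, `z`.
#' @param i Ion index.
#' @param step_local Cube half-width, units of `a`.
#' @param model A [cell_model()].
#' @return A list with `r`, `theta`, `z`, `valid`.
#' @export
propose_local <- function(config, i, step_local, model = attr(config, "model")) {
  p <- cpp_propose_local(config$r[i], config$theta[i], config$z[i],
                         step_local, model$R, model$D, model$H)
  list(r = p[1], theta = p[2], z = p[3], valid = p[4] == 1)
}

#' Propose a centrifugal (log-uniform radial) move
#'
#' Draws `r' = R exp(u Delta)` with `u ~ U(0,1)` — log-uniform over the full
#' cell — and redraws `theta` and `z` uniformly. Because the proposal density
#' is proportional to `1/r'` while the configurational measure carries the
#' cylindrical volume element `r dr`, the Metropolis-Hastings acceptance for
#' this kernel is `min{1, exp(-dH) * (r'/r)^2}`: one factor `r'/r` from the
#' measure and one from the reverse/forward proposal ratio. The chain applies
#' exactly this ratio; detailed balance is validated against exact one-ion
#' marginals in the tests.
#'
#' @inheritParams propose_local
#' @return A list with `r`, `theta`, `z`, `valid = TRUE`.
#' @export
propose_centrifugal <- function(config, i, model = attr(config, "model")) {
  p <- cpp_propose_centrifugal(model$R, model$delta, model$H)
  list(r = p[1], theta = p[2], z = p[3], valid = TRUE)
}

#' Propose a global condensed/unbound swap
#'
#' Picks one condensed ion (`ln(r/R) <= Delta/2`, the same criterion as the
#' condensed-fraction observable) and one unbound ion uniformly at random and
#' exchanges their radial coordinates, keeping `theta` and `z`. The proposal
#' is symmetric, so the plain Metropolis rule applies. When either class is
#' empty the move is skipped (counted as rejected by the chain).
#'
#' @inheritParams propose_local
#' @return A list with indices `i` (condensed), `j` (unbound) and the
#'   candidate configuration tibble, or `NULL` when the move is impossible.
#' @export
propose_global_swap <- function(config, model = attr(config, "model")) {
  ij <- cpp_propose_swap_pair(config$r, model$R, model$delta)
  if (ij[1] == 0) return(NULL)
  cand <- tibble::tibble(r = config$r, theta = config$theta, z = config$z)
  cand$r[c(ij[1], ij[2])] <- cand$r[c(ij[2], ij[1])]
  list(i = ij[1], j = ij[2], candidate = cand)
}

#' Run a Metropolis Monte Carlo chain
#'
#' Samples the reduced Hamiltonian of the cell model with the three-move set
#' (local, centrifugal, global swap; see the `propose_*` functions). The
#' chain is reproducible: a fixed `run$seed` yields a bit-identical result.
#'
#' @param model A [cell_model()].
#' @param run A [run_config()].
#' @param lekner A [lekner_params()].
#' @param init Initial state (see [initial_configuration()]) or a tibble of
#'   starting positions via `init_config`.
#' @param init_config Optional explicit starting configuration.
#' @return An object of class `cylcond_chain`: a list with
#'   \describe{
#'     \item{samples}{tibble: `sample`, `sweep`, `energy` (k_B T),
#'       `n_condensed` (ions with `ln(r/R) <= Delta/2`).}
#'     \item{r_samples}{matrix of radial coordinates, samples x ions.}
#'     \item{histogram}{accumulated counts in 100 bins of `ln(r/R)`.}
#'     \item{acceptance}{tibble of attempted/accepted counts per move type.}
#'     \item{model, run, lekner, seed}{provenance copies.}
#'     \item{final}{final configuration tibble.}
#'     \item{energy_check}{cached vs recomputed final energy.}
#'   }
#' @examples
#' m <- cell_model(N = 5, xi = 2, delta = 3, R = 1)
#' ch <- run_chain(m, run_config(n_equil = 50, n_prod = 200, seed = 7))
#' glance(ch)
#' @export
run_chain <- function(model, run, lekner = lekner_params(),
                      init = c("log_uniform", "condensed", "unbound"),
                      init_config = NULL) {
  stopifnot(inherits(model, "cell_model"), inherits(run, "run_config"))
  set.seed(run$seed)
  cfg <- if (!is.null(init_config)) init_config else
    initial_configuration(model, match.arg(init))
  res <- cpp_run_chain(cfg$r, cfg$theta, cfg$z,
                       model$xi, model$R, model$D, model$H, model$delta,
                       unclass(lekner),
                       run$n_equil, run$n_prod, run$sample_stride,
                       run$move_mix, run$step_local, run$tune_step)
  n_samp <- length(res$energies)
  r_star <- model$R * exp(model$delta / 2)
  n_cond <- as.integer(rowSums(res$r_samples <= r_star))
  samples <- tibble::tibble(
    sample = seq_len(n_samp),
    sweep = run$n_equil + seq_len(n_samp) * run$sample_stride,
    energy = res$energies,
    n_condensed = n_cond)
  acc <- tibble::tibble(
    move = c("local", "centrifugal", "swap"),
    attempted = res$acceptance[, 1],
    accepted = res$acceptance[, 2],
    rate = ifelse(res$acceptance[, 1] > 0,
                  res$acceptance[, 2] / res$acceptance[, 1], NA_real_))
  hist <- bin_log_radii(res$r_samples, model, n_bins = 100L)
  structure(list(
    samples = samples,
    r_samples = res$r_samples,
    histogram = tibble::tibble(ln_r_over_R_lo = hist$lo,
                               ln_r_over_R_hi = hist$hi,
                               count = hist$total),
    acceptance = acc,
    model = model, run = run, lekner = lekner, seed = run$seed,
    final = tibble::tibble(r = res$final_r, theta = res$final_theta,
                           z = res$final_z),
    step_local_final = res$step_local_final,
    energy_check = c(cached = res$energy_cached,
                     recomputed = res$energy_recomputed)),
    class = "cylcond_chain")
}

# per-sample bin counts of ln(r/R) over [0, Delta]; returns edges, the
# samples x bins count matrix and the accumulated total
bin_log_radii <- function(r_samples, model, n_bins) {
  x <- log(r_samples / model$R)
  edges <- seq(0, model$delta, length.out = n_bins + 1)
  idx <- pmin(pmax(floor(x / model$delta * n_bins) + 1L, 1L), n_bins)
  counts <- t(apply(idx, 1, tabulate, nbins = n_bins))
  if (n_bins == 1) counts <- matrix(counts, ncol = 1)
  list(lo = edges[-(n_bins + 1)], hi = edges[-1], counts = counts,
       total = colSums(counts))
}

#' @export
print.cylcond_chain <- function(x, ...) {
  cat("<cylcond_chain> N =", x$model$N, " xi =", format(x$model$xi),
      " Delta =", format(x$model$delta), " seed =", x$seed, "\n")
  cat("  samples:", nrow(x$samples), " (stride", x$run$sample_stride, "sweeps)\n")
  r <- x$acceptance
  cat("  acceptance:", paste(sprintf("%s %.2f", r$move, r$rate), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname run_chain
#' @param x,... A `cylcond_chain` and unused arguments, for the `tidy` method.
#' @export
tidy.cylcond_chain <- function(x, ...) x$samples

#' @rdname run_chain
#' @export
glance.cylcond_chain <- function(x, ...) summarize_chain(x)
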