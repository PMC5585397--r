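#' Run a Manning-parameter sweep
#'
#' Orchestrates one chain per Manning parameter at fixed radius-shrinking
#' exponent `alpha`, lateral extension `Delta` and ion count `N` (the
#' cylinder radius follows `ln(R/a) = -alpha Delta/(alpha+1)`, see
#' [radius_from_alpha()]), and aggregates the condensed fraction and heat
#' capacity per point. Chain seeds are derived from `seed` by offsetting by
#' the point index. Failures at individual grid points are recorded in the
#' `error` column and do not stop the sweep.
#'
#' @param xis Manning parameters to sweep.
#' @param alpha Radius-shrinking exponent.
#' @param delta Lateral extension.
#' @param N Number of counterions.
#' @param n_equil,n_prod,sample_stride,move_mix,step_local See [run_config()].
#' @param seed Base seed.
#' @param lekner A [lekner_params()].
#' @param init Initial state per chain.
#' @param out_dir Optional directory: each chain is written as a CSV
#'   sub-directory plus manifest, along with an aggregated `summary.csv`.
#' @param keep_chains Keep the full chain objects in a list-column?
#' @param verbose Emit a progress line per grid point?
#' @return A tibble with one row per `xi`: `xi`, `f`, `f_err`, `C_tilde`,
#'   `C_err`, `n_samples`, `seed`, `error` (and a `chain` list-column when
#'   `keep_chains = TRUE`).
#' @export
run_experiment_grid <- function(xis, alpha, delta, N,
                                n_equil = 2000L, n_prod = 10000L,
                                sample_stride = 10L,
                                move_mix = c(0.6, 0.3, 0.1),
                                step_local = 1,
                                seed = 1L, lekner = lekner_params(),
                                init = "log_uniform",
                                out_dir = NULL, keep_chains = FALSE,
                                verbose = FALSE) {
  rows <- vector("list", length(xis))
  chains <- vector("list", length(xis))
  for (i in seq_along(xis)) {
    pt_seed <- as.integer((seed + i - 1L) %% .Machine$integer.max)
    if (verbose)
      message(sprintf("[info] grid point %d/%d: xi = %g, seed = %d",
                      i, length(xis), xis[i], pt_seed))
    rows[[i]] <- tryCatch({
      model <- cell_model(N = N, xi = xis[i], delta = delta, alpha = alpha)
      run <- run_config(n_equil = n_equil, n_prod = n_prod,
                        sample_stride = sample_stride, move_mix = move_mix,
                        step_local = step_local, seed = pt_seed)
      ch <- run_chain(model, run, lekner = lekner, init = init)
      if (keep_chains) chains[[i]] <- ch
      if (!is.null(out_dir)) {
        d <- file.path(out_dir, sprintf("xi_%g", xis[i]))
        write_chain_result(ch, d)
      }
      s <- summarize_chain(ch)
      tibble::tibble(xi = xis[i], f = s$f, f_err = s$f_err,
                     C_tilde = s$C_tilde, C_err = s$C_err,
                     n_samples = s$n_samples, seed = pt_seed,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(xi = xis[i], f = NA_real_, f_err = NA_real_,
                     C_tilde = NA_real_, C_err = NA_real_,
                     n_samples = 0L, seed = pt_seed,
                     error = conditionMessage(e))
    })
  }
  out <- purrr::list_rbind(rows)
  if (keep_chains) out$chain <- chains
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out[setdiff(names(out), "chain")],
              file.path(out_dir, "summary.csv"), row.names = FALSE)
    write_manifest(out_dir, command = "grid",
                   params = list(xis = xis, alpha = alpha, delta = delta,
                                 N = N, n_equil = n_equil, n_prod = n_prod,
                                 sample_stride = sample_stride,
                                 move_mix = move_mix, seed = seed),
                   files = file.path(out_dir, "summary.csv"))
  }
  out
}

write_manifest <- function(dir, command, params, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    tool = "cylcond",
    version = as.character(packageVersion("cylcond")),
    command = command,
    params = params,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    units = list(length = "a = q/tau", energy = "k_B T"),
    digests = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a chain result as a directory of CSV files plus a JSON manifest
#'
#' Writes `energies.csv` (sample, energy in k_B T), `counts.csv` (sample,
#' condensed count), `histogram.csv` (accumulated `ln(r/R)` histogram),
#' `r_samples.csv` (per-sample radial coordinates, units of `a`) and
#' `manifest.json` (versions, full parameter echo, seed, timestamps, file
#' digests). Re-running with the recorded seed reproduces the CSV files
#' bit-identically.
#'
#' @param chain A [run_chain()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chain_result <- function(chain, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(sample = chain$samples$sample,
                       energy_kBT = chain$samples$energy),
            file.path(dir, "energies.csv"), row.names = FALSE)
  write.csv(data.frame(sample = chain$samples$sample,
                       n_condensed = chain$samples$n_condensed),
            file.path(dir, "counts.csv"), row.names = FALSE)
  write.csv(data.frame(ln_r_over_R_lo = chain$histogram$ln_r_over_R_lo,
                       ln_r_over_R_hi = chain$histogram$ln_r_over_R_hi,
                       count = chain$histogram$count),
            file.path(dir, "histogram.csv"), row.names = FALSE)
  rs <- as.data.frame(chain$r_samples)
  names(rs) <- paste0("r_over_a_ion", seq_len(ncol(rs)))
  write.csv(rs, file.path(dir, "r_samples.csv"), row.names = FALSE)
  m <- chain$model
  write_manifest(dir, command = "simulate",
                 params = list(model = m[c("N", "xi", "R", "D", "delta",
                                           "H", "Xi", "mu", "alpha")],
                               run = unclass(chain$run),
                               lekner = unclass(chain$lekner),
                               seed = chain$seed,
                               step_local_final = chain$step_local_final),
                 files = file.path(dir, c("energies.csv", "counts.csv",
                                          "histogram.csv", "r_samples.csv")))
  invisible(dir)
}

#' Read a chain result directory back
#'
#' Reconstructs a `cylcond_chain` object (model, samples, histogram,
#' radial samples) from a directory written by [write_chain_result()];
#' observables ([summarize_chain()], [radial_profile()]) work on the result.
#'
#' @param dir Directory written by [write_chain_result()].
#' @return A `cylcond_chain` object.
#' @export
read_chain_result <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  p <- man$params
  model <- cell_model(N = p$model$N, xi = p$model$xi,
                      R = p$model$R, D = p$model$D)
  en <- read.csv(file.path(dir, "energies.csv"))
  ct <- read.csv(file.path(dir, "counts.csv"))
  hist <- read.csv(file.path(dir, "histogram.csv"))
  rs <- as.matrix(read.csv(file.path(dir, "r_samples.csv")))
  dimnames(rs) <- NULL
  run <- run_config(n_equil = p$run$n_equil, n_prod = p$run$n_prod,
                    sample_stride = p$run$sample_stride,
                    move_mix = unlist(p$run$move_mix),
                    step_local = p$run$step_local, seed = p$run$seed,
                    tune_step = p$run$tune_step)
  structure(list(
    samples = tibble::tibble(sample = en$sample,
                             sweep = run$n_equil +
                               en$sample * run$sample_stride,
                             energy = en$energy_kBT,
                             n_condensed = ct$n_condensed),
    r_samples = rs,
    histogram = tibble::as_tibble(hist),
    acceptance = NULL,
    model = model, run = run,
    lekner = do.call(lekner_params, as.list(p$lekner)),
    seed = p$seed, final = NULL,
    step_local_final = p$step_local_final,
    energy_check = NULL), class = "cylcond_chain")
}
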