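#' Assemble a finite-size scaling dataset
#'
#' Collects order-parameter measurements `m` (the condensed fraction
#' `f = m_1` near the Manning transition, or `1 - f = m_2` near the
#' complete-condensation transition) at several lateral extensions `Delta`
#' and Manning parameters `xi`, together with the critical point `xi_c` used
#' to form the reduced Manning parameter `zeta = 1 - xi_c / xi`.
#'
#' @param data A data frame with columns `delta`, `xi`, `m`, `m_err` (and
#'   optionally `k`, the transition branch label, defaulting to 1).
#' @param xi_c The critical Manning parameter (fixed at the theoretical
#'   value, e.g. 1 for the Manning transition or `1 + 1/alpha` for complete
#'   condensation, matching standard usage; it is not fitted).
#' @return A tibble of class `scaling_dataset` with an added `zeta` column
#'   and attribute `xi_c`.
#' @export
scaling_dataset <- function(data, xi_c) {
  stopifnot(is.data.frame(data),
            all(c("delta", "xi", "m", "m_err") %in% names(data)),
            is.numeric(xi_c), length(xi_c) == 1)
  d <- tibble::as_tibble(data)
  if (!"k" %in% names(d)) d$k <- 1L
  if (any(d$m < 0 | d$m > 1)) stop("order parameter m must lie in [0, 1]")
  if (any(d$m_err <= 0)) stop("m_err must be positive")
  d$zeta <- 1 - xi_c / d$xi
  structure(d, xi_c = xi_c, class = c("scaling_dataset", class(d)))
}

#' Power-law exponent ratio from the size dependence at criticality
#'
#' At the critical point the order parameter decays with the system size as
#' `m ~ Delta^(-beta/nu)`. This fits a weighted least-squares line to
#' `ln m` versus `ln Delta` at `xi = at_xi` (records are linearly
#' interpolated in `xi` within each `Delta` when no exact match exists) and
#' returns the sign-flipped slope with a parametric bootstrap error
#' (resampling `m` from its reported Gaussian error, appropriate when each
#' size contributes a single point).
#'
#' @param dataset A [scaling_dataset()].
#' @param at_xi Manning parameter at which the decay is evaluated.
#' @param n_boot Bootstrap replicates.
#' @return A tibble with `beta_over_nu`, `err`, `n_deltas`.
#' @export
exponent_ratio_fit <- function(dataset, at_xi, n_boot = 200L) {
  stopifnot(inherits(dataset, "scaling_dataset"))
  pts <- dataset |>
    dplyr::group_by(.data$delta) |>
    dplyr::group_modify(function(g, key) {
      if (any(abs(g$xi - at_xi) < 1e-10)) {
        g[which.min(abs(g$xi - at_xi)), c("m", "m_err")]
      } else if (min(g$xi) <= at_xi && max(g$xi) >= at_xi && nrow(g) >= 2) {
        tibble::tibble(m = approx(g$xi, g$m, at_xi)$y,
                       m_err = approx(g$xi, g$m_err, at_xi)$y)
      } else {
        tibble::tibble(m = NA_real_, m_err = NA_real_)
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$m), .data$m > 0)
  if (nrow(pts) < 3)
    stop("need data at >= 3 lateral extensions at (or bracketing) at_xi")
  fit_slope <- function(m) {
    ok <- m > 0
    w <- (pts$m[ok] / pts$m_err[ok])^2
    -unname(coef(lm(log(m[ok]) ~ log(pts$delta[ok]), weights = w))[2])
  }
  est <- fit_slope(pts$m)
  boot <- vapply(seq_len(n_boot), function(b) {
    mb <- rnorm(nrow(pts), pts$m, pts$m_err)
    if (sum(mb > 0) < 3) return(NA_real_)
    fit_slope(mb)
  }, numeric(1))
  tibble::tibble(beta_over_nu = est, err = sd(boot, na.rm = TRUE),
                 n_deltas = nrow(pts))
}

# Master-curve objective: transform records to (u, w) = (Delta^{1/nu} zeta,
# Delta^{beta/nu} m), fit an error-weighted local-polynomial master curve to
# ln(w) against u with leave-one-out prediction, and return the chi^2-style
# mean squared standardized residual, minimized over the bandwidth grid
# when more than one bandwidth is offered (the leave-one-out error is
# itself the cross-validation criterion). The fit is on the log scale
# because the scaling function decays exponentially in its tails and the
# order-parameter errors are essentially relative; records with m = 0 carry
# no usable constraint on the log master curve and are dropped here.
# Degree 2 (local quadratic) is the default: it has markedly smaller
# smoothing bias than local-linear at the bandwidths the sparse tails
# require. The fit degrades gracefully to linear/constant where the kernel
# support cannot sustain the higher degree (coincident or isolated points).
collapse_objective <- function(beta, nu, delta, zeta, m, m_err,
                               h_frac = c(0.002, 0.02, 0.05, 0.12),
                               degree = 2L, return_fit = FALSE) {
  keep <- m > 0
  delta <- delta[keep]; zeta <- zeta[keep]
  m_err <- m_err[keep]; m <- m[keep]
  s <- beta / nu
  u <- delta^(1 / nu) * zeta
  w <- log(delta^s * m)           # log-scale master curve
  we <- m_err / m                 # relative error of m = absolute error of w
  n <- length(u)
  if (n < 4) return(Inf)
  rng <- diff(range(u))
  if (rng <= 0) return(Inf)
  Du <- outer(u, u, "-")          # Du[i, j] = u_i - u_j
  iw <- 1 / we^2
  best <- Inf; best_pred <- NULL; best_h <- NA_real_
  for (h in h_frac * rng) {
    # moment sums in the scaled offset d = (u_j - u_i)/h, leave-one-out
    Dh <- -Du / h                 # Dh[i, j] = (u_j - u_i)/h
    K <- exp(-Dh^2)
    diag(K) <- 0
    KW <- sweep(K, 2, iw, `*`)    # kernel * error weights, by source point j
    S0 <- KW %*% rep(1, n)
    S1 <- (KW * Dh) %*% rep(1, n)
    S2 <- (KW * Dh^2) %*% rep(1, n)
    T0 <- KW %*% w
    T1 <- (KW * Dh) %*% w
    pred <- rep(NA_real_, n)
    den_lin <- S0 * S2 - S1^2
    if (degree >= 2L) {
      S3 <- (KW * Dh^3) %*% rep(1, n)
      S4 <- (KW * Dh^4) %*% rep(1, n)
      T2 <- (KW * Dh^2) %*% w
      det3 <- S0 * (S2 * S4 - S3^2) - S1 * (S1 * S4 - S3 * S2) +
              S2 * (S1 * S3 - S2^2)
      num3 <- T0 * (S2 * S4 - S3^2) - S1 * (T1 * S4 - S3 * T2) +
              S2 * (T1 * S3 - S2 * T2)
      ok2 <- is.finite(det3) & det3 > 1e-11 * pmax(S0, 0)^3
      pred[ok2] <- (num3 / det3)[ok2]
    }
    ok1 <- is.na(pred) & is.finite(den_lin) & den_lin > 1e-11 * pmax(S0, 0)^2
    pred[ok1] <- ((S2 * T0 - S1 * T1) / den_lin)[ok1]
    ok0 <- is.na(pred) & S0 > 0
    pred[ok0] <- (T0 / S0)[ok0]
    # isolated points (all kernel weights underflow): nearest neighbour
    if (anyNA(pred)) {
      for (i in which(is.na(pred))) {
        others <- setdiff(seq_len(n), i)
        pred[i] <- w[others[which.min(abs(u[others] - u[i]))]]
      }
    }
    obj <- mean(((w - pred) / we)^2)
    if (is.finite(obj) && obj < best) {
      best <- obj; best_pred <- as.numeric(pred); best_h <- h
    }
  }
  if (return_fit)
    list(objective = best, keep = keep, u = u,
         w = exp(w), w_err = exp(w) * we,      # back on the linear scale
         fitted = exp(best_pred), bandwidth = best_h)
  else best
}

#' Two-parameter finite-size data collapse
#'
#' Finds the critical exponents `(beta, nu)` for which the order-parameter
#' data obey the finite-size scaling form
#' \deqn{m_k = \Delta^{-\beta/\nu}\,\tilde m_k(\Delta^{1/\nu}\zeta_k),}
#' i.e. collapse onto a single master curve \eqn{\tilde m_k}. For trial
#' exponents all records are transformed to
#' `(u, w) = (Delta^{1/nu} zeta, Delta^{beta/nu} m)` and an error-weighted
#' local-quadratic master curve is fit to `ln w` against `u` (the scaling
#' function decays exponentially in its tails and order-parameter errors
#' are essentially relative; zero-`m` records are excluded from the fit);
#' the objective is the leave-one-out mean squared standardized residual,
#' with the kernel bandwidth chosen by the same leave-one-out criterion at
#' each trial pair. A coarse grid search is
#' refined by Nelder-Mead, and errors come from bootstrap resampling of
#' records with replacement.
#'
#' @param dataset A [scaling_dataset()].
#' @param beta_range,nu_range Search intervals for the exponents.
#' @param grid_n Coarse-grid resolution per axis.
#' @param n_boot Bootstrap replicates (default 200).
#' @param h_frac Kernel bandwidth(s) as a fraction of the transformed
#'   scaling-variable range. The default is a single fixed value (0.12,
#'   paired with the local-quadratic master-curve fit) calibrated on
#'   synthetic recovery: selecting the bandwidth anew at each trial pair
#'   makes the objective landscape ragged, inflates the estimator scatter
#'   and biases the exponents upward through oversmoothing. Passing a
#'   vector re-enables leave-one-out selection over that grid.
#' @param fit_xi_c Also fit the critical point? Off by default: `xi_c` is
#'   normally held at its theoretical value (1 for the Manning transition,
#'   `1 + 1/alpha` for complete condensation).
#' @return An object of class `collapse_result` with elements `beta`, `nu`,
#'   `beta_err`, `nu_err`, `objective`, `bandwidth`, `master_curve` (tibble
#'   of transformed points with the fitted curve) and `boot` (bootstrap
#'   draws). `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
data_collapse <- function(dataset, beta_range = c(0.4, 1.6),
                          nu_range = c(0.6, 2.0), grid_n = 7L,
                          n_boot = 200L, h_frac = 0.12, fit_xi_c = FALSE) {
  stopifnot(inherits(dataset, "scaling_dataset"))
  d <- dataset
  xi_c0 <- attr(dataset, "xi_c")
  if (length(unique(d$delta)) < 3) stop("need >= 3 distinct lateral extensions")
  obj <- function(par, dd = d) {
    if (par[1] <= 0 || par[2] <= 0) return(Inf)
    zeta <- if (length(par) >= 3) 1 - par[3] / dd$xi else dd$zeta
    collapse_objective(par[1], par[2], dd$delta, zeta, dd$m, dd$m_err,
                       h_frac = h_frac)
  }
  grid <- tidyr::expand_grid(beta = seq(beta_range[1], beta_range[2],
                                        length.out = grid_n),
                             nu = seq(nu_range[1], nu_range[2],
                                      length.out = grid_n))
  grid$value <- purrr::map2_dbl(grid$beta, grid$nu, function(b, n) obj(c(b, n)))
  start <- unlist(grid[which.min(grid$value), c("beta", "nu")])
  if (fit_xi_c) start <- c(start, xi_c = xi_c0)
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-10))
  xi_c_hat <- if (fit_xi_c) unname(fit$par[3]) else xi_c0
  if (fit_xi_c) d$zeta <- 1 - xi_c_hat / d$xi
  # overlap check at the optimum: some pair of sizes must share u-range
  u <- d$delta^(1 / fit$par[2]) * d$zeta
  rng <- vapply(split(u, d$delta), range, numeric(2))
  overlap <- FALSE
  for (i in seq_len(ncol(rng))) for (j in seq_len(ncol(rng)))
    if (i != j && rng[1, i] <= rng[2, j] && rng[1, j] <= rng[2, i])
      overlap <- TRUE
  if (!overlap)
    stop("transformed scaling-variable ranges do not overlap; ",
         "use wider xi windows per Delta")
  boot <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(d), replace = TRUE)
    if (length(unique(d$delta[idx])) < 3) next
    db <- d[idx, ]
    fb <- optim(fit$par, obj, dd = db, method = "Nelder-Mead",
                control = list(maxit = 60, reltol = 1e-6))
    boot[b, ] <- fb$par[1:2]
  }
  final <- collapse_objective(fit$par[1], fit$par[2], d$delta, d$zeta,
                              d$m, d$m_err, h_frac = h_frac,
                              return_fit = TRUE)
  dk <- d[final$keep, ]
  mc <- tibble::tibble(delta = dk$delta, xi = dk$xi, k = dk$k,
                       u = final$u, w = final$w, w_err = final$w_err,
                       fitted = final$fitted)
  structure(list(beta = unname(fit$par[1]), nu = unname(fit$par[2]),
                 beta_err = sd(boot[, 1], na.rm = TRUE),
                 nu_err = sd(boot[, 2], na.rm = TRUE),
                 objective = final$objective, bandwidth = final$bandwidth,
                 master_curve = mc,
                 boot = tibble::tibble(beta = boot[, 1], nu = boot[, 2]),
                 grid = grid, xi_c = xi_c_hat),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat("<collapse_result>\n")
  cat(sprintf("  beta = %.4f +/- %.4f\n", x$beta, x$beta_err))
  cat(sprintf("  nu   = %.4f +/- %.4f\n", x$nu, x$nu_err))
  cat(sprintf("  objective = %.4g (bandwidth %.4g)\n", x$objective, x$bandwidth))
  invisible(x)
}

#' @rdname data_collapse
#' @param x,... A `collapse_result`, further arguments ignored.
#' @export
tidy.collapse_result <- function(x, ...) {
  tibble::tibble(term = c("beta", "nu"),
                 estimate = c(x$beta, x$nu),
                 std.error = c(x$beta_err, x$nu_err))
}

#' @rdname data_collapse
#' @export
glance.collapse_result <- function(x, ...) {
  tibble::tibble(objective = x$objective, bandwidth = x$bandwidth,
                 n_records = nrow(x$master_curve),
                 n_boot = sum(!is.na(x$boot$beta)))
}
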