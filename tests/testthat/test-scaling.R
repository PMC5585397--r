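test_that("exponent ratio fit recovers noiseless power laws exactly", {
  d <- tibble::tibble(delta = c(20, 40, 60, 80, 100), xi = 1,
                      m = delta^(-0.9), m_err = 1e-3 * m)
  fit <- exponent_ratio_fit(scaling_dataset(d, xi_c = 2), at_xi = 1,
                            n_boot = 50)
  expect_equal(fit$beta_over_nu, 0.9, tolerance = 1e-12)
  dc <- tibble::tibble(delta = c(10, 30, 90), xi = 1, m = 0.4, m_err = 0.01)
  fitc <- exponent_ratio_fit(scaling_dataset(dc, xi_c = 2), at_xi = 1,
                             n_boot = 50)
  expect_equal(fitc$beta_over_nu, 0, tolerance = 1e-12)
  expect_error(exponent_ratio_fit(
    scaling_dataset(dc[1:2, ], xi_c = 2), at_xi = 1), "3 lateral")
})

test_that("exponent ratio fit recovers noisy synthetic decays with coverage", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    deltas <- c(20, 40, 60, 80, 100)
    m_true <- deltas^(-0.88)
    m <- m_true * (1 + rnorm(5, 0, 0.02))
    d <- tibble::tibble(delta = deltas, xi = 1, m = m, m_err = 0.02 * m_true)
    fit <- exponent_ratio_fit(scaling_dataset(d, xi_c = 2), at_xi = 1,
                              n_boot = 200)
    if (abs(fit$beta_over_nu - 0.88) <= 2 * fit$err) hits <- hits + 1
  }
  expect_gte(hits, 17)  # ~95% nominal coverage, allow fluctuation
})

test_that("perfectly collapsed noiseless data give a vanishing objective", {
  syn <- synthetic_collapse_data(0.98, 1.11, 1, c(20, 40, 60, 80, 100),
                                 noise_sd = 0, seed = 5,
                                 u_grid = seq(-2, 2, by = 0.25))
  obj <- cylcond:::collapse_objective(0.98, 1.11, syn$delta, syn$zeta,
                                      syn$m, syn$m_err)
  expect_lt(obj, 1e-20)
})

test_that("data collapse recovers known exponents within bootstrap errors", {
  syn <- synthetic_collapse_data(0.98, 1.11, 1, c(20, 40, 60, 80, 100),
                                 xi_grid = seq(0.90, 1.14, by = 0.02),
                                 noise_sd = 0.03, seed = 42)
  cr <- data_collapse(syn, n_boot = 80)
  expect_lt(abs(cr$beta - 0.98), 2 * cr$beta_err)
  expect_lt(abs(cr$nu - 1.11), 2 * cr$nu_err)
  # objective at the true exponents is close to the optimum
  obj_true <- cylcond:::collapse_objective(0.98, 1.11, syn$delta, syn$zeta,
                                           syn$m, syn$m_err, h_frac = 0.12)
  expect_lt(obj_true, 1.5 * cr$objective + 0.5)
  td <- tidy(cr)
  expect_identical(td$term, c("beta", "nu"))
  expect_identical(td$estimate, c(cr$beta, cr$nu))
})

test_that("scrambled labels destroy the collapse (negative control)", {
  syn <- synthetic_collapse_data(0.98, 1.11, 1, c(20, 40, 60, 80, 100),
                                 xi_grid = seq(0.90, 1.14, by = 0.02),
                                 noise_sd = 0.03, seed = 42)
  set.seed(99)
  scr <- syn
  scr$zeta <- sample(scr$zeta)
  obj_scr <- cylcond:::collapse_objective(0.98, 1.11, scr$delta, scr$zeta,
                                          scr$m, scr$m_err, h_frac = 0.12)
  obj_true <- cylcond:::collapse_objective(0.98, 1.11, syn$delta, syn$zeta,
                                           syn$m, syn$m_err, h_frac = 0.12)
  expect_gt(obj_scr, 20 * obj_true)
})

test_that("objective is invariant under record order and joint rescaling", {
  syn <- synthetic_collapse_data(0.98, 1.11, 1, c(20, 50, 100),
                                 xi_grid = seq(0.92, 1.12, by = 0.04),
                                 noise_sd = 0.02, seed = 3)
  o1 <- cylcond:::collapse_objective(1, 1.2, syn$delta, syn$zeta,
                                     syn$m, syn$m_err, h_frac = 0.12)
  set.seed(1); idx <- sample(nrow(syn))
  o2 <- cylcond:::collapse_objective(1, 1.2, syn$delta[idx], syn$zeta[idx],
                                     syn$m[idx], syn$m_err[idx], h_frac = 0.12)
  expect_equal(o1, o2, tolerance = 1e-8)
  o3 <- cylcond:::collapse_objective(1, 1.2, syn$delta, syn$zeta,
                                     0.5 * syn$m, 0.5 * syn$m_err,
                                     h_frac = 0.12)
  expect_equal(o1, o3, tolerance = 1e-10)
})

test_that("collapse beta/nu is consistent with the direct decay fit", {
  syn <- synthetic_collapse_data(0.98, 1.11, 1, c(20, 40, 60, 80, 100),
                                 xi_grid = c(seq(0.92, 1.12, by = 0.02), 1),
                                 noise_sd = 0.02, seed = 7)
  cr <- data_collapse(syn, n_boot = 60)
  erf <- exponent_ratio_fit(syn, at_xi = 1, n_boot = 100)
  ratio_err <- cr$beta / cr$nu *
    sqrt((cr$beta_err / cr$beta)^2 + (cr$nu_err / cr$nu)^2)
  expect_lt(abs(cr$beta / cr$nu - erf$beta_over_nu),
            3 * sqrt(ratio_err^2 + erf$err^2))
})

test_that("optional critical-point fit stays near the imposed value", {
  syn <- synthetic_collapse_data(0.98, 1.11, 1, c(20, 40, 60, 80, 100),
                                 xi_grid = seq(0.90, 1.14, by = 0.02),
                                 noise_sd = 0.03, seed = 11)
  cr <- data_collapse(syn, n_boot = 10, fit_xi_c = TRUE)
  expect_lt(abs(cr$xi_c - 1), 0.05)
  expect_lt(abs(cr$beta - 0.98), 0.15)
})

test_that("degenerate datasets are rejected with informative errors", {
  d <- tibble::tibble(delta = c(20, 40), xi = 1, m = 0.5, m_err = 0.01)
  expect_error(data_collapse(scaling_dataset(d, 1)), "3 distinct")
  bad <- tibble::tibble(delta = 20, xi = 1, m = 1.5, m_err = 0.1)
  expect_error(scaling_dataset(bad, 1), "\\[0, 1\\]")
})
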