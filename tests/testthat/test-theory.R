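test_that("PB solution satisfies the Gauss-law boundary identities", {
  for (xi in c(0.7, 1.3, 2)) {
    s <- pb_solve(xi, 8)
    expect_equal(s$condensed_fraction_at(1), 0, tolerance = 1e-8)
    expect_equal(s$condensed_fraction_at(exp(8)), 1, tolerance = 1e-8)
    expect_true(all(diff(s$grid$f) > -1e-9))  # monotone accumulation
  }
})

test_that("PB solver matches the closed-form cell-model solution", {
  for (case in list(c(2, 10), c(3, 7), c(1.5, 12))) {
    xi <- case[1]; delta <- case[2]
    expect_equal(pb_midpoint_fraction(xi, delta),
                 cylcond:::pb_fraction_exact(xi, delta), tolerance = 1e-6)
  }
})

test_that("PB midpoint fraction approaches the Manning limit at large cells", {
  expect_equal(pb_midpoint_fraction(2, 40), 1 - 1 / 2, tolerance = 1e-2)
  expect_lt(pb_midpoint_fraction(0.5, 40), 0.05)
  # below threshold the fraction keeps decreasing with cell size
  expect_lt(pb_midpoint_fraction(0.5, 40), pb_midpoint_fraction(0.5, 10))
})

test_that("strong-coupling two-state fraction flips at the Manning threshold", {
  expect_identical(sc_netz_fraction(0.9), 0)
  expect_identical(sc_netz_fraction(1.1), 1)
  expect_identical(sc_netz_fraction(1.1) - sc_netz_fraction(0.9), 1)
  expect_error(sc_netz_fraction(1), "undefined")
})

test_that("strong-coupling profile is a neutrality-normalized power law", {
  xi <- 2; delta <- 5
  prof <- sc_netz_profile(xi, delta)
  r <- c(1, 2, 5, 20)
  expect_equal(diff(log(prof(r))) / diff(log(r)), rep(-2 * xi, 3),
               tolerance = 1e-12)
  expect_equal(prof(2) / prof(1), 2^(-4), tolerance = 1e-12)
  # neutrality: xi * integral r rho_tilde dr over the cell equals 1
  I <- integrate(function(s) s * prof(s), 1, exp(delta), rel.tol = 1e-12)
  expect_equal(xi * I$value, 1, tolerance = 1e-10)
})

test_that("needle-limit profile has the printed contact value and decay", {
  expect_identical(needle_profile(2, 1), 0.5)
  expect_equal(needle_profile(2, 2), 0.5 * 2^(-4))
  expect_lt(needle_profile(1 + 1e-8, 1), 1e-14)  # evaporation as xi -> 1+
  expect_error(needle_profile(0.9, 1), "xi > 1")
  # integrates to the Manning fraction 1 - 1/xi of neutralization
  for (xi in c(1.5, 2, 3)) {
    I <- integrate(function(s) xi * s * needle_profile(xi, s), 1, Inf,
                   rel.tol = 1e-10)
    expect_equal(I$value, 1 - 1 / xi, tolerance = 1e-8)
  }
})

test_that("complete-condensation onset formulas agree and take limits", {
  expect_identical(xi2_of_alpha(1), 2)
  expect_identical(xi2_of_alpha(Inf), 1)
  expect_equal(xi2_of_alpha(0.25), 5)
  expect_identical(xi2_of_alpha(0), Inf)
  expect_error(xi2_of_alpha(-1), "nonnegative")
  # radii form
  expect_equal(xi2_of_radii(exp(-4), exp(1)), 1.25)
  expect_equal(xi2_of_radii(0.5, 2), 2)
  for (D in c(2, 10, 1e5)) for (a in c(0.3, 1, 4))
    expect_equal(xi2_of_radii(D^(-a), D), xi2_of_alpha(a), tolerance = 1e-12)
  expect_error(xi2_of_radii(1.2, 2), "R_tilde")
})

test_that("coupling at the second transition has the right magnitudes", {
  expect_equal(log10(coupling_at_xi2(5, 100)), 10, tolerance = 0.5)
  expect_equal(coupling_at_xi2(1, 7), exp(7))
  expect_equal(coupling_at_xi2(20, 100), 400 * exp(5), tolerance = 1e-12)
})

test_that("radius shrinking schedule and coupling are consistent", {
  expect_equal(radius_from_alpha(1, 100), -50)
  expect_identical(radius_from_alpha(0, 10), 0)
  expect_equal(radius_from_alpha(Inf, 10), -10)
  # finite schedule prefactor c shifts ln R but preserves Delta = ln(D/R)
  lnR <- radius_from_alpha(1, 100, c = exp(2))
  expect_equal(lnR, (2 - 100) / 2)
  # and the implied outer radius still satisfies R = c D^(-alpha)
  lnD <- lnR + 100
  expect_equal(lnR, 2 - 1 * lnD)
  # Xi = xi^2 exp(-ln R/a) at xi = xi2(alpha) tracks the onset coupling
  for (alpha in c(0.2, 0.5, 1, 2, 5)) {
    delta <- 100
    xi2 <- xi2_of_alpha(alpha)
    Xi_model <- xi2^2 * exp(-radius_from_alpha(alpha, delta))
    expect_lt(abs(log(Xi_model / coupling_at_xi2(xi2, delta))), log(2))
  }
})

test_that("lattice energies of the two-configuration argument", {
  le <- lattice_energies(2, 1, 10)
  expect_equal(le$U_a, 2)
  # D/H -> 0 collapses the escaped-ion sum back onto the lattice sum
  le0 <- lattice_energies(50, 1.3, 1e-12)
  expect_equal(le0$U_b, le0$U_a, tolerance = 1e-10)
  # the image-summed difference used in the free-energy argument converges
  # onto 2 xi (ln x + gamma - ln 2) with x = N D / H
  xi <- 1; x <- 1000 * 10
  S <- harmonic_sum_approx_check(x)$partial_sum
  expect_equal(2 * xi * S, 2 * xi * (log(x) - 0.115932), tolerance = 1e-4)
})

test_that("free-energy difference favors complete condensation above xi2", {
  N <- 1000; R <- exp(-50); D <- exp(50)
  root_asym <- complete_condensation_root(N, R, D, form = "asymptotic")
  expect_equal(root_asym, xi2_of_radii(R, D), tolerance = 1e-8)
  root_exact <- complete_condensation_root(N, R, D, form = "exact")
  expect_lt(abs(root_exact - 2) / 2, 0.05)
  fd <- free_energy_difference(N, root_asym + 0.1, R, D)
  expect_gt(fd$delta_F_asymptotic, 0)
  fd2 <- free_energy_difference(N, root_asym - 0.1, R, D)
  expect_lt(fd2$delta_F_asymptotic, 0)
})

test_that("harmonic-sum approximation converges to ln x at large x", {
  h <- harmonic_sum_approx_check(100)
  # converged value is ln x + gamma - ln 2 + O(1/x); direct-sum oracle at
  # cutoff 1e7 gives 4.494239
  expect_equal(h$partial_sum, 4.494239, tolerance = 1e-6)
  expect_lt(abs(h$partial_sum - h$ln_x) / h$ln_x, 0.03)
  # relative error of the ln x approximation shrinks with x
  h2 <- harmonic_sum_approx_check(1e6)
  expect_lt(abs(h2$partial_sum - h2$ln_x) / h2$ln_x, 0.01)
  # O(1) error exposed at x = 1
  h1 <- harmonic_sum_approx_check(1)
  expect_true(is.finite(h1$partial_sum))
  expect_gt(abs(h1$partial_sum - h1$ln_x), 0.1)
  # deviation stays bounded over a wide sweep
  for (x in c(10, 1e3, 1e6)) {
    hh <- harmonic_sum_approx_check(x)
    expect_lt(abs(hh$partial_sum - hh$ln_x), 1)
  }
})
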