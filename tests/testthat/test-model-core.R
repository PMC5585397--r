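lp <- lekner_params()

test_that("cell model geometry and coupling relations are consistent", {
  m <- cell_model(N = 30, xi = 2, delta = 10, alpha = 1)
  expect_equal(m$delta, log(m$D / m$R))
  expect_identical(m$H, 30)
  expect_equal(m$Xi * m$R, m$xi^2)
  expect_equal(m$mu * m$xi, m$R)
  expect_equal(log(m$R), -1 * 10 / 2)   # ln R = -alpha Delta / (alpha + 1)
  m2 <- cell_model(N = 10, xi = 1.5, R = 1, D = exp(3))
  expect_equal(m2$delta, 3)
  expect_error(cell_model(N = 5, xi = 1, R = 2, D = 1), "delta|geometry|> R")
})

test_that("pair potential is even and periodic in the axial separation", {
  for (H in c(1, 7)) {
    rho <- c(0.1, 0.3, 0.8, 2.5) * H
    zeta <- c(0.05, 0.2, 0.45) * H
    g <- expand.grid(rho = rho, zeta = zeta)
    v0 <- pair_potential(g$rho, g$zeta, H, lp)
    expect_equal(pair_potential(g$rho, -g$zeta, H, lp), v0, tolerance = 1e-12)
    expect_equal(pair_potential(g$rho, g$zeta + H, H, lp), v0, tolerance = 1e-12)
    expect_equal(pair_potential(g$rho, g$zeta - 3 * H, H, lp), v0,
                 tolerance = 1e-12)
  }
})

test_that("resummed potential differences match the brute-force image sum", {
  set.seed(7)
  H <- 1
  p0 <- c(0.4, 0.1)
  v0 <- pair_potential(p0[1], p0[2], H, lp)
  for (i in 1:40) {
    p1 <- c(runif(1, 0.002, 3), runif(1, -2, 2))
    bf <- brute_force_periodic_sum_diff(p1, p0, H, M = 40000L)
    expect_lt(abs((pair_potential(p1[1], p1[2], H, lp) - v0) - as.numeric(bf)),
              1e-8)
  }
})

test_that("far transverse separations reduce to the bare logarithm", {
  H <- 1
  v <- pair_potential(20 * H, 0.3 * H, H, lp)
  ln_term <- -2 / H * log(20)
  expect_lt(abs(v - ln_term) / abs(ln_term), 1e-10)
})

test_that("self-overlap is rejected", {
  expect_error(pair_potential(0, 0, 1, lp), "overlap")
  expect_error(pair_potential(0, 3, 3, lp), "overlap")  # on an image plane
})

test_that("total energy reproduces the hand-checkable fixtures", {
  fx <- fixture_configurations(xi = 1.5)
  expect_identical(attr(fx$single_at_R$config, "energy"), 0)
  expect_equal(attr(fx$single_at_eR$config, "energy"), 2 * 1.5)
  # pair term via oracle differences: move one ion axially and compare
  m <- fx$pair_antipodal$model
  c1 <- fx$pair_antipodal$config
  c2 <- ion_configuration(m, r = c1$r, theta = c1$theta, z = c(0, 0.7), lekner = lp)
  de <- attr(c1, "energy") - attr(c2, "energy")
  bf <- brute_force_periodic_sum_diff(c(2, 1), c(2, 0.7), H = m$H, M = 40000L)
  expect_equal(de, m$xi * as.numeric(bf), tolerance = 1e-8)
})

test_that("incremental energies agree with full recomputation", {
  set.seed(21)
  m <- cell_model(N = 5, xi = 2, delta = 3, R = 1)
  cfg <- initial_configuration(m)
  cfg <- ion_configuration(m, cfg$r, cfg$theta, cfg$z, lekner = lp)
  # null move
  expect_equal(energy_delta(cfg, 2, c(cfg$r[2], cfg$theta[2], cfg$z[2]),
                            lekner = lp), 0)
  for (i in 1:5) {
    np <- c(runif(1, m$R, m$D), runif(1, 0, 2 * pi), runif(1, 0, m$H))
    d <- energy_delta(cfg, i, np, lekner = lp)
    cfg2 <- cfg
    cfg2$r[i] <- np[1]; cfg2$theta[i] <- np[2]; cfg2$z[i] <- np[3]
    expect_equal(d, total_energy(cfg2, m, lp) - total_energy(cfg, m, lp),
                 tolerance = 1e-10)
  }
  # radial move of an isolated ion picks up only the one-body log term
  m1 <- cell_model(N = 1, xi = 2, delta = 3, R = 1)
  c1 <- ion_configuration(m1, r = 2, theta = 0, z = 0, lekner = lp)
  expect_equal(energy_delta(c1, 1, c(5, 0, 0), lekner = lp),
               2 * 2 * log(5 / 2), tolerance = 1e-12)
})

test_that("energy is invariant under rigid axial shifts and rotations", {
  set.seed(3)
  m <- cell_model(N = 6, xi = 1.5, delta = 4, R = 1)
  cfg <- initial_configuration(m)
  cfg <- ion_configuration(m, cfg$r, cfg$theta, cfg$z, lekner = lp)
  e0 <- total_energy(cfg, m, lp)
  shifted <- ion_configuration(m, cfg$r, cfg$theta, (cfg$z + 2.31) %% m$H,
                               lekner = lp)
  rotated <- ion_configuration(m, cfg$r, (cfg$theta + 1.234) %% (2 * pi),
                               cfg$z, lekner = lp)
  expect_lt(abs(total_energy(shifted, m, lp) - e0), 1e-10)
  expect_lt(abs(total_energy(rotated, m, lp) - e0), 1e-10)
})

test_that("cached chain energy matches recomputation after many moves", {
  m <- cell_model(N = 8, xi = 1.8, delta = 5, R = 0.5)
  ch <- run_chain(m, run_config(n_equil = 500, n_prod = 1500,
                                sample_stride = 10, seed = 5), lekner = lp)
  rel <- abs(diff(ch$energy_check)) / max(1, abs(ch$energy_check[2]))
  expect_lt(rel, 1e-9)
})
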