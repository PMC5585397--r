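lp <- lekner_params()

test_that("local proposals are uniform in the displacement cube", {
  m <- cell_model(N = 1, xi = 1, delta = 6, R = 1)
  cfg <- tibble::tibble(r = 50, theta = 0, z = 0.5)  # far from both walls
  step <- 0.5
  set.seed(2)
  dx <- replicate(10000, {
    p <- propose_local(cfg, 1, step, m)
    p$r * cos(p$theta) - cfg$r
  })
  ks <- suppressWarnings(ks.test(dx, "punif", -step, step))
  expect_gt(ks$p.value, 0.01)
  # zero step proposes the current position
  p0 <- propose_local(cfg, 1, 0, m)
  expect_equal(c(p0$r, p0$theta %% (2 * pi), p0$z), c(50, 0, 0.5))
  expect_true(p0$valid)
})

test_that("local proposals near the outer wall are rejected at the geometric rate", {
  m <- cell_model(N = 1, xi = 1, delta = 2, R = 1)
  r0 <- m$D - 0.05
  cfg <- tibble::tibble(r = r0, theta = 0, z = 0.5)
  step <- 0.4
  set.seed(4)
  n <- 20000
  inval <- replicate(n, !propose_local(cfg, 1, step, m)$valid)
  # direct Monte Carlo estimate of the cube fraction outside [R, D]
  x <- r0 + runif(n, -step, step); y <- runif(n, -step, step)
  rr <- sqrt(x^2 + y^2)
  p_geom <- mean(rr < m$R | rr > m$D)
  se <- sqrt(2 * p_geom * (1 - p_geom) / n)
  expect_lt(abs(mean(inval) - p_geom), 3 * se)
})

test_that("centrifugal proposals degenerate correctly as the cell closes", {
  m <- cell_model(N = 1, xi = 1, delta = 1e-9, R = 1)
  set.seed(5)
  for (i in 1:20) {
    p <- propose_centrifugal(tibble::tibble(r = 1, theta = 0, z = 0), 1, m)
    expect_lt(abs(p$r - m$R), 3e-9)  # radial move collapses onto R
  }
})

test_that("one-ion sampling reproduces the exact Boltzmann radial marginal", {
  # density ~ r^(1-2 xi) on [R, D] from the one-body term of the Hamiltonian
  m <- cell_model(N = 1, xi = 2, delta = 3, R = 1)
  ch <- run_chain(m, run_config(n_equil = 2000, n_prod = 2e6, sample_stride = 10,
                                move_mix = c(0.3, 0.7, 0), seed = 11),
                  lekner = lp)
  r <- as.numeric(ch$r_samples)
  xi <- 2
  edges <- exp(seq(0, m$delta, length.out = 21))
  obs <- as.numeric(table(cut(r, edges)))
  cdf <- function(r) (r^(2 - 2 * xi) - 1) / (exp(m$delta)^(2 - 2 * xi) - 1)
  expect_gt(suppressWarnings(chisq.test(obs, p = diff(cdf(edges))))$p.value,
            0.01)
  # mean of ln(r/R) against the quadrature expectation, within 3 sigma
  w <- integrate(function(r) r^(1 - 2 * xi), 1, exp(3))$value
  mu <- integrate(function(r) log(r) * r^(1 - 2 * xi), 1, exp(3))$value / w
  se <- blocking_error(log(r))$se
  expect_lt(abs(mean(log(r)) - mu), 3 * se)
})

test_that("at xi = 1/2 the one-ion radial marginal is uniform in r", {
  m <- cell_model(N = 1, xi = 0.5, delta = 3, R = 1)
  ch <- run_chain(m, run_config(n_equil = 2000, n_prod = 4e5, sample_stride = 10,
                                move_mix = c(0.3, 0.7, 0), seed = 12),
                  lekner = lp)
  r <- as.numeric(ch$r_samples)
  edges <- seq(1, exp(3), length.out = 16)
  obs <- as.numeric(table(cut(r, edges)))
  p <- diff(edges) / (exp(3) - 1)
  expect_gt(suppressWarnings(chisq.test(obs, p = p))$p.value, 0.01)
})

test_that("global swap moves leave the equilibrium distribution unchanged", {
  m <- cell_model(N = 2, xi = 1.5, delta = 4, R = 1)
  ch_swap <- run_chain(m, run_config(n_equil = 3000, n_prod = 30000,
                                     sample_stride = 15,
                                     move_mix = c(0.5, 0.3, 0.2), seed = 31),
                       lekner = lp)
  ch_none <- run_chain(m, run_config(n_equil = 3000, n_prod = 30000,
                                     sample_stride = 15,
                                     move_mix = c(0.6, 0.4, 0), seed = 32),
                       lekner = lp)
  ks <- suppressWarnings(ks.test(as.numeric(ch_swap$r_samples),
                                 as.numeric(ch_none$r_samples)))
  expect_gt(ks$p.value, 0.01)
})

test_that("ordered starts converge to the same condensed fraction", {
  m <- cell_model(N = 10, xi = 1.5, delta = 6, R = 1)
  rc <- function(seed) run_config(n_equil = 5000, n_prod = 25000,
                                  sample_stride = 20, seed = seed)
  a <- run_chain(m, rc(41), lekner = lp, init = "condensed")
  b <- run_chain(m, rc(42), lekner = lp, init = "unbound")
  fa <- condensed_fraction(a); fb <- condensed_fraction(b)
  sigma <- sqrt(fa$f_err^2 + fb$f_err^2)
  expect_lt(abs(fa$f - fb$f), 3 * sigma)
})

test_that("swap proposal classifies and exchanges radii symmetrically", {
  m <- cell_model(N = 4, xi = 1, delta = 4, R = 1)
  r <- c(1.1, 1.2, exp(3.5), exp(3.9))  # two condensed, two unbound
  cfg <- ion_configuration(m, r, theta = c(0, 2, 4, 1), z = c(0, 1, 2, 3))
  set.seed(6)
  sw <- propose_global_swap(cfg, m)
  expect_true(sw$i %in% 1:2 && sw$j %in% 3:4)
  expect_setequal(sw$candidate$r, r)    # multiset of radii preserved
  # swapping two ions at equal radii is the identity on the energy
  r_eq <- c(2, 2, exp(3.5), exp(3.9))
  cfg_eq <- ion_configuration(m, r_eq, theta = c(0, 2, 4, 1), z = c(0, 1, 2, 3))
  cand <- cfg_eq
  cand$r[c(1, 2)] <- cand$r[c(2, 1)]
  expect_equal(total_energy(cand, m, lp), total_energy(cfg_eq, m, lp),
               tolerance = 1e-12)
  # move impossible when one side is empty
  all_cond <- ion_configuration(m, rep(1.5, 4), theta = 1:4, z = 0:3)
  expect_null(propose_global_swap(all_cond, m))
})

test_that("chains are reproducible and account for every attempted move", {
  m <- cell_model(N = 5, xi = 2, delta = 3, R = 1)
  rc <- run_config(n_equil = 200, n_prod = 1000, sample_stride = 5, seed = 77)
  a <- run_chain(m, rc, lekner = lp)
  b <- run_chain(m, rc, lekner = lp)
  expect_identical(a$samples$energy, b$samples$energy)
  expect_identical(a$r_samples, b$r_samples)
  expect_identical(sum(a$acceptance$attempted), 5L * (200L + 1000L))
  expect_true(all(a$acceptance$accepted <= a$acceptance$attempted))
  expect_equal(nrow(a$samples), 1000 %/% 5)
  expect_true(all(a$samples$n_condensed >= 0 & a$samples$n_condensed <= 5))
})
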