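# Brownian-dynamics samplers and the exact oracles.

test_that("window trajectories are bit-reproducible from the seed", {
  s <- fix_surface()
  w <- umbrella_window(1, 6.5, 4, n_steps = 2e4, output_stride = 10)
  a <- generate_window(s, w, seed = 7)
  b <- generate_window(s, w, seed = 7)
  expect_identical(a$xi, b$xi)
  expect_identical(a$theta, b$theta)
  c <- generate_window(s, w, seed = 8)
  expect_false(identical(a$xi, c$xi))
})

test_that("a very stiff bias pins the sample mean at the bias center", {
  s <- fix_surface()
  w <- umbrella_window(1, 12, 1000, n_steps = 5e4, dt = 5e-4,
                       output_stride = 5)
  ts <- generate_window(s, w, seed = 3)
  expect_lt(abs(mean(ts$xi) - 12), 0.05)
})

test_that("biased sampling on a flat landscape reproduces the analytic Gaussian", {
  s <- flat_surface()
  st <- fix_state()
  k <- 2
  # high-diffusion run thinned to near-independent samples
  w <- umbrella_window(1, 14, k, n_steps = 6e6, dt = 0.005,
                       output_stride = 300)
  ts <- generate_window(s, w, st, d_xi = 1, seed = 11)
  sigma <- sqrt(1 / (st$beta * k))
  ks <- suppressWarnings(stats::ks.test(ts$xi, "pnorm", 14, sigma))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ts$xi >= 2 & ts$xi <= 25))
})

test_that("the default ladder covers 4-25 A with 17 overlapping windows", {
  lad <- fix_small_ladder()
  expect_length(lad$windows, 17)
  centers <- vapply(lad$windows, function(w) w$window$bias_center, 0)
  expect_equal(range(centers), c(4, 25))
  expect_true(all(lad$overlap$shared_bins >= 1))
})

test_that("halving the output stride doubles the sample count only", {
  s <- flat_surface()
  cfg1 <- ladder_config(xi_min = 6, xi_max = 10, n_windows = 3,
                        force_constant = 0.5, n_steps = 1e4,
                        output_stride = 20, base_seed = 5)
  cfg2 <- ladder_config(xi_min = 6, xi_max = 10, n_windows = 3,
                        force_constant = 0.5, n_steps = 1e4,
                        output_stride = 10, base_seed = 5)
  l1 <- generate_ladder(s, cfg1)
  l2 <- generate_ladder(s, cfg2)
  expect_length(l2$windows, length(l1$windows))
  expect_identical(nrow(l2$windows[[1]]$series),
                   2L * nrow(l1$windows[[1]]$series))
})

test_that("non-overlapping adjacent windows raise a gap error naming the pair", {
  s <- flat_surface()
  cfg <- ladder_config(n_windows = 2, force_constant = 400, n_steps = 5e3,
                       dt = 1e-4, output_stride = 5, base_seed = 1)
  expect_error(generate_ladder(s, cfg), "windows 1 .* and 2")
})

test_that("exact OU sampler has the closed-form moments", {
  st <- fix_state()
  k <- 1 / st$beta  # beta*k = 1 A^-2
  ts <- generate_ou(k, d = 0.1, n_steps = 1e5, dt = 1, seed = 21)
  v <- var(ts$xi)
  se <- sqrt(2 / length(ts$xi)) * 1  # var of sample variance ~ 2 sigma^4/n
  expect_lt(abs(v - 1), 3 * se * sqrt(1 + 2 * 10))  # correlation-inflated
  expect_lt(abs(mean(ts$xi)), 3 * sqrt(2 * 10 / length(ts$xi)))
})

test_that("doubling D halves the OU autocorrelation time", {
  st <- fix_state()
  k <- 1 / st$beta
  t1 <- generate_ou(k, d = 0.05, n_steps = 2e5, dt = 1, seed = 5)
  t2 <- generate_ou(k, d = 0.10, n_steps = 2e5, dt = 1, seed = 6)
  tau1 <- estimate_window_diffusion(t1)$tau
  tau2 <- estimate_window_diffusion(t2)$tau
  expect_equal(tau1 / tau2, 2, tolerance = 0.1)
})

test_that("wobble sampler reproduces the sin-weighted Boltzmann density", {
  st <- fix_state()
  k <- 0.01
  ts <- generate_wobble(3800, list(k = k, center = 40), n_steps = 6e5,
                        dt = 5e-4, seed = 9, output_stride = 30)
  # analytic CDF of sin(theta) * exp(-beta*F) on the simulated domain
  grid <- seq(0.2, 179.8, by = 0.01)
  dens <- sin(grid * pi / 180) * exp(-st$beta * 0.5 * k * (grid - 40)^2)
  cdf_tab <- cumsum(dens) / sum(dens)
  cdf <- function(q) approx(grid, cdf_tab, q, rule = 2)$y
  ks <- suppressWarnings(stats::ks.test(ts$theta, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("wobble sampler is seed-reproducible and confined", {
  a <- generate_wobble(3800, list(k = 0.02, center = 30), n_steps = 1e4,
                       seed = 4)
  b <- generate_wobble(3800, list(k = 0.02, center = 30), n_steps = 1e4,
                       seed = 4)
  expect_identical(a$theta, b$theta)
  expect_true(all(a$theta > 0 & a$theta < 180))
})

test_that("a stiffer confining potential narrows the angular distribution monotonically", {
  sds <- vapply(c(0.005, 0.02, 0.08), function(k)
    sd(generate_wobble(3800, list(k = k, center = 30), n_steps = 5e4,
                       seed = 12)$theta), 0)
  expect_true(all(diff(sds) < 0))
})

test_that("first-passage oracle matches the reflected-origin closed form", {
  # flat potential, reflecting 0, absorbing L, start 0: MFPT = L^2/(2D)
  L <- 10; D <- 0.1
  fp <- simulate_first_passage(function(x) 0 * x, D, start = 0,
                               absorbing_at = L, reflecting_at = 0,
                               n_replicas = 2000, dt = 0.01, seed = 31)
  expect_identical(fp$n_capped, 0L)
  expect_lt(abs(fp$mfpt - L^2 / (2 * D)), 3 * fp$se)
})

test_that("first-passage time from the absorbing boundary is zero", {
  fp <- simulate_first_passage(function(x) 0 * x, 0.1, start = 5,
                               absorbing_at = 5, reflecting_at = 0,
                               n_replicas = 10, seed = 1)
  expect_identical(fp$mfpt, 0)
})

test_that("doubling D halves the mean first-passage time", {
  mf <- vapply(c(0.1, 0.2), function(D)
    simulate_first_passage(function(x) 0 * x, D, start = 0,
                           absorbing_at = 8, reflecting_at = 0,
                           n_replicas = 600, dt = 0.01, seed = 17)$mfpt, 0)
  expect_equal(mf[1] / mf[2], 2, tolerance = 0.1)
})

test_that("unstable integration steps are reported, not silently absorbed", {
  s <- fix_surface()
  w <- umbrella_window(1, 4.2, 4, n_steps = 1e4, dt = 50)
  expect_error(generate_window(s, w, seed = 1), "unstable|reduce dt")
})

test_that("a long unbiased trajectory reproduces the quadrature basin populations", {
  s <- fix_surface()
  st <- fix_state()
  w <- umbrella_window(1, 6, 0.05, n_steps = 4e6, output_stride = 100)
  ts <- generate_window(s, w, st, seed = 77, xi0 = 5, theta0 = 30,
                        domain = c(2, 11))
  # weak restraint keeps the walker in the bound region; compare the
  # basin-I share among bound samples against quadrature with the same
  # residual bias folded in
  xi_g <- seq(2, 11, by = 0.01); th_g <- seq(0, 180, by = 0.5)
  E <- outer(xi_g, th_g, function(x, t) surface_energy(s, x, t)) +
    0.5 * 0.05 * (xi_g - 6)^2
  Wq <- exp(-st$beta * E)
  in_I <- function(x, t) x < 5.5 & t > 90
  p_exact <- sum(Wq[xi_g < 5.5, th_g > 90]) / sum(Wq)
  inI <- in_I(ts$xi, ts$theta)
  blocks <- split(inI, ceiling(seq_along(inI) / 2000))
  p_hat <- mean(inI)
  se <- sd(vapply(blocks, mean, 0)) / sqrt(length(blocks))
  expect_lt(abs(p_hat - p_exact), 3 * se)
})
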