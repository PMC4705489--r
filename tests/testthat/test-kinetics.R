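# Diffusion estimation, Smoluchowski rate, Zwanzig MFPT, wobbling.

test_that("variance/autocorrelation estimator recovers D across a grid of OU parameters", {
  st <- fix_state()
  i <- 0
  for (bk in c(0.5, 1, 2)) {        # beta*k in A^-2
    for (D in c(0.02, 0.1, 0.5)) {
      i <- i + 1
      tau <- 1 / (bk * D)
      ts <- generate_ou(bk / st$beta, D, st, n_steps = 1e5, dt = tau / 8,
                        seed = 300 + i)
      est <- estimate_window_diffusion(ts)
      expect_lt(abs(est$D - D) / D, 0.10)
    }
  }
})

test_that("rescaling the time unit rescales D exactly", {
  st <- fix_state()
  ts <- generate_ou(1 / st$beta, 0.1, st, n_steps = 2e4, dt = 1, seed = 8)
  a <- estimate_window_diffusion(ts, dt = 1, min_samples = 1e4)
  b <- estimate_window_diffusion(ts, dt = 0.1, min_samples = 1e4)
  expect_equal(b$D, 10 * a$D, tolerance = 1e-12)
})

test_that("undersampled or over-correlated series are rejected", {
  st <- fix_state()
  ts <- generate_ou(1 / st$beta, 0.1, st, n_steps = 5e3, dt = 1, seed = 2)
  expect_error(estimate_window_diffusion(ts), "insufficient sampling")
  slow <- generate_ou(1 / st$beta, 1e-4, st, n_steps = 2e4, dt = 1, seed = 3)
  expect_error(estimate_window_diffusion(slow), "insufficient sampling")
})

test_that("diffusion profile interpolates linearly and extrapolates as a constant", {
  dp <- build_diffusion_profile(c(5, 7, 10), c(0.10, 0.20, 0.16))
  expect_identical(diffusion_at(dp, 7), 0.20)
  expect_identical(diffusion_at(dp, 50), 0.16)
  expect_identical(diffusion_at(dp, 1), 0.10)
  expect_equal(diffusion_at(dp, 6), (0.10 + 0.20) / 2, tolerance = 1e-12)
  expect_error(build_diffusion_profile(c(7, 5), c(0.1, 0.2)),
               "strictly increasing")
  expect_error(build_diffusion_profile(c(5, 7), c(0.1, -0.2)), "positive")
})

test_that("association rate reduces to the Debye-Smoluchowski free-diffusion limit", {
  D <- 0.1
  a <- 11
  res <- association_rate(function(x) 0 * x, D, absorbing = a, outer = 1000,
                          jacobian_mode = "bare")
  k_exact <- 4 * pi * D * a * 6.02214076e5
  expect_lt(abs(res$k_on - k_exact) / k_exact, 0.02)
  expect_lt(res$refinement, 0.01)
})

test_that("association rate vanishes with vanishing transport", {
  r1 <- association_rate(function(x) 0 * x, 1e-6, absorbing = 11,
                         outer = 100, jacobian_mode = "bare")
  r2 <- association_rate(function(x) 0 * x, 1e-3, absorbing = 11,
                         outer = 100, jacobian_mode = "bare")
  expect_equal(r1$k_on / r2$k_on, 1e-3, tolerance = 1e-6)
})

test_that("the two Jacobian conventions are mutually consistent", {
  prof <- fix("profile_default", function() project_profile(fix_surface()))
  st <- fix_state()
  # bare on w equals integrated on G = w - (2/beta) log(xi/xi_b)
  pot <- function(x) approx(prof$xi, prof$G, x, rule = 2)$y
  b <- 25
  Gint <- function(x) pot(x) - (2 / st$beta) * log(x / b)
  r_bare <- association_rate(pot, 0.1, 11, b, st, "bare")
  r_int <- association_rate(Gint, 0.1, 11, b, st, "integrated")
  expect_equal(r_int$k_on, r_bare$k_on, tolerance = 1e-6)
})

test_that("association rate agrees with the radial BD first-passage oracle", {
  prof <- fix("profile_default", function() project_profile(fix_surface()))
  st <- fix_state()
  D <- 1
  a <- 11; b <- 100
  res <- association_rate(function(x) approx(prof$xi, prof$G, x, rule = 2)$y,
                          D, absorbing = a, outer = b, state = st,
                          jacobian_mode = "bare")
  # 1D radial process: linear density xi^2 exp(-beta G), i.e. effective
  # potential U = G - (2/beta) log(xi/b)
  U <- function(x) approx(prof$xi, prof$G, x, rule = 2)$y -
    (2 / st$beta) * log(x / b)
  fp <- simulate_first_passage(U, D, start = b, absorbing_at = a,
                               reflecting_at = b, n_replicas = 400,
                               dt = 0.05, seed = 51, state = st)
  xi_g <- seq(a, b, by = 0.01)
  Veff <- 4 * pi * usdimer:::.trapz(xi_g, xi_g^2 *
    exp(-st$beta * approx(prof$xi, prof$G, xi_g, rule = 2)$y))
  k_bd <- 6.02214076e5 * Veff / fp$mfpt  # A^3/ns -> 1/(M s)
  se_rel <- fp$se / fp$mfpt
  expect_lt(abs(res$k_on - k_bd) / k_bd, 3 * se_rel)
})

test_that("Zwanzig MFPT matches the flat-potential closed form with the printed D", {
  D <- 3.8e12  # deg^2/s
  res <- mfpt_zwanzig(function(th) 0 * th, D, 0, 180, reflecting_at = 0)
  expect_lt(abs(res$tau - 180^2 / (2 * D)) / (180^2 / (2 * D)), 0.005)
  expect_lt(res$refinement, 0.01)
  expect_identical(mfpt_zwanzig(function(th) 0 * th, D, 90, 90)$tau, 0)
})

test_that("Zwanzig MFPT is symmetric under mirroring the geometry", {
  pot <- function(th) 2 * exp(-(th - 90)^2 / (2 * 15^2))
  fwd <- mfpt_zwanzig(pot, 3800, 30, 150, reflecting_at = 0)
  bwd <- mfpt_zwanzig(function(th) pot(180 - th), 3800, 150, 30,
                      reflecting_at = 180)
  expect_equal(bwd$tau, fwd$tau, tolerance = 1e-9)
})

test_that("Zwanzig MFPT over a barrier agrees with the BD first-passage oracle", {
  pot <- function(th) 1.5 * exp(-(th - 90)^2 / (2 * 15^2))
  D <- 3800  # deg^2/ns
  tau <- mfpt_zwanzig(pot, D, 30, 150, reflecting_at = 0)$tau
  fp <- simulate_first_passage(pot, D, start = 30, absorbing_at = 150,
                               reflecting_at = 0, n_replicas = 400,
                               dt = 1e-4, seed = 61)
  expect_lt(abs(fp$mfpt - tau), 3 * fp$se)
})

test_that("boundary ordering violations are rejected", {
  expect_error(mfpt_zwanzig(function(th) 0 * th, 1, 30, 150,
                            reflecting_at = 60), "ordering")
  expect_error(mfpt_zwanzig(function(th) 0 * th, -1, 0, 10), "positive")
})

test_that("wobbling estimator recovers the printed rotational diffusion coefficient", {
  d_in <- 3.8e12  # deg^2/s
  k <- fix_state()$kT / 8^2  # sigma = 8 deg
  ts <- generate_wobble(d_in, list(k = k, center = 30), n_steps = 1e5,
                        dt = 5e-13, seed = 71)
  est <- rotational_diffusion_wobbling(ts)
  expect_lt(abs(est$d_rot - d_in) / d_in, 0.15)
})

test_that("wobbling estimator recovers a second diffusion coefficient", {
  d_in <- 1.0e12
  k <- fix_state()$kT / 8^2
  ts <- generate_wobble(d_in, list(k = k, center = 30), n_steps = 1e5,
                        dt = 2e-12, seed = 72)
  est <- rotational_diffusion_wobbling(ts)
  expect_lt(abs(est$d_rot - d_in) / d_in, 0.15)
})

test_that("a stiffer cone narrows sigma but leaves the D estimate invariant", {
  d_in <- 3.8e12
  k1 <- fix_state()$kT / 8^2
  k2 <- fix_state()$kT / 5^2
  e1 <- rotational_diffusion_wobbling(
    generate_wobble(d_in, list(k = k1, center = 30), n_steps = 1e5,
                    dt = 5e-13, seed = 73))
  e2 <- rotational_diffusion_wobbling(
    generate_wobble(d_in, list(k = k2, center = 30), n_steps = 1e5,
                    dt = 5e-13, seed = 74))
  expect_lt(e2$sigma, e1$sigma)
  expect_lt(abs(e2$d_rot - d_in) / d_in, 0.15)
})

test_that("flipping rate is the exact inverse MFPT with audited units", {
  expect_identical(flipping_rate(200e-9), 5e6)
  expect_identical(flipping_rate(1), 1)
  expect_error(flipping_rate(0), "positive")
  # composition: seconds in, Hz out
  tau <- mfpt_zwanzig(function(th) 0 * th, 3.8e12, 0, 180)$tau
  expect_equal(flipping_rate(tau), 2 * 3.8e12 / 180^2, tolerance = 0.01)
})
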