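# WHAM, 2D reweighting, basin populations, minima location.

test_that("single biased window on a flat landscape unbiases to a flat profile", {
  s <- flat_surface()
  w <- umbrella_window(1, 21, 0.5, n_steps = 2e6, output_stride = 100)
  ts <- generate_window(s, w, d_xi = 1, seed = 41)
  res <- solve_wham(list(list(window = w, series = ts)),
                    range = c(19, 23), n_bins = 40, plateau_from = 20)
  well <- res$profile$counts > 200
  expect_lt(max(abs(res$profile$G[well])), 0.25)
})

test_that("WHAM recovers a known harmonic free energy from two Gaussian windows", {
  # exact i.i.d. sampling: harmonic G = K/2 (x - 10)^2 plus harmonic biases
  st <- fix_state()
  K <- 0.5
  k <- 1
  make_win <- function(i, c0, seed) {
    m <- (K * 10 + k * c0) / (K + k)
    sdv <- sqrt(1 / (st$beta * (K + k)))
    set.seed(seed)
    x <- rnorm(4e4, m, sdv)
    s <- data.frame(time = seq_along(x), xi = x)
    class(s) <- c("us_timeseries", "data.frame")
    list(window = umbrella_window(i, c0, k), series = s)
  }
  wl <- list(make_win(1, 9, 101), make_win(2, 11, 102))
  res <- solve_wham(wl, st, n_bins = 60, range = c(8, 12),
                    plateau_from = 8, inefficiency = FALSE)
  well <- res$profile$counts > 300
  G_an <- K / 2 * (res$profile$xi - 10)^2
  d <- (res$profile$G - G_an)[well]
  d <- d - mean(d)  # zero conventions differ by a constant
  expect_lt(sqrt(mean(d^2)), 0.1)
})

test_that("the default ladder recovers the printed minima positions", {
  m <- locate_minima(fix_small_wham()$profile)
  expect_identical(nrow(m$minima), 2L)
  expect_equal(m$minima$xi, c(4.5, 6.5), tolerance = 0.25)
})

test_that("WHAM objective decreases monotonically and offsets are window-1 anchored", {
  off <- fix_small_wham()$offsets
  expect_identical(off$f[1], 0)
  expect_lt(off$residual, 1e-7)
  expect_true(all(diff(off$objective) < 1e-8))
})

test_that("WHAM errors carry diagnostics: non-convergence and sampling gaps", {
  lad <- fix_small_ladder()
  err <- tryCatch(solve_wham(lad, max_iter = 3), error = function(e) e)
  expect_s3_class(err, "usdimer_wham_error")
  expect_true(is.numeric(err$residual_history))
  expect_error(solve_wham(lad, range = c(2, 26)), "sampling gap")
})

test_that("a constant added to all window offsets leaves the reweighted surface unchanged", {
  lad <- fix_small_ladder()
  off <- fix_small_wham()$offsets
  off2 <- off
  off2$f <- off$f + 1.7
  s1 <- reweight_2d(lad, off)
  s2 <- reweight_2d(lad, off2)
  expect_equal(s2$G, s1$G, tolerance = 1e-9)
  expect_equal(basin_populations(s2), basin_populations(s1),
               tolerance = 1e-9)
})

test_that("per-sample weights satisfy the effective-count sum identity", {
  lad <- fix_small_ladder()
  off <- fix_small_wham()$offsets
  s2 <- reweight_2d(lad, off, keep_weights = TRUE)
  got <- sum(s2$samples$weight * s2$samples$denom)
  kept_eff <- sum(vapply(seq_along(lad$windows), function(i)
    sum(lad$windows[[i]]$series$xi >= 4 & lad$windows[[i]]$series$xi <= 25) /
      off$windows$g[i], 0))
  expect_equal(got, kept_eff, tolerance = 1e-9)
})

test_that("offsets from a different window set are rejected", {
  lad <- fix_small_ladder()
  off <- fix_small_wham()$offsets
  lad2 <- lad
  lad2$windows[[3]]$window$bias_center <- 6.0
  expect_error(reweight_2d(lad2, off), "different set of windows")
})

test_that("marginalizing the 2D surface reproduces the 1D WHAM profile", {
  marg <- surface_marginal(fix_small_surface2d())
  prof <- fix_small_wham()$profile
  Gm <- approx(prof$xi, prof$G, marg$xi)$y
  well <- marg$counts > 200 & !is.na(Gm)
  expect_lt(sqrt(mean((marg$G - Gm)[well]^2)), 0.15)
})

test_that("a surface flat in theta reweights to theta-flat slices", {
  s <- flat_surface()
  s$wall_eps <- 1
  lad <- generate_ladder(s, ladder_config(base_seed = 99, n_steps = 4e5,
                                          output_stride = 40))
  wh <- solve_wham(lad)
  s2 <- reweight_2d(lad, wh$offsets)
  dev <- apply(s2$G, 1, function(r) diff(range(r[!is.na(r)])))
  well <- rowSums(s2$counts) > 3000
  expect_lt(max(dev[well]), 0.5)
})

test_that("four basins are present in the reweighted bound region", {
  pops <- basin_populations(fix_small_surface2d())
  expect_length(pops, 4L)
  expect_true(all(pops > 0.1))
  expect_equal(sum(pops), 1, tolerance = 1e-9)
  # most populated basin is II, as in the calibration targets
  expect_identical(names(which.max(pops)), "II")
})

test_that("populations from reweighted sampling agree with the quadrature oracle", {
  pops <- basin_populations(fix_small_surface2d())
  obs <- fix("obs_default", function() surface_observables(fix_surface()))
  # orientation-flip statistics dominate the error of the reduced fixture
  expect_lt(max(abs(pops - obs$populations)), 0.06)
})

test_that("a mirror-symmetric surface yields four equal quadrant populations", {
  s2 <- quadrature_surface2d(symmetric_surface())
  pops <- basin_populations(s2)
  expect_lt(max(abs(pops - 0.25)), 0.01)
})

test_that("overlapping or incomplete region definitions are rejected", {
  s2 <- fix_small_surface2d()
  reg <- default_basin_regions()
  reg$xi_max[1] <- 6.5  # overlaps region II
  expect_error(basin_populations(s2, reg), "overlap")
  reg2 <- default_basin_regions()[-2, ]
  expect_error(basin_populations(s2, reg2), "cover")
})

test_that("locate_minima finds a parabola vertex and matches a brute-force scan", {
  x <- seq(0, 10, by = 0.05)
  p <- data.frame(xi = x, G = (x - 3.21)^2)
  m <- locate_minima(p, smooth = 1)
  expect_identical(nrow(m$minima), 1L)
  expect_equal(m$minima$xi, 3.21, tolerance = 1e-6)
  expect_true(is.na(m$barrier))

  # noiseless analytic profile, smoothing off: grid minima equal the
  # brute-force scan
  prof <- project_profile(fix_surface(), xi = seq(4, 25, by = 0.02))
  m2 <- locate_minima(prof, smooth = 1)
  G <- prof$G
  brute <- which(G[2:(length(G) - 1)] < G[1:(length(G) - 2)] &
                   G[2:(length(G) - 1)] <= G[3:length(G)]) + 1L
  brute <- brute[G[brute] < -0.5]
  expect_identical(nrow(m2$minima), length(brute))
  expect_equal(m2$minima$xi, prof$xi[brute], tolerance = 0.02)
})

test_that("locate_minima errors when no minimum exists", {
  x <- seq(0, 5, 0.1)
  expect_error(locate_minima(data.frame(xi = x, G = x), smooth = 1),
               "no local minima")
})

test_that("orientation statistics split at 90 degrees and need the theta coordinate", {
  s2 <- quadrature_surface2d(symmetric_surface())
  o <- orientation_stats(s2)
  expect_equal(o$p_parallel, 0.5, tolerance = 0.01)
  expect_equal(o$mean_xi_parallel, o$mean_xi_antiparallel, tolerance = 0.01)
  s2phi <- quadrature_surface2d(symmetric_surface(), angle = "phi")
  expect_error(orientation_stats(s2phi), "theta")
})

test_that("orientation statistics of the sampled surface match the quadrature oracle", {
  o <- orientation_stats(fix_small_surface2d())
  obs <- fix("obs_default", function() surface_observables(fix_surface()))
  expect_lt(abs(o$p_antiparallel - obs$p_antiparallel), 0.06)
  expect_lt(abs(o$mean_xi_parallel - obs$mean_xi_parallel), 0.3)
  expect_lt(abs(o$mean_xi_antiparallel - obs$mean_xi_antiparallel), 0.3)
})

test_that("subsampling every second sample moves dG by less than twice the statistical error", {
  lad <- fix_small_ladder()
  sub <- lad
  sub$windows <- lapply(lad$windows, function(w) {
    s <- w$series[seq(1, nrow(w$series), by = 2), ]
    class(s) <- class(w$series)
    list(window = w$window, series = s)
  })
  st <- fix_state()
  d1 <- dimerization_constant(fix_small_wham()$profile, st)$delta_g
  d2 <- dimerization_constant(solve_wham(sub, st)$profile, st)$delta_g
  # statistical error of the small fixture is ~0.15-0.25 kcal/mol
  expect_lt(abs(d1 - d2), 2 * 0.25)
})
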