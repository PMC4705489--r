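# Synthetic biased trajectories: overdamped Langevin dynamics on the
# reference surface under harmonic umbrella biases, plus the exact
# Ornstein-Uhlenbeck, wobbling and first-passage oracles used to validate
# the estimators.  All samplers draw from R's RNG, so set.seed()/the `seed`
# arguments make every run reproducible.

#' Umbrella-sampling window definition
#'
#' @param index window index (1-based).
#' @param bias_center harmonic bias center (A).
#' @param force_constant bias force constant k (kcal mol^-1 A^-2); the bias
#'   is \eqn{w_i(\xi) = k(\xi - \xi_i)^2 / 2}.
#' @param n_steps number of integration steps.
#' @param dt integration time step (ns).
#' @param output_stride store every `output_stride`-th step.
#' @return Object of class `us_window`.
#' @export
umbrella_window <- function(index, bias_center, force_constant = 4,
                            n_steps = 8e6, dt = 0.005, output_stride = 400) {
  stopifnot(force_constant > 0, n_steps >= 1, dt > 0, output_stride >= 1)
  structure(list(index = index, bias_center = bias_center,
                 force_constant = force_constant, n_steps = n_steps,
                 dt = dt, output_stride = output_stride),
            class = "us_window")
}

# light container: data.frame (time, xi[, theta]) + metadata attributes
.new_timeseries <- function(time, xi = NULL, theta = NULL, meta = list()) {
  df <- data.frame(time = time)
  if (!is.null(xi)) df$xi <- xi
  if (!is.null(theta)) df$theta <- theta
  structure(df, class = c("us_timeseries", "data.frame"), meta = meta)
}

#' @export
print.us_timeseries <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Umbrella time series: %d samples, dt = %g ns, columns: %s\n",
              nrow(x), if (nrow(x) > 1) x$time[2] - x$time[1] else NA,
              paste(setdiff(names(x), "time"), collapse = ", ")))
  if (!is.null(m$window)) cat(sprintf("  window %s (center %g A, k %g)\n",
                                      m$window, m$bias_center,
                                      m$force_constant))
  invisible(x)
}

.surface_fingerprint <- function(surface) {
  v <- unlist(.sp(surface), use.names = FALSE)
  # order-sensitive rolling checksum; stable across sessions
  sprintf("%.0f", sum(signif(v, 10) * seq_along(v) * 97) %% 1e12)
}

#' Generate one biased window trajectory
#'
#' Overdamped Langevin dynamics on the reference surface with a harmonic
#' bias on xi only (theta evolves unbiased) and reflecting boundaries on
#' both coordinates, integrated with the stochastic Heun scheme (an
#' Euler-Maruyama predictor followed by a trapezoidal drift correction with
#' the same noise), whose stationary density is accurate to second order in
#' the time step.
#'
#' @param surface a [reference_surface()].
#' @param window an [umbrella_window()].
#' @param state a [thermo_state()].
#' @param d_xi,d_theta diffusion coefficients (A^2/ns, deg^2/ns).
#' @param seed integer seed (runs are bit-reproducible given the seed).
#' @param xi0,theta0 starting point; defaults to the bias center and 90 deg.
#' @param domain reflecting boundaries in xi (A).
#' @return A `us_timeseries` with columns `time` (ns), `xi` (A), `theta`
#'   (deg) and window metadata in `attr(, "meta")`.
#' @export
generate_window <- function(surface, window, state = thermo_state(),
                            d_xi = 0.1, d_theta = 3800, seed = 1,
                            xi0 = NULL, theta0 = 90, domain = c(2, 25)) {
  stopifnot(inherits(surface, "ref_surface"), inherits(window, "us_window"),
            d_xi > 0, d_theta > 0)
  if (is.null(xi0)) xi0 <- min(max(window$bias_center, domain[1]), domain[2])
  set.seed(seed)
  mat <- cpp_umbrella_bd(.sp(surface), state$beta, d_xi, d_theta,
                         window$dt, window$n_steps, window$output_stride,
                         window$bias_center, window$force_constant,
                         xi0, theta0, domain[1], domain[2])
  dt_out <- window$dt * window$output_stride
  .new_timeseries(time = dt_out * seq_len(nrow(mat)),
                  xi = mat[, 1], theta = mat[, 2],
                  meta = list(window = window$index,
                              bias_center = window$bias_center,
                              force_constant = window$force_constant,
                              seed = seed, d_xi = d_xi, d_theta = d_theta,
                              surface = .surface_fingerprint(surface)))
}

#' Umbrella ladder configuration
#'
#' Defaults emulate the published protocol: 17 evenly spaced windows over
#' 4.0 < xi < 25.0 A.  The force constant (4 kcal mol^-1 A^-2, bias width
#' ~0.39 A against a ~1.3 A spacing, stiff enough to convexify the steep
#' shoulder of the landscape) and the Brownian-dynamics settings are the
#' package's own choices; each window covers thousands of relaxation times
#' of the restrained coordinate and hundreds of orientational flips.
#'
#' @param xi_min,xi_max ladder extent (A).
#' @param n_windows number of windows (>= 2).
#' @param force_constant shared bias force constant (kcal mol^-1 A^-2).
#' @param n_steps,dt,output_stride per-window integration settings (ns).
#' @param d_xi,d_theta diffusion coefficients (A^2/ns, deg^2/ns).
#' @param base_seed base seed; per-window seeds are derived from it.
#' @param theta0 starting angle (deg).
#' @param domain reflecting xi boundaries (A).
#' @return Object of class `ladder_config`.
#' @export
ladder_config <- function(xi_min = 4, xi_max = 25, n_windows = 17,
                          force_constant = 4, n_steps = 8e6, dt = 0.005,
                          output_stride = 400, d_xi = 0.1, d_theta = 3800,
                          base_seed = 1, theta0 = 90, domain = c(2, 25)) {
  stopifnot(n_windows >= 2, xi_min < xi_max)
  structure(list(xi_min = xi_min, xi_max = xi_max, n_windows = n_windows,
                 force_constant = force_constant, n_steps = n_steps,
                 dt = dt, output_stride = output_stride, d_xi = d_xi,
                 d_theta = d_theta, base_seed = base_seed, theta0 = theta0,
                 domain = domain),
            class = "ladder_config")
}

#' Generate a full umbrella ladder
#'
#' Runs [generate_window()] for every window of the ladder, derives the
#' per-window seeds deterministically from the base seed, and verifies that
#' every pair of adjacent windows shares histogram support.
#'
#' @param surface a [reference_surface()].
#' @param config a [ladder_config()].
#' @param state a [thermo_state()].
#' @return Object of class `us_ladder`: list with `windows` (a list of
#'   `list(window, series)` pairs), `config` and `overlap` (adjacent-pair
#'   shared-bin counts).
#' @export
generate_ladder <- function(surface, config = ladder_config(),
                            state = thermo_state()) {
  stopifnot(inherits(config, "ladder_config"))
  centers <- seq(config$xi_min, config$xi_max, length.out = config$n_windows)
  breaks <- seq(config$xi_min, config$xi_max, length.out = 201)
  windows <- vector("list", config$n_windows)
  occupied <- vector("list", config$n_windows)
  for (i in seq_len(config$n_windows)) {
    w <- umbrella_window(i, centers[i], config$force_constant,
                         config$n_steps, config$dt, config$output_stride)
    ts <- generate_window(surface, w, state, config$d_xi, config$d_theta,
                          seed = config$base_seed + 7919L * i,
                          theta0 = config$theta0, domain = config$domain)
    windows[[i]] <- list(window = w, series = ts)
    occupied[[i]] <- unique(findInterval(ts$xi, breaks,
                                         rightmost.closed = TRUE))
  }
  shared <- vapply(seq_len(config$n_windows - 1), function(i)
    length(intersect(occupied[[i]], occupied[[i + 1]])), integer(1))
  if (any(shared == 0)) {
    bad <- which(shared == 0)[1]
    stop(sprintf(paste0("sampling gap: windows %d (center %.2f A) and %d ",
                        "(center %.2f A) share no histogram support"),
                 bad, centers[bad], bad + 1, centers[bad + 1]))
  }
  structure(list(windows = windows, config = config,
                 overlap = data.frame(pair = paste(seq_along(shared),
                                                   seq_along(shared) + 1,
                                                   sep = "-"),
                                      shared_bins = shared)),
            class = "us_ladder")
}

#' @export
print.us_ladder <- function(x, ...) {
  cat(sprintf("Umbrella ladder: %d windows over [%g, %g] A, %d samples/window\n",
              x$config$n_windows, x$config$xi_min, x$config$xi_max,
              nrow(x$windows[[1]]$series)))
  invisible(x)
}

#' Exact Ornstein-Uhlenbeck oracle series
#'
#' Samples a 1D harmonically confined diffusion using the exact transition
#' density, so the stationary variance is exactly \eqn{1/(\beta k)} and the
#' relaxation time exactly \eqn{1/(\beta k D)}.  Used as the bias-free
#' oracle for the variance/autocorrelation diffusion estimator.
#'
#' @param force_constant k (kcal mol^-1 A^-2).
#' @param d diffusion coefficient (A^2/ns).
#' @param state a [thermo_state()].
#' @param n_steps number of samples.
#' @param dt sampling interval (ns).
#' @param seed RNG seed.
#' @param x0 initial displacement from the bias center (A); default a draw
#'   from the stationary distribution.
#' @return `us_timeseries` with columns `time`, `xi` (displacement).
#' @export
generate_ou <- function(force_constant, d, state = thermo_state(),
                        n_steps = 1e5, dt = 0.1, seed = 1, x0 = NULL) {
  stopifnot(force_constant > 0, d > 0, n_steps >= 2, dt > 0)
  set.seed(seed)
  sigma2 <- 1 / (state$beta * force_constant)
  tau <- 1 / (state$beta * force_constant * d)
  phi <- exp(-dt / tau)
  if (is.null(x0)) x0 <- rnorm(1, 0, sqrt(sigma2))
  innov <- rnorm(n_steps, 0, sqrt(sigma2 * (1 - phi^2)))
  x <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                init = x0))
  .new_timeseries(time = dt * seq_len(n_steps), xi = x,
                  meta = list(seed = seed, force_constant = force_constant,
                              d = d, tau = tau, sigma2 = sigma2))
}

#' Wobbling orientational diffusion oracle
#'
#' Brownian dynamics of a polar angle theta in a confining potential
#' `F(theta)`, including the geometric \eqn{\sin\theta} weight (the sampled
#' density is proportional to \eqn{\sin\theta\, e^{-\beta F}}), so dividing
#' the sampled distribution by \eqn{\sin\theta} — the entropy correction —
#' recovers \eqn{e^{-\beta F}}.  Oracle for
#' [rotational_diffusion_wobbling()].
#'
#' @param d_rot rotational diffusion coefficient (deg^2 per time unit; the
#'   time unit of `dt` carries through to the output).
#' @param potential confining potential: a `function(theta_deg)` in
#'   kcal/mol, or a list `list(k =, center =)` for a harmonic well.
#' @param n_steps,dt,seed integration settings.
#' @param state a [thermo_state()].
#' @param theta0 starting angle (deg); defaults to the potential minimum.
#' @param output_stride store every n-th step.
#' @param sin_weight include the geometric sin(theta) weight (default TRUE).
#' @param domain reflecting boundaries (deg), inside (0, 180).
#' @return `us_timeseries` with columns `time`, `theta`.
#' @export
generate_wobble <- function(d_rot, potential, n_steps = 1e5, dt = 5e-4,
                            seed = 1, state = thermo_state(), theta0 = NULL,
                            output_stride = 1, sin_weight = TRUE,
                            domain = c(0.2, 179.8)) {
  stopifnot(d_rot > 0, n_steps >= 2, dt > 0)
  if (is.list(potential) && !is.function(potential)) {
    k <- potential$k; ctr <- potential$center
    potential <- function(th) 0.5 * k * (th - ctr)^2
  }
  domain[1] <- max(domain[1], 0.2)
  domain[2] <- min(domain[2], 179.8)
  grid <- seq(domain[1], domain[2], by = 0.05)
  U <- potential(grid)
  if (any(!is.finite(U))) stop("potential must be finite on (0, 180)")
  if (sin_weight) U <- U - state$kT * log(sin(grid * pi / 180))
  force <- -.num_gradient(U, grid[2] - grid[1])
  if (is.null(theta0)) theta0 <- grid[which.min(U)]
  set.seed(seed)
  th <- cpp_traj1d(force, grid[1], grid[2] - grid[1], state$beta, d_rot,
                   dt, as.integer(n_steps), as.integer(output_stride),
                   theta0)
  .new_timeseries(time = dt * output_stride * seq_along(th), theta = th,
                  meta = list(seed = seed, d_rot = d_rot))
}

# central-difference gradient on a uniform grid (one-sided at the ends)
.num_gradient <- function(y, h) {
  n <- length(y)
  g <- numeric(n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  g[1] <- (y[2] - y[1]) / h
  g[n] <- (y[n] - y[n - 1]) / h
  g
}

#' Brownian-dynamics first-passage oracle
#'
#' Simulates independent replicas of 1D overdamped diffusion in an effective
#' potential between a reflecting and an absorbing boundary and returns the
#' mean first-passage time with its standard error.  The potential is taken
#' literally as the 1D free energy of the simulated coordinate; callers
#' emulating a 3D radial process must fold the \eqn{-2 k_BT \ln \xi}
#' Jacobian term into it themselves.
#'
#' @param potential `function(x)` in kcal/mol, or a data.frame/`fe_profile`
#'   with columns `xi` (or `x`/`theta`) and `G` (or `F`); extrapolated as
#'   constant beyond its range.
#' @param diffusion a single number, a `function(x)`, or a
#'   [build_diffusion_profile()] result (units: length^2 per time unit of
#'   `dt`).
#' @param start starting coordinate (strictly between the boundaries, or at
#'   the absorbing boundary, giving 0).
#' @param absorbing_at,reflecting_at boundary positions (must differ).
#' @param n_replicas number of independent replicas.
#' @param dt integration step.
#' @param seed RNG seed.
#' @param state a [thermo_state()].
#' @param max_steps per-replica step cap; capped replicas are counted and
#'   reported, not dropped silently.
#' @param n_grid tabulation grid size for potential and diffusion.
#' @return List of class `fpt_result`: `mfpt`, `se`, `times`, `n_capped`,
#'   `n_replicas`.
#' @export
simulate_first_passage <- function(potential, diffusion, start,
                                   absorbing_at, reflecting_at,
                                   n_replicas = 500, dt = 0.01, seed = 1,
                                   state = thermo_state(), max_steps = 1e7,
                                   n_grid = 2001) {
  if (absorbing_at == reflecting_at)
    stop("absorbing and reflecting boundaries must differ")
  lo <- min(absorbing_at, reflecting_at)
  hi <- max(absorbing_at, reflecting_at)
  if (start == absorbing_at)
    return(structure(list(mfpt = 0, se = 0, times = numeric(0),
                          n_capped = 0L, n_replicas = n_replicas),
                     class = "fpt_result"))
  if (!(start > lo && start < hi) && start != reflecting_at)
    stop("`start` must lie between the boundaries")
  pot <- .as_potential_fun(potential)
  grid <- seq(lo, hi, length.out = n_grid)
  U <- pot(grid)
  force <- -.num_gradient(U, grid[2] - grid[1])
  dvec <- .as_diffusion_values(diffusion, grid)
  if (any(dvec <= 0)) stop("diffusion must be positive everywhere")
  set.seed(seed)
  times <- cpp_fpt(force, dvec, grid[1], grid[2] - grid[1], state$beta, dt,
                   start, absorbing_at, reflecting_at,
                   as.integer(n_replicas), max_steps)
  capped <- sum(is.na(times))
  ok <- times[!is.na(times)]
  if (capped > 0)
    warning(capped, " of ", n_replicas, " replicas hit the step cap (",
            format(max_steps, scientific = TRUE), " steps)")
  structure(list(mfpt = mean(ok), se = sd(ok) / sqrt(length(ok)),
                 times = ok, n_capped = as.integer(capped),
                 n_replicas = n_replicas),
            class = "fpt_result")
}

#' @export
print.fpt_result <- function(x, ...) {
  cat(sprintf("MFPT = %.4g +/- %.2g (n = %d, %d capped)\n",
              x$mfpt, x$se, x$n_replicas, x$n_capped))
  invisible(x)
}

.as_potential_fun <- function(potential) {
  if (is.function(potential)) return(potential)
  df <- as.data.frame(potential)
  xcol <- intersect(c("xi", "x", "theta"), names(df))[1]
  ycol <- intersect(c("G", "F", "U"), names(df))[1]
  if (is.na(xcol) || is.na(ycol))
    stop("tabulated potential needs a coordinate column (xi/x/theta) and ",
         "a value column (G/F/U)")
  f <- stats::approxfun(df[[xcol]], df[[ycol]], rule = 2)
  f
}

.as_diffusion_values <- function(diffusion, grid) {
  if (inherits(diffusion, "diffusion_profile"))
    return(diffusion_at(diffusion, grid))
  if (is.function(diffusion)) return(diffusion(grid))
  if (is.numeric(diffusion) && length(diffusion) == 1)
    return(rep(diffusion, length(grid)))
  stop("`diffusion` must be a number, function or diffusion_profile")
}
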