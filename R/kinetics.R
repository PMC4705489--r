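# Kinetics: position-dependent diffusion from restrained windows
# (D = sigma^2 / tau_A), the steady-state Smoluchowski association rate,
# the Zwanzig mean first-passage time on a 1D angular landscape, and the
# wobbling-in-a-cone rotational diffusion estimate.

# unit conversion: (A^3/ns) * NA / 1e27 A^3/L * 1e9 ns/s = 6.022e5 / (M s)
.RATE_CONV <- 6.02214076e5

#' Diffusion coefficient of a restrained coordinate
#'
#' Variance/autocorrelation estimator \eqn{D = \sigma^2/\tau_A}, with
#' \eqn{\sigma^2} the sample variance of the restrained coordinate and
#' \eqn{\tau_A} its integrated autocorrelation time (trapezoidal sum of the
#' autocorrelation function, truncated at the first negative value).  The
#' first `burn_in` fraction of the series is discarded; the standard error
#' comes from a block bootstrap over contiguous blocks.
#'
#' @param ts a `us_timeseries` (or numeric vector plus `dt`).
#' @param dt sampling interval; taken from the series' time column when
#'   omitted.
#' @param burn_in fraction discarded as equilibration.
#' @param min_samples minimum post-burn-in length.
#' @param n_blocks,n_boot block-bootstrap settings.
#' @return List of class `diffusion_estimate`: `D` (length^2 per time
#'   unit), `se`, `sigma2`, `tau` and `n`.
#' @export
estimate_window_diffusion <- function(ts, dt = NULL, burn_in = 0.1,
                                      min_samples = 1e4, n_blocks = 10,
                                      n_boot = 200) {
  if (inherits(ts, "us_timeseries") || is.data.frame(ts)) {
    x <- ts$xi
    if (is.null(x)) x <- ts$theta
    if (is.null(dt)) dt <- ts$time[2] - ts$time[1]
  } else {
    x <- as.numeric(ts)
    if (is.null(dt)) stop("`dt` required for a bare numeric series")
  }
  x <- x[-seq_len(floor(burn_in * length(x)))]
  n <- length(x)
  if (n < min_samples)
    stop("insufficient sampling: ", n, " samples after burn-in (need >= ",
         min_samples, ")")
  est <- function(y) {
    tau <- .int_act(y) * dt
    var(y) / tau
  }
  tau <- .int_act(x) * dt
  if (tau > n * dt / 50)
    stop(sprintf(paste0("insufficient sampling: tau_A = %.3g exceeds 1/50 ",
                        "of the series length %.3g"), tau, n * dt))
  D <- var(x) / tau
  # block bootstrap over contiguous blocks
  bl <- floor(n / n_blocks)
  blocks <- lapply(seq_len(n_blocks), function(b)
    x[((b - 1) * bl + 1):(b * bl)])
  Db <- vapply(blocks, est, numeric(1))
  boot <- vapply(seq_len(n_boot), function(i)
    mean(Db[sample.int(n_blocks, replace = TRUE)]), numeric(1))
  structure(list(D = D, se = sd(boot), sigma2 = var(x), tau = tau, n = n),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g +/- %.2g (sigma^2 = %.3g, tau = %.3g, n = %d)\n",
              x$D, x$se, x$sigma2, x$tau, x$n))
  invisible(x)
}

#' Position-dependent diffusion profile
#'
#' Linear interpolation between the per-window estimates at the window mean
#' positions, constant extrapolation beyond the sampled interval.
#'
#' @param xi window mean positions (A), strictly increasing.
#' @param D diffusion coefficients at those positions (A^2/ns).
#' @param se optional standard errors.
#' @return Object of class `diffusion_profile`.
#' @export
build_diffusion_profile <- function(xi, D, se = NULL) {
  if (length(xi) < 2) stop("need at least two nodes")
  if (is.unsorted(xi, strictly = TRUE))
    stop("node positions must be strictly increasing")
  if (any(D <= 0)) stop("all diffusion coefficients must be positive")
  structure(list(xi = xi, D = D, se = se), class = "diffusion_profile")
}

#' Evaluate a diffusion profile
#'
#' @param profile a [build_diffusion_profile()] result.
#' @param xi query positions (A).
#' @return D(xi): linear between nodes, constant beyond the first/last node.
#' @export
diffusion_at <- function(profile, xi) {
  stopifnot(inherits(profile, "diffusion_profile"))
  approx(profile$xi, profile$D, xout = xi, rule = 2)$y
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf("Diffusion profile: %d nodes over [%.2f, %.2f] A\n",
              length(x$xi), min(x$xi), max(x$xi)))
  invisible(x)
}

#' Diffusion-controlled association rate (steady-state Smoluchowski)
#'
#' Flux solution with an absorbing inner boundary and an equilibrium outer
#' reservoir:
#' \deqn{k_{on} = N_A \left[\int_{\xi_a}^{\xi_b}
#'   \frac{e^{+\beta w(\xi)}}{4\pi\xi^2 D(\xi)}\, d\xi\right]^{-1}}
#' where \eqn{w(\xi)} is the Jacobian-free radial potential of mean force.
#' With `jacobian_mode = "integrated"` (the default) the input profile is
#' taken as an angular-integrated free energy whose Boltzmann factor
#' already contains the \eqn{4\pi\xi^2} radial volume growth, so
#' \eqn{w(\xi) = G(\xi) + (2/\beta)\ln(\xi/\xi_b)} is restored before use;
#' with `"bare"` the profile is used as w directly.
#'
#' @param profile an [fe_profile()] or `function(xi)` in kcal/mol;
#'   extrapolated as its last value (the plateau) beyond its range.
#' @param diffusion a number, `function(xi)` or [build_diffusion_profile()]
#'   result, in A^2/ns.
#' @param absorbing,outer inner (absorbing) and outer boundary (A).
#' @param state a [thermo_state()].
#' @param jacobian_mode `"integrated"` or `"bare"` (see above).
#' @param n_grid quadrature nodes; the result is checked for stability
#'   against a half-resolution grid.
#' @return List of class `rate_result`: `k_on` (M^-1 s^-1), the resistance
#'   integral, boundaries, mode, and the relative change under grid
#'   halving (`refinement`).
#' @export
association_rate <- function(profile, diffusion, absorbing = 11,
                             outer = 25, state = thermo_state(),
                             jacobian_mode = c("integrated", "bare"),
                             n_grid = 5001) {
  jacobian_mode <- match.arg(jacobian_mode)
  if (absorbing >= outer) stop("`absorbing` must be smaller than `outer`")
  if (absorbing <= 0) stop("boundaries must be positive distances")
  pot <- .as_potential_fun(profile)
  kon_at <- function(n) {
    xi <- seq(absorbing, outer, length.out = n)
    w <- pot(xi)
    if (jacobian_mode == "integrated")
      w <- w + (2 / state$beta) * log(xi / outer)
    D <- .as_diffusion_values(diffusion, xi)
    if (any(D <= 0)) stop("diffusion must be positive everywhere")
    integrand <- exp(state$beta * w) / (4 * pi * xi^2 * D)
    if (any(!is.finite(integrand)))
      stop("diverging resistance integral: infinite free energy inside ",
           "the integration range")
    .trapz(xi, integrand)
  }
  I <- kon_at(n_grid)
  I2 <- kon_at(max(3, (n_grid - 1) %/% 2 + 1))
  k_on <- .RATE_CONV / I
  structure(list(k_on = k_on, resistance = I, absorbing = absorbing,
                 outer = outer, jacobian_mode = jacobian_mode,
                 refinement = abs(I - I2) / I,
                 units = "M^-1 s^-1 (profile kcal/mol, D A^2/ns)"),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("k_on = %.4g M^-1 s^-1 (absorbing %g A, outer %g A, %s)\n",
              x$k_on, x$absorbing, x$outer, x$jacobian_mode))
  invisible(x)
}

#' Zwanzig mean first-passage time on a 1D landscape
#'
#' \deqn{\tau = \frac{1}{D}\int_{\theta_0}^{\theta_1} d\theta'\,
#'   e^{\beta F(\theta')} \int_a^{\theta'} e^{-\beta F(\theta'')}
#'   d\theta''}
#' with a reflecting boundary at `a` (requires `a <= theta0 < theta1`, or
#' the mirrored ordering).  With F in kcal/mol, angles in degrees and
#' `d_rot` in deg^2/s the result is in seconds.
#'
#' @param potential `function(theta)` in kcal/mol or a data.frame/profile
#'   with columns `theta` and `F`.
#' @param d_rot rotational diffusion coefficient (deg^2 per time unit).
#' @param theta0,theta1 start and target angles (deg).
#' @param reflecting_at position of the reflecting barrier (deg),
#'   default 0.
#' @param state a [thermo_state()].
#' @param n_grid quadrature nodes; stability against grid halving is
#'   recorded.
#' @return List of class `mfpt_result`: `tau`, `refinement`.
#' @export
mfpt_zwanzig <- function(potential, d_rot, theta0, theta1,
                         reflecting_at = 0, state = thermo_state(),
                         n_grid = 4001) {
  if (d_rot <= 0) stop("`d_rot` must be positive")
  if (theta0 == theta1)
    return(structure(list(tau = 0, refinement = 0), class = "mfpt_result"))
  a <- reflecting_at
  pot <- .as_potential_fun(potential)
  if (theta1 < theta0) {
    # mirrored geometry: reflecting barrier above both angles;
    # map u = a - theta so the barrier sits at u = 0
    if (!(a >= theta0))
      stop("boundary ordering must satisfy a <= theta0 < theta1 ",
           "(or the mirrored a >= theta0 > theta1)")
    p0 <- pot
    a0 <- a
    pot <- function(u) p0(a0 - u)
    th0 <- a - theta0
    theta1 <- a - theta1
    theta0 <- th0
    a <- 0
  } else if (!(a <= theta0)) {
    stop("boundary ordering must satisfy a <= theta0 < theta1 ",
         "(or the mirrored a >= theta0 > theta1)")
  }
  tau_at <- function(n) {
    grid <- seq(a, theta1, length.out = n)
    h <- grid[2] - grid[1]
    eb <- exp(state$beta * pot(grid))
    # inner cumulative integral of exp(-beta F) from the reflecting barrier
    inner <- cumsum(c(0, (1 / eb[-1] + 1 / eb[-n]) / 2 * h))
    sel <- grid > theta0
    g0 <- approx(grid, eb * inner, theta0)$y
    .trapz(c(theta0, grid[sel]), c(g0, (eb * inner)[sel])) / d_rot
  }
  tau <- tau_at(n_grid)
  tau2 <- tau_at(max(5, (n_grid - 1) %/% 2 + 1))
  structure(list(tau = tau, refinement = abs(tau - tau2) / max(tau, 1e-300)),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat(sprintf("MFPT tau = %.4g (grid-halving change %.2g%%)\n",
              x$tau, 100 * x$refinement))
  invisible(x)
}

#' Flipping rate from a mean first-passage time
#'
#' @param tau mean first-passage time (> 0), in seconds for a rate in Hz.
#' @return Rate 1/tau.
#' @examples
#' flipping_rate(200e-9)  # 5e6 per second
#' @export
flipping_rate <- function(tau) {
  if (!is.numeric(tau) || any(tau <= 0)) stop("`tau` must be positive")
  1 / tau
}

#' Rotational diffusion by the wobbling-in-a-cone method
#'
#' Small-wobble closed form: (i) the apparent relaxation time is the
#' integrated autocorrelation time of the second Legendre polynomial
#' \eqn{P_2(\cos\theta(t))}; (ii) the cone width \eqn{\sigma} comes from a
#' Gaussian fit to the entropy-corrected angular distribution
#' \eqn{p(\theta)/\sin\theta}; (iii) \eqn{D = \sigma^2/\tau_{P2}}, the
#' small-amplitude limit in which the restricted diffusion relaxes as a
#' single-well Ornstein-Uhlenbeck process.
#'
#' @param theta angle series (deg), as numeric vector or `us_timeseries`.
#' @param dt sampling interval (the time unit of the returned D).
#' @param state a [thermo_state()].
#' @param burn_in fraction discarded as equilibration.
#' @param n_bins histogram bins for the angular distribution.
#' @return List of class `rotational_estimate`: `d_rot` (deg^2 per time
#'   unit), `sigma` (deg), `tau_p2`, `fit` (Gaussian fit table).
#' @export
rotational_diffusion_wobbling <- function(theta, dt = NULL,
                                          state = thermo_state(),
                                          burn_in = 0.1, n_bins = 72) {
  if (inherits(theta, "us_timeseries") || is.data.frame(theta)) {
    if (is.null(dt)) dt <- theta$time[2] - theta$time[1]
    theta <- theta$theta
  }
  if (is.null(dt)) stop("`dt` required for a bare numeric series")
  theta <- theta[-seq_len(floor(burn_in * length(theta)))]

  # entropy-corrected distribution and Gaussian fit
  h <- graphics::hist(theta, breaks = n_bins, plot = FALSE)
  mid <- h$mids
  keep <- h$density > 0 & mid > 0 & mid < 180
  y <- h$density[keep] / sin(mid[keep] * pi / 180)
  x <- mid[keep]
  y <- y / sum(y)
  mu0 <- sum(x * y)
  s0 <- sqrt(sum((x - mu0)^2 * y))
  imax <- which.max(y)
  if (imax == 1 || imax == length(y))
    stop("entropy-corrected angular distribution is not unimodal in the ",
         "interior; Gaussian fit aborted (mode at ", x[imax], " deg)")
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
               start = list(a = max(y), mu = mu0, s = s0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e)
      stop("Gaussian fit to the entropy-corrected distribution failed: ",
           conditionMessage(e)))
  cf <- stats::coef(fit)
  sigma <- abs(unname(cf["s"]))

  p2 <- 0.5 * (3 * cos(theta * pi / 180)^2 - 1)
  tau_p2 <- .int_act(p2) * dt
  structure(list(d_rot = sigma^2 / tau_p2, sigma = sigma, tau_p2 = tau_p2,
                 fit = data.frame(parameter = names(cf),
                                  value = as.numeric(cf))),
            class = "rotational_estimate")
}

#' @export
print.rotational_estimate <- function(x, ...) {
  cat(sprintf("D_rot = %.4g deg^2/time (sigma = %.3g deg, tau_P2 = %.3g)\n",
              x$d_rot, x$sigma, x$tau_p2))
  invisible(x)
}
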