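# WHAM reconstruction of the unbiased 1D free-energy profile and binless
# per-sample Boltzmann reweighting onto the 2D (xi, angle) plane.

# autocorrelation function by FFT (biased normalization)
.acf_fft <- function(x, lag_max) {
  n <- length(x)
  x <- x - mean(x)
  m <- nextn(2L * n)
  f <- fft(c(x, rep(0, m - n)))
  ac <- Re(fft(Mod(f)^2, inverse = TRUE))[seq_len(lag_max + 1)] / m
  if (ac[1] <= 0) return(c(1, rep(0, lag_max)))
  ac / ac[1]
}

# integrated autocorrelation time in units of the sampling interval.
# The trapezoidal ACF sum is truncated at the earlier of (i) the first
# negative autocorrelation (initial positive sequence) and (ii) Sokal's
# self-consistent window, the first lag M with M >= 6 tau(M), which stops
# the sum from accumulating pure noise when the ACF tail stays positive by
# chance.  Returns tau >= 1/2.
.int_act <- function(x) {
  n <- length(x)
  lag_max <- min(n - 1L, 256L)
  repeat {
    rho <- .acf_fft(x, lag_max)[-1]
    neg <- which(rho < 0)
    if (length(neg) || lag_max >= n %/% 3) break
    lag_max <- min(n %/% 3, lag_max * 4L)
  }
  cut <- if (length(neg)) neg[1] - 1L else length(rho)
  tau_cum <- 0.5 + cumsum(rho)
  sokal <- which(seq_along(tau_cum) >= 6 * tau_cum)
  if (length(sokal)) cut <- min(cut, sokal[1])
  if (cut < 1L) return(0.5)
  tau_cum[cut]
}

#' Statistical inefficiency of a correlated series
#'
#' \eqn{g = 1 + 2\sum_k \rho_k} with the sum truncated at the first negative
#' autocorrelation.  `n/g` is the effective number of independent samples.
#'
#' @param x numeric series.
#' @return Inefficiency g (>= 1).
#' @export
statistical_inefficiency <- function(x) {
  max(1, 2 * .int_act(x))
}

.as_window_list <- function(windows) {
  if (inherits(windows, "us_ladder")) return(windows$windows)
  if (is.list(windows) && length(windows) &&
      all(vapply(windows, function(w)
        all(c("window", "series") %in% names(w)), logical(1))))
    return(windows)
  stop("`windows` must be a us_ladder or a list of list(window, series)")
}

#' Self-consistent 1D WHAM
#'
#' Iterates the standard WHAM equations for harmonically biased windows
#' until the per-window free-energy offsets are stationary, then returns
#' the unbiased profile shifted so the unbound plateau averages to zero.
#' Per-window sample counts are corrected for autocorrelation (statistical
#' inefficiency) by default, and the WHAM negative log-likelihood is
#' tracked across iterations.
#'
#' @param windows a `us_ladder` from [generate_ladder()] or a list of
#'   `list(window, series)` pairs.
#' @param state a [thermo_state()].
#' @param n_bins number of histogram bins.
#' @param range profile range (A); defaults to the span of the bias centers
#'   or \[4, 25\].
#' @param tol convergence tolerance on the offsets (kcal/mol).
#' @param max_iter maximum number of iterations.
#' @param inefficiency correct sample counts for autocorrelation.
#' @param plateau_from start of the plateau region for the zero convention.
#' @return List of class `wham_result` with `profile` (an [fe_profile()])
#'   and `offsets` (class `wham_offsets`: per-window free energies `f`
#'   relative to window 1, iteration count, final residual, the objective
#'   trace, and the window bookkeeping used — needed by [reweight_2d()]).
#' @export
solve_wham <- function(windows, state = thermo_state(), n_bins = 200,
                       range = c(4, 25), tol = 1e-7, max_iter = 1e5,
                       inefficiency = TRUE, plateau_from = 20) {
  wl <- .as_window_list(windows)
  nw <- length(wl)
  if (nw < 1) stop("need at least one window")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2

  centers <- vapply(wl, function(w) w$window$bias_center, numeric(1))
  ks <- vapply(wl, function(w) w$window$force_constant, numeric(1))
  H <- matrix(0, n_bins, nw)
  g <- rep(1, nw)
  n_raw <- integer(nw)
  for (i in seq_len(nw)) {
    xi <- wl[[i]]$series$xi
    keep <- xi >= range[1] & xi <= range[2]
    n_raw[i] <- sum(keep)
    if (inefficiency) g[i] <- statistical_inefficiency(xi)
    idx <- findInterval(xi[keep], breaks, rightmost.closed = TRUE)
    H[, i] <- tabulate(idx, nbins = n_bins)
  }
  n_eff <- n_raw / g
  Heff <- as.vector(H %*% (1 / g))
  raw_pooled <- rowSums(H)
  if (any(raw_pooled == 0)) {
    empty <- mids[raw_pooled == 0]
    stop(sprintf("sampling gap: no samples in %d bin(s) between %.2f and %.2f A",
                 length(empty), min(empty), max(empty)))
  }

  # bias Boltzmann factors at bin centers: M[b, i] = exp(-beta * w_i(mid_b))
  M <- exp(-state$beta * 0.5 *
             outer(mids, centers, "-")^2 %*% diag(ks, nw, nw))
  f <- numeric(nw)
  objective <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    expf <- exp(state$beta * f)
    denom <- as.vector(M %*% (n_eff * expf))
    p <- Heff / denom
    pn <- p / sum(p)
    objective[iter] <- -sum(Heff * log(pn)) +
      sum(n_eff * log(as.vector(crossprod(M, pn))))
    f_new <- -state$kT * log(as.vector(crossprod(M, p)))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol || iter >= max_iter) break
  }
  if (resid >= tol) {
    cond <- structure(
      class = c("usdimer_wham_error", "error", "condition"),
      list(message = sprintf(
        "WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
        iter, resid),
        call = sys.call(-1), residual_history = objective))
    stop(cond)
  }
  G <- -state$kT * log(p)
  profile <- fe_profile(mids, .plateau_zero(mids, G, plateau_from),
                        counts = raw_pooled, plateau_from = plateau_from)
  offsets <- structure(
    list(f = f, iterations = iter, residual = resid, objective = objective,
         windows = data.frame(center = centers, k = ks, n = n_raw,
                              g = g, n_eff = n_eff)),
    class = "wham_offsets")
  structure(list(profile = profile, offsets = offsets),
            class = "wham_result")
}

#' @export
print.wham_offsets <- function(x, ...) {
  cat(sprintf("WHAM offsets: %d windows, converged in %d iterations (residual %.2g)\n",
              nrow(x$windows), x$iterations, x$residual))
  invisible(x)
}

#' Per-sample Boltzmann reweighting onto the 2D (xi, angle) plane
#'
#' Every sample s receives the unbiased weight
#' \eqn{w_s = 1/\sum_j N_j^{eff} \exp(-\beta(w_j(\xi_s) - f_j))}, the
#' weighted samples are binned on a regular 2D grid and the surface is
#' \eqn{G_2 = -k_BT \ln(\mathrm{weighted\ histogram})}, shifted so its
#' minimum is zero.  Unsampled bins are masked, never imputed.
#'
#' @param windows the same windows the offsets were solved for.
#' @param offsets `wham_offsets` from [solve_wham()].
#' @param state a [thermo_state()].
#' @param xi_breaks,angle_breaks bin edges; defaults 75 xi-bins over the
#'   offsets' window span and 60 angle bins over \[0, 180\].
#' @param angle which angular coordinate the series carry (`"theta"` or
#'   `"phi"`); recorded as the surface's coordinate tag.
#' @param keep_weights attach the per-sample weight table.
#' @return Object of class `fe_surface2d`: bin mids, `G` (matrix, NA on
#'   masked bins), `weight` (weighted histogram), `counts`, `mask`,
#'   `angle`.
#' @export
reweight_2d <- function(windows, offsets, state = thermo_state(),
                        xi_breaks = NULL, angle_breaks = NULL,
                        angle = "theta", keep_weights = FALSE) {
  wl <- .as_window_list(windows)
  stopifnot(inherits(offsets, "wham_offsets"))
  centers <- vapply(wl, function(w) w$window$bias_center, numeric(1))
  ks <- vapply(wl, function(w) w$window$force_constant, numeric(1))
  if (length(centers) != nrow(offsets$windows) ||
      any(abs(centers - offsets$windows$center) > 1e-9) ||
      any(abs(ks - offsets$windows$k) > 1e-9))
    stop("offsets were solved for a different set of windows")
  if (is.null(xi_breaks))
    xi_breaks <- seq(min(centers), max(centers), length.out = 76)
  if (is.null(angle_breaks)) angle_breaks <- seq(0, 180, length.out = 61)

  xi <- unlist(lapply(wl, function(w) w$series$xi), use.names = FALSE)
  th <- unlist(lapply(wl, function(w) w$series[[angle]]), use.names = FALSE)
  if (is.null(th)) stop("series carry no `", angle, "` column")

  n_eff <- offsets$windows$n_eff
  f <- offsets$f
  # denom_s = sum_j n_eff_j exp(-beta (w_j(xi_s) - f_j)); each sample
  # counts as 1/g of its window so numerator and denominator are both on
  # the effective-count scale used when the offsets were solved
  B <- exp(-state$beta * 0.5 * outer(xi, centers, "-")^2 %*%
             diag(ks, length(ks), length(ks)))
  denom <- as.vector(B %*% (n_eff * exp(state$beta * f)))
  g_s <- rep(offsets$windows$g,
             vapply(wl, function(w) nrow(w$series), integer(1)))
  w_s <- 1 / (g_s * denom)

  nxb <- length(xi_breaks) - 1L
  ntb <- length(angle_breaks) - 1L
  ix <- findInterval(xi, xi_breaks, rightmost.closed = TRUE)
  it <- findInterval(th, angle_breaks, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix <= nxb & it >= 1 & it <= ntb
  idx <- (it[keep] - 1L) * nxb + ix[keep]
  W <- matrix(0, nxb, ntb)
  wsum <- rowsum(w_s[keep], idx)
  W[as.integer(rownames(wsum))] <- wsum[, 1]
  Cnt <- matrix(tabulate(idx, nbins = nxb * ntb), nxb, ntb)

  mask <- W <= 0
  G <- matrix(NA_real_, nxb, ntb)
  G[!mask] <- -state$kT * log(W[!mask])
  G <- G - min(G, na.rm = TRUE)
  out <- structure(
    list(xi_mid = (head(xi_breaks, -1) + tail(xi_breaks, -1)) / 2,
         angle_mid = (head(angle_breaks, -1) + tail(angle_breaks, -1)) / 2,
         xi_breaks = xi_breaks, angle_breaks = angle_breaks,
         G = G, weight = W, counts = Cnt, mask = mask, angle = angle),
    class = "fe_surface2d")
  if (keep_weights)
    out$samples <- data.frame(xi = xi[keep], angle = th[keep],
                              weight = w_s[keep], denom = denom[keep])
  out
}

#' @export
print.fe_surface2d <- function(x, ...) {
  cat(sprintf("2D free-energy surface (xi, %s): %d x %d bins, %d masked\n",
              x$angle, length(x$xi_mid), length(x$angle_mid), sum(x$mask)))
  invisible(x)
}

#' Marginalize a 2D surface back onto xi
#'
#' @param surface2d an `fe_surface2d`.
#' @param state a [thermo_state()].
#' @param plateau_from plateau-zero region start (A).
#' @return An [fe_profile()].
#' @export
surface_marginal <- function(surface2d, state = thermo_state(),
                             plateau_from = 20) {
  m <- rowSums(surface2d$weight)
  keep <- m > 0
  G <- -state$kT * log(m[keep])
  fe_profile(surface2d$xi_mid[keep],
             .plateau_zero(surface2d$xi_mid[keep], G, plateau_from),
             counts = rowSums(surface2d$counts)[keep],
             plateau_from = plateau_from)
}

#' Basin populations over the bound region
#'
#' Boltzmann mass of each basin region divided by the total bound-region
#' mass: \eqn{p_b = \sum_{bins \in b} e^{-\beta G_2} / \sum_{bound}
#' e^{-\beta G_2}}.  Masked (unsampled) bins carry zero mass.  The regions
#' must partition the bound area.
#'
#' @param surface2d an `fe_surface2d` from [reweight_2d()].
#' @param regions data.frame as from [default_basin_regions()].
#' @param state a [thermo_state()].
#' @param bound_boundary bound-region limit (A).
#' @return Named vector of population fractions (sums to 1).
#' @export
basin_populations <- function(surface2d, regions = default_basin_regions(),
                              state = thermo_state(), bound_boundary = 11) {
  stopifnot(inherits(surface2d, "fe_surface2d"))
  xm <- surface2d$xi_mid
  tm <- surface2d$angle_mid
  bound <- xm < bound_boundary
  mass <- exp(-state$beta * surface2d$G)
  mass[surface2d$mask] <- 0

  assign_n <- matrix(0L, length(xm), length(tm))
  pops <- setNames(numeric(nrow(regions)), regions$label)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    sel <- outer(xm >= r$xi_min & xm < r$xi_max,
                 tm >= r$theta_min & tm < r$theta_max, "&")
    assign_n <- assign_n + sel
    pops[i] <- sum(mass[sel & bound])
  }
  if (any(assign_n[bound, ] > 1))
    stop("basin regions overlap; they must partition the bound area")
  uncovered <- assign_n == 0 & bound & !surface2d$mask
  if (any(uncovered))
    stop("basin regions do not cover the whole bound area")
  pops / sum(pops)
}

#' Locate minima and the inter-minimum barrier of a 1D profile
#'
#' Finds the local minima of the (optionally smoothed) profile that lie
#' below the plateau level, refines positions sub-bin by parabolic
#' interpolation, and reports the barrier between the two deepest minima
#' (the maximum of the profile between them minus the shallower minimum).
#'
#' @param profile an [fe_profile()] or data.frame with columns `xi`, `G`.
#' @param smooth odd moving-average window in bins; 1 disables smoothing.
#' @param threshold for plateau-zeroed profiles, only dips reaching below
#'   this level (kcal/mol) count as minima; screens out statistical
#'   ripples on the plateau.  Ignored for profiles without a plateau-zero
#'   tag.
#' @return List of class `profile_minima`: `minima` (data.frame `xi`, `G`,
#'   sorted by position), `barrier` (kcal/mol, NA with fewer than two
#'   minima) and `barrier_xi`.
#' @export
locate_minima <- function(profile, smooth = 5, threshold = -0.5) {
  xi <- profile$xi
  G <- profile$G
  stopifnot(length(xi) >= 3, smooth >= 1, smooth %% 2 == 1)
  Gs <- G
  if (smooth > 1) {
    f <- as.numeric(stats::filter(G, rep(1 / smooth, smooth), sides = 2))
    Gs <- ifelse(is.na(f), G, f)
  }
  below <- if (identical(attr(profile, "zero"), "plateau")) threshold else Inf
  n <- length(Gs)
  cand <- which(Gs[2:(n - 1)] < Gs[1:(n - 2)] &
                  Gs[2:(n - 1)] <= Gs[3:n]) + 1L
  cand <- cand[Gs[cand] < below]
  if (!length(cand))
    stop("no local minima found", if (is.finite(below))
      " below the plateau" else "")
  refine <- function(i, neg = FALSE) {
    y <- Gs[(i - 1):(i + 1)] * if (neg) -1 else 1
    den <- y[1] - 2 * y[2] + y[3]
    d <- if (abs(den) < 1e-15) 0 else 0.5 * (y[1] - y[3]) / den
    d <- max(min(d, 0.5), -0.5)
    x <- xi[i] + d * (xi[2] - xi[1])
    g <- y[2] - 0.25 * (y[1] - y[3]) * d
    c(x, (if (neg) -1 else 1) * g)
  }
  ref <- t(vapply(cand, refine, numeric(2)))
  minima <- data.frame(xi = ref[, 1], G = ref[, 2])
  minima <- minima[order(minima$xi), , drop = FALSE]
  rownames(minima) <- NULL

  barrier <- NA_real_
  barrier_xi <- NA_real_
  if (nrow(minima) >= 2) {
    deep <- order(minima$G)[1:2]
    i1 <- cand[order(Gs[cand])[1:2]]
    lo <- min(i1); hi <- max(i1)
    inner <- lo:hi
    j <- inner[which.max(Gs[inner])]
    top <- if (j > 1 && j < n) refine(j, neg = TRUE) else c(xi[j], Gs[j])
    barrier <- top[2] - max(minima$G[deep])
    barrier_xi <- top[1]
  }
  structure(list(minima = minima, barrier = barrier,
                 barrier_xi = barrier_xi),
            class = "profile_minima")
}

#' @export
print.profile_minima <- function(x, ...) {
  cat("Profile minima:\n")
  print(x$minima, digits = 4)
  if (!is.na(x$barrier))
    cat(sprintf("barrier: %.3f kcal/mol at %.2f A\n", x$barrier,
                x$barrier_xi))
  invisible(x)
}

#' Orientation-class statistics of a 2D surface
#'
#' Splits the bound region at theta = 90 deg into parallel (theta < 90) and
#' antiparallel (theta > 90) dimers and reports class probabilities and
#' Boltzmann-weighted mean distances.
#'
#' @param surface2d an `fe_surface2d` carrying the `theta` coordinate.
#' @param state a [thermo_state()].
#' @param bound_boundary bound-region limit (A).
#' @return List: `p_parallel`, `p_antiparallel`, `mean_xi_parallel`,
#'   `mean_xi_antiparallel`.
#' @export
orientation_stats <- function(surface2d, state = thermo_state(),
                              bound_boundary = 11) {
  stopifnot(inherits(surface2d, "fe_surface2d"))
  if (!identical(surface2d$angle, "theta"))
    stop("orientation statistics require the theta coordinate; this ",
         "surface carries `", surface2d$angle, "`")
  mass <- exp(-state$beta * surface2d$G)
  mass[surface2d$mask] <- 0
  bound <- surface2d$xi_mid < bound_boundary
  par_cols <- surface2d$angle_mid < 90
  m_par <- sum(mass[bound, par_cols])
  m_anti <- sum(mass[bound, !par_cols])
  xi <- surface2d$xi_mid[bound]
  list(p_parallel = m_par / (m_par + m_anti),
       p_antiparallel = m_anti / (m_par + m_anti),
       mean_xi_parallel =
         sum(xi * rowSums(mass[bound, par_cols, drop = FALSE])) / m_par,
       mean_xi_antiparallel =
         sum(xi * rowSums(mass[bound, !par_cols, drop = FALSE])) / m_anti)
}
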