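# Analytic reference free-energy surface G(xi, theta) for drug dimerization.
# xi is the interchromophore distance (Angstrom), theta the angle between the
# monomers' long principal axes (degrees); theta < 90 is a parallel dimer,
# theta > 90 antiparallel.

#' Construct an analytic reference free-energy surface
#'
#' The surface is a sum of four bivariate Gaussian basins (the bound dimer
#' geometries), an exponential repulsive wall at short distance and a
#' monotone attraction shoulder that decays to zero at `attr_off`.  A C1
#' switching function takes the surface exactly to `plateau` for
#' `xi >= switch_off`, so the unbound plateau is flat by construction.
#'
#' @param basins data.frame with columns `label` (exactly "I","II","III","IV";
#'   I and II are antiparallel, `center_theta > 90`, III and IV parallel),
#'   `center_xi` (A, in \[4, 11\]), `center_theta` (deg, in \[0, 180\]),
#'   `width_xi` (A), `width_theta` (deg) and `depth` (kcal/mol, <= 0).
#' @param wall_x,wall_scale,wall_eps repulsive wall
#'   `wall_eps * exp(-(xi - wall_x)/wall_scale)`.
#' @param attr_depth depth (kcal/mol, >= 0) of the attraction shoulder, which
#'   equals `-attr_depth` for `xi <= attr_on` and rises smoothly to 0 at
#'   `attr_off`.
#' @param attr_on,attr_off onset and outer extent (A) of the attraction.
#' @param switch_on,switch_off C1 plateau switch: the surface equals
#'   `plateau` exactly for `xi >= switch_off`.
#' @param plateau plateau free-energy level (kcal/mol), default 0.
#' @return Object of class `ref_surface`.
#' @seealso [surface_energy()], [project_profile()], [calibrate_surface()],
#'   [default_surface()]
#' @export
reference_surface <- function(basins,
                              wall_x = 3.2, wall_scale = 0.3, wall_eps = 1,
                              attr_depth = 0.25, attr_on = 7, attr_off = 20,
                              switch_on = 18.5, switch_off = 20,
                              plateau = 0) {
  basins <- as.data.frame(basins)
  need <- c("label", "center_xi", "center_theta", "width_xi", "width_theta",
            "depth")
  if (!all(need %in% names(basins)))
    stop("`basins` must have columns: ", paste(need, collapse = ", "))
  if (!identical(sort(as.character(basins$label)), c("I", "II", "III", "IV")))
    stop("`basins` must contain exactly the four labels I, II, III, IV")
  basins <- basins[match(c("I", "II", "III", "IV"), basins$label), need]
  rownames(basins) <- NULL
  if (any(basins$center_xi < 4 | basins$center_xi > 11))
    stop("basin centers must satisfy 4 <= center_xi <= 11")
  if (any(basins$center_theta < 0 | basins$center_theta > 180))
    stop("basin center_theta must lie in [0, 180]")
  anti <- basins$label %in% c("I", "II")
  if (any(basins$center_theta[anti] <= 90) ||
      any(basins$center_theta[!anti] >= 90))
    stop("basins I and II must have center_theta > 90 (antiparallel), ",
         "III and IV < 90 (parallel)")
  if (any(basins$depth > 0)) stop("basin depths must be <= 0 (kcal/mol)")
  if (any(basins$width_xi <= 0 | basins$width_theta <= 0))
    stop("basin widths must be positive")
  if (attr_depth < 0) stop("`attr_depth` must be >= 0")
  if (!(attr_on < attr_off) || !(switch_on < switch_off))
    stop("need attr_on < attr_off and switch_on < switch_off")
  structure(
    list(basins = basins, wall_x = wall_x, wall_scale = wall_scale,
         wall_eps = wall_eps, attr_depth = attr_depth, attr_on = attr_on,
         attr_off = attr_off, switch_on = switch_on,
         switch_off = switch_off, plateau = plateau),
    class = "ref_surface")
}

# parameter list handed to the C++ kernels
.sp <- function(surface) {
  b <- surface$basins
  list(basins = cbind(b$center_xi, b$center_theta, b$width_xi,
                      b$width_theta, b$depth),
       wall_x = surface$wall_x, wall_scale = surface$wall_scale,
       wall_eps = surface$wall_eps, attr_depth = surface$attr_depth,
       attr_on = surface$attr_on, attr_off = surface$attr_off,
       switch_on = surface$switch_on, switch_off = surface$switch_off,
       plateau = surface$plateau)
}

#' @export
print.ref_surface <- function(x, ...) {
  cat("Reference free-energy surface G(xi, theta)\n")
  cat(sprintf("  plateau %g kcal/mol for xi >= %g A; attraction %0.3g kcal/mol to %g A\n",
              x$plateau, x$switch_off, -x$attr_depth, x$attr_off))
  print(x$basins, digits = 3)
  invisible(x)
}

.check_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 180))
    stop("`theta` must lie in [0, 180] degrees")
}

#' Evaluate the reference surface
#'
#' @param surface a [reference_surface()].
#' @param xi distance(s) in Angstrom (> 0).
#' @param theta angle(s) in degrees, in \[0, 180\]; recycled against `xi`.
#' @return Free energy in kcal/mol, vectorized over inputs.
#' @export
surface_energy <- function(surface, xi, theta) {
  stopifnot(inherits(surface, "ref_surface"))
  if (any(!is.finite(xi)) || any(xi <= 0)) stop("`xi` must be positive")
  .check_theta(theta)
  n <- max(length(xi), length(theta))
  cpp_surface_energy(.sp(surface), rep_len(as.numeric(xi), n),
                     rep_len(as.numeric(theta), n))
}

# energy on the outer grid xi x theta (matrix), used by all quadratures
.surface_grid <- function(surface, xi, theta) {
  cpp_surface_grid(.sp(surface), as.numeric(xi), as.numeric(theta))
}

#' Analytic gradient of the reference surface
#'
#' @inheritParams surface_energy
#' @return data.frame with `dG_dxi` (kcal mol^-1 A^-1) and `dG_dtheta`
#'   (kcal mol^-1 deg^-1).
#' @export
surface_gradient <- function(surface, xi, theta) {
  stopifnot(inherits(surface, "ref_surface"))
  if (any(!is.finite(xi)) || any(xi <= 0)) stop("`xi` must be positive")
  .check_theta(theta)
  n <- max(length(xi), length(theta))
  g <- cpp_surface_gradient(.sp(surface), rep_len(as.numeric(xi), n),
                            rep_len(as.numeric(theta), n))
  data.frame(dG_dxi = g[, 1], dG_dtheta = g[, 2])
}

# ---- free-energy profile container ------------------------------------------

#' Construct a 1D free-energy profile
#'
#' Container for G(xi) on a grid, with the zero convention recorded.  WHAM
#' and the quadrature projections both return this class; the thermodynamics
#' functions consume it.
#'
#' @param xi grid of distances (A), strictly increasing.
#' @param G free energy (kcal/mol) at `xi`.
#' @param counts optional effective sample count per point (WHAM output).
#' @param zero zero convention tag; `"plateau"` means the region
#'   `xi >= plateau_from` averages to zero.
#' @param plateau_from start of the plateau region (A), default 20.
#' @return Object of class `fe_profile` (also a data.frame with columns
#'   `xi`, `G` and optionally `counts`).
#' @export
fe_profile <- function(xi, G, counts = NULL, zero = "plateau",
                       plateau_from = 20) {
  stopifnot(length(xi) == length(G), !is.unsorted(xi, strictly = TRUE))
  df <- data.frame(xi = xi, G = G)
  if (!is.null(counts)) df$counts <- counts
  structure(df, class = c("fe_profile", "data.frame"),
            zero = zero, plateau_from = plateau_from)
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile: %d points over [%.2f, %.2f] A, zero = %s\n",
              nrow(x), min(x$xi), max(x$xi), attr(x, "zero")))
  invisible(x)
}

# trapezoidal quadrature
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# shift so that the plateau region averages to zero
.plateau_zero <- function(xi, G, plateau_from = 20) {
  sel <- xi >= plateau_from
  if (!any(sel)) stop("profile does not reach the plateau region (xi >= ",
                      plateau_from, " A); cannot apply the zero convention")
  G - mean(G[sel])
}

#' Project the surface onto the distance coordinate
#'
#' Computes \eqn{G_1(\xi) = -k_BT \ln \int e^{-\beta G(\xi,\theta)}
#' d\theta / |\Delta\theta|} over the chosen angular range by dense
#' trapezoidal quadrature, then shifts the profile so the unbound plateau
#' (`xi >= plateau_from`) averages to zero.  Normalizing by the width of the
#' filtered range makes the plateau land at the surface's plateau level for
#' every filter, so parallel and antiparallel profiles recombine into the
#' full profile by a log-sum-exp with equal range weights.
#'
#' @param surface a [reference_surface()].
#' @param state a [thermo_state()].
#' @param theta_filter `"all"`, `"parallel"` (theta < 90) or
#'   `"antiparallel"` (theta > 90), or a numeric length-2 range in degrees.
#' @param xi evaluation grid (A).
#' @param n_theta number of quadrature nodes across the filtered range.
#' @param plateau_from start of the plateau region used as the zero (A).
#' @return An [fe_profile()].
#' @export
project_profile <- function(surface, state = thermo_state(),
                            theta_filter = c("all", "parallel", "antiparallel"),
                            xi = seq(4, 25, by = 0.01), n_theta = 361,
                            plateau_from = surface$switch_off) {
  stopifnot(inherits(surface, "ref_surface"), inherits(state, "thermo_state"))
  if (is.numeric(theta_filter)) {
    rng <- sort(theta_filter[1:2])
  } else {
    theta_filter <- match.arg(theta_filter)
    rng <- switch(theta_filter, all = c(0, 180), parallel = c(0, 90),
                  antiparallel = c(90, 180))
  }
  if (diff(rng) <= 0 || rng[1] < 0 || rng[2] > 180)
    stop("empty or invalid theta filter range")
  th <- seq(rng[1], rng[2], length.out = n_theta)
  E <- .surface_grid(surface, xi, th)
  W <- exp(-state$beta * E)
  mass <- apply(W, 1, function(w) .trapz(th, w)) / diff(rng)
  G1 <- -state$kT * log(mass)
  fe_profile(xi, .plateau_zero(xi, G1, plateau_from),
             zero = "plateau", plateau_from = plateau_from)
}

#' Project the bound region onto the angular coordinate
#'
#' \eqn{F(\theta) = -k_BT \ln \int_{\xi_{min}}^{R} e^{-\beta G(\xi,\theta)}
#' d\xi}, shifted so its minimum is zero.  This is the 1D landscape on which
#' the parallel/antiparallel flipping time is computed.
#'
#' @param surface a [reference_surface()].
#' @param state a [thermo_state()].
#' @param bound_boundary upper distance bound R of the dimeric state (A).
#' @param theta evaluation grid (deg).
#' @param xi_min lower integration limit (A).
#' @param n_xi quadrature nodes in xi.
#' @return data.frame with columns `theta` (deg) and `F` (kcal/mol),
#'   class `angle_profile`.
#' @export
project_angle <- function(surface, state = thermo_state(),
                          bound_boundary = 11,
                          theta = seq(0, 180, by = 0.5),
                          xi_min = 4, n_xi = 701) {
  stopifnot(inherits(surface, "ref_surface"), inherits(state, "thermo_state"))
  if (bound_boundary <= xi_min) stop("`bound_boundary` must exceed `xi_min`")
  xi <- seq(xi_min, bound_boundary, length.out = n_xi)
  E <- .surface_grid(surface, xi, theta)
  W <- exp(-state$beta * E)
  mass <- apply(W, 2, function(w) .trapz(xi, w))
  FF <- -state$kT * log(mass)
  structure(data.frame(theta = theta, F = FF - min(FF)),
            class = c("angle_profile", "data.frame"))
}

#' Scan the bound region for local minima of the surface
#'
#' Dense-grid scan used to verify that a calibrated surface has exactly the
#' intended number of bound-state minima.
#'
#' @param surface a [reference_surface()].
#' @param bound_boundary bound-region limit in xi (A).
#' @param dxi,dtheta grid steps.
#' @return data.frame of strict interior local minima (xi, theta, G).
#' @export
surface_minima <- function(surface, bound_boundary = 11,
                           dxi = 0.05, dtheta = 1) {
  xi <- seq(3.2, bound_boundary, by = dxi)
  th <- seq(0, 180, by = dtheta)
  E <- .surface_grid(surface, xi, th)
  nx <- length(xi); nt <- length(th)
  res <- list()
  for (j in 2:(nt - 1)) {
    for (i in 2:(nx - 1)) {
      e <- E[i, j]
      nb <- c(E[i - 1, j], E[i + 1, j], E[i, j - 1], E[i, j + 1],
              E[i - 1, j - 1], E[i - 1, j + 1], E[i + 1, j - 1],
              E[i + 1, j + 1])
      if (all(e < nb))
        res[[length(res) + 1]] <- data.frame(xi = xi[i], theta = th[j], G = e)
    }
  }
  if (!length(res)) return(data.frame(xi = numeric(), theta = numeric(),
                                      G = numeric()))
  do.call(rbind, res)
}

# ---- serialization ----------------------------------------------------------

#' Write / read a reference surface as a YAML config
#'
#' @param surface a [reference_surface()].
#' @param path file path.
#' @return `write_surface` returns `path` invisibly; `read_surface` returns
#'   the [reference_surface()].
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "ref_surface"))
  obj <- c(list(format_version = 1L), unclass(surface))
  obj$basins <- lapply(seq_len(nrow(surface$basins)), function(i)
    as.list(surface$basins[i, ]))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$format_version) && obj$format_version > 1)
    stop("surface file format version ", obj$format_version,
         " is newer than this package supports")
  basins <- do.call(rbind, lapply(obj$basins, as.data.frame))
  do.call(reference_surface,
          c(list(basins = basins),
            obj[setdiff(names(obj), c("basins", "format_version"))]))
}
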