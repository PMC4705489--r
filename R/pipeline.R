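# End-to-end pipeline: calibrated surface -> umbrella ladder -> WHAM ->
# 2D reweighting -> dimerization thermodynamics -> diffusion profile ->
# association rate -> rotational diffusion and flipping MFPT -> report.

#' Pipeline configuration
#'
#' A fully serializable description of one pipeline run; a run is
#' reproducible from the configuration alone.  All stochastic stages derive
#' their seeds deterministically from `seed`.
#'
#' @param seed base seed for every stochastic stage.
#' @param temperature temperature (K).
#' @param ladder named list of [ladder_config()] overrides.
#' @param wham named list: `n_bins`, `tol`, `max_iter`, `smooth`.
#' @param bound_boundary dimeric boundary R (A).
#' @param box_volume simulation-box volume (A^3).
#' @param concentrations total concentrations (mol/L) at which to report
#'   dimer fractions.
#' @param onset_fraction dimeric fraction defining the onset concentration.
#' @param kinetics named list: `outer` boundary (A), `jacobian_mode`,
#'   `wobble_steps`, `wobble_dt` (ns), `wobble_domain` (deg).
#' @param recalibrate re-run [calibrate_surface()] instead of loading the
#'   shipped calibrated surface.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, temperature = 300,
                            ladder = list(), wham = list(),
                            bound_boundary = 11, box_volume = 62.5^3,
                            concentrations = 1e-6, onset_fraction = 0.10,
                            kinetics = list(), recalibrate = FALSE) {
  ladder <- modifyList(list(xi_min = 4, xi_max = 25, n_windows = 17,
                            force_constant = 4, n_steps = 8e6, dt = 0.005,
                            output_stride = 400, d_xi = 0.1, d_theta = 3800,
                            theta0 = 90, domain = c(2, 25)), ladder)
  wham <- modifyList(list(n_bins = 200, tol = 1e-7, max_iter = 1e5,
                          smooth = 5), wham)
  kinetics <- modifyList(list(outer = 25, jacobian_mode = "integrated",
                              wobble_steps = 2e5, wobble_dt = 5e-4,
                              wobble_domain = c(0.2, 90)), kinetics)
  structure(list(seed = seed, temperature = temperature, ladder = ladder,
                 wham = wham, bound_boundary = bound_boundary,
                 box_volume = box_volume, concentrations = concentrations,
                 onset_fraction = onset_fraction, kinetics = kinetics,
                 recalibrate = recalibrate),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path (YAML).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj)
}

.stage <- function(name, expr, verbose = TRUE) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

# dG and basin-II population recomputed on temporal halves of every window;
# half the spread is a cheap two-replicate error estimate
.half_errors <- function(ladder, state, cfg, regions) {
  halves <- lapply(1:2, function(h) {
    wl <- lapply(ladder$windows, function(w) {
      n <- nrow(w$series)
      idx <- if (h == 1) seq_len(n %/% 2) else (n %/% 2 + 1):n
      s <- w$series[idx, ]
      attr(s, "meta") <- attr(w$series, "meta")
      class(s) <- class(w$series)
      list(window = w$window, series = s)
    })
    wh <- solve_wham(wl, state, n_bins = cfg$wham$n_bins,
                     range = c(cfg$ladder$xi_min, cfg$ladder$xi_max),
                     tol = cfg$wham$tol, max_iter = cfg$wham$max_iter)
    s2 <- reweight_2d(wl, wh$offsets, state)
    dg <- dimerization_constant(wh$profile, state, R = cfg$bound_boundary,
                                box_volume = cfg$box_volume)$delta_g
    pop <- basin_populations(s2, regions, state, cfg$bound_boundary)
    c(dg = dg, pop_II = unname(pop["II"]))
  })
  list(delta_g_se = abs(halves[[1]]["dg"] - halves[[2]]["dg"]) / 2,
       pop_II_se = abs(halves[[1]]["pop_II"] - halves[[2]]["pop_II"]) / 2)
}

#' Run the full analysis pipeline
#'
#' Executes generate -> WHAM -> reweight -> thermodynamics -> kinetics on
#' the calibrated reference surface and collects every headline quantity in
#' a run report.  Rerunning with an identical configuration reproduces all
#' numbers exactly.
#'
#' @param config a [pipeline_config()].
#' @param surface optional [reference_surface()]; defaults to the shipped
#'   calibrated surface (or a fresh calibration when
#'   `config$recalibrate`).
#' @param output_dir optional directory for intermediate artifacts
#'   (profile/surface/diffusion TSVs, report JSON, config YAML).
#' @param verbose narrate stages.
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), surface = NULL,
                         output_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  state <- thermo_state(config$temperature)

  surface <- .stage("surface", {
    if (!is.null(surface)) surface
    else if (isTRUE(config$recalibrate)) calibrate_surface(state = state)
    else default_surface()
  }, verbose)

  ladder <- .stage("generate", {
    lc <- do.call(ladder_config,
                  c(config$ladder, list(base_seed = config$seed)))
    generate_ladder(surface, lc, state)
  }, verbose)

  wham <- .stage("wham", {
    solve_wham(ladder, state, n_bins = config$wham$n_bins,
               range = c(config$ladder$xi_min, config$ladder$xi_max),
               tol = config$wham$tol, max_iter = config$wham$max_iter)
  }, verbose)

  surf2d <- .stage("reweight", reweight_2d(ladder, wham$offsets, state),
                   verbose)

  regions <- default_basin_regions(xi_min = config$ladder$xi_min,
                                   bound_boundary = config$bound_boundary)
  mins <- .stage("minima", locate_minima(wham$profile,
                                         smooth = config$wham$smooth),
                 verbose)
  pops <- .stage("populations",
                 basin_populations(surf2d, regions, state,
                                   config$bound_boundary), verbose)
  orient <- .stage("orientation",
                   orientation_stats(surf2d, state, config$bound_boundary),
                   verbose)

  thermo <- .stage("thermo", {
    dres <- dimerization_constant(wham$profile, state,
                                  R = config$bound_boundary,
                                  box_volume = config$box_volume)
    list(dres = dres,
         fractions = dimer_fraction(dres$delta_g, config$concentrations,
                                    state),
         onset = onset_concentration(dres$delta_g, config$onset_fraction,
                                     state))
  }, verbose)

  errs <- .stage("errors", .half_errors(ladder, state, config, regions),
                 verbose)

  diff_prof <- .stage("diffusion", {
    est <- lapply(ladder$windows, function(w)
      estimate_window_diffusion(w$series,
                                min_samples = min(1e4, nrow(w$series) * 0.8)))
    mx <- vapply(ladder$windows, function(w) mean(w$series$xi), numeric(1))
    o <- order(mx)
    list(profile = build_diffusion_profile(mx[o],
                                           vapply(est, `[[`, 0, "D")[o],
                                           vapply(est, `[[`, 0, "se")[o]),
         table = data.frame(xi = mx[o],
                            D = vapply(est, `[[`, 0, "D")[o],
                            se = vapply(est, `[[`, 0, "se")[o]))
  }, verbose)

  kon <- .stage("association", {
    association_rate(wham$profile, diff_prof$profile,
                     absorbing = config$bound_boundary,
                     outer = config$kinetics$outer, state = state,
                     jacobian_mode = config$kinetics$jacobian_mode)
  }, verbose)

  flip <- .stage("flipping", {
    # angular free energy of the bound region from the reweighted surface
    bound <- surf2d$xi_mid < config$bound_boundary
    m <- colSums(surf2d$weight[bound, , drop = FALSE])
    keep <- m > 0
    Ftab <- data.frame(theta = surf2d$angle_mid[keep],
                       F = -state$kT * log(m[keep]))
    Ftab$F <- Ftab$F - min(Ftab$F)
    par_side <- Ftab$theta < 90
    theta0 <- Ftab$theta[par_side][which.min(Ftab$F[par_side])]
    theta1 <- Ftab$theta[!par_side][which.min(Ftab$F[!par_side])]
    # rotational diffusion from a wobble run confined to the parallel cone
    wob <- generate_wobble(config$ladder$d_theta,
                           .as_potential_fun(Ftab),
                           n_steps = config$kinetics$wobble_steps,
                           dt = config$kinetics$wobble_dt,
                           seed = config$seed + 555L, state = state,
                           domain = config$kinetics$wobble_domain)
    rot <- rotational_diffusion_wobbling(wob, state = state)
    d_rot_per_s <- rot$d_rot * 1e9  # deg^2/ns -> deg^2/s
    mf <- mfpt_zwanzig(Ftab, d_rot_per_s, theta0, theta1,
                       reflecting_at = 0, state = state)
    list(Ftab = Ftab, theta0 = theta0, theta1 = theta1, rot = rot,
         d_rot_per_s = d_rot_per_s, tau_s = mf$tau,
         rate_per_s = flipping_rate(mf$tau))
  }, verbose)

  report <- structure(list(
    seed = config$seed,
    temperature_K = state$temperature,
    delta_g_kcal = thermo$dres$delta_g,
    delta_g_se = unname(errs$delta_g_se),
    K = thermo$dres$K,
    P_bound = thermo$dres$P_b,
    onset_uM = thermo$onset * 1e6,
    dimer_fraction_pct = setNames(100 * thermo$fractions,
                                  paste0(config$concentrations * 1e6, "uM")),
    populations_pct = 100 * pops,
    pop_II_se_pct = unname(100 * errs$pop_II_se),
    minima_xi_A = mins$minima$xi,
    minima_depth_kcal = mins$minima$G,
    barrier_kcal = mins$barrier,
    p_parallel = orient$p_parallel,
    p_antiparallel = orient$p_antiparallel,
    mean_xi_parallel_A = orient$mean_xi_parallel,
    mean_xi_antiparallel_A = orient$mean_xi_antiparallel,
    diffusion_table = diff_prof$table,
    k_on_per_M_s = kon$k_on,
    d_rot_deg2_s = flip$d_rot_per_s,
    mfpt_flip_ns = flip$tau_s * 1e9,
    flipping_rate_per_s = flip$rate_per_s,
    convention = thermo$dres$convention),
    class = "run_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile(wham$profile, file.path(output_dir, "profile.tsv"))
    write_surface2d(surf2d, file.path(output_dir, "surface2d.tsv"))
    write.table(diff_prof$table, file.path(output_dir, "diffusion.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_pipeline_config(config, file.path(output_dir, "config.yml"))
    write_report(report, file.path(output_dir, "report.json"))
  }
  report
}

#' Write a run report as JSON
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  obj$diffusion_table <- as.list(obj$diffusion_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  dG0 = %.2f +/- %.2f kcal/mol (K = %.3g)\n",
              x$delta_g_kcal, x$delta_g_se, x$K))
  cat(sprintf("  onset (10%% dimeric): %.3f uM\n", x$onset_uM))
  cat(sprintf("  dimer fraction: %s\n",
              paste(sprintf("%s -> %.1f%%", names(x$dimer_fraction_pct),
                            x$dimer_fraction_pct), collapse = ", ")))
  cat(sprintf("  basin populations (%%): %s\n",
              paste(sprintf("%s %.1f", names(x$populations_pct),
                            x$populations_pct), collapse = ", ")))
  cat(sprintf("  minima: %s A, depths %s kcal/mol, barrier %.2f\n",
              paste(sprintf("%.2f", x$minima_xi_A), collapse = "/"),
              paste(sprintf("%.2f", x$minima_depth_kcal), collapse = "/"),
              x$barrier_kcal))
  cat(sprintf("  k_on = %.3g 1/(M s); flip MFPT = %.1f ns (%.3g 1/s)\n",
              x$k_on_per_M_s, x$mfpt_flip_ns, x$flipping_rate_per_s))
  invisible(x)
}
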