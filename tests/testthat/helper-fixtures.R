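# Shared fixtures, computed lazily and cached for the whole run.

.fix <- new.env(parent = emptyenv())

fix <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_state <- function() thermo_state()

fix_surface <- function() fix("surface", default_surface)

# a surface that is flat in both coordinates (zero basins, no wall, no
# attraction); basin rows still carry valid metadata
flat_surface <- function(plateau = 0) {
  reference_surface(
    data.frame(label = c("I", "II", "III", "IV"),
               center_xi = c(4.5, 6.5, 4.5, 6.5),
               center_theta = c(150, 150, 30, 30),
               width_xi = 1, width_theta = 30, depth = 0),
    wall_eps = 0, attr_depth = 0, plateau = plateau)
}

# mirror-symmetric surface: equal depths/widths, centers symmetric about
# xi = 5.5 and theta = 90
symmetric_surface <- function() {
  reference_surface(
    data.frame(label = c("I", "II", "III", "IV"),
               center_xi = c(4.5, 6.5, 4.5, 6.5),
               center_theta = c(150, 150, 30, 30),
               width_xi = 0.7, width_theta = 30, depth = -5),
    wall_eps = 0, attr_depth = 0.2)
}

# reduced-size ladder on the calibrated surface: enough sampling for
# position-level checks at a fraction of the default cost
fix_small_ladder <- function() fix("small_ladder", function() {
  generate_ladder(fix_surface(),
                  ladder_config(base_seed = 424, n_steps = 1e6,
                                output_stride = 100))
})

fix_small_wham <- function() fix("small_wham", function() {
  solve_wham(fix_small_ladder())
})

fix_small_surface2d <- function() fix("small_surface2d", function() {
  reweight_2d(fix_small_ladder(), fix_small_wham()$offsets)
})

# the full "reproduce" pipeline run shared by the acceptance tests
fix_pipeline_report <- function() fix("pipeline_report", function() {
  run_pipeline(pipeline_config(seed = 19109), verbose = FALSE)
})

# build an fe_surface2d container directly from an analytic surface by
# dense quadrature (used to test the surface-consumers in isolation)
quadrature_surface2d <- function(surface, state = thermo_state(),
                                 nx = 150, nt = 120, angle = "theta") {
  xb <- seq(4, 25, length.out = nx + 1)
  tb <- seq(0, 180, length.out = nt + 1)
  xm <- (head(xb, -1) + tail(xb, -1)) / 2
  tm <- (head(tb, -1) + tail(tb, -1)) / 2
  E <- outer(xm, tm, function(x, t) surface_energy(surface, x, t))
  W <- exp(-state$beta * E)
  structure(list(xi_mid = xm, angle_mid = tm, xi_breaks = xb,
                 angle_breaks = tb, G = E - min(E), weight = W,
                 counts = matrix(1, nx, nt),
                 mask = matrix(FALSE, nx, nt), angle = angle),
            class = "fe_surface2d")
}
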