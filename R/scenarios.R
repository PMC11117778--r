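# Scenario configuration and the four in-study example geometries.

#' Scenario configuration
#'
#' Collects every knob of a simulation scenario: domain and
#' discretisation, the lumen / release-region geometry, sprout positions,
#' mechanical loading, branching-law constants and engine controls.
#' Distances in mm, concentrations in g/mm^3, diffusivity in mm^2/s,
#' pressure in MPa.
#'
#' @param name Scenario label.
#' @param side Domain side length (mm).
#' @param nodes_per_side Nodes per side of the regular cloud.
#' @param gauss_order Background quadrature order per direction.
#' @param n_influence Influence-domain size (nodes per evaluation point).
#' @param mq [mq_params()].
#' @param D_base Basal VEGF diffusion coefficient (mm^2/s).
#' @param conc_lumen Basal VEGF concentration at the capillary lumen.
#' @param conc_release VEGF concentration in the release region.
#' @param lumen_rects,release_rects Lists of rectangles
#'   (xmin, ymin, xmax, ymax) whose nodes carry the essential
#'   concentrations; tips stop on entering a release rectangle.
#' @param sprouts Matrix of initial sprout positions (on the endothelial
#'   monolayer).
#' @param loading `"none"`, `"compression"` or `"traction"`.
#' @param alpha Coupling magnitude (the analysed values are 0.5, 1, 1.5).
#' @param pressure Applied hydrostatic pressure magnitude (MPa).
#' @param region_center,region_radius Loaded circle (mm).
#' @param d0 Branching-law base distance (mm).
#' @param compression_factor Branching-threshold multiplier inside the
#'   compressed circle.
#' @param branch_angle Initial deflection of child tips from the parent
#'   direction (rad).
#' @param theta_mode `"zero"` (deterministic gradient ascent) or
#'   `"uniform"` (random rotation per step, used for multi-seed
#'   experiments).
#' @param theta_range Half-width of the uniform rotation law (rad).
#' @param step_length Migration step (average cell-to-cell distance, mm).
#' @param max_iter Iteration cap.
#' @param seed RNG seed.
#' @param consistency_edges Domain edges carrying essential concentrations
#'   along their whole length (adds the boundary consistency term there).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom",
                            side = 5, nodes_per_side = 51L,
                            gauss_order = 3L, n_influence = 16L,
                            mq = mq_params(),
                            D_base = 1.16e-6,
                            conc_lumen = 2.35e-13,
                            conc_release = 6.43e-13,
                            lumen_rects = list(),
                            release_rects = list(),
                            sprouts = matrix(numeric(0), 0, 2),
                            loading = c("none", "compression", "traction"),
                            alpha = 1.0, pressure = 0.0067,
                            region_center = c(2.5, 2.5),
                            region_radius = 1.0,
                            d0 = 1.0, compression_factor = 0.5,
                            branch_angle = pi / 6,
                            theta_mode = c("zero", "uniform"),
                            theta_range = pi / 4,
                            step_length = NULL,
                            max_iter = 300L, seed = 1L,
                            consistency_edges = NULL) {
  loading <- match.arg(loading)
  theta_mode <- match.arg(theta_mode)
  spacing <- side / (nodes_per_side - 1)
  if (is.null(step_length)) step_length <- spacing
  sprouts <- matrix(as.numeric(sprouts), ncol = 2)
  if (nrow(sprouts) > 0) {
    if (any(sprouts[, 1] < 0 | sprouts[, 1] > side |
            sprouts[, 2] < 0 | sprouts[, 2] > side))
      amech_stop("sprout positions must lie inside the domain",
                 "invalid_argument")
  }
  structure(list(name = name, side = side,
                 nodes_per_side = as.integer(nodes_per_side),
                 gauss_order = as.integer(gauss_order),
                 n_influence = as.integer(n_influence), mq = mq,
                 D_base = D_base, conc_lumen = conc_lumen,
                 conc_release = conc_release,
                 lumen_rects = lumen_rects,
                 release_rects = release_rects,
                 sprouts = sprouts, loading = loading, alpha = alpha,
                 pressure = pressure, region_center = region_center,
                 region_radius = region_radius, d0 = d0,
                 compression_factor = compression_factor,
                 branch_angle = branch_angle, theta_mode = theta_mode,
                 theta_range = theta_range, step_length = step_length,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 consistency_edges = consistency_edges),
            class = "scenario_config")
}

# Geometry of the four example presets, on the 5 x 5 mm, 51 x 51 cloud.
# Boundary strips are one internodal spacing thick; positions are read
# qualitatively off the published domain sketches.
preset_table <- function(side = 5, h = 0.1) {
  hh <- h / 2
  list(
    example1 = list(
      lumen = list(c(0, 0, side, hh)),
      release = list(c(0, side - hh, side, side)),
      sprouts = matrix(c(side / 2, h), 1, 2),
      edges = c("bottom", "top")),
    example2 = list(
      lumen = list(c(0, 0, side, hh)),
      release = list(c(0, side - hh, side, side)),
      sprouts = matrix(c(1.5, h, 3.5, h), 2, 2, byrow = TRUE),
      edges = c("bottom", "top")),
    example3 = list(
      lumen = list(c(0, 0, side, hh)),
      release = list(c(side - 1, side - 1, side, side)),
      sprouts = matrix(c(side / 2, h), 1, 2),
      edges = "bottom"),
    example4 = list(
      lumen = list(c(0, 0, side, hh), c(0, side - hh, side, side)),
      release = list(c(side / 2 - 0.5, side / 2 - hh,
                       side / 2 + 0.5, side / 2 + hh)),
      sprouts = matrix(c(1.5, h, 3.5, h,
                         1.5, side - h, 3.5, side - h),
                       4, 2, byrow = TRUE),
      edges = c("bottom", "top")))
}

#' Scenario presets
#'
#' The four example geometries: Examples 1 and 2 place the parent vessel
#' on the lower boundary and the VEGF release region on the upper
#' boundary, with one and two initial sprouting cells; Example 3 moves
#' the release region to the upper-right corner (one sprout); Example 4
#' has parent vessels on both the lower and upper boundaries, a
#' mid-domain release region and four sprouts.  All use the 5 x 5 mm
#' domain with 2601 nodes, the basal/release VEGF concentrations and the
#' basal diffusion coefficient of the study conditions.
#'
#' @param name One of `"example1"` ... `"example4"`.
#' @param ... Overrides passed to [scenario_config()] (e.g. `loading`,
#'   `alpha`, `seed`, `theta_mode`).
#' @return A `scenario_config`.
#' @export
scenario_factory <- function(name, ...) {
  tab <- preset_table()
  if (!name %in% names(tab))
    amech_stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                       paste(names(tab), collapse = ", ")),
               "invalid_argument")
  g <- tab[[name]]
  args <- list(name = name,
               lumen_rects = g$lumen, release_rects = g$release,
               sprouts = g$sprouts, consistency_edges = g$edges)
  user <- list(...)
  args[names(user)] <- user
  do.call(scenario_config, args)
}

#' Convert a pressure from mmHg to MPa
#'
#' 1 mmHg = 133.322 Pa.  The conversion is linear and invertible; for
#' display the study quotes pressures to 2 significant figures (50 mmHg
#' = 0.0067 MPa).
#'
#' @param mmHg Pressure in millimetres of mercury.
#' @return Pressure in MPa.
#' @export
convert_pressure <- function(mmHg) {
  if (!all(is.finite(mmHg)))
    amech_stop("pressure must be finite", "invalid_argument")
  mmHg * 133.322e-6
}
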