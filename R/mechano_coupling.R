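# Coupling of applied hydrostatic pressure to the VEGF diffusion
# coefficient: a circular loaded region with a parabolic pressure falloff
# rescales the local diffusivity, D_H = D * (1 + f).

#' Define a circular loaded region
#'
#' A hydrostatic pressure is applied over a circle inside the domain; the
#' pressure decays parabolically from the centre to the rim.  Negative
#' pressure denotes compression, positive traction.
#'
#' @param center Circle centre (mm).
#' @param radius Circle radius rc (mm), > 0.
#' @param pressure Applied hydrostatic pressure p_H in MPa (default the
#'   studied 50 mmHg compression, -0.0067 MPa).
#' @param alpha Dimensionless magnitude of the coupling in direct mode;
#'   restricted to the analysed magnitudes 0.5, 1.0, 1.5 unless
#'   `allow_any_alpha`.
#' @param mode `"direct"` (alpha given) or `"from-field"` (alpha computed
#'   from the elastic pressure field as p_H_bar / p_H).
#' @param allow_any_alpha Allow alpha magnitudes outside {0.5, 1, 1.5}.
#' @return Object of class `loaded_region`.
#' @export
loaded_region <- function(center = c(2.5, 2.5), radius = 1.0,
                          pressure = -0.0067, alpha = 1.0,
                          mode = c("direct", "from-field"),
                          allow_any_alpha = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(radius) || radius <= 0)
    amech_stop("radius must be positive", "invalid_argument")
  if (!allow_any_alpha && !isTRUE(abs(alpha) %in% c(0.5, 1.0, 1.5)))
    amech_stop("|alpha| restricted to the analysed magnitudes 0.5, 1.0, 1.5 (set allow_any_alpha = TRUE to override)",
               "invalid_argument")
  structure(list(center = as.numeric(center), radius = radius,
                 pressure = pressure, alpha = alpha, mode = mode),
            class = "loaded_region")
}

check_region_inside <- function(region, cloud) {
  b <- cloud$bounds
  ok <- region$center[1] - region$radius >= b["xmin"] &&
        region$center[1] + region$radius <= b["xmax"] &&
        region$center[2] - region$radius >= b["ymin"] &&
        region$center[2] + region$radius <= b["ymax"]
  if (!ok)
    amech_stop("loaded region extends outside the domain", "invalid_argument")
  invisible(TRUE)
}

#' Parabolic pressure falloff factor
#'
#' f = alpha * (1 - d^2 / rc^2) inside the circle and 0 outside, where d
#' is the distance to the circle centre.  The sign of f follows the sign
#' of alpha (negative under compression).
#'
#' @param point m x 2 matrix (or length-2 vector) of positions (mm).
#' @param region A [loaded_region()].
#' @param alpha Signed coupling value; defaults to the region's alpha.
#' @return Numeric vector of factors f.
#' @export
pressure_falloff_factor <- function(point, region, alpha = region$alpha) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  d2 <- (pts[, 1] - region$center[1])^2 + (pts[, 2] - region$center[2])^2
  f <- alpha * (1 - d2 / region$radius^2)
  f[d2 > region$radius^2] <- 0
  f
}

#' Alpha from a computed pressure field
#'
#' alpha = p_H_bar / p_H: the ratio of the locally computed hydrostatic
#' pressure to the applied one, signed.
#'
#' @param p_H_bar Locally computed hydrostatic pressure (MPa).
#' @param p_H Applied pressure (MPa), nonzero.
#' @return The signed ratio.
#' @export
compute_alpha <- function(p_H_bar, p_H) {
  if (!is.numeric(p_H) || p_H == 0)
    amech_stop("applied pressure p_H must be nonzero", "invalid_argument")
  p_H_bar / p_H
}

#' Pressure-modified diffusivity map
#'
#' Per-integration-point diffusion coefficients D_H = D * (1 + f) with the
#' parabolic falloff f of [pressure_falloff_factor()].  Compression
#' (negative alpha) lowers the coefficient, traction raises it,
#' proportionally to |alpha|.  A map with any negative value is flagged
#' invalid (`valid = FALSE`) and refused by the assembly: at compression
#' magnitudes above 1 the coupling leaves its stable regime.
#'
#' @param base_D Basal VEGF diffusion coefficient (mm^2/s), > 0.
#' @param region A [loaded_region()].
#' @param alpha Signed alpha (negative = compression); defaults to the
#'   region's stored value.
#' @param int_mesh Background integration mesh whose points the map covers.
#' @return Object of class `diffusivity_map`: `base`, `values`
#'   (pre-clamp), `valid`, plus the generating `region` and `alpha`.
#' @export
modified_diffusion_map <- function(base_D, region, alpha = region$alpha,
                                   int_mesh = NULL, points = NULL) {
  if (!is.numeric(base_D) || base_D <= 0)
    amech_stop("base_D must be positive", "invalid_argument")
  pts <- if (!is.null(int_mesh)) int_mesh$points else points
  if (is.null(pts))
    amech_stop("supply int_mesh or points", "invalid_argument")
  f <- pressure_falloff_factor(pts, region, alpha)
  vals <- base_D * (1 + f)
  structure(list(base = base_D, values = vals,
                 valid = !any(vals < 0),
                 region = region, alpha = alpha),
            class = "diffusivity_map")
}

# Evaluate the map's diffusivity law at arbitrary positions.
evaluate_diffusivity <- function(map, points) {
  map$base * (1 + pressure_falloff_factor(points, map$region, map$alpha))
}
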