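#' Calibration curve between a material parameter and predicted contact area
#'
#' Ordered (parameter, area) support points with monotone linear
#' interpolants in both directions, used by the inverse procedures that
#' recover compressive Poisson's ratio and equivalent elastic modulus from
#' measured contact areas.
#'
#' @param parameter ordered numeric support values.
#' @param area_mm2 predicted contact areas at the support values.
#' @param kind configuration descriptor: `"cylinder-compression"` or
#'   `"ball-on-flat"`.
#' @return object of class `calibration_curve`.
#' @export
calibration_curve <- function(parameter, area_mm2,
                              kind = c("cylinder-compression", "ball-on-flat")) {
  kind <- match.arg(kind)
  if (length(parameter) < 5) stop("calibration needs at least 5 support points")
  if (length(parameter) != length(area_mm2)) stop("length mismatch")
  o <- order(parameter)
  parameter <- parameter[o]; area_mm2 <- area_mm2[o]
  d <- diff(area_mm2)
  if (!(all(d > 0) || all(d < 0))) {
    stop("calibration error: predicted contact area is not strictly monotone ",
         "in the parameter over the requested range")
  }
  structure(list(parameter = parameter, area_mm2 = area_mm2, kind = kind),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve (%s): %d points, parameter [%.4g, %.4g], area [%.4g, %.4g] mm^2\n",
              x$kind, length(x$parameter), min(x$parameter), max(x$parameter),
              min(x$area_mm2), max(x$area_mm2)))
  invisible(x)
}

#' Poisson's-ratio calibration curve from confined cylinder compression
#'
#' Emulates the displacement-controlled compression test used to identify
#' the compressive Poisson's ratio: a polyethylene cylinder (default 12 mm
#' diameter, 10.2 mm length) is compressed by a prescribed 1 mm displacement
#' against rigid flat platens and the end-face contact area is recorded as a
#' function of the assumed Poisson's ratio. Because the test is displacement
#' controlled, the contact area is independent of the elastic modulus.
#'
#' The forward model is a homogeneous-deformation end-expansion
#' approximation: at axial engineering strain `eps = compression / length`,
#' the contact radius grows by the lateral strain `nu * eps`, giving
#' `A(nu) = pi (r0 (1 + nu eps))^2`. This deliberately simple kinematic
#' stand-in preserves the two properties the inverse procedure relies on
#' (strict monotonicity in `nu`, independence of `E`) and is exact at
#' `nu = 0` where the face area is the nominal `pi r0^2`.
#'
#' @param cyl_diameter specimen diameter, mm.
#' @param length specimen length, mm.
#' @param compression applied compressive displacement, mm.
#' @param E_any elastic modulus, MPa; accepted and ignored (displacement
#'   control makes the area E-independent), kept in the signature to document
#'   that invariance.
#' @param nu_grid Poisson's-ratio support grid in `[0, 0.49]`.
#' @return a [calibration_curve()] of kind `"cylinder-compression"`.
#' @export
build_poisson_curve <- function(cyl_diameter = 12, length = 10.2,
                                compression = 1, E_any = 553,
                                nu_grid = seq(0.05, 0.45, by = 0.05)) {
  if (any(nu_grid < 0 | nu_grid > 0.49)) stop("nu_grid must lie in [0, 0.49]")
  eps <- compression / length
  r0 <- cyl_diameter / 2
  area <- pi * (r0 * (1 + nu_grid * eps))^2
  calibration_curve(nu_grid, area, kind = "cylinder-compression")
}

#' Elastic-modulus calibration curve from ball-on-flat compression
#'
#' Emulates the dynamic ball-on-flat test used to identify the equivalent
#' compressive elastic modulus: a rigid ball (default 63.5 mm diameter) is
#' pressed into a polyethylene flat under a sinusoidal load of 250 N mean
#' (zero to 500 N), and the predicted contact area at the 500 N load peak is
#' recorded as a function of the assumed modulus. The contact stage is the
#' elastic-foundation backend with its layer thickness calibrated to the
#' Hertz solution at each modulus ([calibrate_layer_thickness()]); the
#' contact area is the moment-based estimate ([contact_area_moment()]),
#' which is smooth under mesh refinement. The area measured under the
#' dynamic load peak absorbs creep into the "equivalent" modulus, which is
#' why the peak (not mean) load is used.
#'
#' @param ball_diameter rigid ball diameter, mm.
#' @param mean_load mean of the zero-to-peak sinusoidal load, N; the curve is
#'   evaluated at the peak `2 * mean_load`.
#' @param nu Poisson's ratio of the flat.
#' @param E_grid modulus support grid, MPa.
#' @param grid mesh resolution of the flat and ball cap.
#' @return a [calibration_curve()] of kind `"ball-on-flat"`.
#' @export
build_modulus_curve <- function(ball_diameter = 63.5, mean_load = 250,
                                nu = 0.32, E_grid = seq(300, 900, by = 100),
                                grid = 96L) {
  if (length(E_grid) < 5) {
    stop("degenerate modulus grid: need at least 5 support moduli")
  }
  R <- ball_diameter / 2
  Fpk <- 2 * mean_load
  a_max <- hertz_ball_on_flat(Fpk, R, material_properties(E = min(E_grid), nu = nu))$contact_radius
  flat <- make_primitive("flat_plate", list(width = 5 * a_max, depth = 5 * a_max,
                                            grid = grid))
  ball <- make_primitive("sphere", list(diameter = ball_diameter, grid = grid,
                                        extent = min(2.5 * a_max, 0.7 * R / sqrt(2))))
  # place the ball apex at first touch above the flat
  ball$vertices[, 2] <- ball$vertices[, 2] + R
  area <- vapply(E_grid, function(E) {
    m <- material_properties(E = E, nu = nu)
    h <- calibrate_layer_thickness(Fpk, R, m)
    sol <- solve_contact(ball, flat, contact_pose(), Fpk, m,
                         layer_thickness = h, allow_aa = FALSE)
    contact_area_moment(sol, flat)
  }, numeric(1))
  calibration_curve(E_grid, area, kind = "ball-on-flat")
}

#' Invert a calibration curve at a measured contact area
#'
#' Monotone linear interpolation of the parameter as a function of area.
#' Areas outside the calibrated range are refused rather than extrapolated.
#'
#' @param curve a [calibration_curve()].
#' @param measured_area measured contact area(s), mm^2.
#' @return parameter estimate(s).
#' @export
invert_calibration <- function(curve, measured_area) {
  rng <- range(curve$area_mm2)
  if (any(measured_area < rng[1] | measured_area > rng[2])) {
    stop(sprintf(paste0("measured area outside the calibrated range ",
                        "[%.4g, %.4g] mm^2; extrapolation refused"),
                 rng[1], rng[2]))
  }
  o <- order(curve$area_mm2)             # modulus curves are area-decreasing
  stats::approx(curve$area_mm2[o], curve$parameter[o], xout = measured_area,
                ties = "ordered")$y
}

#' Parameter estimate with confidence interval from specimen areas
#'
#' Inverts the calibration curve for each specimen's measured area and
#' summarises the estimates as mean +/- 95% CI (t distribution, n - 1 df).
#'
#' @param curve a [calibration_curve()].
#' @param areas per-specimen measured contact areas, mm^2.
#' @return list with `per_specimen`, `mean`, `ci95`, `n`.
#' @export
estimate_from_areas <- function(curve, areas) {
  est <- invert_calibration(curve, areas)
  n <- length(est)
  list(per_specimen = data.frame(area_mm2 = areas, estimate = est),
       mean = mean(est),
       ci95 = if (n > 1) stats::qt(0.975, n - 1) * stats::sd(est) / sqrt(n) else NA_real_,
       n = n)
}

#' Write a calibration curve as CSV
#' @param curve a [calibration_curve()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_calibration_csv <- function(curve, path) {
  utils::write.csv(data.frame(parameter = curve$parameter,
                              area_mm2 = curve$area_mm2),
                   path, row.names = FALSE)
  invisible(path)
}
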