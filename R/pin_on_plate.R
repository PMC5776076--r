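#' Bundled multidirectional pin-on-plate test matrix
#'
#' The twelve test conditions of the moderately cross-linked UHMWPE
#' pin-on-plate study: six pin-diameter/load combinations spanning nominal
#' contact stresses of 4-80 MPa at a common multidirectional motion
#' (28 mm stroke, +/-30 deg in-phase pin rotation), plus five motion
#' combinations spanning cross-shear ratios from 0 (unidirectional) to 0.18
#' at selected stresses. Reported stress, P/E and CS columns carry the
#' published values for reference; the package recomputes all three.
#'
#' @return data frame with columns `pin_diameter_mm, load_N, stroke_mm,
#'   rotation_deg, weeks, stress_reported_mpa, p_over_e_reported,
#'   cs_reported`.
#' @export
pop_conditions <- function() {
  path <- system.file("extdata", "pop_conditions.csv", package = "tkrwear")
  utils::read.csv(path)
}

#' Simulate one pin-on-plate condition
#'
#' Runs the full prediction chain for one multidirectional pin-on-plate
#' condition: nominal uniform contact stress from load and pin area,
#' frictional-work tensors per pin-face sample point over one in-phase cycle,
#' face-averaged (area-weighted) and centre-point cross-shear ratios,
#' per-cycle sliding distance at the pin centre, the wear coefficient from
#' the surface model, and the predicted wear rate `A * S * C` per cycle
#' scaled to mm^3 per million cycles.
#'
#' @param cfg a [pop_config()].
#' @param mat a [material_properties()].
#' @param model a [wear_coefficient_model()].
#' @param n_r,n_a pin-face sampling density (radial rings x angular sectors).
#' @return object of class `pop_result`: list with `stress_mpa`, `p_over_e`,
#'   `cs_face`, `cs_center`, `sliding_per_cycle_mm`, `wear_coefficient`,
#'   `wear_rate_mm3_per_mc`, `pin_area_mm2` and the input `cfg`.
#' @export
run_pop <- function(cfg, mat = material_properties(),
                    model = wear_coefficient_model(), n_r = 16L, n_a = 32L) {
  stopifnot(inherits(cfg, "pop_config"))
  A_pin <- pi * (cfg$pin_diameter / 2)^2
  if (A_pin <= 0) stop("zero pin area")
  P <- cfg$load / A_pin
  p_over_e <- P / mat$E

  sp <- sample_pin_face(cfg$pin_diameter, n_r = n_r, n_a = n_a, include_center = TRUE)
  traj <- pop_trajectory(cfg, sample_points = sp$points)
  inc <- traj$increments
  k <- nrow(sp$points)
  mag <- sqrt(inc[, , 1]^2 + inc[, , 2]^2)          # n_steps x k
  # uniform nominal pressure: per-increment work weight mu * P * a * |ds|;
  # the common factor mu * P * a cancels inside CS, so weight by |ds|
  ux <- ifelse(mag > 0, inc[, , 1] / mag, 0)
  uy <- ifelse(mag > 0, inc[, , 2] / mag, 0)
  m11 <- colSums(mag * ux * ux)
  m22 <- colSums(mag * uy * uy)
  m12 <- colSums(mag * ux * uy)
  csr <- cs_from_components(m11, m22, m12)
  cs_pt <- csr$cs
  cs_pt[is.na(cs_pt)] <- 0                          # zero-work points do not wear
  w <- sp$weights
  cs_face <- sum(cs_pt[w > 0] * w[w > 0]) / sum(w[w > 0])
  cs_center <- cs_pt[1]                             # exact centre sample
  S <- traj$path_length[1]                          # centre-point path per cycle
  C <- wear_coefficient(model, cs_face, p_over_e)
  structure(list(stress_mpa = P, p_over_e = p_over_e,
                 cs_face = cs_face, cs_center = cs_center,
                 sliding_per_cycle_mm = S,
                 wear_coefficient = C,
                 wear_rate_mm3_per_mc = volumetric_wear(A_pin, S, C) * 1e6,
                 pin_area_mm2 = A_pin, cfg = cfg),
            class = "pop_result")
}

#' @export
print.pop_result <- function(x, ...) {
  cat(sprintf(paste0("pin-on-plate: d %.3g mm, %.5g N -> P %.4g MPa (P/E %.4g), ",
                     "CS face %.4g / centre %.4g, S %.4g mm per cycle\n",
                     "  predicted C %.4g, wear rate %.4g mm^3 per Mc\n"),
              x$cfg$pin_diameter, x$cfg$load, x$stress_mpa, x$p_over_e,
              x$cs_face, x$cs_center, x$sliding_per_cycle_mm,
              x$wear_coefficient, x$wear_rate_mm3_per_mc))
  invisible(x)
}

#' Reduce gravimetric pin-on-plate measurements to wear coefficients
#'
#' Converts per-specimen mass loss to wear volume through the material
#' density, divides by (pin area x total sliding distance) to obtain the
#' measured non-dimensional wear coefficient, and summarises the group as
#' mean +/- 95% confidence interval using the t distribution on n - 1
#' degrees of freedom.
#'
#' @param weights data frame with columns `specimen`, `delta_mass_mg`, and
#'   `cycles` (cycles completed per specimen); or a path to such a CSV.
#' @param cfg the [pop_config()] the specimens were run under.
#' @param rho material density, mg/mm^3.
#' @return list with `per_specimen` (data frame including `wear_coefficient`)
#'   and `summary` (`mean`, `ci95`, `n`).
#' @export
reduce_experiment <- function(weights, cfg, rho = 0.93) {
  df <- if (is.character(weights)) utils::read.csv(weights) else as.data.frame(weights)
  need <- c("specimen", "delta_mass_mg", "cycles")
  if (!all(need %in% names(df))) {
    stop("weights table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) < 1) stop("need at least one specimen")
  if (any(is.na(df$cycles)) || any(df$cycles <= 0)) {
    stop("missing or non-positive cycle counts")
  }
  A <- pi * (cfg$pin_diameter / 2)^2
  S_cycle <- 2 * cfg$stroke_length       # centre-point sliding per cycle
  if (A * S_cycle <= 0) stop("condition has zero area-sliding product")
  W <- mass_to_volume(df$delta_mass_mg, rho)
  C <- coefficient_from_measurement(W, A, S_cycle * df$cycles)
  df$wear_volume_mm3 <- W
  df$wear_coefficient <- C
  n <- nrow(df)
  m <- mean(C)
  ci <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(C) / sqrt(n) else NA_real_
  list(per_specimen = df, summary = list(mean = m, ci95 = ci, n = n))
}

#' One-way ANOVA across pin-on-plate groups (convenience)
#'
#' @param data data frame with a numeric response column and a grouping
#'   column.
#' @param response name of the response column (default
#'   `"wear_coefficient"`).
#' @param group name of the grouping column (default `"condition"`).
#' @return the `summary.aov` of the one-way fit.
#' @export
pop_anova <- function(data, response = "wear_coefficient", group = "condition") {
  df <- as.data.frame(data)
  if (!all(c(response, group) %in% names(df))) {
    stop("data must contain columns '", response, "' and '", group, "'")
  }
  df[[group]] <- factor(df[[group]])
  summary(stats::aov(stats::reformulate(group, response), data = df))
}

#' Run the bundled (or a user) test matrix end-to-end
#'
#' @param conditions data frame in the [pop_conditions()] schema, or a path
#'   to such a CSV; default the bundled matrix.
#' @param mat,model material and wear-coefficient model.
#' @param n_steps trajectory steps per cycle.
#' @return data frame: the input conditions plus computed `stress_mpa`,
#'   `p_over_e`, `cs_face`, `cs_center`, `sliding_per_cycle_mm`,
#'   `wear_coefficient` and `wear_rate_mm3_per_mc`, one row per condition.
#' @export
run_pop_matrix <- function(conditions = pop_conditions(),
                           mat = material_properties(),
                           model = wear_coefficient_model(),
                           n_steps = 128L) {
  df <- if (is.character(conditions)) utils::read.csv(conditions) else as.data.frame(conditions)
  need <- c("pin_diameter_mm", "load_N", "stroke_mm", "rotation_deg")
  if (!all(need %in% names(df)) || nrow(df) == 0) {
    stop("conditions table must be non-empty with columns: ",
         paste(need, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(df)), function(i) {
    cfg <- pop_config(df$pin_diameter_mm[i], df$load_N[i], df$stroke_mm[i],
                      df$rotation_deg[i], n_steps = n_steps)
    r <- run_pop(cfg, mat, model)
    data.frame(stress_mpa = r$stress_mpa, p_over_e = r$p_over_e,
               cs_face = r$cs_face, cs_center = r$cs_center,
               sliding_per_cycle_mm = r$sliding_per_cycle_mm,
               wear_coefficient = r$wear_coefficient,
               wear_rate_mm3_per_mc = r$wear_rate_mm3_per_mc)
  })
  cbind(df, do.call(rbind, res))
}
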