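#' Configuration of a knee wear simulation
#'
#' @param total_cycles total gait cycles to simulate.
#' @param update_interval_cycles cycles between worn-surface updates (default
#'   500,000); must divide `total_cycles`. One representative cycle is solved
#'   per interval and its nodal wear scaled linearly across the block.
#' @param n_steps steps per gait cycle (default 128).
#' @param medial_offset_fraction medial offset of the load / tibial-rotation
#'   axis as a fraction of insert width (default 0.07), in `[0, 0.5)`.
#' @param layer_thickness elastic-foundation layer thickness, mm (default 10,
#'   the insert thickness).
#' @param activity activity name for [generate_profile()], or `NULL` when a
#'   profile is supplied directly to the run functions.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(total_cycles, update_interval_cycles = 500000,
                              n_steps = 128L, medial_offset_fraction = 0.07,
                              layer_thickness = 10, activity = "walking") {
  if (total_cycles <= 0 || update_interval_cycles <= 0) {
    stop("cycle counts must be positive")
  }
  if (total_cycles %% update_interval_cycles != 0) {
    stop("update_interval_cycles (", update_interval_cycles,
         ") must divide total_cycles (", total_cycles, ")")
  }
  if (medial_offset_fraction < 0 || medial_offset_fraction >= 0.5) {
    stop("medial_offset_fraction must be in [0, 0.5)")
  }
  structure(list(total_cycles = total_cycles,
                 update_interval_cycles = update_interval_cycles,
                 n_steps = as.integer(n_steps),
                 medial_offset_fraction = medial_offset_fraction,
                 layer_thickness = layer_thickness,
                 activity = activity),
            class = "simulation_config")
}

insert_width_of <- function(insert) diff(range(insert$vertices[, 3]))

#' Solve one representative gait cycle and its nodal wear
#'
#' Two-pass scheme over the `n_steps` poses of one cycle. Pass 1: at every
#' step the foundation contact equilibrium is solved (vertical approach and
#' unconstrained adduction-abduction under the medially offset load axis) and
#' the tangential sliding increment to the next pose is computed for every
#' contacting insert vertex; each vertex accumulates its frictional-work
#' tensor `M += mu p a |ds| u u^T`. Pass 2: the whole-cycle cross-shear ratio
#' of each vertex is taken from its accumulated tensor, and the linear wear
#' depth is integrated per increment,
#' `delta += |ds| * C(CS_cycle, p_step / E)`. Vertices with zero total
#' frictional work accrue zero wear.
#'
#' @param femoral,insert articulating [surface_mesh()]es (femoral rigid,
#'   insert deformable).
#' @param profile a [kinematic_profile()].
#' @param mat a [material_properties()].
#' @param model a [wear_coefficient_model()].
#' @param cfg a [simulation_config()].
#' @param cs_override optional fixed cross-shear ratio applied to every
#'   contacting vertex in pass 2 (bypasses the tensor aggregation; used for
#'   closed-form verification against `W = A S C`).
#' @return list with `wear` (a `wear_field`: per-vertex `delta` mm,
#'   `volumetric` mm^3, `total` mm^3 for one cycle), `summary` (a
#'   `cycle_summary`: per-step contact area, average contact stress and wear
#'   contribution, plus cycle averages and the wear rate in mm^3 per million
#'   cycles) and `solutions_pose` (per-step equilibrium depth and tilt).
#' @export
run_cycle <- function(femoral, insert, profile, mat = material_properties(),
                      model = wear_coefficient_model(),
                      cfg = simulation_config(1e6), cs_override = NULL) {
  n <- profile$n_steps
  nv <- nrow(insert$vertices)
  z_off <- cfg$medial_offset_fraction * insert_width_of(insert)
  poses <- lapply(seq_len(n), function(t) {
    contact_pose(fe = profile$fe_deg[t], ap = profile$ap_mm[t],
                 ie = profile$ie_deg[t], axis_offset_z = z_off)
  })
  sols <- vector("list", n)
  warm <- NULL
  for (t in seq_len(n)) {
    sols[[t]] <- tryCatch(
      solve_contact(femoral, insert, poses[[t]], profile$load_N[t], mat,
                    layer_thickness = cfg$layer_thickness, warm_start = warm),
      error = function(err) {
        stop("contact solve failed at cycle step ", t, ": ", conditionMessage(err))
      })
    if (profile$load_N[t] > 0) {
      warm <- c(sols[[t]]$equilibrium_pose[1],
                sols[[t]]$equilibrium_pose[2] * pi / 180)
    }
  }
  # pass 1: sliding increments and frictional-work tensors
  m11 <- m22 <- m12 <- numeric(nv)
  step_idx <- step_mag <- step_p <- step_u1 <- step_u2 <- vector("list", n)
  area <- insert$vertex_area
  for (t in seq_len(n)) {
    t1 <- t %% n + 1L
    inc <- knee_step_sliding(femoral, insert, poses[[t]], poses[[t1]], sols[[t]])
    idx <- attr(inc, "vertex")
    if (!length(idx)) { step_idx[[t]] <- integer(0); next }
    mag <- sqrt(inc[, 1]^2 + inc[, 2]^2)
    # midpoint pressure over the increment (second-order in the step size)
    p <- (sols[[t]]$pressure[idx] + sols[[t1]]$pressure[idx]) / 2
    keep <- mag > 0
    idx <- idx[keep]; mag <- mag[keep]; p <- p[keep]
    if (!length(idx)) { step_idx[[t]] <- integer(0); next }
    u1 <- inc[keep, 1] / mag; u2 <- inc[keep, 2] / mag
    w <- mat$mu * p * area[idx] * mag
    m11[idx] <- m11[idx] + w * u1 * u1
    m22[idx] <- m22[idx] + w * u2 * u2
    m12[idx] <- m12[idx] + w * u1 * u2
    step_idx[[t]] <- idx; step_mag[[t]] <- mag; step_p[[t]] <- p
  }
  # pass 2: whole-cycle nodal cross-shear, then per-increment wear
  trace <- m11 + m22
  cs_v <- numeric(nv)
  active <- trace > 0
  if (any(active)) {
    cs_v[active] <- cs_from_components(m11[active], m22[active], m12[active])$cs
  }
  if (!is.null(cs_override)) cs_v[active] <- cs_override
  delta <- numeric(nv)
  step_wear <- numeric(n)
  for (t in seq_len(n)) {
    idx <- step_idx[[t]]
    if (!length(idx)) next
    C <- wear_coefficient(model, cs_v[idx], step_p[[t]] / mat$E)
    dd <- linear_wear(step_mag[[t]], C)
    delta[idx] <- delta[idx] + dd
    step_wear[t] <- sum(dd * area[idx])
  }
  W <- sum(delta * area)
  step_area <- vapply(sols, function(s) s$contact_area, numeric(1))
  step_stress <- vapply(sols, function(s) {
    if (s$contact_area > 0) s$resultant_force / s$contact_area else 0
  }, numeric(1))
  cs_mean <- if (any(active)) sum(cs_v[active] * trace[active]) / sum(trace[active]) else 0
  summary <- structure(list(
    steps = data.frame(step = seq_len(n),
                       contact_area_mm2 = step_area,
                       avg_contact_stress_mpa = step_stress,
                       wear_fraction_pct = if (W > 0) 100 * step_wear / W else
                         rep(0, n)),
    avg_contact_area_mm2 = mean(step_area),
    avg_contact_stress_mpa = mean(step_stress),
    avg_cs = cs_mean,
    wear_rate_mm3_per_mc = W * 1e6), class = "cycle_summary")
  wear <- structure(list(delta = delta, volumetric = delta * area,
                         total = W, cycles = 1), class = "wear_field")
  list(wear = wear, summary = summary,
       solutions_pose = t(vapply(sols, function(s) s$equilibrium_pose, numeric(2))))
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat(sprintf(paste0("cycle summary: wear rate %.4g mm^3 per Mc; averages: ",
                     "area %.4g mm^2, stress %.4g MPa, CS %.4g\n"),
              x$wear_rate_mm3_per_mc, x$avg_contact_area_mm2,
              x$avg_contact_stress_mpa, x$avg_cs))
  invisible(x)
}

#' Iterative wear simulation with periodic worn-surface update
#'
#' Alternates between solving one representative gait cycle on the current
#' geometry, scaling its nodal linear wear linearly over the update interval,
#' and receding the insert vertices along their inward normals before the
#' next block. The default interval is 500,000 cycles.
#'
#' @inheritParams run_cycle
#' @param frame optional 3 x 3 rotation giving the orientation of the input
#'   meshes relative to the canonical anatomical frame (x anterior,
#'   y superior, z medial); inputs are mapped to the canonical frame before
#'   solving, making the results independent of the frame the scene is
#'   expressed in.
#' @return list with `wear` (accumulated `wear_field` over all cycles),
#'   `insert_worn` (the receded [surface_mesh()]), `rates` (data frame of
#'   block wear rates, mm^3 per Mc, and cumulative wear), and `summaries`
#'   (per-block `cycle_summary`).
#' @export
run_simulation <- function(femoral, insert, profile = NULL,
                           mat = material_properties(),
                           model = wear_coefficient_model(),
                           cfg = simulation_config(1e6), frame = NULL) {
  if (is.null(profile)) {
    profile <- generate_profile(cfg$activity, n_steps = cfg$n_steps)
  }
  if (!is.null(frame)) {
    femoral <- rotate_mesh(femoral, t(frame))
    insert <- rotate_mesh(insert, t(frame))
  }
  n_blocks <- as.integer(round(cfg$total_cycles / cfg$update_interval_cycles))
  thickness <- if (!is.null(insert$params)) insert$params$insert_thickness else Inf
  delta_total <- numeric(nrow(insert$vertices))
  rates <- data.frame(block = integer(0), cycles_end = numeric(0),
                      wear_rate_mm3_per_mc = numeric(0),
                      cumulative_wear_mm3 = numeric(0))
  summaries <- vector("list", n_blocks)
  W_cum <- 0
  cur <- insert
  for (b in seq_len(n_blocks)) {
    res <- run_cycle(femoral, cur, profile, mat, model, cfg)
    d_block <- res$wear$delta * cfg$update_interval_cycles
    delta_total <- delta_total + d_block
    if (max(delta_total) >= thickness) {
      stop(sprintf(paste0("insert thickness exhausted in block %d: accumulated ",
                          "linear wear %.3g mm exceeds the %.3g mm insert"),
                   b, max(delta_total), thickness))
    }
    W_cum <- W_cum + res$wear$total * cfg$update_interval_cycles
    rates <- rbind(rates, data.frame(
      block = b, cycles_end = b * cfg$update_interval_cycles,
      wear_rate_mm3_per_mc = res$summary$wear_rate_mm3_per_mc,
      cumulative_wear_mm3 = W_cum))
    summaries[[b]] <- res$summary
    # recede the worn surface along the inward vertex normal
    cur <- surface_mesh(cur$vertices - d_block * cur$vertex_normal,
                        cur$faces, grid = cur$grid,
                        extra = list(params = cur$params))
  }
  wear <- structure(list(delta = delta_total,
                         volumetric = delta_total * insert$vertex_area,
                         total = W_cum, cycles = cfg$total_cycles),
                    class = "wear_field")
  list(wear = wear, insert_worn = cur, rates = rates, summaries = summaries)
}

#' Tabulate predicted against experimental activity wear rates
#'
#' @param predicted data frame with columns `activity` and a wear-rate column
#'   (`mm^3` per Mc); the first numeric column is used.
#' @param experimental data frame with columns `activity`, a wear-rate column
#'   and optionally a 95% CI column.
#' @return object of class `wear_validation`: the merged table (input
#'   activity order preserved, rates in mm^3 per mc) with the coefficient of
#'   determination (squared Pearson correlation) as `$r_squared`.
#' @export
compare_activities <- function(predicted, experimental) {
  p <- as.data.frame(predicted)
  e <- as.data.frame(experimental)
  if (!"activity" %in% names(p) || !"activity" %in% names(e)) {
    stop("both tables need an 'activity' column")
  }
  pnum <- names(p)[vapply(p, is.numeric, logical(1))][1]
  enum <- names(e)[vapply(e, is.numeric, logical(1))][1]
  m <- match(p$activity, e$activity)
  if (any(is.na(m))) stop("experimental table is missing activities: ",
                          paste(p$activity[is.na(m)], collapse = ", "))
  tab <- data.frame(activity = p$activity,
                    predicted_mm3_per_mc = p[[pnum]],
                    experimental_mm3_per_mc = e[[enum]][m])
  ci_col <- grep("ci", names(e), ignore.case = TRUE, value = TRUE)
  if (length(ci_col)) tab$experimental_ci95 <- e[[ci_col[1]]][m]
  structure(list(table = tab,
                 r_squared = r_squared(tab$predicted_mm3_per_mc,
                                       tab$experimental_mm3_per_mc)),
            class = "wear_validation")
}

#' @export
print.wear_validation <- function(x, ...) {
  cat("Predicted vs experimental volumetric wear rates [mm^3/mc]\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("coefficient of determination (squared Pearson r): %.2f\n",
              x$r_squared))
  invisible(x)
}

#' Export per-vertex wear depths as CSV
#' @param wear a `wear_field`.
#' @param insert the insert [surface_mesh()] it refers to.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_wear_csv <- function(wear, insert, path) {
  utils::write.csv(data.frame(vertex = seq_along(wear$delta),
                              x_mm = insert$vertices[, 1],
                              y_mm = insert$vertices[, 2],
                              z_mm = insert$vertices[, 3],
                              linear_wear_mm = wear$delta,
                              volumetric_wear_mm3 = wear$volumetric),
                   path, row.names = FALSE)
  invisible(path)
}
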