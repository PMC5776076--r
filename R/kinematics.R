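#' Activity kinematic profile
#'
#' A per-cycle time series of the four controlled simulator axes: axial load,
#' femoral flexion-extension, tibial anterior-posterior translation and
#' tibial internal-external rotation. One cycle lasts `period` seconds and is
#' sampled at `n_steps` equally spaced instants `t = (0:(n-1))/n * period`;
#' the waveforms are periodic, so step `n` wraps to step 1.
#'
#' Sign conventions: AP is positive anterior; anterior tibial shift producing
#' femoral rollback is negative. IE is positive internal. Angles are degrees
#' at this interface.
#'
#' @param load_N axial load per step, N (>= 0).
#' @param fe_deg flexion-extension angle per step, degrees.
#' @param ap_mm anterior-posterior translation per step, mm.
#' @param ie_deg internal-external rotation per step, degrees.
#' @param period cycle period, s.
#' @return object of class `kinematic_profile`.
#' @export
kinematic_profile <- function(load_N, fe_deg, ap_mm, ie_deg, period = 1) {
  n <- length(load_N)
  if (n < 4) stop("a profile needs at least 4 steps")
  if (length(fe_deg) != n || length(ap_mm) != n || length(ie_deg) != n) {
    stop("all profile channels must have the same length")
  }
  if (any(load_N < 0)) stop("loads must be non-negative")
  # cyclic check: compare the first sample with the wrap-around extrapolation
  for (ch in list(load_N, fe_deg, ap_mm, ie_deg)) {
    span <- diff(range(ch))
    if (span > 0 && abs(ch[n] - ch[1]) > 0.75 * span) {
      stop("profile channels must be cyclic (first and last samples of a ",
           "1-cycle waveform may not sit at opposite extremes)")
    }
  }
  structure(list(load_N = load_N, fe_deg = fe_deg, ap_mm = ap_mm,
                 ie_deg = ie_deg, n_steps = n, period = period),
            class = "kinematic_profile")
}

# printed extrema of the three daily activities (N, mm, deg)
activity_extrema <- list(
  walking       = list(load_max = 2600, ap_max = 14, fe = c(0, 58),  ie = c(-5, 5)),
  deep_squat    = list(load_max = 2879, ap_max = 17, fe = c(0, 104), ie = c(0, 5)),
  stairs_ascent = list(load_max = 3008, ap_max = 12, fe = c(0, 60),  ie = c(-5, 5))
)

#' Generate a daily-activity profile from its printed extrema
#'
#' Builds smooth 1 Hz periodic waveforms whose extrema equal the published
#' values exactly: maximum axial loads 2600 / 2879 / 3008 N, maximum AP
#' translations 14 / 17 / 12 mm, FE ranges 0-58 / 0-104 / 0-60 degrees and IE
#' ranges -5..5 / 0..5 / -5..5 degrees for walking, deep squat and stairs
#' ascent respectively. Only the extrema are contractual; the waveform shapes
#' are raised-cosine stand-ins (double-peaked load for walking, single-peaked
#' otherwise), since the source activity curves are not available in tabular
#' form. Users with measured (e.g. ISO) profiles should load them with
#' [read_profile_csv()].
#'
#' Extrema exactness relies on the peaks falling on grid samples, so
#' `n_steps` must be a multiple of 4. The swing-phase load minimum is 150 N,
#' a typical simulator value.
#'
#' @param activity `"walking"`, `"deep_squat"` or `"stairs_ascent"`.
#' @param n_steps samples per cycle (multiple of 4, default 128).
#' @return a [kinematic_profile()].
#' @export
generate_profile <- function(activity = c("walking", "deep_squat", "stairs_ascent"),
                             n_steps = 128L) {
  activity <- match.arg(activity)
  n_steps <- as.integer(n_steps)
  if (n_steps < 8L || n_steps %% 4L != 0L) {
    stop("n_steps must be a multiple of 4 (>= 8) so waveform extrema fall on samples")
  }
  ex <- activity_extrema[[activity]]
  tau <- (seq_len(n_steps) - 1) / n_steps
  s2 <- (1 - cospi(2 * tau)) / 2        # 0 at tau = 0, exactly 1 at tau = 0.5
  s4 <- (1 - cospi(4 * tau)) / 2        # two exact unit peaks (tau = 1/4, 3/4)
  s2q <- (1 - cospi(2 * tau - 0.5)) / 2 # quadrature: exact extrema at 1/4, 3/4
  load_min <- 150
  load <- load_min + (ex$load_max - load_min) * (if (activity == "walking") s4 else s2)
  fe <- ex$fe[1] + diff(ex$fe) * s2
  ap <- -ex$ap_max * s2                 # anterior tibial shift: negative polarity
  # tibial rotation in quadrature with flexion, as in gait, so that slip
  # directions rotate over the cycle and generate cross-shear
  ie <- ex$ie[1] + diff(ex$ie) * s2q
  kinematic_profile(load, fe, ap, ie, period = 1)
}

#' Read / write activity profiles as CSV
#'
#' Column schema: `time_s, load_N, fe_deg, ap_mm, ie_deg`. Values are written
#' at full double precision so a write/read round trip reproduces the arrays
#' exactly.
#'
#' @param path CSV file path.
#' @return for `read_profile_csv`, a [kinematic_profile()].
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "load_N", "fe_deg", "ap_mm", "ie_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("profile CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (any(diff(df$time_s) <= 0)) stop("profile time_s must be strictly increasing")
  n <- nrow(df)
  period <- df$time_s[n] * n / (n - 1)   # samples at (0:(n-1))/n * period
  kinematic_profile(df$load_N, df$fe_deg, df$ap_mm, df$ie_deg, period = period)
}

#' @rdname read_profile_csv
#' @param profile a [kinematic_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  n <- profile$n_steps
  df <- data.frame(time_s = (seq_len(n) - 1) / n * profile$period,
                   load_N = profile$load_N, fe_deg = profile$fe_deg,
                   ap_mm = profile$ap_mm, ie_deg = profile$ie_deg)
  # full precision so that read_profile_csv() round-trips bit-exactly
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                              sep = ",")), con)
  invisible(path)
}

# ---- pin-on-plate trajectories ---------------------------------------------

#' Pin-on-plate test configuration
#'
#' One multidirectional pin-on-plate condition: a polyethylene pin of
#' diameter `pin_diameter` loaded with `load` against a reciprocating plate
#' (stroke `stroke_length` along x), while the pin oscillates about its axis
#' with amplitude `rotation_amplitude`. Plate reciprocation and pin rotation
#' are in phase with common frequency `frequency`:
#' `x(t) = (stroke/2) cos(2 pi f t)`, `theta(t) = amplitude cos(2 pi f t)`.
#'
#' @param pin_diameter mm.
#' @param load N.
#' @param stroke_length mm (peak-to-peak plate travel).
#' @param rotation_amplitude degrees (+/- amplitude), >= 0.
#' @param frequency Hz.
#' @param n_steps trajectory samples per cycle.
#' @return object of class `pop_config`.
#' @export
pop_config <- function(pin_diameter, load, stroke_length, rotation_amplitude,
                       frequency = 1, n_steps = 128L) {
  if (pin_diameter <= 0 || load <= 0 || frequency <= 0) {
    stop("pin_diameter, load and frequency must be positive")
  }
  if (stroke_length < 0 || rotation_amplitude < 0) {
    stop("stroke_length and rotation_amplitude must be non-negative")
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 8L) stop("n_steps must be at least 8")
  structure(list(pin_diameter = pin_diameter, load = load,
                 stroke_length = stroke_length,
                 rotation_amplitude = rotation_amplitude,
                 frequency = frequency, n_steps = n_steps),
            class = "pop_config")
}

#' Area-weighted polar sampling of the pin face
#'
#' @param diameter pin diameter, mm.
#' @param n_r radial rings (default 16).
#' @param n_a angular sectors (default 32).
#' @param include_center prepend the exact centre point with zero weight.
#' @return list with `points` (k x 2 pin-frame coordinates, mm) and `weights`
#'   (sector areas, mm^2; zero for the centre point).
#' @export
sample_pin_face <- function(diameter, n_r = 16L, n_a = 32L, include_center = TRUE) {
  R <- diameter / 2
  redges <- seq(0, R, length.out = n_r + 1L)
  rc <- (redges[-1L] + redges[-(n_r + 1L)]) / 2
  warea <- pi * (redges[-1L]^2 - redges[-(n_r + 1L)]^2) / n_a
  ang <- (seq_len(n_a) - 1) * 2 * pi / n_a
  pts <- cbind(rep(rc, each = n_a) * cos(rep(ang, n_r)),
               rep(rc, each = n_a) * sin(rep(ang, n_r)))
  wts <- rep(warea, each = n_a)
  if (include_center) {
    pts <- rbind(c(0, 0), pts)
    wts <- c(0, wts)
  }
  list(points = pts, weights = wts)
}

#' Per-step sliding increments of a pin-on-plate cycle
#'
#' Integrates the relative slip of the plate with respect to each pin-face
#' material point over one cycle, expressed in the rotating material frame of
#' the polyethylene pin (the frame in which molecular orientation, and hence
#' cross-shear, is defined). Increment `k` covers the interval between steps
#' `k` and `k+1`.
#'
#' @param cfg a [pop_config()].
#' @param sample_points optional k x 2 matrix of pin-frame points; default is
#'   the [sample_pin_face()] 16 x 32 polar grid plus the centre point.
#' @return list with `points`, `weights`, `increments` (array
#'   `n_steps x k x 2`, mm, pin material frame) and `path_length` (per-point
#'   per-cycle sliding distance, mm).
#' @export
pop_trajectory <- function(cfg, sample_points = NULL) {
  stopifnot(inherits(cfg, "pop_config"))
  if (is.null(sample_points)) {
    sp <- sample_pin_face(cfg$pin_diameter)
  } else {
    pts <- as.matrix(sample_points)
    if (any(sqrt(rowSums(pts^2)) > cfg$pin_diameter / 2 + 1e-9)) {
      stop("sample points must lie on the pin face")
    }
    sp <- list(points = pts, weights = rep(1, nrow(pts)))
  }
  n <- cfg$n_steps
  if (n < 1) stop("zero steps")
  A <- cfg$rotation_amplitude * pi / 180
  L <- cfg$stroke_length
  tt <- (0:n) / n                    # step boundaries over one cycle (f folds out)
  th <- A * cospi(2 * tt)
  xp <- (L / 2) * cospi(2 * tt)
  px <- sp$points[, 1]; py <- sp$points[, 2]
  k <- length(px)
  inc <- array(0, dim = c(n, k, 2))
  for (s in seq_len(n)) {
    th0 <- th[s]; th1 <- th[s + 1L]
    # lab positions of the pin material points at both step boundaries
    X0 <- cos(th0) * px - sin(th0) * py; Y0 <- sin(th0) * px + cos(th0) * py
    X1 <- cos(th1) * px - sin(th1) * py; Y1 <- sin(th1) * px + cos(th1) * py
    dsx <- (xp[s + 1L] - xp[s]) - (X1 - X0)   # plate minus pin displacement
    dsy <- -(Y1 - Y0)
    thm <- (th0 + th1) / 2                     # midpoint material frame
    mx <- cos(thm) * dsx + sin(thm) * dsy      # rotate by -thm into pin frame
    my <- -sin(thm) * dsx + cos(thm) * dsy
    inc[s, , 1] <- mx
    inc[s, , 2] <- my
  }
  path <- colSums(matrix(sqrt(inc[, , 1]^2 + inc[, , 2]^2), nrow = n))
  list(points = sp$points, weights = sp$weights, increments = inc,
       path_length = path)
}

# ---- knee step sliding ------------------------------------------------------

rot_z <- function(th) matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
rot_y <- function(ps) matrix(c(cos(ps), 0, -sin(ps), 0, 1, 0, sin(ps), 0, cos(ps)), 3, 3)

#' Tangential sliding increments between two consecutive knee poses
#'
#' Computes, for every insert vertex in contact, the tangential displacement
#' of the femoral surface material point relative to the insert vertex between
#' two consecutive poses of one activity profile, expressed in the insert
#' material frame (the frame in which the polyethylene's molecular orientation
#' lives). Flexion acts about the femoral centre of rotation; AP translation
#' and IE rotation move the insert; the solved vertical approach enters as a
#' vertical offset and contributes no tangential slip; the small
#' adduction-abduction tilt is neglected in the slip kinematics.
#'
#' @param femoral femoral [surface_mesh()] (must record `$cor`).
#' @param insert insert [surface_mesh()].
#' @param pose0,pose1 consecutive [contact_pose()]s.
#' @param contact the [solve_contact()] solution at `pose0`.
#' @return k x 2 matrix of tangential increments (mm) in the insert tangent
#'   basis (rows = contacting vertex indices, given as attribute `vertex`).
#' @export
knee_step_sliding <- function(femoral, insert, pose0, pose1, contact) {
  idx <- which(contact$pressure > 0)
  out <- matrix(0, length(idx), 2)
  if (!length(idx)) {
    attr(out, "vertex") <- idx
    return(out)
  }
  cor <- femoral$cor
  if (is.null(cor)) stop("femoral mesh must record its centre of rotation")
  th0 <- pose0$fe * pi / 180; th1 <- pose1$fe * pi / 180
  ps0 <- pose0$ie * pi / 180; ps1 <- pose1$ie * pi / 180
  ci <- c(0, 0, pose0$axis_offset_z)

  p <- insert$vertices[idx, , drop = FALSE]
  # world position of the insert vertices at both poses
  w0 <- sweep(sweep(p, 2, ci) %*% t(rot_y(ps0)), 2, ci, `+`)
  w0[, 1] <- w0[, 1] + pose0$ap
  w1 <- sweep(sweep(p, 2, ci) %*% t(rot_y(ps1)), 2, ci, `+`)
  w1[, 1] <- w1[, 1] + pose1$ap
  d_ins <- w1 - w0

  # femoral material point currently at the contact: its motion between the
  # poses is the net flexion increment about the centre of rotation (exactly
  # zero displacement for identical poses)
  dth <- th1 - th0
  rel <- sweep(w0, 2, cor)
  d_fem <- rel %*% t(rot_z(dth)) - rel

  slip_w <- d_fem - d_ins
  # back to the insert material frame at t0
  slip_m <- slip_w %*% rot_y(ps0)          # R_y(-ps0) = t(R_y(ps0)); x A' = (A x')'
  nrm <- insert$vertex_normal[idx, , drop = FALSE]
  # tangent basis per vertex: e1 ~ anterior projected to the tangent plane
  e1 <- cbind(1 - nrm[, 1]^2, -nrm[, 1] * nrm[, 2], -nrm[, 1] * nrm[, 3])
  l1 <- sqrt(rowSums(e1^2)); e1 <- e1 / l1
  e2 <- cbind(nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
              nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
              nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1])
  out <- cbind(rowSums(slip_m * e1), rowSums(slip_m * e2))
  attr(out, "vertex") <- idx
  out
}
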