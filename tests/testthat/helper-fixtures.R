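# shared fixtures: small grids keep the contact solves fast while staying
# fine enough for the stated tolerances
small_params <- function(grid = 32L) implant_params(grid_resolution = grid)

default_mat <- material_properties()           # E 553, nu 0.32, rho 0.93, mu 0.04
default_model <- wear_coefficient_model()      # published surface constants

# flat-on-flat bench: rigid plate overhanging a soft plate, both at y = 0
flat_bench <- function(soft_size = 10, rigid_size = 40, grid_soft = 24L,
                       grid_rigid = 16L) {
  soft <- make_primitive("flat_plate",
                         list(width = soft_size, depth = soft_size, grid = grid_soft))
  rigid <- make_primitive("flat_plate",
                          list(width = rigid_size, depth = rigid_size, grid = grid_rigid))
  rigid$cor <- c(0, 0, 0)   # flexion axis for the (flat) counterface
  list(rigid = rigid, soft = soft)
}

# ball-on-flat bench at first touch, layer calibrated to Hertz at load F
ball_bench <- function(F = 500, R = 31.75, mat = default_mat, grid = 96L) {
  a_h <- hertz_ball_on_flat(F, R, mat)$contact_radius
  ball <- make_primitive("sphere", list(diameter = 2 * R, grid = grid,
                                        extent = 3 * a_h))
  ball$vertices[, 2] <- ball$vertices[, 2] + R
  flat <- make_primitive("flat_plate", list(width = 6 * a_h, depth = 6 * a_h,
                                            grid = grid))
  list(ball = ball, flat = flat, h = calibrate_layer_thickness(F, R, mat))
}

# random PSD 2x2 frictional-work tensor from a handful of random increments
random_work_tensor <- function() {
  k <- sample(2:6, 1)
  ang <- stats::runif(k, 0, 2 * pi)
  w <- stats::runif(k, 0.1, 2)
  m11 <- sum(w * cos(ang)^2); m22 <- sum(w * sin(ang)^2)
  m12 <- sum(w * cos(ang) * sin(ang))
  matrix(c(m11, m12, m12, m22), 2, 2)
}

# brute-force cross-shear: scan candidate molecular orientations on a 1 deg
# grid, take the direction of maximum resolved work as the PMO
brute_force_cs <- function(M) {
  th <- seq(0, pi, by = pi / 180)
  res <- vapply(th, function(a) {
    n <- c(cos(a), sin(a))
    sum(n * (M %*% n))
  }, numeric(1))
  1 - max(res) / sum(diag(M))
}
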