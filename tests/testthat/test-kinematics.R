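test_that("generated activity profiles hit the printed extrema bit-exactly", {
  ex <- list(walking = list(2600, c(0, 58), 14, c(-5, 5)),
             deep_squat = list(2879, c(0, 104), 17, c(0, 5)),
             stairs_ascent = list(3008, c(0, 60), 12, c(-5, 5)))
  for (a in names(ex)) {
    pr <- generate_profile(a, 128)
    expect_identical(max(pr$load_N), ex[[a]][[1]])
    expect_identical(range(pr$fe_deg), ex[[a]][[2]])
    expect_identical(max(abs(pr$ap_mm)), ex[[a]][[3]])
    expect_identical(range(pr$ie_deg), ex[[a]][[4]])
    expect_identical(pr$n_steps, 128L)
    expect_identical(pr$period, 1)
    expect_true(all(pr$load_N >= 0))
  }
  expect_error(generate_profile("jogging"), "arg")
  expect_error(generate_profile("walking", 30), "multiple of 4")
})

test_that("profile CSV round trip is exact; schema and time monotonicity enforced", {
  pr <- generate_profile("deep_squat", 64)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(pr, tmp)
  back <- read_profile_csv(tmp)
  expect_identical(back$load_N, pr$load_N)
  expect_identical(back$fe_deg, pr$fe_deg)
  expect_identical(back$ap_mm, pr$ap_mm)
  expect_identical(back$ie_deg, pr$ie_deg)
  expect_equal(back$period, pr$period)

  df <- read.csv(tmp)
  df$fe_deg <- NULL
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_profile_csv(bad), "missing column")

  df2 <- read.csv(tmp)
  df2$time_s[3] <- df2$time_s[5]
  write.csv(df2, bad, row.names = FALSE)
  expect_error(read_profile_csv(bad), "increasing")
})

test_that("pin-on-plate trajectories reduce to the closed-form degenerate cases", {
  # pure reciprocation: collinear increments, path exactly twice the stroke
  cfg <- pop_config(5, 80, 28, 0, n_steps = 128)
  tr <- pop_trajectory(cfg, sample_points = rbind(c(0, 0), c(1.5, 0.5)))
  expect_equal(tr$path_length, c(56, 56))
  dirs <- tr$increments[, 2, ] / sqrt(rowSums(tr$increments[, 2, ]^2))
  expect_lt(max(abs(abs(dirs[, 1]) - 1)), 1e-12)   # all along +/- x

  # pure rotation: arc path r * 4 * amplitude per cycle (O(1/n^2) discretisation)
  cfg <- pop_config(5, 80, 0, 30, n_steps = 256)
  r <- c(0.8, 2.0)
  tr <- pop_trajectory(cfg, sample_points = cbind(r, 0))
  expect_equal(tr$path_length, r * 4 * (30 * pi / 180), tolerance = 1e-3)

  # centre point of a 28 mm stroke slides 56 mm per cycle regardless of rotation
  cfg <- pop_config(5, 80, 28, 30, n_steps = 128)
  tr <- pop_trajectory(cfg, sample_points = rbind(c(0, 0)))
  expect_equal(tr$path_length, 56)
})

test_that("pin-face sampling is area-weighted and bounded to the face", {
  sp <- sample_pin_face(5, n_r = 16, n_a = 32)
  expect_equal(sum(sp$weights), pi * 2.5^2)
  expect_true(all(sqrt(rowSums(sp$points^2)) <= 2.5))
  cfg <- pop_config(5, 80, 28, 30)
  expect_error(pop_trajectory(cfg, sample_points = rbind(c(3, 0))), "pin face")
})

test_that("knee step sliding reproduces rigid-body kinematics", {
  b <- flat_bench()
  off <- 2
  sol <- solve_contact(b$rigid, b$soft, contact_pose(axis_offset_z = off), 500,
                       default_mat, 10)
  # identical poses: zero slip
  p0 <- contact_pose(axis_offset_z = off)
  inc <- knee_step_sliding(b$rigid, b$soft, p0, p0, sol)
  expect_identical(max(abs(inc)), 0)
  # pure AP translation d: every increment has magnitude d
  p1 <- contact_pose(ap = 0.37, axis_offset_z = off)
  inc <- knee_step_sliding(b$rigid, b$soft, p0, p1, sol)
  expect_equal(sqrt(rowSums(inc^2)), rep(0.37, nrow(inc)), tolerance = 1e-9)
  # pure IE rotation about the offset axis: |ds| proportional to the distance
  # from that axis
  p2 <- contact_pose(ie = 2, axis_offset_z = off)
  inc <- knee_step_sliding(b$rigid, b$soft, p0, p2, sol)
  idx <- attr(inc, "vertex")
  r <- sqrt(b$soft$vertices[idx, 1]^2 + (b$soft$vertices[idx, 3] - off)^2)
  mag <- sqrt(rowSums(inc^2))
  chord <- 2 * r * sin(2 * pi / 180 / 2)
  expect_equal(mag, chord, tolerance = 1e-9)
})

test_that("profile validation rejects malformed channels", {
  expect_error(kinematic_profile(c(1, 2), c(0, 0), c(0, 0), c(0, 0)), "at least 4")
  expect_error(kinematic_profile(rep(1, 8), rep(0, 7), rep(0, 8), rep(0, 8)),
               "same length")
  expect_error(kinematic_profile(c(-1, rep(1, 7)), rep(0, 8), rep(0, 8), rep(0, 8)),
               "non-negative")
  expect_error(kinematic_profile(rep(100, 8), seq(0, 70, length.out = 8),
                                 rep(0, 8), rep(0, 8)), "cyclic")
})
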