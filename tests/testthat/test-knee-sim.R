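knee_fixture <- local({
  p <- small_params(32)
  list(p = p, fem = make_femoral_surface(p), ins = make_insert_surface(p))
})

test_that("a zero-motion cycle accrues zero wear (undefined cross-shear nodes
           do not wear)", {
  f <- knee_fixture
  prof <- kinematic_profile(rep(1000, 16), rep(10, 16), rep(-2, 16), rep(1, 16))
  res <- run_cycle(f$fem, f$ins, prof, cfg = simulation_config(1e5, 1e5, n_steps = 16))
  expect_identical(res$wear$total, 0)
  expect_true(all(res$wear$delta == 0))
})

test_that("with uniform pressure and forced constant cross-shear the cycle
           reproduces the closed-form wear volume A * S * C", {
  b <- flat_bench(soft_size = 10, rigid_size = 60)
  n <- 32
  tau <- (seq_len(n) - 1) / n
  d_ap <- 6
  prof <- kinematic_profile(rep(400, n), rep(0, n),
                            -d_ap * (1 - cospi(2 * tau)) / 2, rep(0, n))
  cs_star <- 0.09
  cfg <- simulation_config(1e5, 1e5, n_steps = n, medial_offset_fraction = 0)
  res <- run_cycle(b$rigid, b$soft, prof, cfg = cfg, cs_override = cs_star)
  A <- sum(b$soft$vertex_area)
  S <- 2 * d_ap
  C <- wear_coefficient(default_model, cs_star, (400 / A) / default_mat$E)
  expect_lt(abs(res$wear$total - volumetric_wear(A, S, C)) /
              volumetric_wear(A, S, C), 0.01)
})

test_that("cycle wear bookkeeping is conservative and step fractions sum to 100%", {
  f <- knee_fixture
  prof <- generate_profile("walking", 32)
  res <- run_cycle(f$fem, f$ins, prof, cfg = simulation_config(1e5, 1e5, n_steps = 32))
  expect_gt(res$wear$total, 0)
  expect_true(is.finite(res$summary$wear_rate_mm3_per_mc))
  expect_lt(abs(sum(res$wear$delta * f$ins$vertex_area) - res$wear$total) /
              res$wear$total, 1e-9)
  expect_equal(sum(res$summary$steps$wear_fraction_pct), 100, tolerance = 1e-6)
  expect_true(all(res$wear$delta >= 0))
  expect_equal(res$summary$wear_rate_mm3_per_mc, res$wear$total * 1e6)
})

test_that("block wear is linear in the model scale and zero for a zero-scale model", {
  f <- knee_fixture
  prof <- generate_profile("walking", 16)
  cfg <- simulation_config(1e5, 1e5, n_steps = 16)
  m0 <- wear_coefficient_model(a = 0)
  sim0 <- run_simulation(f$fem, f$ins, prof, model = m0, cfg = cfg)
  expect_identical(sim0$wear$total, 0)
  expect_identical(sim0$insert_worn$vertices, f$ins$vertices)   # geometry untouched
  m1 <- default_model
  m2 <- wear_coefficient_model(a = 2 * m1$a)
  r1 <- run_cycle(f$fem, f$ins, prof, model = m1, cfg = cfg)
  r2 <- run_cycle(f$fem, f$ins, prof, model = m2, cfg = cfg)
  expect_equal(r2$wear$total, 2 * r1$wear$total, tolerance = 1e-12)
})

test_that("halving the surface-update interval changes total wear by < 5%", {
  f <- knee_fixture
  prof <- generate_profile("walking", 16)
  total <- 4e5
  one <- run_simulation(f$fem, f$ins, prof,
                        cfg = simulation_config(total, total, n_steps = 16))
  two <- run_simulation(f$fem, f$ins, prof,
                        cfg = simulation_config(total, total / 2, n_steps = 16))
  expect_lt(abs(one$wear$total - two$wear$total) / two$wear$total, 0.05)
})

test_that("without the medial offset, symmetric geometry wears 50/50
           medial/lateral", {
  f <- knee_fixture
  prof <- generate_profile("walking", 32)
  cfg <- simulation_config(1e5, 1e5, n_steps = 32, medial_offset_fraction = 0)
  res <- run_cycle(f$fem, f$ins, prof, cfg = cfg)
  vol <- res$wear$delta * f$ins$vertex_area
  med <- sum(vol[f$ins$vertices[, 3] > 0])
  lat <- sum(vol[f$ins$vertices[, 3] < 0])
  expect_lt(abs(med - lat) / (med + lat), 0.02)
})

test_that("results are invariant to the frame the scene is expressed in", {
  f <- knee_fixture
  prof <- generate_profile("walking", 16)
  cfg <- simulation_config(1e5, 1e5, n_steps = 16)
  base <- run_simulation(f$fem, f$ins, prof, cfg = cfg)
  th <- 25 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- run_simulation(rotate_mesh(f$fem, Rz), rotate_mesh(f$ins, Rz), prof,
                        cfg = cfg, frame = Rz)
  # agreement is limited by the 0.1% equilibrium tolerance of the contact stage
  expect_equal(rot$wear$total, base$wear$total, tolerance = 1e-3)
  expect_equal(rot$wear$delta, base$wear$delta, tolerance = 1e-3)
})

test_that("the worn surface recedes along the inward normal and exhausting the
           insert thickness aborts", {
  f <- knee_fixture
  prof <- generate_profile("walking", 16)
  cfg <- simulation_config(2e5, 1e5, n_steps = 16)
  sim <- run_simulation(f$fem, f$ins, prof, cfg = cfg)
  dy <- f$ins$vertices[, 2] - sim$insert_worn$vertices[, 2]
  expect_true(all(dy >= -1e-12))                      # material only removed
  expect_gt(max(dy), 0)
  expect_identical(nrow(sim$rates), 2L)
  expect_equal(sim$rates$cumulative_wear_mm3[2], sim$wear$total)
  huge <- wear_coefficient_model(a = 1e-3)            # pathological scale
  expect_error(run_simulation(f$fem, f$ins, prof, model = huge, cfg = cfg),
               "thickness exhausted")
})

test_that("simulation configuration invariants are enforced", {
  expect_error(simulation_config(1e6, 3e5), "must divide")
  expect_error(simulation_config(1e6, 1e6, medial_offset_fraction = 0.6), "0.5")
  expect_error(simulation_config(0, 1e5), "positive")
})

test_that("activity comparison tabulates rates in input order with the
           validation statistic", {
  pred <- data.frame(activity = c("walking", "deep_squat", "stairs_ascent"),
                     wear_rate = c(4.5, 3.7, 5.6))
  exp_ <- data.frame(activity = c("stairs_ascent", "walking", "deep_squat"),
                     wear_rate = c(7.1, 5.8, 3.5), ci95 = c(2.0, 1.4, 0.8))
  rep <- compare_activities(pred, exp_)
  expect_identical(rep$table$activity, pred$activity)   # input order preserved
  expect_identical(round(rep$r_squared, 2), 0.94)
  expect_equal(rep$table$experimental_mm3_per_mc, c(5.8, 3.5, 7.1))
  expect_equal(rep$table$experimental_ci95, c(1.4, 0.8, 2.0))
  same <- compare_activities(pred, data.frame(activity = pred$activity,
                                              wear_rate = pred$wear_rate))
  expect_equal(same$r_squared, 1)
  out <- capture.output(print(rep))
  expect_true(any(grepl("mm\\^3/mc", out)))
})
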