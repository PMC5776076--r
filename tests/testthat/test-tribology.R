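test_that("cross-shear is 0 for collinear sliding and 0.5 for isotropic sliding", {
  M <- frictional_work_tensor(rbind(c(1, 1), c(-2, -2), c(0.5, 0.5)),
                              pressure = 4, area = 0.1, mu = 0.04)
  r <- cross_shear(M)
  expect_equal(r$cs, 0)
  expect_equal(abs(r$pmo), c(1, 1) / sqrt(2), tolerance = 1e-12)

  M <- frictional_work_tensor(rbind(c(1, 0), c(0, 1)), 4, 0.1, 0.04)
  r <- cross_shear(M)
  expect_equal(r$cs, 0.5)
  expect_identical(r$pmo, c(1, 0))   # degenerate: deterministic first basis vector
  expect_error(cross_shear(matrix(0, 2, 2)), "zero total frictional work")
})

test_that("cross-shear is basis-invariant, bounded, and matches a brute-force
           orientation scan on random tensors", {
  set.seed(42)
  for (i in 1:40) {
    M <- random_work_tensor()
    cs <- cross_shear(M)$cs
    expect_gte(cs, 0); expect_lte(cs, 0.5)
    expect_lt(abs(cs - brute_force_cs(M)), 1e-4)
    th <- runif(1, 0, 2 * pi)
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(cross_shear(Q %*% M %*% t(Q))$cs, cs, tolerance = 1e-10)
  }
})

test_that("the wear-coefficient surface evaluates to its closed-form values", {
  m <- default_model
  expect_identical(wear_coefficient(m, 0, 0.05), 0)          # 1 - exp(0) = 0
  # saturated cross-shear, zero stress: a * c
  expect_equal(wear_coefficient(m, 1e6, 0), 1.47e-9 * 0.84)
  # frozen from a 40-digit arbitrary-precision evaluation of the surface
  expect_equal(wear_coefficient(m, 0.087, 0.007), 1.6420645883511108e-9)
  expect_error(wear_coefficient(m, -0.1, 0.01), "non-negative")
  expect_error(wear_coefficient_model(b = -5), "non-negative")
})

test_that("wear coefficient is non-decreasing in CS and P/E for non-negative
           parameters", {
  set.seed(7)
  for (i in 1:20) {
    m <- wear_coefficient_model(a = runif(1, 1e-10, 1e-8), b = runif(1, 1, 300),
                                c = runif(1, 0, 2), d = runif(1, 0, 800),
                                e = runif(1, 0.5, 3))
    cs <- sort(runif(5, 0, 0.5)); pe <- sort(runif(5, 0, 0.2))
    expect_true(all(diff(wear_coefficient(m, cs, 0.01)) >= 0))
    expect_true(all(diff(wear_coefficient(m, 0.1, pe)) >= 0))
  }
})

test_that("wear relations multiply and invert exactly", {
  expect_identical(linear_wear(0, 1e-9), 0)
  expect_identical(linear_wear(56, 0), 0)
  expect_equal(linear_wear(56, 1e-9), 5.6e-8)
  expect_identical(volumetric_wear(0, 56, 1e-9), 0)
  expect_equal(volumetric_wear(19.6, 56, 1e-9), 19.6 * 56 * 1e-9)
  expect_equal(volumetric_wear(19.6, 56, 1e-9),
               19.6 * linear_wear(56, 1e-9))
  W <- volumetric_wear(19.6, 56, 3.2e-9)
  expect_equal(coefficient_from_measurement(W, 19.6, 56), 3.2e-9)
  expect_identical(coefficient_from_measurement(0, 19.6, 56), 0)
  expect_error(coefficient_from_measurement(1, 0, 56), "positive")
  # cycle bookkeeping: a 660,000-cycle test at 56 mm per cycle
  C <- coefficient_from_measurement(2.03, 19.635, 56 * 660000)
  expect_equal(C * 56 * 19.635 * 660000, 2.03)
})

test_that("gravimetric conversion uses the polyethylene density", {
  expect_equal(mass_to_volume(0.93), 1)
  expect_identical(mass_to_volume(0), 0)
  expect_equal(mass_to_volume(3 * 0.93), 3 * mass_to_volume(0.93))
  expect_error(mass_to_volume(1, rho = 0), "positive")
})

test_that("r_squared is the squared Pearson correlation", {
  expect_equal(r_squared(1:5, 1:5), 1)
  expect_equal(round(r_squared(c(4.5, 3.7, 5.6), c(5.8, 3.5, 7.1)), 2), 0.94)
  x <- c(4.5, 3.7, 5.6); y <- c(5.8, 3.5, 7.1)
  expect_equal(r_squared(-x, y), r_squared(x, y))   # symmetry under sign flip
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("surface fit recovers the generating parameters from noise-free samples", {
  grid <- expand.grid(cs = seq(0.01, 0.2, length.out = 6),
                      p_over_e = seq(0.007, 0.15, length.out = 6))
  grid$c <- wear_coefficient(default_model, grid$cs, grid$p_over_e)
  fit <- fit_coefficient_model(grid)
  expect_lt(abs(fit$model$e - 1.49), 1e-3)
  expect_lt(abs(fit$model$b - 116.21) / 116.21, 1e-3)
  expect_lt(abs(fit$model$d - 450.23) / 450.23, 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("degenerate observation designs are rejected as unidentifiable", {
  pe <- seq(0.01, 0.1, length.out = 6)
  obs0 <- data.frame(cs = 0, p_over_e = pe,
                     c = wear_coefficient(default_model, 0, pe))
  expect_error(fit_coefficient_model(obs0), "unidentifiable cross-shear")
  obs1 <- data.frame(cs = seq(0.01, 0.2, length.out = 6), p_over_e = 0.02,
                     c = 1e-9)
  expect_error(fit_coefficient_model(obs1), "unidentifiable stress")
  expect_error(fit_coefficient_model(data.frame(cs = 1, p_over_e = 1, c = 1)),
               "at least 5")
})

test_that("fitted models round-trip through YAML and JSON", {
  m <- wear_coefficient_model(a = 2e-9, b = 90, c = 0.5, d = 300, e = 1.2)
  for (ext in c(".yaml", ".json")) {
    tmp <- withr::local_tempfile(fileext = ext)
    write_model(m, tmp)
    back <- read_model(tmp)
    expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  }
})
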