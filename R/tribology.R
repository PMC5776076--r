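#' Accumulate a frictional-work tensor from sliding increments
#'
#' Builds the symmetric 2 x 2 frictional-work tensor of a surface node,
#' `M = sum_k mu * p_k * a_k * |ds_k| * u_k u_k^T`, where `u_k` is the unit
#' direction of the k-th tangential sliding increment in the node's material
#' tangent plane. The trace of `M` is the total frictional work (N mm); the
#' work resolved perpendicular to the principal molecular orientation is the
#' cross-shear component.
#'
#' @param increments k x 2 matrix of tangential sliding increments, mm.
#' @param pressure contact pressure per increment, MPa (scalar or length k).
#' @param area node area, mm^2 (scalar or length k).
#' @param mu friction coefficient.
#' @return 2 x 2 symmetric matrix, N mm.
#' @export
frictional_work_tensor <- function(increments, pressure, area, mu) {
  inc <- as.matrix(increments)
  mag <- sqrt(rowSums(inc^2))
  w <- mu * pressure * area * mag
  ok <- mag > 0
  if (!any(ok)) return(matrix(0, 2, 2))
  ux <- inc[ok, 1] / mag[ok]; uy <- inc[ok, 2] / mag[ok]
  wk <- w[ok]
  m11 <- sum(wk * ux * ux); m22 <- sum(wk * uy * uy); m12 <- sum(wk * ux * uy)
  matrix(c(m11, m12, m12, m22), 2, 2)
}

#' Cross-shear ratio and principal molecular orientation
#'
#' The principal molecular orientation (PMO) is the direction accumulating
#' the most frictional work: the eigenvector of the larger eigenvalue of the
#' frictional-work tensor. The cross-shear ratio is the fraction of the total
#' frictional work resolved perpendicular to the PMO,
#' `CS = E_cross / E_total = lambda_min / (lambda_min + lambda_max)`,
#' bounded in `[0, 0.5]`: 0 for unidirectional sliding, 0.5 for isotropic
#' sliding. For a degenerate (isotropic) tensor the PMO is reported
#' deterministically as the first basis vector.
#'
#' @param M symmetric 2 x 2 frictional-work tensor (N mm), e.g. from
#'   [frictional_work_tensor()].
#' @return list with `cs` in `[0, 0.5]` and `pmo`, a unit 2-vector.
#' @export
cross_shear <- function(M) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(2L, 2L)))
  if (abs(M[1, 2] - M[2, 1]) > 1e-9 * max(abs(M), 1)) stop("M must be symmetric")
  tr <- M[1, 1] + M[2, 2]
  if (tr <= 0) {
    stop("zero total frictional work: cross-shear is undefined (non-wearing node)")
  }
  r <- cs_from_components(M[1, 1], M[2, 2], M[1, 2])
  list(cs = r$cs, pmo = c(r$pmo1, r$pmo2))
}

# vectorised closed-form eigen-decomposition of 2x2 symmetric tensors
cs_from_components <- function(m11, m22, m12) {
  tr <- m11 + m22
  disc <- sqrt(((m11 - m22) / 2)^2 + m12^2)
  lmax <- tr / 2 + disc
  lmin <- tr / 2 - disc
  lmin <- pmax(lmin, 0)                 # PSD up to round-off
  cs <- ifelse(tr > 0, lmin / (lmax + lmin), NA_real_)
  # major eigenvector; with m12 ~ 0 the axes are principal already, and the
  # fully degenerate case resolves deterministically to the first basis vector
  tolv <- 1e-14 * pmax(tr, 1)
  vx <- ifelse(abs(m12) > tolv, lmax - m22, ifelse(m11 >= m22, 1, 0))
  vy <- ifelse(abs(m12) > tolv, m12, ifelse(m11 >= m22, 0, 1))
  nl <- sqrt(vx^2 + vy^2)
  list(cs = pmin(cs, 0.5), pmo1 = vx / nl, pmo2 = vy / nl)
}

#' Wear-coefficient surface model
#'
#' The non-dimensional wear coefficient of moderately cross-linked UHMWPE as
#' a function of the cross-shear ratio CS and the non-dimensional contact
#' stress P/E:
#' `C = a * (1 - exp(-b * CS)) * (c + d * (P/E)^e)`.
#' The defaults are the published fitted constants for moderately
#' cross-linked UHMWPE against polished CoCr
#' (`a = 1.47e-9, b = 116.21, c = 0.84, d = 450.23, e = 1.49`; the 1e-9
#' scale of the original expression is folded into `a`).
#'
#' @param a scale (dimensionless; carries the 1e-9 order of magnitude).
#' @param b cross-shear saturation rate.
#' @param c stress-independent offset inside the stress factor.
#' @param d stress gain.
#' @param e stress exponent.
#' @return object of class `wear_coef_model`.
#' @export
wear_coefficient_model <- function(a = 1.47e-9, b = 116.21, c = 0.84,
                                   d = 450.23, e = 1.49) {
  v <- c(a = a, b = b, c = c, d = d, e = e)
  if (any(v < 0)) stop("all wear-coefficient model parameters must be non-negative")
  structure(as.list(v), class = "wear_coef_model")
}

#' @export
print.wear_coef_model <- function(x, ...) {
  cat(sprintf("wear coefficient surface: C = %.4g * (1 - exp(-%.4g CS)) * (%.4g + %.4g (P/E)^%.4g)\n",
              x$a, x$b, x$c, x$d, x$e))
  invisible(x)
}

#' Evaluate the wear-coefficient surface
#'
#' @param model a [wear_coefficient_model()].
#' @param cs cross-shear ratio(s), >= 0.
#' @param p_over_e non-dimensional contact stress(es), >= 0.
#' @return non-dimensional wear coefficient(s); zero wherever `cs` is zero.
#' @export
wear_coefficient <- function(model, cs, p_over_e) {
  if (any(cs < 0) || any(p_over_e < 0)) {
    stop("cs and p_over_e must be non-negative")
  }
  model$a * (1 - exp(-model$b * cs)) * (model$c + model$d * p_over_e^model$e)
}

#' Linear wear depth from sliding distance and wear coefficient
#' @param S sliding distance, mm.
#' @param C non-dimensional wear coefficient.
#' @return linear wear depth, mm.
#' @export
linear_wear <- function(S, C) S * C

#' Volumetric wear from contact area, sliding distance and wear coefficient
#' @param A contact area, mm^2.
#' @param S sliding distance, mm.
#' @param C non-dimensional wear coefficient.
#' @return wear volume, mm^3.
#' @export
volumetric_wear <- function(A, S, C) A * S * C

#' Wear coefficient from a measured wear volume
#'
#' Inverts the wear-volume relation: `C = W / (A * S)`.
#' @param W measured wear volume, mm^3.
#' @param A contact area, mm^2.
#' @param S total sliding distance, mm.
#' @return non-dimensional wear coefficient.
#' @export
coefficient_from_measurement <- function(W, A, S) {
  if (any(A * S <= 0)) stop("A * S must be positive")
  W / (A * S)
}

#' Convert gravimetric mass loss to wear volume
#' @param delta_mass mass loss, mg.
#' @param rho material density, mg/mm^3 (default UHMWPE, 0.93).
#' @return wear volume, mm^3.
#' @export
mass_to_volume <- function(delta_mass, rho = 0.93) {
  if (rho <= 0) stop("rho must be positive")
  delta_mass / rho
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' Agreement between predicted and observed values, computed as the squared
#' Pearson correlation coefficient. Note this convention (not
#' `1 - SS_res/SS_tot`) is used everywhere in this package for
#' predicted-versus-measured comparisons; it measures linear association and
#' is symmetric in its arguments and invariant to joint sign flips.
#'
#' @param predicted numeric vector.
#' @param observed numeric vector of the same length.
#' @return value in `[0, 1]`.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 2) {
    stop("predicted and observed must have equal length >= 2")
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("r_squared undefined for constant inputs")
  }
  stats::cor(predicted, observed)^2
}

#' Fit the wear-coefficient surface to measurements
#'
#' Nonlinear least squares of
#' `C = a (1 - exp(-b CS)) (c + d (P/E)^e)` against measured wear
#' coefficients. The model has an exact scale degeneracy between `a` and
#' `(c, d)`, so the scale `a` is held fixed (default 1.47e-9) and only the
#' shape parameters `b, c, d, e` are free; residuals are computed on
#' `C / a`, which keeps the problem well scaled. On failure the fit is
#' retried from up to `n_multistart` jittered initialisations drawn under a
#' fixed seed.
#'
#' @param observations data frame with columns `cs`, `p_over_e`, `c`
#'   (measured non-dimensional wear coefficient).
#' @param init named list of starting values for `b, c, d, e`.
#' @param fixed_scale the fixed scale parameter `a`.
#' @param n_multistart extra jittered starts attempted after a failure.
#' @param seed RNG seed for the multi-start jitter.
#' @return list with `model` (a [wear_coefficient_model()]), `r_squared` of
#'   the fit (squared Pearson correlation of fitted vs observed), and `fit`
#'   (the underlying `nls`-type object).
#' @export
fit_coefficient_model <- function(observations,
                                  init = list(b = 100, c = 1, d = 400, e = 1.5),
                                  fixed_scale = 1.47e-9,
                                  n_multistart = 5L, seed = 0L) {
  obs <- as.data.frame(observations)
  need <- c("cs", "p_over_e", "c")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns cs, p_over_e, c")
  }
  if (nrow(obs) < 5) stop("need at least 5 observations spanning both axes")
  if (length(unique(obs$cs)) < 2) {
    stop("unidentifiable cross-shear rate b: all observations share one CS value")
  }
  if (length(unique(obs$p_over_e)) < 2) {
    stop("unidentifiable stress exponent e: all observations share one P/E value")
  }
  df <- data.frame(cs = obs$cs, x = obs$p_over_e, y = obs$c / fixed_scale)
  starts <- list(init)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (i in seq_len(n_multistart)) {
    starts[[i + 1L]] <- lapply(init, function(v) v * exp(stats::rnorm(1, 0, 0.4)))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  fit <- NULL
  residual_history <- character(0)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ (1 - exp(-b * cs)) * (cc + d * x^e),
                        data = df,
                        start = list(b = st$b, cc = st$c, d = st$d, e = st$e),
                        lower = c(0, 0, 0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(err) {
        residual_history <<- c(residual_history, conditionMessage(err))
        NULL
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("wear-coefficient fit did not converge from any start:\n  ",
         paste(residual_history, collapse = "\n  "))
  }
  cf <- stats::coef(fit)
  model <- wear_coefficient_model(a = fixed_scale, b = cf[["b"]], c = cf[["cc"]],
                                  d = cf[["d"]], e = cf[["e"]])
  pred <- wear_coefficient(model, obs$cs, obs$p_over_e)
  r2 <- if (stats::sd(pred) > 0 && stats::sd(obs$c) > 0) r_squared(pred, obs$c) else 1
  list(model = model, r_squared = r2, fit = fit)
}

#' Read / write wear-coefficient observation tables and fitted models
#'
#' Observation CSV columns: `cs, p_over_e, c`. Fitted models are stored as
#' YAML (or JSON if the path ends in `.json`).
#' @param path file path.
#' @return for `read_observations_csv` a data frame; for `read_model` a
#'   [wear_coefficient_model()].
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("cs", "p_over_e", "c") %in% names(df)) || nrow(df) == 0) {
    stop("observations CSV must be non-empty with columns cs, p_over_e, c")
  }
  df
}

#' @rdname read_observations_csv
#' @param model a [wear_coefficient_model()].
#' @export
write_model <- function(model, path) {
  vals <- list(a = model$a, b = model$b, c = model$c, d = model$d, e = model$e)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @rdname read_observations_csv
#' @export
read_model <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else yaml::read_yaml(path)
  wear_coefficient_model(a = vals$a, b = vals$b, c = vals$c, d = vals$d, e = vals$e)
}
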