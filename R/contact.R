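#' Material properties of the polyethylene bearing
#'
#' Defaults are the compressive properties of moderately cross-linked UHMWPE
#' (GUR 1020, 5 Mrad gamma-irradiated) measured under realistic compressive
#' loading: equivalent elastic modulus 553 MPa, Poisson's ratio 0.32, density
#' 0.93 mg/mm^3, and an isotropic friction coefficient of 0.04 against
#' polished CoCr.
#'
#' @param E equivalent elastic modulus, MPa.
#' @param nu Poisson's ratio (0 <= nu < 0.5).
#' @param rho density, mg/mm^3.
#' @param mu friction coefficient (dimensionless).
#' @return object of class `material_properties`.
#' @export
material_properties <- function(E = 553, nu = 0.32, rho = 0.93, mu = 0.04) {
  if (E <= 0) stop("E must be positive")
  if (nu < 0 || nu >= 0.5) stop("nu must satisfy 0 <= nu < 0.5 (nu = 0.5 is incompressible)")
  if (rho <= 0) stop("rho must be positive")
  if (mu < 0) stop("mu must be non-negative")
  structure(list(E = E, nu = nu, rho = rho, mu = mu), class = "material_properties")
}

#' Elastic-foundation (Winkler) contact pressure
#'
#' Pressure of a thin elastic layer of thickness `layer_thickness` under a
#' rigid indenter penetrating by `penetration`:
#' `p = (1 - nu) E / ((1 + nu)(1 - 2 nu)) * penetration / layer_thickness`
#' for positive penetration, zero otherwise. This confined-layer modulus is
#' the standard foundation substitute for conforming implant contact.
#'
#' @param penetration local penetration, mm (vectorised).
#' @param mat a [material_properties()].
#' @param layer_thickness foundation layer thickness, mm (> 0).
#' @return contact pressure, MPa.
#' @export
foundation_pressure <- function(penetration, mat, layer_thickness) {
  if (layer_thickness <= 0) stop("layer_thickness must be positive")
  if (mat$nu >= 0.5) stop("nu = 0.5: incompressible layer has singular foundation modulus")
  K <- foundation_modulus(mat)
  K * pmax(penetration, 0) / layer_thickness
}

foundation_modulus <- function(mat) {
  (1 - mat$nu) * mat$E / ((1 + mat$nu) * (1 - 2 * mat$nu))
}

#' Hertzian rigid-ball-on-elastic-flat closed form
#'
#' Contact of a rigid sphere of radius `R` on an elastic half-space:
#' `a = (3 F R / (4 E*))^(1/3)` with `E* = E / (1 - nu^2)`,
#' `p_max = 3 F / (2 pi a^2)`. Used as the independent accuracy anchor for
#' the foundation backend and for the modulus calibration curve.
#'
#' @param F normal load, N.
#' @param R ball radius, mm.
#' @param mat a [material_properties()] for the flat.
#' @return list with `contact_radius` (mm), `area` (mm^2), `p_max` (MPa).
#' @export
hertz_ball_on_flat <- function(F, R, mat) {
  if (F <= 0 || R <= 0) stop("F and R must be positive")
  Estar <- mat$E / (1 - mat$nu^2)
  a <- (3 * F * R / (4 * Estar))^(1 / 3)
  area <- pi * a^2
  list(contact_radius = a, area = area, p_max = 3 * F / (2 * area))
}

#' Foundation layer thickness calibrated to the Hertz solution
#'
#' For ball-on-flat configurations the foundation layer thickness is the
#' model's only free constant. This helper chooses `h` so that the foundation
#' contact radius at load `F` equals the Hertz radius: with parabolic
#' penetration the foundation gives `F = K pi R d0^2 / h` and contact radius
#' `sqrt(2 R d0)`; equating the radius to Hertz yields
#' `h = K pi R (a_h^2 / (2 R))^2 / F`.
#'
#' @param F calibration load, N.
#' @param R ball radius, mm.
#' @param mat a [material_properties()].
#' @return layer thickness, mm.
#' @export
calibrate_layer_thickness <- function(F, R, mat) {
  a_h <- hertz_ball_on_flat(F, R, mat)$contact_radius
  d0 <- a_h^2 / (2 * R)
  foundation_modulus(mat) * pi * R * d0^2 / F
}

#' Pose of the rigid counterface relative to the deformable surface
#'
#' @param fe flexion-extension angle of the rigid (femoral) component,
#'   degrees, about the z axis through its recorded centre of rotation.
#' @param ap anterior-posterior translation of the deformable (tibial)
#'   component, mm (+ anterior).
#' @param ie internal-external rotation of the deformable component, degrees,
#'   about the vertical axis through `(0, 0, axis_offset_z)`.
#' @param axis_offset_z medial offset of the load / tibial-rotation axis, mm.
#' @return list of class `contact_pose`.
#' @export
contact_pose <- function(fe = 0, ap = 0, ie = 0, axis_offset_z = 0) {
  structure(list(fe = fe, ap = ap, ie = ie, axis_offset_z = axis_offset_z),
            class = "contact_pose")
}

# ---- rigid-surface lower envelope ------------------------------------------

# Build a vertical lower-envelope interpolator of a structured rigid mesh,
# optionally flexed by `fe_deg` about the z axis through `cor`. Returns a
# function (x, z) -> y (NA where the rigid surface does not cover the point).
rigid_envelope <- function(rigid, fe_deg = 0) {
  if (is.null(rigid$grid) || is.null(rigid$grid$index)) {
    stop("the rigid counterface must carry a structured grid descriptor; ",
         "use the parametric generators (STL triangle soup is not supported here)")
  }
  idx <- rigid$grid$index
  v <- rigid$vertices
  if (fe_deg != 0) {
    if (is.null(rigid$cor)) {
      stop("flexion requested but the rigid mesh records no centre of rotation")
    }
    th <- fe_deg * pi / 180
    cx <- rigid$cor[1]; cy <- rigid$cor[2]
    dx <- v[, 1] - cx; dy <- v[, 2] - cy
    v <- cbind(cx + cos(th) * dx - sin(th) * dy,
               cy + sin(th) * dx + cos(th) * dy,
               v[, 3])
  }
  nz <- ncol(idx)
  zcol <- vapply(seq_len(nz), function(j) mean(v[idx[, j], 3]), numeric(1))
  # keep only the branch below the centre of rotation: a flexed condyle arc
  # can fold over in x, and the vertical envelope is single-valued only on
  # the lower branch
  keep_row <- if (!is.null(rigid$cor)) {
    function(j) v[idx[, j], 2] < rigid$cor[2] - 1e-9
  } else {
    function(j) rep(TRUE, nrow(idx))
  }
  # regular x grid spanning the (possibly rotated) columns; odd count so the
  # midline x = 0 is sampled exactly on symmetric meshes
  xr <- range(v[, 1])
  nxq <- max(nrow(idx) * 2L, 64L) + 1L
  xq <- seq(xr[1], xr[2], length.out = nxq)
  Y <- matrix(NA_real_, nxq, nz)
  for (j in seq_len(nz)) {
    ok <- keep_row(j)
    if (sum(ok) < 2L) ok <- rep(TRUE, nrow(idx))   # unfolded surface (e.g. plate)
    xs <- v[idx[ok, j], 1]; ys <- v[idx[ok, j], 2]
    o <- order(xs)
    Y[, j] <- approx(xs[o], ys[o], xout = xq, ties = min)$y
  }
  dxq <- xq[2] - xq[1]
  function(x, z) {
    # bilinear interpolation on (xq, zcol); NA outside coverage
    fi <- (x - xq[1]) / dxq + 1
    i0 <- floor(fi); tx <- fi - i0
    ji <- findInterval(z, zcol)
    ok <- i0 >= 1 & i0 < nxq & ji >= 1 & ji < nz
    out <- rep(NA_real_, length(x))
    if (!any(ok)) return(out)
    i0k <- i0[ok]; jik <- ji[ok]; txk <- tx[ok]
    tz <- (z[ok] - zcol[jik]) / (zcol[jik + 1L] - zcol[jik])
    y00 <- Y[cbind(i0k, jik)];     y10 <- Y[cbind(i0k + 1L, jik)]
    y01 <- Y[cbind(i0k, jik + 1L)]; y11 <- Y[cbind(i0k + 1L, jik + 1L)]
    out[ok] <- (1 - txk) * (1 - tz) * y00 + txk * (1 - tz) * y10 +
      (1 - txk) * tz * y01 + txk * tz * y11
    out
  }
}

# world coordinates of the deformable mesh vertices under a pose (AP + IE)
posed_soft_coords <- function(soft, pose) {
  v <- soft$vertices
  psi <- pose$ie * pi / 180
  cz <- pose$axis_offset_z
  if (psi != 0) {
    dx <- v[, 1]; dzz <- v[, 3] - cz
    # rotation about +y: x' = cos*x + sin*z, z' = -sin*x + cos*z
    xw <- cos(psi) * dx + sin(psi) * dzz + pose$ap
    zw <- -sin(psi) * dx + cos(psi) * dzz + cz
  } else {
    xw <- v[, 1] + pose$ap
    zw <- v[, 3]
  }
  cbind(xw, v[, 2], zw)
}

#' Solve vertical and varus-valgus equilibrium of foundation contact
#'
#' The rigid counterface (femoral component, ball or plate) is lowered onto
#' the deformable surface along the superior axis, and additionally tilted in
#' adduction-abduction (rotation about the anterior axis), until the foundation
#' pressure field balances the applied axial load (relative tolerance `tol`)
#' and the varus-valgus moment about the medially offset load axis vanishes
#' (tolerance `tol * load * 1 mm`). Penetration is measured by vertical ray
#' projection onto the rigid surface's lower envelope; adduction-abduction is
#' applied in small-angle form.
#'
#' @param rigid rigid counterface [surface_mesh()] with a structured grid.
#' @param soft deformable polyethylene [surface_mesh()]; pressures are
#'   reported at its vertices.
#' @param pose a [contact_pose()].
#' @param axial_load applied load, N (>= 0).
#' @param mat a [material_properties()] for the deformable body.
#' @param layer_thickness foundation layer thickness, mm (default 10, the
#'   insert thickness).
#' @param allow_aa solve the adduction-abduction tilt (default TRUE); set
#'   FALSE to constrain the tilt to zero (bench configurations).
#' @param tol relative force tolerance.
#' @param max_iter iteration cap for the equilibrium search.
#' @param warm_start optional `c(depth, tilt)` initial guess from a previous
#'   solve.
#' @return object of class `contact_solution`: per-vertex `pressure` (MPa),
#'   `contact_area` (mm^2), `resultant_force` (N), `equilibrium_pose`
#'   (`depth` mm of vertical approach, `aa_deg` tilt), `penetration`,
#'   `converged`, and the residuals.
#' @export
solve_contact <- function(rigid, soft, pose = contact_pose(), axial_load,
                          mat = material_properties(), layer_thickness = 10,
                          allow_aa = TRUE, tol = 1e-3, max_iter = 80L,
                          warm_start = NULL) {
  if (axial_load < 0) stop("axial_load must be >= 0")
  nv <- nrow(soft$vertices)
  if (axial_load == 0) {
    return(new_contact_solution(numeric(nv), soft, c(0, 0), 0, TRUE, 0, 0))
  }
  env_fun <- rigid_envelope(rigid, fe_deg = pose$fe)
  w <- posed_soft_coords(soft, pose)
  env0 <- env_fun(w[, 1], w[, 3])
  covered <- !is.na(env0)
  if (!any(covered)) {
    stop("contact solve failed: rigid surface does not cover any deformable vertex ",
         "at this pose (fe = ", pose$fe, ", ap = ", pose$ap, ", ie = ", pose$ie, ")")
  }
  ys <- w[, 2]; zs <- w[, 3]
  area <- soft$vertex_area
  K_h <- foundation_modulus(mat) / layer_thickness
  if (mat$nu >= 0.5) stop("nu = 0.5: incompressible layer")
  zoff <- pose$axis_offset_z
  gap0 <- env0[covered] - ys[covered]        # initial vertical gap (>= 0 apart)
  zc <- zs[covered] - zoff
  ac <- area[covered]

  eval_fm <- function(d, phi) {
    pen <- d + phi * zc - gap0
    p <- K_h * pmax(pen, 0)
    Fz <- sum(p * ac)
    Mx <- sum(p * ac * zc)
    list(F = Fz, M = Mx, p = p, pen = pen)
  }

  # initial approach: start from first touch
  d <- if (!is.null(warm_start)) warm_start[1] else min(gap0) + 1e-4
  phi <- if (!is.null(warm_start) && allow_aa) warm_start[2] else 0
  ftol <- tol * axial_load
  mtol <- tol * axial_load * 1    # N mm
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- eval_fm(d, phi)
    rF <- s$F - axial_load
    rM <- s$M
    if (abs(rF) <= ftol && (!allow_aa || abs(rM) <= mtol)) {
      converged <- TRUE
      break
    }
    # numeric Jacobian
    hd <- max(1e-6, 1e-3 * max(abs(d), 1e-3))
    sF <- eval_fm(d + hd, phi)
    dFdd <- (sF$F - s$F) / hd
    dMdd <- (sF$M - s$M) / hd
    if (dFdd <= 0) { # lost contact: jump back to first touch at this tilt
      d <- min(gap0 - phi * zc) + 1e-3
      next
    }
    if (allow_aa) {
      hp <- 1e-5
      sP <- eval_fm(d, phi + hp)
      dFdp <- (sP$F - s$F) / hp
      dMdp <- (sP$M - s$M) / hp
      det <- dFdd * dMdp - dFdp * dMdd
      if (abs(det) < 1e-12) {
        step <- c(rF / dFdd, 0)
      } else {
        step <- c((rF * dMdp - rM * dFdp) / det,
                  (dFdd * rM - dMdd * rF) / det)
      }
    } else {
      step <- c(rF / dFdd, 0)
    }
    # damped Newton: limit the vertical step to keep the search stable
    step[1] <- sign(step[1]) * min(abs(step[1]), 0.5 * max(abs(d), 0.05))
    step[2] <- sign(step[2]) * min(abs(step[2]), 0.02)
    d <- d - step[1]
    # adduction-abduction tilt stays in a physical range (small-angle model)
    phi <- min(max(phi - step[2], -0.15), 0.15)
  }
  if (!converged) {
    s <- eval_fm(d, phi)
    stop(sprintf(paste0("contact equilibrium did not converge in %d iterations: ",
                        "force residual %.3g N (tol %.3g), moment residual %.3g N mm"),
                 max_iter, s$F - axial_load, ftol, s$M))
  }
  pressure <- numeric(nv)
  pressure[covered] <- s$p
  penetration <- numeric(nv)
  penetration[covered] <- pmax(s$pen, 0)
  new_contact_solution(pressure, soft, c(d, phi * 180 / pi), axial_load,
                       TRUE, s$F - axial_load, s$M, penetration)
}

new_contact_solution <- function(pressure, soft, eq_pose, load, converged,
                                 res_f, res_m, penetration = NULL) {
  in_contact <- pressure > 0
  structure(list(
    pressure = pressure,
    contact_area = sum(soft$vertex_area[in_contact]),
    resultant_force = sum(pressure * soft$vertex_area),
    equilibrium_pose = c(depth = eq_pose[1], aa_deg = eq_pose[2]),
    penetration = penetration,
    applied_load = load,
    converged = converged,
    residual_force = res_f,
    residual_moment = res_m), class = "contact_solution")
}

#' @export
print.contact_solution <- function(x, ...) {
  cat(sprintf("contact_solution: load %.6g N, area %.6g mm^2, p_max %.6g MPa\n",
              x$applied_load, x$contact_area, max(x$pressure)))
  cat(sprintf("  equilibrium depth %.5g mm, AA tilt %.5g deg, residuals %.2g N / %.2g N mm\n",
              x$equilibrium_pose[1], x$equilibrium_pose[2],
              x$residual_force, x$residual_moment))
  invisible(x)
}

#' Moment-based contact area estimate for ball-type contact
#'
#' For a foundation pressure field under a spherical indenter the pressure is
#' a paraboloid cap, for which the pressure-weighted mean squared radius about
#' the contact centroid equals `a^2 / 3`. Estimating the contact radius this
#' way is smooth under mesh refinement, unlike counting loaded vertices.
#'
#' @param sol a `contact_solution`.
#' @param soft the deformable [surface_mesh()] the solution refers to.
#' @return estimated circular contact area, mm^2.
#' @export
contact_area_moment <- function(sol, soft) {
  p <- sol$pressure
  w <- p * soft$vertex_area
  if (sum(w) <= 0) return(0)
  x <- soft$vertices[, 1]; z <- soft$vertices[, 3]
  cx <- sum(w * x) / sum(w); cz <- sum(w * z) / sum(w)
  r2 <- sum(w * ((x - cx)^2 + (z - cz)^2)) / sum(w)
  pi * 3 * r2
}

#' Export a contact solution as CSV
#'
#' Writes one row per deformable-surface vertex: id, coordinates, vertex area
#' and pressure.
#' @param sol a `contact_solution`.
#' @param soft the deformable [surface_mesh()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_contact_csv <- function(sol, soft, path) {
  df <- data.frame(vertex = seq_len(nrow(soft$vertices)),
                   x_mm = soft$vertices[, 1],
                   y_mm = soft$vertices[, 2],
                   z_mm = soft$vertices[, 3],
                   area_mm2 = soft$vertex_area,
                   pressure_mpa = sol$pressure)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
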