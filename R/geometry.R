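#' Parameters of the synthetic implant geometry
#'
#' The package replaces proprietary implant CAD with a parametric stand-in: a
#' bicondylar femoral component (two toroidal condyles, constant distal radius
#' across the flexion arc) articulating on a biconcave insert (two toroidal
#' dishes, one per condyle). The defaults describe a moderately conforming
#' fixed-bearing curved insert of realistic size; the articular radii are
#' synthetic values chosen by this package, not measured from any commercial
#' implant.
#'
#' @param condyle_distal_radius sagittal (distal) radius of each femoral
#'   condyle, mm. Constant over the modelled flexion arc, so the flexion axis
#'   is the condylar centre.
#' @param condyle_frontal_radius frontal (coronal) radius of each condyle, mm.
#' @param condyle_spacing medial-lateral distance between condyle (and dish)
#'   centres, mm.
#' @param insert_dish_sagittal_radius sagittal radius of each insert dish, mm;
#'   must be >= `condyle_distal_radius` (conforming, non-penetrating at rest).
#' @param insert_dish_frontal_radius frontal radius of each insert dish, mm;
#'   must be >= `condyle_frontal_radius`.
#' @param insert_thickness insert thickness below the dish low point, mm.
#' @param insert_width medial-lateral insert width, mm.
#' @param grid_resolution vertices per edge of the generated structured grids.
#' @return an object of class `implant_params` (named list).
#' @export
implant_params <- function(condyle_distal_radius = 30,
                           condyle_frontal_radius = 20,
                           condyle_spacing = 46,
                           insert_dish_sagittal_radius = 45,
                           insert_dish_frontal_radius = 26,
                           insert_thickness = 10,
                           insert_width = 70,
                           grid_resolution = 64L) {
  p <- list(condyle_distal_radius = condyle_distal_radius,
            condyle_frontal_radius = condyle_frontal_radius,
            condyle_spacing = condyle_spacing,
            insert_dish_sagittal_radius = insert_dish_sagittal_radius,
            insert_dish_frontal_radius = insert_dish_frontal_radius,
            insert_thickness = insert_thickness,
            insert_width = insert_width,
            grid_resolution = as.integer(grid_resolution))
  if (any(vapply(p[1:7], function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all implant dimensions must be positive")
  }
  if (insert_dish_sagittal_radius < condyle_distal_radius) {
    stop("non-conforming geometry: insert_dish_sagittal_radius (",
         insert_dish_sagittal_radius, " mm) must be >= condyle_distal_radius (",
         condyle_distal_radius, " mm), otherwise the condyle penetrates the dish rim")
  }
  if (insert_dish_frontal_radius < condyle_frontal_radius) {
    stop("non-conforming geometry: insert_dish_frontal_radius must be >= ",
         "condyle_frontal_radius")
  }
  if (p$grid_resolution < 8L) stop("grid_resolution must be at least 8")
  class(p) <- "implant_params"
  p
}

# dish/condyle cross-section helpers; sqrt arguments clamped near the rim
# (at `cap * R`) so the heightfield stays defined over the whole grid
sag_drop <- function(x, R, cap = 0.95) {
  R - sqrt(pmax(R^2 - pmin(x^2, (cap * R)^2), 0))
}

# symmetric axis of ~n points guaranteed to contain 0 (odd count)
sym_axis <- function(halfspan, n) {
  n2 <- if (n %% 2L == 0L) n + 1L else n
  seq(-halfspan, halfspan, length.out = n2)
}

# symmetric z axis guaranteed to contain the exact condyle centres +/- c
z_axis_with_centres <- function(halfspan, n, c) {
  sort(unique(c(sym_axis(halfspan, n), -c, c)))
}

#' Synthetic tibial insert articulating surface
#'
#' Generates the upper (articulating) sheet of a biconcave insert as a
#' structured heightfield: two toroidal dishes symmetric about the sagittal
#' midplane, with the dish low points at y = 0, x = 0, z = +/-
#' `condyle_spacing / 2`. The dish surface is
#' `y(x, z) = f_sag(x) + f_frontal(|z| - spacing/2)` with circular-arc drop
#' functions, i.e. a two-radius (toroidal) cup per condyle. The raised ridge
#' between the dishes plays the role of the intercondylar eminence.
#'
#' @param params an [implant_params()].
#' @return a [surface_mesh()] with a structured `grid` descriptor; the mesh
#'   carries `params` and the insert AP length as metadata.
#' @export
make_insert_surface <- function(params = implant_params()) {
  stopifnot(inherits(params, "implant_params"))
  n <- params$grid_resolution
  w <- params$insert_width
  len <- 0.65 * w                      # AP footprint, synthetic proportion
  half <- params$condyle_spacing / 2
  xs <- sym_axis(len / 2, n)           # contains x = 0 (dish low line)
  zs <- z_axis_with_centres(w / 2, n, half)
  fx <- sag_drop(xs, params$insert_dish_sagittal_radius)
  dz <- abs(abs(zs) - half)
  # the frontal rim is capped earlier than the condyle clamp so the
  # intercondylar ridge always clears the femoral notch
  fz <- sag_drop(dz, params$insert_dish_frontal_radius, cap = 0.85)
  y <- outer(fx, fz, `+`)
  heightfield_mesh(xs, zs, y, extra = list(params = params, ap_length = len))
}

#' Synthetic femoral component articulating surface
#'
#' Generates the distal articulating sheet of a bicondylar femoral component:
#' each condyle is a barrel of constant sagittal radius
#' `condyle_distal_radius` about the flexion axis (the z axis through the
#' centre of rotation), with a frontal radius `condyle_frontal_radius`. The
#' mesh is a structured grid in (arc angle, z); constant distal radius means
#' the recorded flexion axis is the condylar centre, so flexion produces pure
#' sliding at the contact. At the neutral pose the condyle low points rest
#' exactly on the matching insert dish low points.
#'
#' @param params an [implant_params()].
#' @param arc_deg half-angle of the meshed sagittal arc, degrees.
#' @return a [surface_mesh()] with the centre of rotation in `$cor`
#'   (`c(0, condyle_distal_radius, 0)`) and a structured `grid`.
#' @export
make_femoral_surface <- function(params = implant_params(), arc_deg = 115) {
  stopifnot(inherits(params, "implant_params"))
  n <- params$grid_resolution
  Rd <- params$condyle_distal_radius
  Rf <- params$condyle_frontal_radius
  half <- params$condyle_spacing / 2
  zs <- z_axis_with_centres(params$insert_width / 2, n, half)
  us <- sym_axis(arc_deg, n) * pi / 180
  dz <- abs(abs(zs) - half)
  # local sagittal radius: Rd at the condyle centre line, receding towards the
  # notch and edges along the frontal arc
  Rz <- Rd - sag_drop(dz, Rf)
  ycor <- Rd
  nu <- length(us); nz <- length(zs)
  x <- outer(sin(us), Rz)
  y <- ycor - outer(cos(us), Rz)
  z <- matrix(zs, nu, nz, byrow = TRUE)
  verts <- cbind(as.vector(x), as.vector(y), as.vector(z))
  idx <- matrix(seq_len(nu * nz), nu, nz)
  faces <- grid_faces(idx)
  surface_mesh(verts, faces,
               grid = list(index = idx, kind = "arc"),
               extra = list(cor = c(0, ycor, 0), params = params))
}

#' Primitive surfaces for bench tests
#'
#' Generates the simple geometries used by the pin-on-plate and material
#' calibration stages:
#' * `flat_plate`: a rectangular heightfield at y = 0
#'   (`dims = list(width, depth, grid)`, width along z, depth along x);
#' * `cylindrical_pin_face`: a flat disc meshed as a polar fan at y = 0
#'   (`dims = list(diameter, grid)`), representing the polyethylene pin end;
#' * `sphere`: the lower cap of a sphere centred at the origin
#'   (`dims = list(diameter, grid, extent)`), apex (lowest point) at
#'   y = -radius; used as the rigid calibration ball.
#'
#' @param kind one of `"flat_plate"`, `"cylindrical_pin_face"`, `"sphere"`.
#' @param dims named list of dimensions in mm (see above); `grid` defaults
#'   to 64.
#' @return a [surface_mesh()]; plates and spheres carry the structured `grid`
#'   descriptor required for use as the rigid counterface.
#' @export
make_primitive <- function(kind = c("flat_plate", "cylindrical_pin_face", "sphere"),
                           dims = list()) {
  kind <- match.arg(kind)
  g <- as.integer(dims$grid %||% 64L)
  if (kind == "flat_plate") {
    w <- dims$width %||% 40
    d <- dims$depth %||% w
    xs <- seq(-d / 2, d / 2, length.out = g)
    zs <- seq(-w / 2, w / 2, length.out = g)
    heightfield_mesh(xs, zs, matrix(0, g, g))
  } else if (kind == "cylindrical_pin_face") {
    dia <- dims$diameter %||% 5
    R <- dia / 2
    n_a <- g
    n_r <- max(4L, g %/% 4L)
    redges <- seq(0, R, length.out = n_r + 1L)
    ang <- seq(0, 2 * pi, length.out = n_a + 1L)[-(n_a + 1L)]
    rings <- lapply(redges[-1L], function(r) cbind(r * cos(ang), 0, r * sin(ang)))
    verts <- rbind(c(0, 0, 0), do.call(rbind, rings))
    id <- function(i, j) 1L + (i - 1L) * n_a + ((j - 1L) %% n_a) + 1L  # ring i, sector j
    faces <- matrix(0L, 0L, 3L)
    fan <- t(vapply(seq_len(n_a), function(j) c(1L, id(1L, j), id(1L, j + 1L)),
                    integer(3)))
    quads <- do.call(rbind, lapply(seq_len(n_r - 1L), function(i) {
      do.call(rbind, lapply(seq_len(n_a), function(j) {
        a <- id(i, j); b <- id(i, j + 1L); cc <- id(i + 1L, j); d <- id(i + 1L, j + 1L)
        rbind(c(a, cc, b), c(b, cc, d))
      }))
    }))
    faces <- rbind(fan[, c(1L, 3L, 2L)], quads)
    surface_mesh(verts, faces, extra = list(radius = R))
  } else {
    dia <- dims$diameter %||% 63.5
    R <- dia / 2
    ext <- dims$extent %||% (0.6 * R)   # half-width of the meshed cap footprint
    if (ext > R / sqrt(2)) stop("sphere cap extent too large for a heightfield")
    xs <- seq(-ext, ext, length.out = g)
    zs <- seq(-ext, ext, length.out = g)
    r2 <- outer(xs^2, zs^2, `+`)
    y <- -sqrt(R^2 - r2)
    heightfield_mesh(xs, zs, y, extra = list(radius = R, center = c(0, 0, 0)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a surface_mesh from a heightfield y[i, j] over xs (rows) x zs (cols)
heightfield_mesh <- function(xs, zs, y, extra = list()) {
  nx <- length(xs); nz <- length(zs)
  stopifnot(all(dim(y) == c(nx, nz)))
  verts <- cbind(rep(xs, times = nz), as.vector(y), rep(zs, each = nx))
  idx <- matrix(seq_len(nx * nz), nx, nz)
  surface_mesh(verts, grid_faces(idx),
               grid = list(index = idx, kind = "heightfield"),
               extra = extra)
}

grid_faces <- function(idx) {
  nx <- nrow(idx); nz <- ncol(idx)
  a <- idx[-nx, -nz]; b <- idx[-1L, -nz]; cc <- idx[-nx, -1L]; d <- idx[-1L, -1L]
  rbind(cbind(as.vector(a), as.vector(b), as.vector(cc)),
        cbind(as.vector(b), as.vector(d), as.vector(cc)))
}

#' Lowest points of the two insert dishes
#'
#' @param insert a mesh from [make_insert_surface()].
#' @return a 2 x 3 matrix: the lowest vertex of the lateral (z < 0) and
#'   medial (z > 0) dish.
#' @export
insert_low_points <- function(insert) {
  v <- insert$vertices
  lat <- v[v[, 3] < 0, , drop = FALSE]
  med <- v[v[, 3] >= 0, , drop = FALSE]
  rbind(lateral = lat[which.min(lat[, 2]), ],
        medial = med[which.min(med[, 2]), ])
}
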