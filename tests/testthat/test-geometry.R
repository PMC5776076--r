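test_that("insert dishes are symmetric with low points at the condyle spacing", {
  p <- small_params()
  ins <- make_insert_surface(p)
  low <- insert_low_points(ins)
  expect_equal(unname(low["lateral", 2]), unname(low["medial", 2]))
  expect_identical(abs(unname(low["lateral", 3])), abs(unname(low["medial", 3])))
  expect_equal(unname(low["medial", 3] - low["lateral", 3]), p$condyle_spacing)
  expect_identical(unname(low[, 1]), c(0, 0))
  # z -> -z mirror symmetry of the generated heightfield
  v <- ins$vertices
  key <- paste(signif(v[, 1], 12), signif(v[, 2], 12), signif(abs(v[, 3]), 12))
  expect_true(all(table(key) %in% c(1L, 2L)))   # midline vs mirrored pairs
})

test_that("vertex areas partition the mesh area exactly and generators are deterministic", {
  for (mesh in list(make_insert_surface(small_params()),
                    make_femoral_surface(small_params()),
                    make_primitive("sphere", list(diameter = 63.5, grid = 32)))) {
    expect_lt(abs(sum(mesh$vertex_area) - mesh_area(mesh)) / mesh_area(mesh), 1e-9)
    expect_true(all(abs(sqrt(rowSums(mesh$vertex_normal^2)) - 1) < 1e-9))
  }
  expect_identical(make_insert_surface(small_params()),
                   make_insert_surface(small_params()))
  expect_identical(make_femoral_surface(small_params()),
                   make_femoral_surface(small_params()))
})

test_that("insert surface area converges under grid refinement", {
  a32 <- mesh_area(make_insert_surface(small_params(32)))
  a128 <- mesh_area(make_insert_surface(small_params(128)))
  expect_lt(abs(a32 - a128) / a128, 0.01)
})

test_that("non-conforming radii are rejected with an explanatory error", {
  expect_error(implant_params(insert_dish_sagittal_radius = 20,
                              condyle_distal_radius = 30),
               "non-conforming")
  expect_error(implant_params(insert_thickness = 0), "positive")
})

test_that("femoral condyle cross-section through the condyle centre is a circle
           of the distal radius about the recorded flexion axis", {
  p <- small_params()
  fem <- make_femoral_surface(p)
  half <- p$condyle_spacing / 2
  sel <- abs(fem$vertices[, 3] - half) < 1e-12
  expect_gt(sum(sel), 10)
  r <- sqrt(fem$vertices[sel, 1]^2 + (fem$vertices[sel, 2] - fem$cor[2])^2)
  expect_equal(r, rep(p$condyle_distal_radius, sum(sel)), tolerance = 1e-12)
})

test_that("femoral component rests on the insert with zero gap at the two dish centres", {
  p <- small_params()
  fem <- make_femoral_surface(p)
  ins <- make_insert_surface(p)
  env <- tkrwear:::rigid_envelope(fem)
  gap <- env(ins$vertices[, 1], ins$vertices[, 3]) - ins$vertices[, 2]
  gap <- gap[!is.na(gap)]
  expect_gt(min(gap), -1e-6)                      # non-penetrating at rest
  low <- insert_low_points(ins)
  g_low <- env(low[, 1], low[, 3]) - low[, 2]
  expect_equal(unname(g_low), c(0, 0), tolerance = 1e-6)  # touching at both dishes
})

test_that("primitive surfaces have the constructed dimensions", {
  pin <- make_primitive("cylindrical_pin_face", list(diameter = 5, grid = 64))
  expect_lt(abs(mesh_area(pin) - pi * 2.5^2) / (pi * 2.5^2), 0.005)
  sph <- make_primitive("sphere", list(diameter = 63.5, grid = 33))
  expect_equal(min(sph$vertices[, 2]), -63.5 / 2)   # apex depth = radius
  plate <- make_primitive("flat_plate", list(width = 20, depth = 10, grid = 16))
  expect_true(all(abs(plate$vertex_normal[, 2] - 1) < 1e-12))  # planar, parallel normals
})

test_that("STL write/read round-trips in both dialects", {
  ins <- make_insert_surface(small_params(16))
  for (ascii in c(FALSE, TRUE)) {
    tmp <- withr::local_tempfile(fileext = ".stl")
    write_stl(ins, tmp, ascii = ascii)
    back <- read_stl(tmp)
    expect_identical(nrow(back$faces), nrow(ins$faces))
    # vertex sets match within single-precision storage error
    o1 <- order(ins$vertices[, 1], ins$vertices[, 2], ins$vertices[, 3])
    o2 <- order(back$vertices[, 1], back$vertices[, 2], back$vertices[, 3])
    expect_lt(max(abs(ins$vertices[o1, ] - back$vertices[o2, ])), 1e-5)
  }
})

test_that("STL reader handles a 2-triangle ASCII fixture and rejects empty files", {
  tmp <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid two",
               "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 0", "      vertex 1 0 0", "      vertex 0 1 0",
               "    endloop", "  endfacet",
               "  facet normal 0 0 1", "    outer loop",
               "      vertex 1 0 0", "      vertex 1 1 0", "      vertex 0 1 0",
               "    endloop", "  endfacet",
               "endsolid two"), tmp)
  m <- read_stl(tmp)
  expect_identical(nrow(m$faces), 2L)
  expect_identical(nrow(m$vertices), 4L)
  empty <- withr::local_tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_stl(empty), "empty")
  expect_error(read_stl(file.path(tempdir(), "does-not-exist.stl")), "no such file")
})

test_that("mesh summary reports counts, area and bounding box", {
  ins <- make_insert_surface(small_params(16))
  s <- mesh_summary(ins)
  expect_identical(s$n_vertices, nrow(ins$vertices))
  expect_equal(s$area_mm2, mesh_area(ins))
  tmp <- withr::local_tempfile(fileext = ".json")
  mesh_summary(ins, tmp)
  expect_identical(jsonlite::read_json(tmp)$n_faces, nrow(ins$faces))
})
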