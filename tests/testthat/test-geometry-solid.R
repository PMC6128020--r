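# Parametric vertebra construction: frustum, wedge cuts, tilts.

test_that("rotation solid reproduces closed-form volumes", {
  cyl <- build_rotation_solid(20, 15, 15)
  expect_equal(frustum_volume(cyl), pi * 15^2 * 20)
  expect_equal(mesh_volume(cyl), pi * 15^2 * 20, tolerance = 0.01)

  fru <- build_rotation_solid(20, 15, 10)
  expect_equal(frustum_volume(fru), pi * 20 / 3 * (15^2 + 15 * 10 + 10^2))
  expect_equal(mesh_volume(fru), frustum_volume(fru), tolerance = 0.01)
})

test_that("degenerate or invalid frustum parameters are rejected", {
  expect_error(build_rotation_solid(20, 15, 0), "parameter_error")
  expect_error(build_rotation_solid(-1, 15, 10), "parameter_error")
  expect_error(build_rotation_solid(20, 0, 10), "parameter_error")
})

test_that("solid meshes are watertight with a partitioned boundary", {
  for (s in list(build_rotation_solid(20, 15, 15),
                 apply_wedge(build_rotation_solid(20, 15, 10), 7,
                             "top", "coronal"))) {
    m <- solid_mesh(s)
    expect_true(all(tet_volumes(m$nodes, m$tets) > 0))
    bf <- vertefem:::boundary_faces(m$tets)
    tagged <- nrow(m$tags$top_face) + nrow(m$tags$bottom_face) +
      nrow(m$tags$lateral)
    expect_identical(nrow(bf), tagged)
    expect_gt(face_area(m, m$tags$top_face), 0)
    expect_gt(face_area(m, m$tags$bottom_face), 0)
  }
})

test_that("zero-angle wedge is the identity and cuts never add material", {
  cyl <- build_rotation_solid(20, 15, 15)
  expect_identical(apply_wedge(cyl, 0, "top", "coronal"), cyl)

  v0 <- mesh_volume(cyl)
  cut <- apply_wedge(cyl, 5, "top", "coronal")
  v1 <- mesh_volume(cut)
  expect_lt(v1, v0)
  # re-cutting with the original face plane removes nothing
  recut <- apply_wedge(cut, 1e-12, "top", "coronal")
  expect_equal(mesh_volume(recut), v1)
  # a second identical cut is idempotent
  again <- apply_wedge(cut, 5, "top", "coronal")
  expect_equal(mesh_volume(again), v1, tolerance = 1e-12)
})

test_that("wedge cut angles are recovered from the meshed faces", {
  for (ang in c(1, 2, 5, 10)) {
    cut <- apply_wedge(build_rotation_solid(20, 15, 15), ang,
                       "top", "coronal")
    expect_equal(face_dihedral(cut), ang, tolerance = 0.5)
  }
  # composition: top and bottom coronal wedges add up
  s <- apply_wedge(build_rotation_solid(25, 15, 15), 5, "top", "coronal")
  s <- apply_wedge(s, 3, "bottom", "coronal")
  expect_equal(face_dihedral(s), 8, tolerance = 0.5)
  # opposite-sign hinge: top +5 with bottom -3 tilts faces the same way
  s2 <- apply_wedge(build_rotation_solid(25, 15, 15), 5, "top", "coronal")
  s2 <- apply_wedge(s2, -3, "bottom", "coronal")
  expect_equal(face_dihedral(s2), 2, tolerance = 0.5)
})

test_that("overly aggressive wedge cuts raise a geometry error", {
  expect_error(apply_wedge(build_rotation_solid(10, 15, 15), 40,
                           "top", "coronal"),
               "geometry_error")
  expect_error(apply_wedge(build_rotation_solid(10, 15, 15), 50,
                           "top", "coronal"),
               "parameter_error")
})

test_that("tilting is rigid: volume exact, axis mapped as expected", {
  s <- apply_wedge(build_rotation_solid(20, 15, 12), 5, "top", "coronal")
  v0 <- mesh_volume(s)
  t1 <- apply_tilt(s, 10, -7)
  expect_equal(mesh_volume(t1), v0, tolerance = 1e-12)
  expect_identical(apply_tilt(s, 0, 0), s)

  # 90 deg about x maps the +z axis direction to -y
  cyl <- build_rotation_solid(20, 5, 5)
  t2 <- apply_tilt(cyl, 90, 0)
  m <- solid_mesh(t2)
  fr_top <- vertefem:::face_frame(m, m$tags$top_face)
  fr_bot <- vertefem:::face_frame(m, m$tags$bottom_face)
  axis <- fr_top$centroid - fr_bot$centroid
  expect_equal(axis / sqrt(sum(axis^2)), c(0, -1, 0), tolerance = 1e-9)
})

test_that("build_vertebra composes the stages", {
  p0 <- vertebra_params(20, 15, 12)
  plain <- build_vertebra(p0)
  expect_equal(mesh_volume(plain), frustum_volume(plain), tolerance = 0.01)

  p1 <- vertebra_params(20, 15, 12, wedge_top_cor_deg = 5)
  expect_equal(face_dihedral(build_vertebra(p1)), 5, tolerance = 0.5)

  # placement: centroid lands on center_mm
  p2 <- vertebra_params(20, 15, 12, wedge_top_cor_deg = 5, tilt_y_deg = 4,
                        center_mm = c(3, -2, 40))
  m2 <- as_mesh(build_vertebra(p2))
  expect_equal(vertefem:::mesh_centroid(m2), c(3, -2, 40), tolerance = 1e-6)
})

test_that("mirroring parameters across the sagittal plane mirrors the solid", {
  p <- vertebra_params(20, 15, 12, wedge_top_cor_deg = 8,
                       wedge_bot_cor_deg = 3, wedge_top_sag_deg = -4,
                       tilt_y_deg = 6)
  pm <- vertebra_params(20, 15, 12, wedge_top_cor_deg = -8,
                        wedge_bot_cor_deg = -3, wedge_top_sag_deg = -4,
                        tilt_y_deg = -6)
  m <- as_mesh(build_vertebra(p))
  mm <- as_mesh(build_vertebra(pm))
  # tilt pivots on the discrete centroid, whose tetrahedral decomposition is
  # not mirror-symmetric, so agreement is to mesh tolerance, not FP epsilon
  expect_equal(mesh_volume(m), mesh_volume(mm), tolerance = 1e-5)
  refl <- mm$nodes %*% diag(c(-1, 1, 1))
  ord <- function(x) x[order(round(x[, 1], 3), round(x[, 2], 3),
                             round(x[, 3], 3)), ]
  expect_equal(ord(m$nodes), ord(refl), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("vertebra_params validates its invariants", {
  expect_error(vertebra_params(0, 15, 15), "parameter_error")
  expect_error(vertebra_params(20, 15, 15, wedge_top_cor_deg = 45),
               "parameter_error")
  expect_silent(vertebra_params(20, 15, 15, wedge_top_cor_deg = 44.9))
})
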