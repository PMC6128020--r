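# Segment assembly, discs, quadrants, shear patches.

test_that("straight stack assembles to the expected extent and labels", {
  sp <- straight_spine()
  m <- sp$mesh
  expect_equal(range(m$nodes[, 3]), c(0, 3 * 20 + 2 * 5))
  expect_identical(sort(unique(m$domain)), 1:5)
  expect_true(all(vertefem:::tet_volumes(m$nodes, m$tets) > 0))
  # conforming single connected mesh: every node is used
  expect_identical(length(unique(as.vector(m$tets))), nrow(m$nodes))
  v <- sum(vertefem:::tet_volumes(m$nodes, m$tets))
  expect_equal(v, 3 * pi * 225 * 20 + 2 * pi * 225 * 5, tolerance = 0.01)
})

test_that("invalid disc gaps are rejected", {
  vp <- vertebra_params(20, 15, 15)
  expect_error(assemble_spine(vp, vp, vp, c(-1, 5)), "parameter_error")
  expect_error(assemble_spine(vp, vp, vp, c(0, 5)), "parameter_error")
})

test_that("synthetic scoliotic patients assemble into valid meshes", {
  row <- scoliotic_patient()
  sp <- assemble_spine(row$lower[[1]], row$apex[[1]], row$upper[[1]],
                       row$disc_gaps_mm[[1]])
  m <- sp$mesh
  expect_true(all(vertefem:::tet_volumes(m$nodes, m$tets) > 0))
  expect_identical(sort(unique(m$domain)), 1:5)
  # tagged faces have positive area and the boundary is closed
  for (tag in c("bottom_face", "top_face", "apex_top")) {
    expect_gt(face_area(m, sp$tags[[tag]]), 0)
  }
  bf <- vertefem:::boundary_faces(m$tets)
  expect_gt(nrow(bf), 0)
})

test_that("disc loft reproduces closed-form volumes", {
  g <- disc_grid(6)
  cyl <- build_disc(circle_face(12, 0, g), circle_face(12, 5, g))
  expect_equal(sum(vertefem:::tet_volumes(cyl$nodes, cyl$tets)),
               pi * 144 * 5, tolerance = 0.01)
  fru <- build_disc(circle_face(12, 0, g), circle_face(10, 5, g))
  expect_equal(sum(vertefem:::tet_volumes(fru$nodes, fru$tets)),
               pi * 5 / 3 * (144 + 120 + 100), tolerance = 0.01)
  # tilted upper face: volume equals mean gap x base area
  tilted <- build_disc(circle_face(12, 0, g),
                       circle_face(12, 5, g, tilt_y_deg = 5))
  base <- sum(vertefem:::triangle_areas(cbind(12 * g$uv, 0), g$tri))
  expect_equal(sum(vertefem:::tet_volumes(tilted$nodes, tilted$tets)),
               base * 5, tolerance = 0.01)
  expect_error(build_disc(circle_face(12, 0, g), circle_face(12, 0, g)),
               "geometry_error")
})

test_that("quadrant subdivision is a partition with near-equal areas", {
  sp <- top_face_quadrants(straight_spine(), 0)
  m <- sp$mesh
  qa <- vapply(sp$tags$quadrants, function(q) face_area(m, q), numeric(1))
  top_area <- face_area(m, sp$tags$top_face)
  expect_equal(sum(qa), top_area, tolerance = 1e-12)
  expect_equal(unname(qa), rep(top_area / 4, 4), tolerance = 0.05)
  # disjoint triangle sets
  all_rows <- do.call(rbind, sp$tags$quadrants)
  expect_identical(nrow(all_rows), nrow(sp$tags$top_face))
  expect_false(any(duplicated(all_rows)))
})

test_that("quadrant partition holds for arbitrary sacrum angles", {
  sp0 <- straight_spine()
  top_area <- face_area(sp0$mesh, sp0$tags$top_face)
  set.seed(42)
  for (ang in stats::runif(20, -180, 180)) {
    sp <- top_face_quadrants(sp0, ang)
    qa <- vapply(sp$tags$quadrants, function(q) face_area(sp$mesh, q),
                 numeric(1))
    expect_equal(sum(qa), top_area, tolerance = 1e-12)
    expect_identical(nrow(do.call(rbind, sp$tags$quadrants)),
                     nrow(sp$tags$top_face))
  }
})

test_that("shear patches are disjoint, mirror-symmetric and sized right", {
  vp <- vertebra_params(20, 15, 15)
  sp <- assemble_spine(vp, vp, vp, c(5, 5), size = 1.5)
  sp <- lateral_shear_patches(sp, 5, 0.5)
  aL <- face_area(sp$mesh, sp$tags$shear_left)
  aR <- face_area(sp$mesh, sp$tags$shear_right)
  # geodesic disc of radius 5 on a developable cylinder has area pi 5^2
  expect_equal(aL, pi * 25, tolerance = 0.05)
  expect_equal(aR, pi * 25, tolerance = 0.05)
  both <- rbind(sp$tags$shear_left, sp$tags$shear_right)
  expect_false(any(duplicated(both)))
  cL <- colMeans(vertefem:::triangle_centroids(sp$mesh$nodes,
                                               sp$tags$shear_left))
  cR <- colMeans(vertefem:::triangle_centroids(sp$mesh$nodes,
                                               sp$tags$shear_right))
  expect_equal(cL * c(-1, 1, 1), cR, tolerance = 0.05)
})

test_that("ill-fitting shear patches raise geometry errors", {
  sp <- straight_spine()
  expect_error(lateral_shear_patches(sp, 15, 0.5), "geometry_error")
  expect_error(lateral_shear_patches(sp, 5, 0.1), "geometry_error")
})
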