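# Linear-elastic solver: patch test, uniaxial benchmark, energy formulas.

test_that("affine displacement fields reproduce constant stress exactly", {
  m <- solid_mesh(build_rotation_solid(10, 5, 5), n_rings = 2, n_layers = 2)
  C <- unclass(iso_bone())
  asm <- fem_assemble(m, C)
  A <- matrix(c(1e-3, 2e-4, 0, 0, -5e-4, 3e-4, 1e-4, 0, -2e-3), 3, 3,
              byrow = TRUE)
  uex <- as.vector(t(m$nodes %*% t(A)))
  bnodes <- unique(as.vector(rbind(m$tags$top_face, m$tags$bottom_face,
                                   m$tags$lateral)))
  bdofs <- as.vector(outer(1:3, 3 * (bnodes - 1), `+`))
  free <- setdiff(seq_len(3 * nrow(m$nodes)), bdofs)
  u <- numeric(length(uex))
  u[bdofs] <- uex[bdofs]
  u[free] <- as.vector(Matrix::solve(asm$K[free, free],
                                     -(asm$K[free, bdofs] %*% uex[bdofs])))
  expect_equal(u, uex, tolerance = 1e-10)
  pp <- vertefem:::fem_postprocess(m, C, asm$grads,
                                   matrix(u, ncol = 3, byrow = TRUE))
  eps <- c(A[1, 1], A[2, 2], A[3, 3], A[2, 3] + A[3, 2],
           A[1, 3] + A[3, 1], A[1, 2] + A[2, 1])
  sig_exact <- as.vector(C %*% eps)
  for (p in 1:6) {
    expect_equal(pp$stress[, p], rep(sig_exact[p], nrow(pp$stress)),
                 tolerance = 1e-9)
  }
})

test_that("uniaxial compression gives unit von Mises and the closed-form
           distortion energy in the interior", {
  m <- solid_mesh(build_rotation_solid(20, 15, 15))
  sol <- fem_solve(m, iso_bone(), m$tags$bottom_face,
                   list(list(list(tri = m$tags$top_face,
                                  traction = c(0, 0, -1)))))[[1]]
  expect_lt(sol$residual, 1e-8)
  ctr <- element_centroids(m)
  interior <- ctr[, 3] > 8 & ctr[, 3] < 18
  expect_equal(mean(sol$von_mises[interior]), 1, tolerance = 0.05)
  ud_exact <- (1 + 0.25) / (3 * 3500)
  expect_equal(mean(sol$energy_density[interior]), ud_exact,
               tolerance = 0.05)
})

test_that("solutions scale linearly with the load", {
  m <- solid_mesh(build_rotation_solid(20, 15, 15), n_rings = 3,
                  n_layers = 3)
  case <- function(p) list(list(tri = m$tags$top_face,
                                traction = c(0, 0, -p)))
  sols <- fem_solve(m, iso_bone(), m$tags$bottom_face,
                    list(case(1), case(2)))
  expect_equal(sols[[2]]$U, 2 * sols[[1]]$U, tolerance = 1e-10)
  expect_equal(sols[[2]]$energy_density, 4 * sols[[1]]$energy_density,
               tolerance = 1e-8)
})

test_that("reaction forces balance the applied tractions", {
  m <- solid_mesh(build_rotation_solid(20, 15, 12))
  C <- iso_bone()
  patches <- list(list(tri = m$tags$top_face, traction = c(0.2, 0, -1)))
  sol <- fem_solve(m, C, m$tags$bottom_face, list(patches))[[1]]
  asm <- fem_assemble(m, unclass(C))
  F <- vertefem:::traction_forces(m, patches)
  R <- as.vector(asm$K %*% as.vector(t(sol$U))) - F
  Rm <- matrix(R, ncol = 3, byrow = TRUE)
  fixed <- unique(as.vector(m$tags$bottom_face))
  applied <- colSums(matrix(F, ncol = 3, byrow = TRUE))
  expect_equal(colSums(Rm[fixed, ]), -applied, tolerance = 0.01 *
                 sqrt(sum(applied^2)))
})

test_that("distortion energy density has the expected closed forms", {
  E <- 3500; nu <- 0.25; G <- E / (2 * (1 + nu))
  C <- unclass(isotropic_stiffness(isotropic_material(E, nu)))
  S <- solve(C)
  # hydrostatic state: deviator vanishes
  sig_h <- matrix(c(5, 5, 5, 0, 0, 0), 1)
  eps_h <- sig_h %*% t(S)
  expect_equal(distortion_energy_density(sig_h, eps_h), 0)
  # pure shear tau: U_d = tau^2 / (2 G)
  tau <- 0.7
  sig_s <- matrix(c(0, 0, 0, tau, 0, 0), 1)
  eps_s <- sig_s %*% t(S)
  expect_equal(distortion_energy_density(sig_s, eps_s), tau^2 / (2 * G),
               tolerance = 1e-12)
  # random stress states match the von Mises form for isotropic material
  set.seed(7)
  sig <- matrix(rnorm(600), 100, 6)
  eps <- sig %*% t(S)
  expect_equal(distortion_energy_density(sig, eps),
               (1 + nu) * von_mises_stress(sig)^2 / (3 * E),
               tolerance = 1e-10)
})

test_that("orthotropic tensor in the isotropy limit reproduces the
           isotropic displacement field", {
  row <- scoliotic_patient()
  sp <- assemble_spine(row$lower[[1]], row$apex[[1]], row$upper[[1]],
                       row$disc_gaps_mm[[1]], size = 4)
  sp <- top_face_quadrants(sp, row$sacrum_angle_deg)
  E <- 3500; nu <- 0.25; G <- E / (2 * (1 + nu))
  mats_iso <- list(bone_isotropic = isotropic_material(E, nu),
                   disc = isotropic_material(252, 0.47))
  mats_ort <- list(bone_orthotropic = orthotropic_material(E, E, E, G, G, G,
                                                           nu, nu, nu),
                   disc = isotropic_material(252, 0.47))
  st_iso <- vertefem:::spine_stiffness(sp, mats_iso, "isotropic")
  st_ort <- vertefem:::spine_stiffness(sp, mats_ort, "orthotropic")
  states <- enumerate_load_states(1, 0.5)[1, ]
  sol_iso <- solve_load_states(sp, st_iso, states)$solutions[[1]]
  sol_ort <- solve_load_states(sp, st_ort, states)$solutions[[1]]
  rel <- max(abs(sol_ort$U - sol_iso$U)) / max(abs(sol_iso$U))
  expect_lt(rel, 1e-6)
})

test_that("strain energy converges under uniform refinement", {
  s <- build_rotation_solid(20, 15, 15)
  energies <- vapply(list(c(3L, 3L), c(5L, 5L), c(7L, 7L)), function(nn) {
    m <- solid_mesh(s, n_rings = nn[1], n_layers = nn[2])
    sol <- fem_solve(m, iso_bone(), m$tags$bottom_face,
                     list(list(list(tri = m$tags$top_face,
                                    traction = c(0, 0, -1)))))[[1]]
    F <- vertefem:::traction_forces(m, list(list(tri = m$tags$top_face,
                                                 traction = c(0, 0, -1))))
    0.5 * sum(F * as.vector(t(sol$U))) # external work = strain energy
  }, numeric(1))
  # softening monotonically towards the continuum limit, Cauchy-converging
  expect_true(all(diff(energies) > 0))
  expect_lt(abs(energies[3] - energies[2]), abs(energies[2] - energies[1]))
})

test_that("void constraints are rejected", {
  m <- solid_mesh(build_rotation_solid(10, 5, 5), n_rings = 2, n_layers = 2)
  expect_error(fem_solve(m, iso_bone(), matrix(integer(0), 0, 3),
                         list(list(list(tri = m$tags$top_face,
                                        traction = c(0, 0, -1))))),
               "constraint_error")
})
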