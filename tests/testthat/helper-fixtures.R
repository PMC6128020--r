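# Shared fixtures, built once per test run.

# memoise expensive fixtures within one session
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# straight stack of three identical cylinders, gaps 5 mm
straight_spine <- function() fixture("straight_spine", {
  vp <- vertebra_params(20, 15, 15)
  assemble_spine(vp, vp, vp, c(5, 5))
})

# one synthetic scoliotic patient (reference cohort, patient 1)
scoliotic_patient <- function() fixture("scoliotic_patient", {
  generate_cohort(cohort_spec())[1, ]
})

iso_bone <- function() isotropic_stiffness(isotropic_material(3500, 0.25))

# brute-force focus oracle: centroid of the argmax-connected component,
# independent of the package implementation (direct grid walk)
brute_focus <- function(x, y, values, tol = 0.02) {
  vmax <- max(values, na.rm = TRUE)
  sel <- !is.na(values) & values >= (1 - tol) * vmax
  at <- which(values == vmax, arr.ind = TRUE)[1, ]
  # flood fill from the argmax over the 8-neighbourhood
  nr <- nrow(sel); nc <- ncol(sel)
  inc <- matrix(FALSE, nr, nc)
  queue <- list(at)
  inc[at[1], at[2]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (di in -1:1) for (dj in -1:1) {
      i <- p[1] + di; j <- p[2] + dj
      if (i >= 1 && i <= nr && j >= 1 && j <= nc && sel[i, j] && !inc[i, j]) {
        inc[i, j] <- TRUE
        queue[[length(queue) + 1]] <- c(i, j)
      }
    }
  }
  xs <- matrix(x, nr, nc)
  ys <- matrix(y, nr, nc, byrow = TRUE)
  c(mean(xs[inc]), mean(ys[inc]))
}

# gaussian bump field on a disc section
bump_field <- function(cx, cy, sigma = 2, radius = 12, n = 61,
                       second = NULL) {
  g <- seq(-radius, radius, length.out = n)
  xs <- matrix(g, n, n)
  ys <- matrix(g, n, n, byrow = TRUE)
  v <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
  if (!is.null(second)) {
    v <- pmax(v, exp(-((xs - second[1])^2 + (ys - second[2])^2) /
                       (2 * sigma^2)))
  }
  v[xs^2 + ys^2 > radius^2] <- NA
  planar_field(g, g, v)
}

element_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
     mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
}
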