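# Small-strain linear elasticity on labelled tetrahedral meshes.
#
# Linear (P1) tetrahedra with element-wise constant strain/stress; stiffness
# assembly is vectorised over elements.  Displacements are fixed to zero on
# the constrained patches; tractions enter as constant surface loads
# distributed to the patch-triangle nodes.  The reduced system is solved by
# sparse Cholesky factorisation (Matrix), reusing the factor across the
# load-states of one model.

# Selection tensor T[p, a, c]: strain component p receives u_{a} * grad_c
# (Voigt order xx, yy, zz, yz, xz, xy; engineering shear).
strain_selector <- function() {
  T <- array(0, c(6L, 3L, 3L))
  T[1L, 1L, 1L] <- 1
  T[2L, 2L, 2L] <- 1
  T[3L, 3L, 3L] <- 1
  T[4L, 2L, 3L] <- T[4L, 3L, 2L] <- 1
  T[5L, 1L, 3L] <- T[5L, 3L, 1L] <- 1
  T[6L, 1L, 2L] <- T[6L, 2L, 1L] <- 1
  T
}

# Per-element shape-function gradients and volumes, vectorised.
# Returns list(G = list of four m x 3 gradient matrices, V = volumes).
element_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3L], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4L], , drop = FALSE] - p1
  det <- e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
    e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
    e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])
  # columns of inv(M) for M with rows e1,e2,e3: grad(lambda_{k+1}) = inv(M)[,k]
  inv <- list()
  cof <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  # inv(M) = [e2 x e3, e3 x e1, e1 x e2] / det (as columns)
  g2 <- cof(e2, e3) / det
  g3 <- cof(e3, e1) / det
  g4 <- cof(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  list(G = list(g1, g2, g3, g4), V = det / 6)
}

# 3x3 coefficient matrices M_ab with block K_ij[a,b] = V * g_i' M_ab g_j.
mab_matrices <- function(C) {
  T <- strain_selector()
  M <- vector("list", 9L)
  for (a in 1:3) for (b in 1:3) {
    m <- matrix(0, 3L, 3L)
    for (p in 1:6) for (q in 1:6) {
      if (C[p, q] == 0) next
      m <- m + C[p, q] * tcrossprod(T[p, a, ], T[q, b, ])
    }
    M[[(a - 1L) * 3L + b]] <- m
  }
  M
}

#' Assemble the global elastic stiffness matrix
#'
#' @param mesh A labelled tetrahedral mesh (`nodes`, `tets`, optional
#'   per-element `domain` + `domains`).
#' @param stiffness Either a single 6x6 stiffness matrix or a named list of
#'   matrices, one per domain label.
#' @return A list with `K` (sparse symmetric 3n x 3n, MPa/mm), `grads`
#'   (element gradients, reused for stress recovery).
#' @export
fem_assemble <- function(mesh, stiffness) {
  nodes <- mesh$nodes; tets <- mesh$tets
  m <- nrow(tets); n <- nrow(nodes)
  eg <- element_gradients(nodes, tets)
  if (any(eg$V <= 0)) {
    stop("vertefem_geometry_error: mesh contains inverted tetrahedra",
         call. = FALSE)
  }
  if (is.matrix(stiffness)) {
    groups <- list(seq_len(m))
    Cs <- list(unclass(stiffness))
  } else {
    stopifnot(!is.null(mesh$domain))
    labs <- mesh$domains[mesh$domain]
    groups <- split(seq_len(m), labs)
    Cs <- lapply(names(groups), function(nm) unclass(stiffness[[nm]]))
  }
  ii <- vector("list", length(groups) * 144L)
  jj <- ii; xx <- ii
  slot <- 0L
  for (gidx in seq_along(groups)) {
    idx <- groups[[gidx]]
    M <- mab_matrices(Cs[[gidx]])
    V <- eg$V[idx]
    G <- lapply(eg$G, function(g) g[idx, , drop = FALSE])
    Tt <- tets[idx, , drop = FALSE]
    for (i in 1:4) for (j in 1:4) for (a in 1:3) for (b in 1:3) {
      vals <- V * rowSums((G[[i]] %*% M[[(a - 1L) * 3L + b]]) * G[[j]])
      slot <- slot + 1L
      ii[[slot]] <- 3L * (Tt[, i] - 1L) + a
      jj[[slot]] <- 3L * (Tt[, j] - 1L) + b
      xx[[slot]] <- vals
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3L * n, 3L * n))
  list(K = K, grads = eg)
}

# Nodal force vector from constant tractions on tagged triangles.
# `patches` is a list of lists(tri = k x 3 matrix, traction = 3-vector or
# k x 3 matrix of per-triangle tractions in MPa).
traction_forces <- function(mesh, patches) {
  F <- numeric(3L * nrow(mesh$nodes))
  for (p in patches) {
    tri <- p$tri
    if (nrow(tri) == 0L) next
    ar <- triangle_areas(mesh$nodes, tri)
    tr <- p$traction
    if (is.null(dim(tr))) tr <- matrix(tr, nrow(tri), 3L, byrow = TRUE)
    for (a in 1:3) {
      idx <- 3L * (as.vector(tri) - 1L) + a         # column-stacked corners
      contrib <- rep(ar / 3 * tr[, a], times = 3L)
      agg <- rowsum(contrib, idx)                   # indices may repeat
      at <- as.integer(rownames(agg))
      F[at] <- F[at] + agg[, 1L]
    }
  }
  F
}

#' Solve linear elasticity under one or more load-states
#'
#' Fixes all displacement components on the constrained patches, assembles
#' the traction loads of each state and solves the reduced sparse system.
#' The Cholesky factor is computed once and reused across states.
#'
#' @param mesh A labelled mesh (typically `spine$mesh`).
#' @param stiffness Per-domain stiffness list or a single matrix.
#' @param fixed_tri Triangle matrix (or list of them) whose nodes are fully
#'   constrained.
#' @param load_patches A list of load cases; each case is a list of patches
#'   (`tri`, `traction`) as in `traction_forces`.
#' @return A list of `fem_solution` objects (one per load case): each has
#'   `U` (n x 3 nodal displacements, mm), `strain`, `stress` (m x 6 Voigt,
#'   element-wise), `von_mises`, `energy_density` (MPa), `residual`.
#' @export
fem_solve <- function(mesh, stiffness, fixed_tri, load_patches) {
  if (is.list(fixed_tri) && !is.matrix(fixed_tri)) {
    fixed_tri <- do.call(rbind, fixed_tri)
  }
  if (is.null(fixed_tri) || nrow(fixed_tri) == 0L) {
    stop("vertefem_constraint_error: load-state has no fixed patch ",
         "(Dirichlet constraints are required for solvability)", call. = FALSE)
  }
  n <- nrow(mesh$nodes)
  asm <- fem_assemble(mesh, stiffness)
  fixed_nodes <- unique(as.vector(fixed_tri))
  fixed_dofs <- as.vector(outer(1:3, 3L * (fixed_nodes - 1L), `+`))
  free <- setdiff(seq_len(3L * n), fixed_dofs)
  Kff <- asm$K[free, free, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
  Fmat <- vapply(load_patches, function(lp) traction_forces(mesh, lp),
                 numeric(3L * n))
  if (all(abs(Fmat) == 0)) {
    stop("vertefem_constraint_error: all load cases are void", call. = FALSE)
  }
  Uf <- as.matrix(Matrix::solve(ch, Fmat[free, , drop = FALSE]))
  lapply(seq_along(load_patches), function(s) {
    u <- numeric(3L * n)
    u[free] <- Uf[, s]
    res <- sqrt(sum((asm$K %*% u - Fmat[, s])[free]^2)) /
      max(sqrt(sum(Fmat[free, s]^2)), .Machine$double.eps)
    U <- matrix(u, ncol = 3L, byrow = TRUE)
    post <- fem_postprocess(mesh, stiffness, asm$grads, U)
    structure(c(list(U = U, residual = res), post), class = "fem_solution")
  })
}

# Element-wise strain, stress, von Mises and distortion-energy density.
fem_postprocess <- function(mesh, stiffness, grads, U) {
  tets <- mesh$tets
  m <- nrow(tets)
  eps <- matrix(0, m, 6L)
  for (i in 1:4) {
    Ui <- U[tets[, i], , drop = FALSE]
    Gi <- grads$G[[i]]
    eps[, 1L] <- eps[, 1L] + Gi[, 1L] * Ui[, 1L]
    eps[, 2L] <- eps[, 2L] + Gi[, 2L] * Ui[, 2L]
    eps[, 3L] <- eps[, 3L] + Gi[, 3L] * Ui[, 3L]
    eps[, 4L] <- eps[, 4L] + Gi[, 3L] * Ui[, 2L] + Gi[, 2L] * Ui[, 3L]
    eps[, 5L] <- eps[, 5L] + Gi[, 3L] * Ui[, 1L] + Gi[, 1L] * Ui[, 3L]
    eps[, 6L] <- eps[, 6L] + Gi[, 2L] * Ui[, 1L] + Gi[, 1L] * Ui[, 2L]
  }
  sig <- matrix(0, m, 6L)
  if (is.matrix(stiffness)) {
    sig <- eps %*% t(unclass(stiffness))
  } else {
    labs <- mesh$domains[mesh$domain]
    for (nm in unique(labs)) {
      idx <- labs == nm
      sig[idx, ] <- eps[idx, , drop = FALSE] %*% t(unclass(stiffness[[nm]]))
    }
  }
  list(strain = eps, stress = sig,
       von_mises = von_mises_stress(sig),
       energy_density = distortion_energy_density(sig, eps))
}

#' Von Mises equivalent stress from Voigt stress components
#'
#' @param stress m x 6 matrix (xx, yy, zz, yz, xz, xy), MPa.
#' @return Vector of equivalent stresses, MPa.
#' @export
von_mises_stress <- function(stress) {
  s <- stress
  sqrt(0.5 * ((s[, 1L] - s[, 2L])^2 + (s[, 2L] - s[, 3L])^2 +
                (s[, 3L] - s[, 1L])^2) +
         3 * (s[, 4L]^2 + s[, 5L]^2 + s[, 6L]^2))
}

#' Distortion-energy density
#'
#' The deviatoric elastic strain-energy density `U_d = 1/2 s_dev : e_dev`
#' (MPa = MJ/m^3).  For isotropic materials this equals the classical
#' von-Mises form `(1 + nu) sigma_vM^2 / (3 E)`; the deviatoric product
#' extends it consistently to orthotropic materials.
#'
#' @param stress,strain m x 6 Voigt matrices (engineering shear strains).
#' @return Non-negative vector, MPa.
#' @export
distortion_energy_density <- function(stress, strain) {
  stopifnot(is.matrix(stress), is.matrix(strain),
            ncol(stress) == 6L, ncol(strain) == 6L,
            nrow(stress) == nrow(strain))
  pm <- (stress[, 1L] + stress[, 2L] + stress[, 3L]) / 3
  em <- (strain[, 1L] + strain[, 2L] + strain[, 3L]) / 3
  u <- 0.5 * ((stress[, 1L] - pm) * (strain[, 1L] - em) +
                (stress[, 2L] - pm) * (strain[, 2L] - em) +
                (stress[, 3L] - pm) * (strain[, 3L] - em) +
                stress[, 4L] * strain[, 4L] +
                stress[, 5L] * strain[, 5L] +
                stress[, 6L] * strain[, 6L])
  pmax(u, 0)
}

#' @export
print.fem_solution <- function(x, ...) {
  cat("<fem_solution> max |u| =", format(max(abs(x$U))),
      "mm; max von Mises =", format(max(x$von_mises)),
      "MPa; residual =", format(x$residual), "\n")
  invisible(x)
}
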