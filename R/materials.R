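# Elasticity tensors in Voigt notation.
#
# Component order is fixed package-wide to (xx, yy, zz, yz, xz, xy) with
# engineering shear strains (gamma = 2 eps).  With that convention the
# stiffness matrix maps engineering strain to stress without extra factors;
# the classical 1/2 factors of the tensorial-to-engineering map are absorbed
# into the strain vector.

#' Isotropic linear-elastic material
#'
#' @param E Young modulus, MPa (> 0).
#' @param nu Poisson ratio, in (-1, 0.5).
#' @param rho Density, kg/m^3 (> 0); used only when self-weight loads are
#'   enabled.
#' @return An `isotropic_material` list.
#' @export
isotropic_material <- function(E, nu, rho = 1000) {
  stopifnot(is.finite(E), is.finite(nu), is.finite(rho))
  if (E <= 0 || rho <= 0) {
    stop("vertefem_parameter_error: E and rho must be > 0", call. = FALSE)
  }
  if (nu <= -1 || nu >= 0.5) {
    stop("vertefem_incompressibility_error: Poisson ratio must lie in ",
         "(-1, 0.5)", call. = FALSE)
  }
  structure(list(E = E, nu = nu, rho = rho), class = "isotropic_material")
}

#' Orthotropic linear-elastic material (engineering constants)
#'
#' @param Yxx,Yyy,Yzz Axial Young moduli, MPa.
#' @param Gxy,Gyz,Gxz Shear moduli, MPa.
#' @param nu_xy,nu_yz,nu_zx Poisson ratios (subscript order as usual:
#'   `nu_ij` couples a stress along i to strain along j; reciprocal ratios
#'   follow from symmetry of the compliance).
#' @param rho Density, kg/m^3.
#' @return An `orthotropic_material` list.
#' @export
orthotropic_material <- function(Yxx, Yyy, Yzz, Gxy, Gyz, Gxz,
                                 nu_xy, nu_yz, nu_zx, rho = 1000) {
  vals <- c(Yxx, Yyy, Yzz, Gxy, Gyz, Gxz, rho)
  stopifnot(all(is.finite(c(vals, nu_xy, nu_yz, nu_zx))))
  if (any(vals <= 0)) {
    stop("vertefem_parameter_error: moduli and density must be > 0",
         call. = FALSE)
  }
  structure(list(Yxx = Yxx, Yyy = Yyy, Yzz = Yzz, Gxy = Gxy, Gyz = Gyz,
                 Gxz = Gxz, nu_xy = nu_xy, nu_yz = nu_yz, nu_zx = nu_zx,
                 rho = rho),
            class = "orthotropic_material")
}

new_stiffness <- function(C) {
  structure(C, class = c("stiffness_tensor", "matrix"))
}

check_spd <- function(C, context) {
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C))) {
    stop("vertefem_consistency_error: ", context,
         " produced a non-symmetric stiffness matrix", call. = FALSE)
  }
  ev <- eigen(0.5 * (C + t(C)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("vertefem_consistency_error: ", context, " violates thermodynamic ",
         "stability (stiffness eigenvalue ", format(min(ev)), " <= 0)",
         call. = FALSE)
  }
  invisible(ev)
}

#' Stiffness matrix of an isotropic material (Lamé construction)
#'
#' @param mat An [isotropic_material()].
#' @return 6x6 `stiffness_tensor` in MPa, Voigt order (xx, yy, zz, yz, xz, xy).
#' @export
isotropic_stiffness <- function(mat) {
  stopifnot(inherits(mat, "isotropic_material"))
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- mat$E / (2 * (1 + mat$nu))
  C <- diag(c(rep(2 * mu, 3L), rep(mu, 3L)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lam
  C <- new_stiffness(C)
  check_spd(C, "isotropic construction")
  C
}

#' Stiffness matrix of an orthotropic material
#'
#' Assembles the 6x6 compliance from engineering constants (reciprocal
#' relations `nu_ji = nu_ij * Yj / Yi` are implied by compliance symmetry)
#' and inverts it.  Positive definiteness is checked, not assumed; a
#' violation names the condition.
#'
#' @param mat An [orthotropic_material()].
#' @return 6x6 `stiffness_tensor` in MPa.
#' @export
orthotropic_stiffness <- function(mat) {
  stopifnot(inherits(mat, "orthotropic_material"))
  S <- matrix(0, 6L, 6L)
  diag(S) <- c(1 / mat$Yxx, 1 / mat$Yyy, 1 / mat$Yzz,
               1 / mat$Gyz, 1 / mat$Gxz, 1 / mat$Gxy)
  S[1L, 2L] <- S[2L, 1L] <- -mat$nu_xy / mat$Yxx
  S[2L, 3L] <- S[3L, 2L] <- -mat$nu_yz / mat$Yyy
  S[1L, 3L] <- S[3L, 1L] <- -mat$nu_zx / mat$Yzz
  C <- tryCatch(solve(S), error = function(e) {
    stop("vertefem_consistency_error: compliance matrix is singular",
         call. = FALSE)
  })
  C <- new_stiffness(0.5 * (C + t(C)))
  check_spd(C, "orthotropic construction")
  C
}

# Voigt pair map for our component order
VOIGT_PAIRS <- matrix(c(1L, 1L, 2L, 2L, 3L, 3L, 2L, 3L, 1L, 3L, 1L, 2L),
                      ncol = 2L, byrow = TRUE)

voigt_to_tensor <- function(C) {
  A <- array(0, c(3L, 3L, 3L, 3L))
  for (p in 1:6) for (q in 1:6) {
    i <- VOIGT_PAIRS[p, 1L]; j <- VOIGT_PAIRS[p, 2L]
    k <- VOIGT_PAIRS[q, 1L]; l <- VOIGT_PAIRS[q, 2L]
    A[i, j, k, l] <- A[j, i, k, l] <- A[i, j, l, k] <- A[j, i, l, k] <- C[p, q]
  }
  A
}

tensor_to_voigt <- function(A) {
  C <- matrix(0, 6L, 6L)
  for (p in 1:6) for (q in 1:6) {
    C[p, q] <- A[VOIGT_PAIRS[p, 1L], VOIGT_PAIRS[p, 2L],
                 VOIGT_PAIRS[q, 1L], VOIGT_PAIRS[q, 2L]]
  }
  C
}

#' Rotate a stiffness tensor by the vertebral tilt
#'
#' Applies the rigid rotation (about x by `tilt_x_deg`, then about y by
#' `tilt_y_deg`, matching [apply_tilt()]) to the 4th-order elasticity
#' tensor, so an orthotropic bone model follows its vertebra.  Implemented
#' by the full tensor transformation `C'_ijkl = R_ia R_jb R_kc R_ld C_abcd`;
#' the eigen-spectrum of the Voigt matrix is preserved.
#'
#' @param C A 6x6 `stiffness_tensor` (or plain matrix).
#' @param tilt_x_deg,tilt_y_deg Tilt angles in degrees.
#' @return The rotated `stiffness_tensor`.
#' @export
rotate_stiffness <- function(C, tilt_x_deg, tilt_y_deg) {
  stopifnot(is.matrix(C), all(dim(C) == c(6L, 6L)))
  if (tilt_x_deg == 0 && tilt_y_deg == 0) return(new_stiffness(unclass(C)))
  R <- rot_y(tilt_y_deg) %*% rot_x(tilt_x_deg)
  A <- voigt_to_tensor(unclass(C))
  # contract one index at a time: X_{i b c d} = R_{ia} A_{a b c d}, etc.
  contract1 <- function(A, R, pos) {
    A <- aperm(A, c(pos, setdiff(1:4, pos)))
    dim(A) <- c(3L, 27L)
    A <- R %*% A
    dim(A) <- rep(3L, 4L)
    aperm(A, order(c(pos, setdiff(1:4, pos))))
  }
  for (pos in 1:4) A <- contract1(A, R, pos)
  new_stiffness(tensor_to_voigt(A))
}

#' Eigen-spectrum of a stiffness tensor (Kelvin representation)
#'
#' Returns the six eigenvalues of the elasticity tensor in its Kelvin
#' (Mandel) representation, i.e. with sqrt(2) weights on the shear rows and
#' columns.  These are the representation-independent tensor eigenvalues:
#' they are exactly preserved by [rotate_stiffness()], unlike the raw
#' eigenvalues of the engineering-Voigt matrix.
#'
#' @param C A 6x6 stiffness matrix.
#' @return Sorted eigenvalues (MPa).
#' @export
stiffness_spectrum <- function(C) {
  D <- diag(c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2)))
  sort(eigen(D %*% unclass(C) %*% D, symmetric = TRUE,
             only.values = TRUE)$values)
}

#' Default material constants of the segment model
#'
#' Bone is available both as an isotropic model (E = 3500 MPa, nu = 0.25,
#' rho ~ 1908 kg/m^3) and as an orthotropic model (moduli 11300, 11300,
#' 22000 MPa axially, shear 3800/5400/5400 MPa, Poisson 0.484/0.203/0.203);
#' the intervertebral disc is always isotropic (E ~ 252 MPa, nu ~ 0.47,
#' rho ~ 1120 kg/m^3).  Values can be overridden via a YAML file with the
#' same layout as the shipped default (`inst/extdata/materials.yaml`).
#'
#' @param file Optional YAML file path overriding the defaults.
#' @return List with `bone_isotropic`, `bone_orthotropic`, `disc`.
#' @export
default_materials <- function(file = NULL) {
  file <- file %||% system.file("extdata", "materials.yaml",
                                package = "vertefem")
  y <- yaml::read_yaml(file)
  list(
    bone_isotropic = isotropic_material(y$bone_isotropic$E, y$bone_isotropic$nu,
                                        y$bone_isotropic$rho),
    bone_orthotropic = orthotropic_material(
      y$bone_orthotropic$Yxx, y$bone_orthotropic$Yyy, y$bone_orthotropic$Yzz,
      y$bone_orthotropic$Gxy, y$bone_orthotropic$Gyz, y$bone_orthotropic$Gxz,
      y$bone_orthotropic$nu_xy, y$bone_orthotropic$nu_yz,
      y$bone_orthotropic$nu_zx, y$bone_orthotropic$rho),
    disc = isotropic_material(y$disc$E, y$disc$nu, y$disc$rho))
}

# Per-domain stiffness for the five-solid segment.  Vertebral tensors are
# rotated by each vertebra's tilt in the orthotropic case (tilting affects
# the material frame); isotropic tensors are rotation-invariant.
spine_stiffness <- function(spine, materials, model = c("isotropic",
                                                        "orthotropic")) {
  model <- match.arg(model)
  disc_C <- isotropic_stiffness(materials$disc)
  if (model == "isotropic") {
    bone_C <- isotropic_stiffness(materials$bone_isotropic)
    bones <- list(bone_C, bone_C, bone_C)
  } else {
    C0 <- orthotropic_stiffness(materials$bone_orthotropic)
    bones <- lapply(list(spine$params$lower, spine$params$apex,
                         spine$params$upper), function(p) {
      rotate_stiffness(C0, p$tilt_x_deg, p$tilt_y_deg)
    })
  }
  list(vertebra_lower = bones[[1L]], disc_lower = disc_C,
       vertebra_apex = bones[[2L]], disc_upper = disc_C,
       vertebra_upper = bones[[3L]])
}
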