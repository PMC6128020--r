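# Parametric construction of an artificial vertebral body.
#
# A vertebra is modelled in four stages: (1) a preliminary rectangle /
# trapezoid in the coronal plane fixes the body height and the lower/upper
# face radii; (2) revolving the trapezoid gives a conical frustum; (3) the
# coronal and sagittal wedge properties of the deformed body are imposed by
# cutting the top/bottom faces with planes hinged at the face edge (material
# is only ever removed); (4) the wedged solid is rigidly tilted about the x-
# and then the y-axis about its centroid.
#
# Coordinate convention (scanner-bed frame, used package-wide):
#   +z axial/up (stacking direction), +x patient-left, +y anterior.
#
# A `solid_model` is stored analytically: frustum parameters, cut planes for
# each face (a cut is z = z0 + gx*x + gy*y; the top surface is the minimum
# over the top cuts and the flat top, the bottom surface the maximum over the
# bottom cuts and z = 0) and an affine placement p -> A p + b.  Meshes are
# generated on demand by sweeping the triangulated disc cross-section
# between the bottom and top surfaces.

new_solid_model <- function(height, r_lower, r_upper,
                            top_cuts = list(), bot_cuts = list(),
                            A = diag(3), b = c(0, 0, 0)) {
  structure(list(height = height, r_lower = r_lower, r_upper = r_upper,
                 top_cuts = top_cuts, bot_cuts = bot_cuts, A = A, b = b),
            class = "solid_model")
}

#' Preliminary rotational solid (conical frustum) of a vertebral body
#'
#' Revolves the trapezoid with the given height and lower/upper radii about
#' its vertical side, producing a frustum with axis along +z, base at z = 0.
#'
#' @param height_mm Body height (projection on the central line), mm.
#' @param r_lower_mm,r_upper_mm Radii of the approximating circles of the
#'   lower and upper faces, mm.  Both must be strictly positive; a degenerate
#'   cone (`r_upper_mm = 0`) is rejected.
#' @return A `solid_model` with tagged `top_face`, `bottom_face` and
#'   `lateral` boundary patches on its meshes.
#' @examples
#' s <- build_rotation_solid(20, 15, 10)
#' frustum_volume(s)
#' @export
build_rotation_solid <- function(height_mm, r_lower_mm, r_upper_mm) {
  if (!all(is.finite(c(height_mm, r_lower_mm, r_upper_mm))) ||
      height_mm <= 0 || r_lower_mm <= 0 || r_upper_mm <= 0) {
    stop("vertefem_parameter_error: height and both radii must be > 0 ",
         "(degenerate cones are rejected)", call. = FALSE)
  }
  new_solid_model(height_mm, r_lower_mm, r_upper_mm)
}

#' Closed-form volume of the uncut frustum underlying a solid
#'
#' @param solid A `solid_model`.
#' @return Volume in mm^3 of the frustum before any wedge cut.
#' @export
frustum_volume <- function(solid) {
  stopifnot(inherits(solid, "solid_model"))
  with(solid, pi * height / 3 * (r_lower^2 + r_lower * r_upper + r_upper^2))
}

#' Impose a wedge property by cutting a face
#'
#' Re-cuts the selected face so that its plane is rotated by `angle_deg`
#' about an in-plane hinge axis through the face edge; the hinge sits on the
#' side where the body heights coincide, so the cut only removes material.
#' A coronal wedge varies the face height with x (hinge along y), a sagittal
#' wedge with y (hinge along x).  Positive coronal angle thins the body
#' towards patient-right (-x), i.e. leaves it thicker on the convex left
#' side; positive sagittal angle thins towards posterior (-y).
#'
#' @param solid A `solid_model`.
#' @param angle_deg Wedge angle in degrees, |angle| < 45.  0 is the identity.
#' @param face `"top"` or `"bottom"`.
#' @param plane `"coronal"` (xz) or `"sagittal"` (yz).
#' @return The cut `solid_model`.
#' @export
apply_wedge <- function(solid, angle_deg, face = c("top", "bottom"),
                        plane = c("coronal", "sagittal")) {
  stopifnot(inherits(solid, "solid_model"))
  face <- match.arg(face)
  plane <- match.arg(plane)
  if (!is.finite(angle_deg) || abs(angle_deg) >= 45) {
    stop("vertefem_parameter_error: wedge angle must lie in (-45, 45) degrees",
         call. = FALSE)
  }
  if (angle_deg == 0) return(solid)
  r_face <- if (face == "top") solid$r_upper else solid$r_lower
  slope <- abs(tan(rad(angle_deg)))
  s <- sign(angle_deg)
  # cut plane z = z0 + g * q (q = x coronal, y sagittal) passing through the
  # hinge edge at q = s * r_face: the top cut descends away from the hinge,
  # the bottom cut ascends, so material is only removed
  if (face == "top") {
    g <- slope * s
    z0 <- solid$height - slope * r_face
    cut <- if (plane == "coronal") c(z0, g, 0) else c(z0, 0, g)
    solid$top_cuts <- c(solid$top_cuts, list(cut))
  } else {
    g <- -slope * s
    z0 <- slope * r_face
    cut <- if (plane == "coronal") c(z0, g, 0) else c(z0, 0, g)
    solid$bot_cuts <- c(solid$bot_cuts, list(cut))
  }
  # reject cuts that consume the whole solid (checked on the column heights)
  check <- try(solid_mesh(solid, n_rings = 3L, n_layers = 2L), silent = TRUE)
  if (inherits(check, "try-error")) {
    stop("vertefem_geometry_error: wedge cut consumes the solid (top and ",
         "bottom faces intersect inside the lateral surface)", call. = FALSE)
  }
  solid
}

# Evaluate the top/bottom surfaces of the (local-frame) cut frustum at the
# in-plane points (x, y).  Returns a list(bottom, top) of heights.
solid_surfaces <- function(solid, x, y) {
  zt <- rep(solid$height, length(x))
  for (cut in solid$top_cuts) zt <- pmin(zt, cut[1L] + cut[2L] * x + cut[3L] * y)
  zb <- rep(0, length(x))
  for (cut in solid$bot_cuts) zb <- pmax(zb, cut[1L] + cut[2L] * x + cut[3L] * y)
  list(bottom = zb, top = zt)
}

rot_x <- function(a) {
  c <- cos(rad(a)); s <- sin(rad(a))
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}
rot_y <- function(a) {
  c <- cos(rad(a)); s <- sin(rad(a))
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}
rot_z <- function(a) {
  c <- cos(rad(a)); s <- sin(rad(a))
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

#' Rigidly tilt a solid about the x- and then the y-axis
#'
#' The rotation pivots on the solid's centroid, so tilting never translates
#' the body; volume is preserved exactly (rigid motion).
#'
#' @param solid A `solid_model`.
#' @param tilt_x_deg,tilt_y_deg Rotation angles in degrees; the x-rotation is
#'   applied first.
#' @return The tilted `solid_model`.
#' @export
apply_tilt <- function(solid, tilt_x_deg, tilt_y_deg) {
  stopifnot(inherits(solid, "solid_model"),
            is.finite(tilt_x_deg), is.finite(tilt_y_deg))
  if (tilt_x_deg == 0 && tilt_y_deg == 0) return(solid)
  R <- rot_y(tilt_y_deg) %*% rot_x(tilt_x_deg)
  ctr <- mesh_centroid(as_mesh(solid))
  # p -> R (p - ctr) + ctr composed after the existing placement A p + b:
  # new affine is (R A) p + (R b - R ctr + ctr)
  solid$A <- R %*% solid$A
  solid$b <- as.vector(R %*% (solid$b - ctr)) + ctr
  solid
}

translate_solid <- function(solid, v) {
  solid$b <- solid$b + v
  solid
}

#' Per-vertebra parameter set
#'
#' Bundles the parameters driving the artificial geometric construction of
#' one vertebral body and validates their invariants.
#'
#' @param height_mm Body height, mm (> 0).
#' @param r_lower_mm,r_upper_mm Lower/upper face radii, mm (> 0).
#' @param wedge_top_cor_deg,wedge_bot_cor_deg Coronal (xz) wedge angles of
#'   the top/bottom faces, degrees, each in (-45, 45).
#' @param wedge_top_sag_deg,wedge_bot_sag_deg Sagittal (yz) wedge angles.
#' @param tilt_x_deg,tilt_y_deg Rigid tilts about x then y, degrees.
#' @param center_mm 3-vector placement of the body centre in the bed frame.
#' @return A `vertebra_params` object (validated list).
#' @export
vertebra_params <- function(height_mm, r_lower_mm, r_upper_mm,
                            wedge_top_cor_deg = 0, wedge_bot_cor_deg = 0,
                            wedge_top_sag_deg = 0, wedge_bot_sag_deg = 0,
                            tilt_x_deg = 0, tilt_y_deg = 0,
                            center_mm = c(0, 0, 0)) {
  p <- list(height_mm = height_mm, r_lower_mm = r_lower_mm,
            r_upper_mm = r_upper_mm,
            wedge_top_cor_deg = wedge_top_cor_deg,
            wedge_bot_cor_deg = wedge_bot_cor_deg,
            wedge_top_sag_deg = wedge_top_sag_deg,
            wedge_bot_sag_deg = wedge_bot_sag_deg,
            tilt_x_deg = tilt_x_deg, tilt_y_deg = tilt_y_deg,
            center_mm = center_mm)
  stopifnot(all(vapply(p[1:9], function(v) is.numeric(v) && length(v) == 1L &&
                         is.finite(v), logical(1))),
            is.numeric(center_mm), length(center_mm) == 3L,
            all(is.finite(center_mm)))
  if (height_mm <= 0 || r_lower_mm <= 0 || r_upper_mm <= 0) {
    stop("vertefem_parameter_error: height and radii must be > 0", call. = FALSE)
  }
  w <- unlist(p[4:7])
  if (any(abs(w) >= 45)) {
    stop("vertefem_parameter_error: wedge angles must lie in (-45, 45) degrees",
         call. = FALSE)
  }
  structure(p, class = "vertebra_params")
}

#' Construct an artificial vertebral body from its parameter set
#'
#' Composes the four construction stages: frustum, the four wedge cuts
#' (top/bottom x coronal/sagittal), the rigid tilt, and translation so that
#' the body centroid sits at `center_mm`.
#'
#' @param params A [vertebra_params()] object.
#' @return A `solid_model`.
#' @export
build_vertebra <- function(params) {
  stopifnot(inherits(params, "vertebra_params"))
  s <- build_rotation_solid(params$height_mm, params$r_lower_mm,
                            params$r_upper_mm)
  if (params$wedge_top_cor_deg != 0)
    s <- apply_wedge(s, params$wedge_top_cor_deg, "top", "coronal")
  if (params$wedge_top_sag_deg != 0)
    s <- apply_wedge(s, params$wedge_top_sag_deg, "top", "sagittal")
  if (params$wedge_bot_cor_deg != 0)
    s <- apply_wedge(s, params$wedge_bot_cor_deg, "bottom", "coronal")
  if (params$wedge_bot_sag_deg != 0)
    s <- apply_wedge(s, params$wedge_bot_sag_deg, "bottom", "sagittal")
  s <- apply_tilt(s, params$tilt_x_deg, params$tilt_y_deg)
  ctr <- mesh_centroid(as_mesh(s))
  translate_solid(s, params$center_mm - ctr)
}

#' Mesh an analytic solid with tetrahedra
#'
#' Sweeps the triangulated disc cross-section between the solid's bottom and
#' top surfaces.  Nodes at sweep fraction t carry the frustum radius r(t);
#' each column is compressed between the bottom and top cut surfaces, so the
#' cut faces are meshed exactly planar.
#'
#' @param solid A `solid_model`.
#' @param size Target characteristic edge length, mm.  Defaults to
#'   `min(r_lower, r_upper) / 5`.
#' @param n_rings,n_layers Explicit discretization overrides.
#' @return A mesh: list with `nodes` (n x 3), `tets` (m x 4), `tags`
#'   (`top_face`, `bottom_face`, `lateral` triangle matrices), `grid`,
#'   `n_cross`, `n_layers`.
#' @export
solid_mesh <- function(solid, size = NULL, n_rings = NULL, n_layers = NULL) {
  stopifnot(inherits(solid, "solid_model"))
  size <- size %||% (min(solid$r_lower, solid$r_upper) / 5)
  n_rings <- n_rings %||% max(3L, ceiling(max(solid$r_lower, solid$r_upper) / size))
  n_layers <- n_layers %||% max(2L, ceiling(solid$height / size))
  g <- disc_grid(n_rings)
  N <- nrow(g$uv)
  t_frac <- seq(0, 1, length.out = n_layers + 1L)
  nodes <- matrix(0, nrow = N * (n_layers + 1L), ncol = 3L)
  for (l in seq_along(t_frac)) {
    t <- t_frac[l]
    r_t <- solid$r_lower + t * (solid$r_upper - solid$r_lower)
    x <- r_t * g$uv[, 1L]; y <- r_t * g$uv[, 2L]
    zs <- solid_surfaces(solid, x, y)
    if (any(zs$top - zs$bottom <= 0)) {
      stop("vertefem_geometry_error: cut surfaces intersect inside the solid",
           call. = FALSE)
    }
    z <- zs$bottom + t * (zs$top - zs$bottom)
    nodes[(l - 1L) * N + seq_len(N), ] <- cbind(x, y, z)
  }
  nodes <- t(solid$A %*% t(nodes)) + matrix(solid$b, nrow(nodes), 3L,
                                            byrow = TRUE)
  tets <- orient_tets(nodes, extrude_tets(g$tri, N, n_layers, g$priority))
  bottom <- g$tri
  top <- g$tri + n_layers * N
  bf <- boundary_faces(tets)
  layer_of <- (bf - 1L) %/% N
  lateral <- bf[!(apply(layer_of == 0L, 1L, all) |
                    apply(layer_of == n_layers, 1L, all)), , drop = FALSE]
  structure(list(nodes = nodes, tets = tets,
                 tags = list(top_face = top, bottom_face = bottom,
                             lateral = lateral),
                 grid = g, n_cross = N, n_layers = n_layers),
            class = "vertefem_mesh")
}

#' Coerce a solid or spine model to its tetrahedral mesh
#'
#' @param x A `solid_model`, `spine_model`, or an existing mesh.
#' @param ... Passed to [solid_mesh()] for analytic solids.
#' @export
as_mesh <- function(x, ...) UseMethod("as_mesh")

#' @export
as_mesh.vertefem_mesh <- function(x, ...) x

#' @export
as_mesh.solid_model <- function(x, ...) solid_mesh(x, ...)

#' @export
as_mesh.spine_model <- function(x, ...) x$mesh

#' @export
as_mesh.list <- function(x, ...) {
  stopifnot(!is.null(x$nodes), !is.null(x$tets))
  x
}

#' @export
print.solid_model <- function(x, ...) {
  cat("<solid_model> frustum h=", x$height, " r_lower=", x$r_lower,
      " r_upper=", x$r_upper, "; ", length(x$top_cuts), " top cut(s), ",
      length(x$bot_cuts), " bottom cut(s)\n", sep = "")
  invisible(x)
}

#' @export
print.vertebra_params <- function(x, ...) {
  cat("<vertebra_params> h=", x$height_mm, "mm r=[", x$r_lower_mm, ",",
      x$r_upper_mm, "] wedges cor[", x$wedge_top_cor_deg, ",",
      x$wedge_bot_cor_deg, "] sag[", x$wedge_top_sag_deg, ",",
      x$wedge_bot_sag_deg, "] tilt[", x$tilt_x_deg, ",", x$tilt_y_deg, "]\n",
      sep = "")
  invisible(x)
}
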