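# Assembly of the three-vertebra / two-disc segment model.
#
# The five solids share one triangulated disc cross-section, so the disc
# meshes can reuse the vertebral face nodes verbatim: a disc is the linear
# loft between the top-face nodes of the vertebra below and the bottom-face
# nodes of the vertebra above.  Interfaces are therefore conforming by
# construction (shared node layers, no duplicated nodes).

DOMAIN_LEVELS <- c("vertebra_lower", "disc_lower", "vertebra_apex",
                   "disc_upper", "vertebra_upper")

#' Loft an intervertebral disc between two faces
#'
#' Builds a watertight disc solid by linear interpolation between two planar
#' (or mildly tilted) faces discretized on the same cross-section grid.  The
#' disc's lateral radius follows the interpolated face radii.
#'
#' @param lower_face,upper_face Faces as returned by [solid_face()]: lists
#'   with `points` (N x 3 node coordinates) and `grid` (the shared
#'   [disc_grid()]).
#' @param n_layers Number of element layers through the disc height.
#' @return A tetrahedral mesh with `top_face`, `bottom_face`, `lateral` tags.
#' @export
build_disc <- function(lower_face, upper_face, n_layers = 2L) {
  stopifnot(is.list(lower_face), is.list(upper_face),
            nrow(lower_face$points) == nrow(upper_face$points),
            identical(dim(lower_face$grid$tri), dim(upper_face$grid$tri)))
  gap <- upper_face$points[, 3L] - lower_face$points[, 3L]
  if (any(gap <= 0)) {
    stop("vertefem_geometry_error: disc faces intersect or have zero gap",
         call. = FALSE)
  }
  g <- lower_face$grid
  N <- nrow(g$uv)
  s <- seq(0, 1, length.out = n_layers + 1L)
  nodes <- do.call(rbind, lapply(s, function(t) {
    (1 - t) * lower_face$points + t * upper_face$points
  }))
  tets <- orient_tets(nodes, extrude_tets(g$tri, N, n_layers, g$priority))
  bf <- boundary_faces(tets)
  layer_of <- (bf - 1L) %/% N
  lateral <- bf[!(apply(layer_of == 0L, 1L, all) |
                    apply(layer_of == n_layers, 1L, all)), , drop = FALSE]
  structure(list(nodes = nodes, tets = tets,
                 tags = list(top_face = g$tri + n_layers * N,
                             bottom_face = g$tri, lateral = lateral),
                 grid = g, n_cross = N, n_layers = n_layers),
            class = "vertefem_mesh")
}

#' Extract a face of an analytic solid as loft input
#'
#' @param solid A `solid_model`.
#' @param which `"top"` or `"bottom"`.
#' @param grid A [disc_grid()]; all solids being assembled must share it.
#' @return List with `points` (N x 3) and `grid`.
#' @export
solid_face <- function(solid, which = c("top", "bottom"), grid) {
  which <- match.arg(which)
  t <- if (which == "top") 1 else 0
  r_t <- solid$r_lower + t * (solid$r_upper - solid$r_lower)
  x <- r_t * grid$uv[, 1L]; y <- r_t * grid$uv[, 2L]
  zs <- solid_surfaces(solid, x, y)
  z <- if (which == "top") zs$top else zs$bottom
  pts <- cbind(x, y, z)
  pts <- t(solid$A %*% t(pts)) + matrix(solid$b, nrow(pts), 3L, byrow = TRUE)
  list(points = pts, grid = grid)
}

#' Helper: a flat circular face on a shared cross-section grid
#'
#' @param radius Face radius, mm.
#' @param z Axial position of the face plane, mm.
#' @param grid A [disc_grid()].
#' @param tilt_y_deg Optional tilt of the face plane about the y-axis.
#' @return A face usable with [build_disc()].
#' @export
circle_face <- function(radius, z, grid, tilt_y_deg = 0) {
  x <- radius * grid$uv[, 1L]; y <- radius * grid$uv[, 2L]
  zz <- rep(z, length(x)) - tan(rad(tilt_y_deg)) * x
  list(points = cbind(x, y, zz), grid = grid)
}

# Build one vertebra solid (frustum + wedges + tilt) placed with its base
# section at axial position z_base before tilting; tilt pivots on the solid
# centroid so the stacking position is preserved.
spine_vertebra_solid <- function(p, z_base) {
  s <- build_rotation_solid(p$height_mm, p$r_lower_mm, p$r_upper_mm)
  for (w in list(list(p$wedge_top_cor_deg, "top", "coronal"),
                 list(p$wedge_top_sag_deg, "top", "sagittal"),
                 list(p$wedge_bot_cor_deg, "bottom", "coronal"),
                 list(p$wedge_bot_sag_deg, "bottom", "sagittal"))) {
    if (w[[1L]] != 0) s <- apply_wedge(s, w[[1L]], w[[2L]], w[[3L]])
  }
  s <- translate_solid(s, c(0, 0, z_base))
  apply_tilt(s, p$tilt_x_deg, p$tilt_y_deg)
}

#' Assemble the apex segment: three vertebrae and two discs
#'
#' Stacks the lower neighbour, apex and upper neighbour along +z with the
#' given disc gaps, lofts the two discs between the adjacent faces, and
#' merges everything into a single conforming labelled tetrahedral mesh.
#'
#' @param lower,apex,upper [vertebra_params()] for the three bodies.
#' @param disc_gaps_mm Length-2 positive vector: heights of the lower and
#'   upper disc, mm.
#' @param size Target mesh edge length, mm; default `min(r_lower)/5`.
#' @param n_rings Optional override of the cross-section refinement.
#' @return A `spine_model`: list with `mesh` (nodes, tets, per-element
#'   `domain` in `r DOMAIN_LEVELS`), `tags` (bottom_face, top_face,
#'   apex_top, lateral_upper) and `params`.
#' @export
assemble_spine <- function(lower, apex, upper, disc_gaps_mm,
                           size = NULL, n_rings = NULL) {
  stopifnot(inherits(lower, "vertebra_params"),
            inherits(apex, "vertebra_params"),
            inherits(upper, "vertebra_params"),
            is.numeric(disc_gaps_mm), length(disc_gaps_mm) == 2L)
  if (any(disc_gaps_mm <= 0)) {
    stop("vertefem_parameter_error: disc gaps must be > 0", call. = FALSE)
  }
  plist <- list(lower, apex, upper)
  size <- size %||% (min(vapply(plist, `[[`, 1, "r_lower_mm")) / 5)
  rmax <- max(unlist(lapply(plist, function(p) c(p$r_lower_mm, p$r_upper_mm))))
  n_rings <- n_rings %||% max(3L, ceiling(rmax / size))
  g <- disc_grid(n_rings)
  N <- nrow(g$uv)

  z_base <- c(0,
              lower$height_mm + disc_gaps_mm[1L],
              lower$height_mm + disc_gaps_mm[1L] + apex$height_mm +
                disc_gaps_mm[2L])
  solids <- Map(spine_vertebra_solid, plist, z_base)

  vert_layers <- vapply(plist,
                        function(p) max(2L, as.integer(ceiling(p$height_mm / size))),
                        integer(1))
  disc_layers <- as.integer(pmax(2L, ceiling(disc_gaps_mm / size)))

  vert_nodes <- Map(function(s, L) {
    t_frac <- seq(0, 1, length.out = L + 1L)
    blocks <- lapply(t_frac, function(t) {
      r_t <- s$r_lower + t * (s$r_upper - s$r_lower)
      x <- r_t * g$uv[, 1L]; y <- r_t * g$uv[, 2L]
      zs <- solid_surfaces(s, x, y)
      if (any(zs$top - zs$bottom <= 0)) {
        stop("vertefem_geometry_error: cut surfaces intersect inside a vertebra",
             call. = FALSE)
      }
      cbind(x, y, zs$bottom + t * (zs$top - zs$bottom))
    })
    pts <- do.call(rbind, blocks)
    t(s$A %*% t(pts)) + matrix(s$b, nrow(pts), 3L, byrow = TRUE)
  }, solids, vert_layers)

  # disc node blocks interpolate between the neighbouring face layers
  disc_nodes <- vector("list", 2L)
  for (d in 1:2) {
    lo_face <- vert_nodes[[d]][vert_layers[d] * N + seq_len(N), , drop = FALSE]
    hi_face <- vert_nodes[[d + 1L]][seq_len(N), , drop = FALSE]
    if (any(hi_face[, 3L] - lo_face[, 3L] <= 0)) {
      stop("vertefem_geometry_error: solids overlap after tilting between ",
           DOMAIN_LEVELS[2L * d - 1L], " and ", DOMAIN_LEVELS[2L * d + 1L],
           call. = FALSE)
    }
    s_frac <- seq(0, 1, length.out = disc_layers[d] + 1L)
    inner <- s_frac[-c(1L, length(s_frac))]
    disc_nodes[[d]] <- do.call(rbind, lapply(inner, function(t) {
      (1 - t) * lo_face + t * hi_face
    }))
  }

  nodes <- rbind(vert_nodes[[1L]], disc_nodes[[1L]], vert_nodes[[2L]],
                 disc_nodes[[2L]], vert_nodes[[3L]])
  # global layer count per piece (intervals)
  piece_intervals <- c(vert_layers[1L], disc_layers[1L], vert_layers[2L],
                       disc_layers[2L], vert_layers[3L])
  n_layers_tot <- sum(piece_intervals)
  stopifnot(nrow(nodes) == (n_layers_tot + 1L) * N)

  tets <- orient_tets(nodes, extrude_tets(g$tri, N, n_layers_tot, g$priority))
  tets_per_interval <- 3L * nrow(g$tri)
  domain <- rep(rep(seq_len(5L), piece_intervals), each = tets_per_interval)

  piece_end_layer <- cumsum(piece_intervals) # 0-based top layer of each piece
  apex_top_layer <- piece_end_layer[3L]
  upper_range <- c(piece_end_layer[4L], piece_end_layer[5L])

  bf <- boundary_faces(tets)
  layer_of <- (bf - 1L) %/% N
  in_upper <- apply(layer_of >= upper_range[1L] & layer_of <= upper_range[2L],
                    1L, all)
  on_top <- apply(layer_of == n_layers_tot, 1L, all)
  lateral_upper <- bf[in_upper & !on_top &
                        !apply(layer_of == upper_range[1L], 1L, all), ,
                      drop = FALSE]

  mesh <- structure(list(nodes = nodes, tets = tets, domain = domain,
                         domains = DOMAIN_LEVELS, grid = g, n_cross = N,
                         n_layers = n_layers_tot,
                         piece_intervals = piece_intervals),
                    class = "vertefem_mesh")
  tags <- list(bottom_face = g$tri,
               top_face = g$tri + n_layers_tot * N,
               apex_top = g$tri + apex_top_layer * N,
               lateral_upper = lateral_upper)
  structure(list(mesh = mesh, tags = tags,
                 params = list(lower = lower, apex = apex, upper = upper,
                               disc_gaps_mm = disc_gaps_mm),
                 solids = solids),
            class = "spine_model")
}

#' Subdivide the top face into four sacrum-aligned quadrants
#'
#' The "horizontal" split line runs parallel to the sacrum line through the
#' top-face centroid; the second line is its in-plane perpendicular.
#' Quadrant labels in the sacrum-aligned frame: `q1` anterior-left, `q2`
#' anterior-right, `q3` posterior-right, `q4` posterior-left.
#'
#' @param spine A `spine_model`.
#' @param sacrum_angle_deg Sacrum-to-table angle, degrees, positive when the
#'   sacrum line is rotated clockwise viewed from above.
#' @return The `spine_model` with `tags$quadrants` (list `q1`..`q4` of
#'   triangle matrices) and `sacrum_angle_deg` recorded.
#' @export
top_face_quadrants <- function(spine, sacrum_angle_deg) {
  stopifnot(inherits(spine, "spine_model"), is.finite(sacrum_angle_deg))
  mesh <- spine$mesh
  top <- spine$tags$top_face
  fr <- face_frame(mesh, top)
  ell <- c(cos(rad(sacrum_angle_deg)), -sin(rad(sacrum_angle_deg)), 0)
  u <- ell - sum(ell * fr$normal) * fr$normal
  u <- u / sqrt(sum(u^2))
  if (u[1L] < 0) u <- -u
  v <- c(fr$normal[2L] * u[3L] - fr$normal[3L] * u[2L],
         fr$normal[3L] * u[1L] - fr$normal[1L] * u[3L],
         fr$normal[1L] * u[2L] - fr$normal[2L] * u[1L])
  ctr <- triangle_centroids(mesh$nodes, top)
  d <- sweep(ctr, 2L, fr$centroid)
  cu <- d %*% u
  cv <- d %*% v
  spine$tags$quadrants <- list(
    q1 = top[cu >= 0 & cv >= 0, , drop = FALSE],
    q2 = top[cu < 0 & cv >= 0, , drop = FALSE],
    q3 = top[cu < 0 & cv < 0, , drop = FALSE],
    q4 = top[cu >= 0 & cv < 0, , drop = FALSE])
  spine$sacrum_angle_deg <- sacrum_angle_deg
  spine
}

#' Tag circular lateral shear patches on the uppermost vertebra
#'
#' Marks two approximately circular patches on opposite lateral sides (+x
#' patient-left, -x patient-right) of the top vertebra, where tangential
#' tractions of the shear load-state variants are applied.
#'
#' @param spine A `spine_model`.
#' @param patch_radius_mm Patch radius, mm.
#' @param height_fraction Patch centre height as a fraction of the top
#'   vertebra's height (0 = bottom face, 1 = top face).
#' @return The `spine_model` with `tags$shear_left`, `tags$shear_right` and
#'   `shear_axis` recorded.
#' @export
lateral_shear_patches <- function(spine, patch_radius_mm,
                                  height_fraction = 0.5) {
  stopifnot(inherits(spine, "spine_model"), patch_radius_mm > 0,
            height_fraction > 0, height_fraction < 1)
  p <- spine$params$upper
  h <- p$height_mm
  if (height_fraction * h - patch_radius_mm < 0 ||
      height_fraction * h + patch_radius_mm > h) {
    stop("vertefem_geometry_error: shear patch exceeds the lateral extent ",
         "of the uppermost vertebra", call. = FALSE)
  }
  mesh <- spine$mesh
  N <- mesh$n_cross
  top_layer <- mesh$n_layers
  upper_bot_layer <- sum(mesh$piece_intervals[1:4])
  lay_nodes <- function(l) mesh$nodes[l * N + seq_len(N), , drop = FALSE]
  c_bot <- colMeans(lay_nodes(upper_bot_layer))
  c_top <- colMeans(lay_nodes(top_layer))
  axis <- (c_top - c_bot) / sqrt(sum((c_top - c_bot)^2))
  c_axis <- c_bot + height_fraction * (c_top - c_bot)
  r_loc <- p$r_lower_mm + height_fraction * (p$r_upper_mm - p$r_lower_mm)
  xdir <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
  xdir <- xdir / sqrt(sum(xdir^2))
  centers <- list(left = c_axis + r_loc * xdir,
                  right = c_axis - r_loc * xdir)
  lat <- spine$tags$lateral_upper
  ctr <- triangle_centroids(mesh$nodes, lat)
  sel <- lapply(centers, function(cc) {
    d2 <- rowSums(sweep(ctr, 2L, cc)^2)
    lat[d2 <= patch_radius_mm^2, , drop = FALSE]
  })
  if (nrow(sel$left) == 0L || nrow(sel$right) == 0L) {
    stop("vertefem_geometry_error: shear patch selects no lateral triangles; ",
         "increase the patch radius or mesh refinement", call. = FALSE)
  }
  spine$tags$shear_left <- sel$left
  spine$tags$shear_right <- sel$right
  spine$shear_axis <- list(axis = axis, point = c_axis)
  spine
}

#' @export
print.spine_model <- function(x, ...) {
  cat("<spine_model> ", nrow(x$mesh$nodes), " nodes, ", nrow(x$mesh$tets),
      " tets, 5 domains", sep = "")
  if (!is.null(x$tags$quadrants)) cat(", quadrants tagged")
  if (!is.null(x$tags$shear_left)) cat(", shear patches tagged")
  cat("\n")
  invisible(x)
}
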