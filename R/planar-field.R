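# The response variable: distortion-energy field on the apex top plane,
# its focus point, and the apex top response angle.
#
# The analysis plane Lambda is the plane containing the apex top face (the
# apex/upper-disc interface, planar by construction).  The element-wise
# distortion-energy density of the apex elements adjacent to that interface
# is laid out on a regular in-plane grid; the focus point is the area
# centroid of the largest connected near-maximal region, and the response
# angle is measured from the projected sacrum line to the centroid-to-focus
# direction (counter-clockwise positive viewed from +z).

#' Sample the distortion-energy field on the apex top plane
#'
#' @param spine A `spine_model`.
#' @param solution A `fem_solution` for that spine.
#' @param resolution Grid points per axis (default 41).
#' @param sacrum_angle_deg Sacrum-to-table angle defining the in-plane
#'   reference direction (projection of the sacrum line).  Defaults to the
#'   angle recorded on the spine by [top_face_quadrants()], else 0.
#' @return A `planar_field`: list with `x`, `y` (in-plane grid axes, mm,
#'   origin at the section centroid), `values` (matrix, MPa; NA outside the
#'   section), `mask`, `centroid` (c(0, 0) by construction), `ell`
#'   (projected sacrum-line direction, in-plane unit 2-vector), `frame`
#'   (3D origin/basis of the plane).
#' @export
sample_apex_plane <- function(spine, solution, resolution = 41L,
                              sacrum_angle_deg = NULL) {
  stopifnot(inherits(spine, "spine_model"), inherits(solution, "fem_solution"))
  sacrum_angle_deg <- sacrum_angle_deg %||% spine$sacrum_angle_deg %||% 0
  mesh <- spine$mesh
  tri <- spine$tags$apex_top
  fr <- face_frame(mesh, tri)
  n <- fr$normal
  # right-handed in-plane basis (e1 x e2 = n, n points up)
  e1 <- c(1, 0, 0) - n[1L] * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])

  # continuous field on the interface: volume-weighted nodal average of the
  # adjacent apex elements' energy density (element-constant values are too
  # rough for a stable near-maximal-set extraction)
  apex_ids <- which(mesh$domains[mesh$domain] == "vertebra_apex")
  nval <- nodal_average(mesh$tets[apex_ids, , drop = FALSE],
                        tet_volumes(mesh$nodes, mesh$tets)[apex_ids],
                        solution$energy_density[apex_ids],
                        nrow(mesh$nodes))

  # project triangle vertices into the plane frame
  proj <- function(p) {
    d <- sweep(p, 2L, fr$centroid)
    cbind(d %*% e1, d %*% e2)
  }
  v1 <- proj(mesh$nodes[tri[, 1L], , drop = FALSE])
  v2 <- proj(mesh$nodes[tri[, 2L], , drop = FALSE])
  v3 <- proj(mesh$nodes[tri[, 3L], , drop = FALSE])

  rng_x <- range(v1[, 1L], v2[, 1L], v3[, 1L])
  rng_y <- range(v1[, 2L], v2[, 2L], v3[, 2L])
  gx <- seq(rng_x[1L], rng_x[2L], length.out = resolution)
  gy <- seq(rng_y[1L], rng_y[2L], length.out = resolution)
  pts <- cbind(rep(gx, times = resolution), rep(gy, each = resolution))

  values <- rep(NA_real_, nrow(pts))
  # barycentric interpolation of the nodal values, looped over triangles
  for (t in seq_len(nrow(tri))) {
    a <- v1[t, ]; b <- v2[t, ]; c <- v3[t, ]
    det <- (b[1L] - a[1L]) * (c[2L] - a[2L]) -
      (c[1L] - a[1L]) * (b[2L] - a[2L])
    if (abs(det) < 1e-12) next
    px <- pts[, 1L] - a[1L]; py <- pts[, 2L] - a[2L]
    l1 <- (px * (c[2L] - a[2L]) - py * (c[1L] - a[1L])) / det
    l2 <- (py * (b[1L] - a[1L]) - px * (b[2L] - a[2L])) / det
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & (l1 + l2) <= 1 + 1e-9
    fill <- inside & is.na(values)
    vt <- nval[tri[t, ]]
    values[fill] <- (1 - l1[fill] - l2[fill]) * vt[1L] +
      l1[fill] * vt[2L] + l2[fill] * vt[3L]
  }
  vm <- matrix(values, nrow = resolution) # rows ~ x, cols ~ y
  ell3 <- c(cos(rad(sacrum_angle_deg)), -sin(rad(sacrum_angle_deg)), 0)
  ell2 <- c(sum(ell3 * e1), sum(ell3 * e2))
  ell2 <- ell2 / sqrt(sum(ell2^2))
  structure(list(x = gx, y = gy, values = vm, mask = !is.na(vm),
                 centroid = c(0, 0), ell = ell2,
                 frame = list(origin = fr$centroid, e1 = e1, e2 = e2,
                              normal = n),
                 sacrum_angle_deg = sacrum_angle_deg),
            class = "planar_field")
}

# Volume-weighted average of element-constant values onto nodes.
nodal_average <- function(tets, volumes, values, n_nodes) {
  idx <- as.vector(tets)
  wv <- rep(volumes * values, times = 4L)
  w <- rep(volumes, times = 4L)
  num <- rowsum(wv, idx)
  den <- rowsum(w, idx)
  out <- rep(NA_real_, n_nodes)
  out[as.integer(rownames(num))] <- num[, 1L] / den[, 1L]
  out
}

#' Construct a planar field from raw grid values
#'
#' Mainly for testing the focus-point and response-angle operations on
#' synthetic fields.
#'
#' @param x,y Grid axes (mm).
#' @param values Matrix `length(x)` x `length(y)`; NA marks points outside
#'   the section.
#' @param centroid In-plane section centroid (2-vector).
#' @param ell In-plane reference (sacrum line) direction.
#' @return A `planar_field`.
#' @export
planar_field <- function(x, y, values, centroid = c(0, 0), ell = c(1, 0)) {
  stopifnot(is.matrix(values), nrow(values) == length(x),
            ncol(values) == length(y))
  mask <- !is.na(values)
  if (!any(mask)) {
    stop("vertefem_parameter_error: field has no unmasked points",
         call. = FALSE)
  }
  if (any(values[mask] < 0)) {
    stop("vertefem_parameter_error: distortion-energy values must be >= 0",
         call. = FALSE)
  }
  structure(list(x = x, y = y, values = values, mask = mask,
                 centroid = centroid, ell = ell / sqrt(sum(ell^2))),
            class = "planar_field")
}

# 8-connected component labelling of a logical matrix (two-pass union-find).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    neigh <- integer(0)
    if (i > 1L && mask[i - 1L, j]) neigh <- c(neigh, lab[i - 1L, j])
    if (j > 1L) {
      if (mask[i, j - 1L]) neigh <- c(neigh, lab[i, j - 1L])
      if (i > 1L && mask[i - 1L, j - 1L]) neigh <- c(neigh, lab[i - 1L, j - 1L])
      if (i < nr && mask[i + 1L, j - 1L]) neigh <- c(neigh, lab[i + 1L, j - 1L])
    }
    if (length(neigh) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(neigh, find, integer(1))
      r <- min(roots)
      lab[i, j] <- r
      for (o in roots) parent[o] <- r
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    remap <- match(roots, unique(roots))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Focus point of a planar distortion-energy field
#'
#' Thresholds the field at `(1 - plateau_tol)` of its maximum, labels the
#' 8-connected components of the near-maximal set, and returns the area
#' centroid of the largest component whose area exceeds the curve/point
#' cutoff.  Components tying in area (within `area_tol`) are averaged
#' (`kind = "tie_mean"`); if no component is large enough the location of
#' the maximum is returned (`kind = "curve_or_point"`).  All candidate
#' components are reported so an investigator can override the automatic
#' rule.
#'
#' @param field A `planar_field`.
#' @param plateau_tol Relative plateau tolerance (default 0.02).
#' @param min_cells Minimum component size, in grid cells, to count as a
#'   subdomain (default 4).
#' @param area_tol Relative area tolerance for ties (default 0.05).
#' @return A `focus_point`: list with `point` (2-vector, mm), `kind`,
#'   `component_area` (mm^2) and `candidates` (tibble of all components).
#' @export
focus_point <- function(field, plateau_tol = 0.02, min_cells = 4L,
                        area_tol = 0.05) {
  stopifnot(inherits(field, "planar_field"))
  v <- field$values
  vmax <- max(v, na.rm = TRUE)
  vmin <- min(v, na.rm = TRUE)
  if (!(vmax > vmin)) {
    stop("vertefem_nonconstancy_error: focus point requires a non-constant ",
         "field", call. = FALSE)
  }
  sel <- field$mask & !is.na(v) & v >= (1 - plateau_tol) * vmax
  lab <- label_components(sel)
  cell <- (field$x[2L] - field$x[1L]) * (field$y[2L] - field$y[1L])
  ids <- setdiff(unique(as.vector(lab)), 0L)
  xs <- matrix(field$x, nrow(v), ncol(v))
  ys <- matrix(field$y, nrow(v), ncol(v), byrow = TRUE)
  cand <- purrr::map_dfr(ids, function(id) {
    in_c <- lab == id
    tibble::tibble(component = id, n_cells = sum(in_c),
                   area = sum(in_c) * cell,
                   cx = mean(xs[in_c]), cy = mean(ys[in_c]))
  })
  subdom <- cand[cand$n_cells >= min_cells, , drop = FALSE]
  if (nrow(subdom) == 0L) {
    at <- which(v == vmax & field$mask, arr.ind = TRUE)[1L, ]
    out <- list(point = c(field$x[at[1L]], field$y[at[2L]]),
                kind = "curve_or_point", component_area = cell)
  } else {
    amax <- max(subdom$area)
    tied <- subdom[subdom$area >= (1 - area_tol) * amax, , drop = FALSE]
    if (nrow(tied) > 1L) {
      out <- list(point = c(mean(tied$cx), mean(tied$cy)), kind = "tie_mean",
                  component_area = mean(tied$area))
    } else {
      out <- list(point = c(tied$cx, tied$cy), kind = "subdomain",
                  component_area = tied$area)
    }
  }
  structure(c(out, list(candidates = cand)), class = "focus_point")
}

#' Apex top response angle
#'
#' Signed angle, in degrees, from the projected sacrum line to the line
#' through the section centroid and the focus point; counter-clockwise
#' positive viewed from above (+z).  Both references are lines (the sacrum
#' line carries no intrinsic orientation), so the angle is reduced to
#' (-90, 90]; this makes the measurement continuous and exactly
#' sign-equivariant under sagittal mirroring.
#'
#' @param field A `planar_field`.
#' @param plateau_tol,min_cells,area_tol Passed to [focus_point()].
#' @return Angle in degrees in (-90, 90].
#' @export
apex_top_response_angle <- function(field, plateau_tol = 0.02,
                                    min_cells = 4L, area_tol = 0.05) {
  fp <- focus_point(field, plateau_tol, min_cells, area_tol)
  d <- fp$point - field$centroid
  celld <- sqrt((field$x[2L] - field$x[1L])^2 + (field$y[2L] - field$y[1L])^2)
  if (sqrt(sum(d^2)) <= celld) {
    stop("vertefem_undefined_angle_error: focus point coincides with the ",
         "section centroid (within one grid cell)", call. = FALSE)
  }
  ell <- field$ell
  ang <- deg(atan2(ell[1L] * d[2L] - ell[2L] * d[1L], sum(ell * d)))
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' @export
print.planar_field <- function(x, ...) {
  cat("<planar_field> ", length(x$x), "x", length(x$y), " grid, ",
      sum(x$mask), " points in section, value range [",
      format(min(x$values, na.rm = TRUE)), ", ",
      format(max(x$values, na.rm = TRUE)), "] MPa\n", sep = "")
  invisible(x)
}

#' @export
print.focus_point <- function(x, ...) {
  cat("<focus_point> (", format(x$point[1L]), ", ", format(x$point[2L]),
      ") mm, kind = ", x$kind, ", area = ", format(x$component_area),
      " mm^2, ", nrow(x$candidates), " candidate component(s)\n", sep = "")
  invisible(x)
}

#' Tidy a planar field into a tibble
#'
#' @param x A `planar_field`.
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `energy_density` for in-section points.
#' @method as_tibble planar_field
#' @export
as_tibble.planar_field <- function(x, ...) {
  gx <- rep(x$x, times = length(x$y))
  gy <- rep(x$y, each = length(x$x))
  gv <- as.vector(x$values)
  grid <- tibble::tibble(x = gx, y = gy, energy_density = gv)
  grid[!is.na(grid$energy_density), ]
}
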