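# Structured tetrahedral meshing of swept (extruded) solids.
#
# All solids in the segment model are swept bodies over a common triangulated
# unit-disc cross-section: concentric rings of nodes (ring k carries 6k nodes)
# triangulated ring-to-ring, then extruded layer by layer along the stacking
# axis.  Each triangular prism between consecutive layers is split into three
# tetrahedra with the minimum-global-index diagonal rule (Dompierre et al.),
# which guarantees that the quad faces of neighbouring prisms are split
# compatibly, i.e. the mesh is conforming without any node duplication.

#' Triangulated unit-disc cross-section grid
#'
#' Builds the reference cross-section used by every swept solid: a centre
#' node plus `n_rings` concentric rings, ring `k` holding `8k` equally
#' spaced nodes at radius `k / n_rings`, triangulated into `8 n_rings^2`
#' triangles.  One quarter is triangulated explicitly and replicated by the
#' two axis reflections, so the triangulation is exactly symmetric under
#' x -> -x and y -> -y; together with the reflection-invariant node
#' `priority` (used for prism-diagonal selection during extrusion) this
#' makes swept meshes of mirrored solids exact mirror images.
#'
#' @param n_rings Number of concentric node rings (>= 1).
#' @return A list with `uv` (n x 2 node coordinates in the unit disc),
#'   `tri` (m x 3 triangle node indices, counter-clockwise), `boundary`
#'   (indices of the outermost ring, in angular order) and `priority`
#'   (mirror-invariant strict ordering of the nodes).
#' @export
disc_grid <- function(n_rings) {
  stopifnot(is.numeric(n_rings), length(n_rings) == 1L, n_rings >= 1)
  K <- as.integer(n_rings)
  n_nodes <- 1L + 4L * K * (K + 1L)
  uv <- matrix(0, nrow = n_nodes, ncol = 2L)
  ring_of <- integer(n_nodes)
  j_of <- integer(n_nodes)
  ring_start <- integer(K + 1L) # ring_start[k+1] = first node id of ring k
  ring_start[1L] <- 1L          # ring 0 = centre
  idx <- 1L
  for (k in seq_len(K)) {
    ring_start[k + 1L] <- idx + 1L
    jj <- seq_len(8L * k) - 1L
    ang <- 2 * pi * jj / (8L * k)
    uv[idx + jj + 1L, ] <- (k / K) * cbind(cos(ang), sin(ang))
    ring_of[idx + jj + 1L] <- k
    j_of[idx + jj + 1L] <- jj
    idx <- idx + 8L * k
  }
  node_id <- function(k, j) {
    if (k == 0L) return(1L)
    ring_start[k + 1L] + (j %% (8L * k))
  }
  # triangulate the first quarter (theta in [0, pi/2]) of each ring strip,
  # then replicate by the two reflections and the half-turn
  tri_list <- vector("list", K)
  # ring 1: fan of 8 triangles around the centre; quarter = 2 triangles
  fan_q <- lapply(0:1, function(j) {
    c(node_id(0L, 0L), node_id(1L, j), node_id(1L, j + 1L))
  })
  tri_list[[1L]] <- do.call(rbind, fan_q)
  if (K >= 2L) {
    for (k in 2:K) {
      m_q <- 2L * (k - 1L) # inner intervals in the quarter
      n_q <- 2L * k        # outer intervals
      inner <- vapply(0:m_q, function(j) node_id(k - 1L, j), integer(1))
      outer <- vapply(0:n_q, function(j) node_id(k, j), integer(1))
      tri_list[[k]] <- strip_triangulate_open(
        inner, outer,
        ang_in = (pi / 2) * (0:m_q) / m_q,
        ang_out = (pi / 2) * (0:n_q) / n_q)
    }
  }
  quarter_tri <- do.call(rbind, tri_list)
  # reflections expressed on (ring, j): sigma_y: j -> -j ; sigma_x: j -> 4k-j
  map_tri <- function(tri, f) {
    t(apply(tri, 1L, function(v) {
      vapply(v, function(id) {
        k <- ring_of[id]
        if (k == 0L) 1L else node_id(k, f(j_of[id], k))
      }, integer(1))
    }))
  }
  s_y <- map_tri(quarter_tri, function(j, k) -j)
  s_x <- map_tri(quarter_tri, function(j, k) 4L * k - j)
  s_xy <- map_tri(quarter_tri, function(j, k) 4L * k + j)
  tri <- rbind(quarter_tri, s_y, s_x, s_xy)
  tri <- tri[!duplicated(t(apply(tri, 1L, sort))), , drop = FALSE]
  # enforce counter-clockwise orientation
  a <- uv[tri[, 1L], ]; b <- uv[tri[, 2L], ]; c <- uv[tri[, 3L], ]
  cw <- (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
    (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L]) < 0
  tri[cw, 2:3] <- tri[cw, 3:2]
  # mirror-invariant priority: (ring, circular distance to the y-axis nodes,
  # j) -- any two nodes sharing a mesh primitive differ before the j tie
  d_axis <- integer(n_nodes)
  for (id in seq_len(n_nodes)) {
    k <- ring_of[id]
    if (k == 0L) next
    per <- 8L * k
    dd <- abs(j_of[id] - c(2L * k, 6L * k))
    d_axis[id] <- min(pmin(dd, per - dd))
  }
  priority <- order(ring_of, d_axis, j_of)
  priority <- match(seq_len(n_nodes), priority) # rank of each node
  list(uv = uv, tri = tri,
       boundary = ring_start[K + 1L] + seq_len(8L * K) - 1L,
       priority = priority)
}

# Triangulate the open strip between two concentric node arcs sharing their
# endpoint angles (two-pointer merge by angle).  `inner`/`outer` are global
# node ids including both endpoints.  Returns
# (length(inner) + length(outer) - 2) x 3 triangles.
strip_triangulate_open <- function(inner, outer, ang_in, ang_out) {
  li <- length(inner); lo <- length(outer)
  tri <- matrix(0L, nrow = li + lo - 2L, ncol = 3L)
  i <- 1L; j <- 1L
  for (t in seq_len(li + lo - 2L)) {
    advance_outer <- j < lo && (i >= li || ang_out[j + 1L] <= ang_in[i + 1L])
    if (advance_outer) {
      tri[t, ] <- c(outer[j], outer[j + 1L], inner[i])
      j <- j + 1L
    } else {
      tri[t, ] <- c(inner[i], outer[j], inner[i + 1L])
      i <- i + 1L
    }
  }
  tri
}

# Split one triangular prism into 3 tetrahedra with the minimum-priority
# rule (Dompierre et al.).  v = 6 global node ids, bottom triangle
# (v1,v2,v3), top (v4,v5,v6), v4 above v1; `pr` is a strict total order on
# nodes.  Neighbouring prisms sharing a quad face receive the same diagonal,
# so the meshes conform; with the mirror-invariant grid priority, mirrored
# meshes receive mirrored diagonals.
prism_split <- function(v, pr) {
  rot <- function(p) p[c(2L, 3L, 1L, 5L, 6L, 4L)]
  flip <- function(p) p[c(4L, 6L, 5L, 1L, 3L, 2L)]
  perms <- list(v, rot(v), rot(rot(v)))
  perms <- c(perms, lapply(perms, flip))
  w <- perms[[which.min(vapply(perms, function(p) pr[p[1L]], numeric(1)))[1L]]]
  if (min(pr[w[2L]], pr[w[6L]]) < min(pr[w[3L]], pr[w[5L]])) {
    rbind(w[c(1L, 2L, 3L, 6L)], w[c(1L, 2L, 6L, 5L)], w[c(1L, 5L, 6L, 4L)])
  } else {
    rbind(w[c(1L, 2L, 3L, 5L)], w[c(1L, 5L, 3L, 6L)], w[c(1L, 5L, 6L, 4L)])
  }
}

# Tetrahedralize the extrusion of cross-section triangles `tri` through
# `n_layers + 1` node layers of `n_cross` nodes each (layer l occupies global
# node ids (l-1)*n_cross + 1 .. l*n_cross).  `cross_priority` (default: the
# node index) orders nodes within a layer for diagonal selection.
extrude_tets <- function(tri, n_cross, n_layers, cross_priority = NULL) {
  cross_priority <- cross_priority %||% seq_len(n_cross)
  pr <- as.vector(outer(cross_priority, (seq_len(n_layers + 1L) - 1L) *
                          n_cross, `+`))
  out <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lo <- (l - 1L) * n_cross
    hi <- l * n_cross
    tets <- matrix(0L, nrow = 3L * nrow(tri), ncol = 4L)
    for (t in seq_len(nrow(tri))) {
      v <- c(tri[t, ] + lo, tri[t, ] + hi)
      tets[(3L * t - 2L):(3L * t), ] <- prism_split(v, pr)
    }
    out[[l]] <- tets
  }
  do.call(rbind, out)
}

# Signed tetrahedron volumes; mesh constructors reorder nodes so these are
# positive.
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - a
  e2 <- nodes[tets[, 3L], , drop = FALSE] - a
  e3 <- nodes[tets[, 4L], , drop = FALSE] - a
  (e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
     e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
     e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])) / 6
}

orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  tets[neg, 3:4] <- tets[neg, 4:3]
  tets
}

#' Total volume of a tetrahedral mesh or meshed solid
#'
#' @param x A mesh (list with `nodes`, `tets`), a `solid_model`, or a
#'   `spine_model`.
#' @param ... Passed to the mesh generator for analytic solids.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(x, ...) {
  m <- as_mesh(x, ...)
  sum(tet_volumes(m$nodes, m$tets))
}

mesh_centroid <- function(mesh) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  cent <- (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
             mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
             mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
             mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
  colSums(cent * v) / sum(v)
}

# All boundary faces of a tet mesh (faces belonging to exactly one tet),
# returned as a k x 3 matrix with outward orientation not guaranteed.
boundary_faces <- function(tets) {
  faces <- rbind(tets[, c(1L, 2L, 3L)], tets[, c(1L, 2L, 4L)],
                 tets[, c(1L, 3L, 4L)], tets[, c(2L, 3L, 4L)])
  lo <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  hi <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  mid <- as.numeric(faces[, 1L]) + faces[, 2L] + faces[, 3L] - lo - hi
  n1 <- max(hi) + 1
  key <- (lo * n1 + mid) * n1 + hi # exact in doubles for n < ~2e5 nodes
  r <- rle(sort(key))
  faces[key %in% r$values[r$lengths == 1L], , drop = FALSE]
}

triangle_areas <- function(nodes, tri) {
  a <- nodes[tri[, 1L], , drop = FALSE]
  e1 <- nodes[tri[, 2L], , drop = FALSE] - a
  e2 <- nodes[tri[, 3L], , drop = FALSE] - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

triangle_centroids <- function(nodes, tri) {
  (nodes[tri[, 1L], , drop = FALSE] + nodes[tri[, 2L], , drop = FALSE] +
     nodes[tri[, 3L], , drop = FALSE]) / 3
}

#' Total area of a tagged triangle patch
#'
#' @param mesh A mesh with `nodes`.
#' @param tri k x 3 triangle node-index matrix (a boundary tag).
#' @return Area in mm^2.
#' @export
face_area <- function(mesh, tri) sum(triangle_areas(mesh$nodes, tri))

# Least-squares plane through a set of points: returns list(point, normal).
fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  n <- sv$v[, 3L]
  list(point = ctr, normal = n / sqrt(sum(n^2)))
}

# Area-weighted centroid and unit normal of a tagged planar face.
face_frame <- function(mesh, tri) {
  ar <- triangle_areas(mesh$nodes, tri)
  ctr <- colSums(triangle_centroids(mesh$nodes, tri) * ar) / sum(ar)
  pl <- fit_plane(mesh$nodes[unique(as.vector(tri)), , drop = FALSE])
  n <- pl$normal
  if (n[3L] < 0) n <- -n # orient towards +z (upwards)
  list(centroid = ctr, normal = n, area = sum(ar))
}

#' Dihedral angle between the top and bottom faces of a meshed solid
#'
#' Fits planes to the tagged top and bottom boundary patches and returns the
#' angle between their normals, the standard readout for wedge recovery.
#'
#' @param x A `solid_model` or a mesh with `tags$top_face` / `tags$bottom_face`.
#' @param ... Passed to the mesh generator.
#' @return Angle in degrees in \[0, 90\).
#' @export
face_dihedral <- function(x, ...) {
  m <- as_mesh(x, ...)
  nt <- fit_plane(m$nodes[unique(as.vector(m$tags$top_face)), , drop = FALSE])$normal
  nb <- fit_plane(m$nodes[unique(as.vector(m$tags$bottom_face)), , drop = FALSE])$normal
  deg(acos(pmin(1, abs(sum(nt * nb)))))
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180
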