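# File interfaces: parameter sets and cohorts as JSON/YAML, landmark sets
# as JSON/CSV, meshes and solutions as legacy-ASCII VTK, surfaces as STL.

#' Write / read vertebra parameter sets
#'
#' A patient file holds the three [vertebra_params()] (lower, apex, upper),
#' the disc gaps, the sacrum angle and the apex rotation, as YAML or JSON
#' (chosen by file extension).
#'
#' @param row One row of a [generate_cohort()] tibble.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @export
write_patient <- function(row, path) {
  obj <- list(patient = row$patient,
              apex_rotation_deg = row$apex_rotation_deg,
              sacrum_angle_deg = row$sacrum_angle_deg,
              disc_gaps_mm = row$disc_gaps_mm[[1L]],
              lower = unclass(row$lower[[1L]]),
              apex = unclass(row$apex[[1L]]),
              upper = unclass(row$upper[[1L]]))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 12L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_patient
#' @param path Input path.
#' @return `read_patient`: a one-row tibble compatible with
#'   [simulate_patient()].
#' @export
read_patient <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vp <- function(l) do.call(vertebra_params, l[setdiff(names(l), NULL)])
  tibble::tibble(patient = obj$patient,
                 apex_rotation_deg = obj$apex_rotation_deg,
                 sacrum_angle_deg = obj$sacrum_angle_deg,
                 coronal_wedge_deg = obj$apex$wedge_top_cor_deg +
                   obj$apex$wedge_bot_cor_deg,
                 lower = list(vp(obj$lower)), apex = list(vp(obj$apex)),
                 upper = list(vp(obj$upper)),
                 disc_gaps_mm = list(as.numeric(obj$disc_gaps_mm)))
}

#' Read a landmark set from JSON or CSV
#'
#' JSON: an object of named 3-vectors.  CSV: columns `landmark`, `x`, `y`,
#' `z` (mm, bed frame).
#'
#' @param path File path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    args <- lapply(obj, as.numeric)
  } else {
    df <- utils::read.csv(path)
    stopifnot(all(c("landmark", "x", "y", "z") %in% names(df)))
    args <- stats::setNames(
      lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, c("x", "y", "z")])),
      df$landmark)
  }
  do.call(landmark_set, args)
}

#' Export a mesh (and optionally a solution) as legacy-ASCII VTK
#'
#' Writes an unstructured-grid VTK file with domain labels as cell data;
#' when a solution is supplied, nodal displacements are written as point
#' data and von Mises stress / distortion-energy density as cell data.
#'
#' @param x A mesh, `solid_model` or `spine_model`.
#' @param path Output `.vtk` path.
#' @param solution Optional `fem_solution`.
#' @export
write_vtk <- function(x, path, solution = NULL) {
  mesh <- as_mesh(x)
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "vertefem unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  utils::write.table(format(mesh$nodes, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("CELLS", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(10L, m)), con)
  cell_blocks <- character(0)
  if (!is.null(mesh$domain)) {
    cell_blocks <- c(cell_blocks, "SCALARS domain int 1",
                     "LOOKUP_TABLE default", as.character(mesh$domain))
  }
  if (!is.null(solution)) {
    writeLines(c(paste("POINT_DATA", n), "VECTORS displacement double"), con)
    utils::write.table(format(solution$U, digits = 10), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    cell_blocks <- c(cell_blocks,
                     "SCALARS von_mises double 1", "LOOKUP_TABLE default",
                     format(solution$von_mises, digits = 10),
                     "SCALARS distortion_energy double 1",
                     "LOOKUP_TABLE default",
                     format(solution$energy_density, digits = 10))
  }
  if (length(cell_blocks) > 0L) {
    writeLines(paste("CELL_DATA", m), con)
    writeLines(cell_blocks, con)
  }
  invisible(path)
}

#' Export the boundary surface of a mesh as ASCII STL
#'
#' @param x A mesh, `solid_model` or `spine_model`.
#' @param path Output `.stl` path.
#' @export
write_stl <- function(x, path) {
  mesh <- as_mesh(x)
  tri <- boundary_faces(mesh$tets)
  a <- mesh$nodes[tri[, 1L], , drop = FALSE]
  b <- mesh$nodes[tri[, 2L], , drop = FALSE]
  c <- mesh$nodes[tri[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vertefem", con)
  for (k in seq_len(nrow(tri))) {
    writeLines(c(sprintf("  facet normal %g %g %g", nrm[k, 1L], nrm[k, 2L],
                         nrm[k, 3L]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", a[k, 1L], a[k, 2L], a[k, 3L]),
                 sprintf("      vertex %g %g %g", b[k, 1L], b[k, 2L], b[k, 3L]),
                 sprintf("      vertex %g %g %g", c[k, 1L], c[k, 2L], c[k, 3L]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid vertefem", con)
  invisible(path)
}
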