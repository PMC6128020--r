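# Image-derived angle measurements formalised as pure geometry on supplied
# landmark coordinates (mm, scanner-bed frame: +z up, +x patient-left,
# +y anterior).  Landmark picking itself happens in the PACS viewer and is
# out of scope; this module reproduces the two manual measurements: the
# apex axial rotation (Aaro-Dahlborn variant through the neural groove) and
# the sacrum-to-table angle with its sacrum line.

#' Bundle a landmark set
#'
#' @param neural_groove,body_symmetry_point,sternum_mid 3-vectors (mm) for
#'   the apex-rotation measurement: the neural groove, a second point on the
#'   vertebral-body symmetry line, and the exterior mid of the sternum.
#' @param promontorium 3-vector, promontorium sacrum.
#' @param foramen_left,foramen_right Most anterior points of the two
#'   foramina in the axial view.
#' @param notch_left,notch_right Valley points of the superior sacral
#'   notches.
#' @param si_joint_left,si_joint_right Frontolateral (anterosuperior) points
#'   of the sacroiliac joints.
#' @return A `landmark_set` list.
#' @export
landmark_set <- function(neural_groove, body_symmetry_point, sternum_mid,
                         promontorium, foramen_left, foramen_right,
                         notch_left, notch_right,
                         si_joint_left, si_joint_right) {
  lm <- list(neural_groove = neural_groove,
             body_symmetry_point = body_symmetry_point,
             sternum_mid = sternum_mid, promontorium = promontorium,
             foramen_left = foramen_left, foramen_right = foramen_right,
             notch_left = notch_left, notch_right = notch_right,
             si_joint_left = si_joint_left, si_joint_right = si_joint_right)
  ok <- vapply(lm, function(p) is.numeric(p) && length(p) == 3L &&
                 all(is.finite(p)), logical(1))
  if (!all(ok)) {
    stop("vertefem_parameter_error: landmarks must be finite 3-vectors (",
         paste(names(lm)[!ok], collapse = ", "), ")", call. = FALSE)
  }
  for (pair in list(c("foramen_left", "foramen_right"),
                    c("notch_left", "notch_right"),
                    c("si_joint_left", "si_joint_right"))) {
    if (sqrt(sum((lm[[pair[1L]]] - lm[[pair[2L]]])^2)) < 1e-9) {
      stop("vertefem_degenerate_landmark_error: ", pair[1L], " and ",
           pair[2L], " coincide", call. = FALSE)
    }
  }
  structure(lm, class = "landmark_set")
}

project_to_plane <- function(p, normal) {
  n <- normal / sqrt(sum(normal^2))
  p - sum(p * n) * n
}

#' Apex axial rotation (Aaro-Dahlborn variant through the neural groove)
#'
#' Projects the three landmarks to the measurement plane and returns the
#' unsigned angle between the body-symmetry line and the groove-to-sternum
#' line, both anchored at the neural groove.
#'
#' @param neural_groove,body_symmetry_point,sternum_mid 3-vectors, mm.
#' @param plane_normal Normal of the (axial, possibly tilted) measurement
#'   plane; default c(0, 0, 1).
#' @return Angle in degrees in \[0, 180).
#' @export
apex_rotation <- function(neural_groove, body_symmetry_point, sternum_mid,
                          plane_normal = c(0, 0, 1)) {
  g <- project_to_plane(neural_groove, plane_normal)
  s <- project_to_plane(body_symmetry_point, plane_normal)
  t <- project_to_plane(sternum_mid, plane_normal)
  d1 <- s - g
  d2 <- t - g
  if (sqrt(sum(d1^2)) < 1e-9 || sqrt(sum(d2^2)) < 1e-9) {
    stop("vertefem_degenerate_landmark_error: projected landmarks coincide ",
         "with the neural groove", call. = FALSE)
  }
  ang <- deg(acos(pmin(1, pmax(-1, sum(d1 * d2) /
                                 sqrt(sum(d1^2) * sum(d2^2))))))
  if (ang >= 180) ang <- 0
  ang
}

#' A-posteriori symmetry check of the chosen body-symmetry line
#'
#' Intersects a circle centred at the neural groove with a boundary
#' polyline (e.g. the interior boundary of the sacral canal); the chosen
#' symmetry line should bisect the angle subtended at the groove by the two
#' intersection points.  Returns the deviation between line and bisector
#' (0 = perfectly symmetric choice).
#'
#' @param neural_groove,body_symmetry_point 3-vectors defining the line
#'   (projected to the axial plane z = const).
#' @param boundary_points k x 3 (or k x 2) matrix of polyline vertices.
#' @param radius Circle radius, mm.
#' @return Deviation angle in degrees in \[0, 90\].
#' @export
symmetry_bisector_check <- function(neural_groove, body_symmetry_point,
                                    boundary_points, radius) {
  stopifnot(radius > 0, is.matrix(boundary_points),
            nrow(boundary_points) >= 2L)
  g <- neural_groove[1:2]
  line_dir <- (body_symmetry_point - neural_groove)[1:2]
  line_dir <- line_dir / sqrt(sum(line_dir^2))
  bp <- boundary_points[, 1:2, drop = FALSE]
  hits <- list()
  for (k in seq_len(nrow(bp) - 1L)) {
    a <- bp[k, ] - g
    b <- bp[k + 1L, ] - g
    d <- b - a
    # |a + t d|^2 = r^2
    qa <- sum(d^2); qb <- 2 * sum(a * d); qc <- sum(a^2) - radius^2
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0 || qa == 0) next
    for (t in (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa)) {
      if (t >= 0 && t < 1) hits[[length(hits) + 1L]] <- a + t * d
    }
  }
  if (length(hits) != 2L) {
    stop("vertefem_check_inapplicable_error: circle of radius ", radius,
         " intersects the boundary in ", length(hits),
         " points (need exactly 2)", call. = FALSE)
  }
  u1 <- hits[[1L]] / sqrt(sum(hits[[1L]]^2))
  u2 <- hits[[2L]] / sqrt(sum(hits[[2L]]^2))
  bis <- u1 + u2
  bis <- bis / sqrt(sum(bis^2))
  deg(acos(pmin(1, abs(sum(bis * line_dir)))))
}

#' Sacrum-to-table angle and sacrum line
#'
#' Implements the five manual steps on coordinates: the measurement plane
#' passes through the promontorium, tilted so that its coronal trace is
#' parallel to the line through the two sacral-notch valleys; the line
#' through the frontolateral sacroiliac-joint points is projected to the
#' axial view and its signed angle to the bed x-axis is returned, positive
#' when the sacrum line is rotated clockwise viewed from above (+z).
#'
#' @param landmarks A [landmark_set()].
#' @return List with `angle_deg` in (-90, 90\], `direction` (unit 3-vector
#'   of the projected sacrum line, oriented towards +x) and `plane_normal`
#'   (normal of the tilted measurement plane).
#' @export
sacrum_table_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  # tilted plane: spanned by the notch-valley line (coronal trace) and the
  # axial trace through the anterior foramina, anchored at the promontorium
  notch_dir <- landmarks$notch_left - landmarks$notch_right
  foramen_dir <- landmarks$foramen_left - landmarks$foramen_right
  nrm <- c(notch_dir[2L] * foramen_dir[3L] - notch_dir[3L] * foramen_dir[2L],
           notch_dir[3L] * foramen_dir[1L] - notch_dir[1L] * foramen_dir[3L],
           notch_dir[1L] * foramen_dir[2L] - notch_dir[2L] * foramen_dir[1L])
  if (sqrt(sum(nrm^2)) < 1e-9) {
    stop("vertefem_degenerate_landmark_error: notch and foramen lines are ",
         "parallel; measurement plane undefined", call. = FALSE)
  }
  nrm <- nrm / sqrt(sum(nrm^2))
  d <- landmarks$si_joint_left - landmarks$si_joint_right
  dxy <- c(d[1:2], 0)
  if (sqrt(sum(dxy^2)) < 1e-9) {
    stop("vertefem_degenerate_landmark_error: sacroiliac joint line is ",
         "vertical; axial projection undefined", call. = FALSE)
  }
  if (dxy[1L] < 0) dxy <- -dxy
  ang <- -deg(atan2(dxy[2L], dxy[1L])) # clockwise-positive viewed from +z
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(angle_deg = ang, direction = dxy / sqrt(sum(dxy^2)),
       plane_normal = nrm)
}
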