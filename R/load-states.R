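# Enumeration of the fifteen load-states.
#
# Five basic states: LS1..LS4 each press one sacrum-aligned quadrant of the
# top face downwards (-z traction), LS5 presses all four.  Each basic state
# is also emitted with additional clockwise and counter-clockwise tangential
# tractions on the lateral shear patches of the uppermost vertebra:
# 5 x {none, cw, ccw} = 15 states.  Every state fixes the bottom face of the
# lowest vertebra, so the non-void fixed/loaded conditions always hold.

#' Enumerate the fifteen load-states
#'
#' @param axial_traction_MPa Downward traction magnitude on the loaded
#'   quadrants, MPa (> 0); the default 1 MPa is the reference load.
#' @param shear_traction_MPa Tangential traction magnitude on the lateral
#'   patches for the cw/ccw variants, MPa (> 0).
#' @return A tibble with one row per state: `state` (LS1..LS5), `shear`
#'   (none/cw/ccw), `name`, `quadrants` (list of loaded quadrant labels),
#'   `axial_MPa`, `shear_MPa`.
#' @export
enumerate_load_states <- function(axial_traction_MPa = 1,
                                  shear_traction_MPa = 0.5) {
  if (!is.finite(axial_traction_MPa) || axial_traction_MPa <= 0 ||
      !is.finite(shear_traction_MPa) || shear_traction_MPa <= 0) {
    stop("vertefem_parameter_error: traction magnitudes must be > 0",
         call. = FALSE)
  }
  quads <- list(LS1 = "q1", LS2 = "q2", LS3 = "q3", LS4 = "q4",
                LS5 = c("q1", "q2", "q3", "q4"))
  grid <- tidyr::expand_grid(state = names(quads),
                             shear = c("none", "cw", "ccw"))
  tibble::tibble(
    state = grid$state,
    shear = grid$shear,
    name = paste0(grid$state,
                  ifelse(grid$shear == "none", "", paste0("_", grid$shear))),
    quadrants = unname(quads[grid$state]),
    axial_MPa = axial_traction_MPa,
    shear_MPa = ifelse(grid$shear == "none", 0, shear_traction_MPa))
}

# Tangential traction matrix (per-triangle rows) for one shear patch.
# `sense` +1 = counter-clockwise about the vertebral axis viewed from +z,
# -1 = clockwise.
shear_traction <- function(spine, tri, magnitude, sense) {
  ax <- spine$shear_axis
  ctr <- triangle_centroids(spine$mesh$nodes, tri)
  rel <- sweep(ctr, 2L, ax$point)
  rel <- rel - (rel %*% ax$axis) %*% t(ax$axis) # radial components
  ttheta <- cbind(ax$axis[2L] * rel[, 3L] - ax$axis[3L] * rel[, 2L],
                  ax$axis[3L] * rel[, 1L] - ax$axis[1L] * rel[, 3L],
                  ax$axis[1L] * rel[, 2L] - ax$axis[2L] * rel[, 1L])
  ttheta <- ttheta / sqrt(rowSums(ttheta^2))
  sense * magnitude * ttheta
}

# Convert one enumerated state row into solver patches.  Requires quadrants
# and (for shear variants) shear patches to be tagged on the spine.
load_state_patches <- function(spine, state_row) {
  stopifnot(!is.null(spine$tags$quadrants))
  patches <- lapply(state_row$quadrants[[1L]], function(q) {
    list(tri = spine$tags$quadrants[[q]],
         traction = c(0, 0, -state_row$axial_MPa))
  })
  if (state_row$shear != "none") {
    stopifnot(!is.null(spine$tags$shear_left))
    sense <- if (state_row$shear == "ccw") 1 else -1
    patches <- c(patches, lapply(c("shear_left", "shear_right"), function(tag) {
      tri <- spine$tags[[tag]]
      list(tri = tri,
           traction = shear_traction(spine, tri, state_row$shear_MPa, sense))
    }))
  }
  patches
}

#' Solve a spine model under enumerated load-states
#'
#' Tags quadrants/shear patches if not yet present, builds every requested
#' load-state and solves them against one Cholesky factorisation.
#'
#' @param spine A `spine_model`.
#' @param stiffness Per-domain stiffness list (see `spine_stiffness`).
#' @param states Tibble from [enumerate_load_states()] (or a subset of its
#'   rows).
#' @param sacrum_angle_deg Sacrum-to-table angle used for the quadrant
#'   subdivision if quadrants are not yet tagged.
#' @param patch_radius_mm,patch_height_fraction Shear patch geometry.
#' @return List with `spine` (tagged) and `solutions` (named by state
#'   `name`).
#' @export
solve_load_states <- function(spine, stiffness, states,
                              sacrum_angle_deg = 0,
                              patch_radius_mm = NULL,
                              patch_height_fraction = 0.5) {
  if (is.null(spine$tags$quadrants)) {
    spine <- top_face_quadrants(spine, sacrum_angle_deg)
  }
  if (any(states$shear != "none") && is.null(spine$tags$shear_left)) {
    patch_radius_mm <- patch_radius_mm %||%
      (0.35 * spine$params$upper$height_mm)
    spine <- lateral_shear_patches(spine, patch_radius_mm,
                                   patch_height_fraction)
  }
  cases <- lapply(seq_len(nrow(states)),
                  function(i) load_state_patches(spine, states[i, ]))
  sols <- fem_solve(spine$mesh, stiffness, spine$tags$bottom_face, cases)
  names(sols) <- states$name
  list(spine = spine, solutions = sols)
}
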