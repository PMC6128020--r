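# Seeded generator of synthetic patient parameter sets with the statistical
# structure the cohort analysis assumes: right-convex thoracic curves whose
# coronal wedge grows linearly with apex axial rotation (plus optional
# Gaussian noise), a slight apical lordosis carried by the sagittal wedge,
# and neighbours with half the apex wedge for a smooth curve.  Apex rotation
# itself has no direct geometric effect on an axisymmetric body; the
# wedge/tilt mapping is the explicit stand-in for severity.

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of patients (>= 2).
#' @param apex_rotation_deg Vector of apex rotations (degrees), one per
#'   patient, or a length-2 range to sample uniformly.  Defaults to the
#'   reference cohort rotations.
#' @param wedge_slope Coronal wedge degrees per degree of apex rotation
#'   (default 0.2).
#' @param wedge_noise_sd_deg Gaussian noise on the apex coronal wedge,
#'   degrees (default 0).
#' @param lordosis_deg Apical sagittal wedge, degrees; negative = lordosis
#'   (default -5).
#' @param sacrum_angle_deg Vector (per patient) or range of sacrum-to-table
#'   angles; defaults to the reference cohort values.
#' @param height_range_mm,radius_range_mm Base geometry ranges for vertebral
#'   heights and face radii (thoracic defaults).
#' @param disc_gap_range_mm Range of disc heights.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 5L,
                        apex_rotation_deg = c(33, 9.7, 49.9, 22.9, 40.5),
                        wedge_slope = 0.2,
                        wedge_noise_sd_deg = 0,
                        lordosis_deg = -5,
                        sacrum_angle_deg = c(-1.5, 7.3, 0.4, 2.1, 2.7),
                        height_range_mm = c(18, 22),
                        radius_range_mm = c(12, 15),
                        disc_gap_range_mm = c(4, 6),
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               apex_rotation_deg = apex_rotation_deg,
               wedge_slope = wedge_slope,
               wedge_noise_sd_deg = wedge_noise_sd_deg,
               lordosis_deg = lordosis_deg,
               sacrum_angle_deg = sacrum_angle_deg,
               height_range_mm = height_range_mm,
               radius_range_mm = radius_range_mm,
               disc_gap_range_mm = disc_gap_range_mm,
               seed = as.integer(seed))
  if (spec$n_patients < 2L) {
    stop("vertefem_parameter_error: need at least 2 patients", call. = FALSE)
  }
  if (spec$wedge_noise_sd_deg < 0) {
    stop("vertefem_parameter_error: noise sd must be >= 0", call. = FALSE)
  }
  for (nm in c("height_range_mm", "radius_range_mm", "disc_gap_range_mm")) {
    r <- spec[[nm]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] <= 0) {
      stop("vertefem_parameter_error: ", nm, " must be a positive ",
           "non-degenerate range", call. = FALSE)
    }
  }
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic cohort of patient parameter sets
#'
#' Deterministic given the spec (including its seed).  The apex coronal
#' wedge is `wedge_slope * apex_rotation + noise`, oriented right-convex
#' (thicker on patient-left, +x); neighbours carry half the apex wedge and
#' lean into the curve; the apical lordosis enters as the sagittal wedge.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per patient: `patient`, `apex_rotation_deg`,
#'   `sacrum_angle_deg`, `coronal_wedge_deg`, list-columns `lower`, `apex`,
#'   `upper` ([vertebra_params()]) and `disc_gaps_mm`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  rng <- withr::with_seed(spec$seed, {
    rot <- spec$apex_rotation_deg
    if (length(rot) == 2L && n != 2L) {
      rot <- stats::runif(n, rot[1L], rot[2L])
    } else if (length(rot) != n) {
      stop("vertefem_parameter_error: apex_rotation_deg must have one value ",
           "per patient or be a range", call. = FALSE)
    }
    sac <- spec$sacrum_angle_deg
    if (length(sac) == 2L && n != 2L) {
      sac <- stats::runif(n, sac[1L], sac[2L])
    } else if (length(sac) != n) {
      stop("vertefem_parameter_error: sacrum_angle_deg must have one value ",
           "per patient or be a range", call. = FALSE)
    }
    list(rot = rot, sac = sac,
         noise = stats::rnorm(n, 0, spec$wedge_noise_sd_deg),
         h = stats::runif(n, spec$height_range_mm[1L],
                          spec$height_range_mm[2L]),
         r = stats::runif(n, spec$radius_range_mm[1L],
                          spec$radius_range_mm[2L]),
         gap = matrix(stats::runif(2L * n, spec$disc_gap_range_mm[1L],
                                   spec$disc_gap_range_mm[2L]), n, 2L))
  })
  wedge <- spec$wedge_slope * rng$rot + rng$noise
  # keep the construction valid: total face wedge stays well inside (-45, 45)
  wedge <- pmin(pmax(wedge, -40), 40)
  purrr::map_dfr(seq_len(n), function(i) {
    w <- wedge[i]
    lord <- spec$lordosis_deg
    h <- rng$h[i]; r <- rng$r[i]
    apex <- vertebra_params(
      height_mm = h, r_lower_mm = r, r_upper_mm = 0.95 * r,
      wedge_top_cor_deg = w / 2, wedge_bot_cor_deg = w / 2,
      wedge_top_sag_deg = lord / 2, wedge_bot_sag_deg = lord / 2)
    lower <- vertebra_params(
      height_mm = h, r_lower_mm = r, r_upper_mm = r,
      wedge_top_cor_deg = w / 4, wedge_bot_cor_deg = w / 4,
      wedge_top_sag_deg = lord / 4, wedge_bot_sag_deg = lord / 4,
      tilt_y_deg = -w / 4)
    upper <- vertebra_params(
      height_mm = h, r_lower_mm = 0.95 * r, r_upper_mm = r,
      wedge_top_cor_deg = w / 4, wedge_bot_cor_deg = w / 4,
      wedge_top_sag_deg = lord / 4, wedge_bot_sag_deg = lord / 4,
      tilt_y_deg = w / 4)
    tibble::tibble(patient = i,
                   apex_rotation_deg = rng$rot[i],
                   sacrum_angle_deg = rng$sac[i],
                   coronal_wedge_deg = w,
                   lower = list(lower), apex = list(apex),
                   upper = list(upper),
                   disc_gaps_mm = list(rng$gap[i, ]))
  })
}

#' Reference cohort metadata
#'
#' The five-patient right-convex idiopathic thoracic cohort used as the
#' default study design: apex levels, Cobb angles, apex rotations,
#' sacrum-to-table angles and ages.
#'
#' @return Tibble with one row per patient.
#' @export
reference_cohort <- function() {
  tibble::tibble(
    patient = 1:5,
    convexity = "Right-convex",
    diagnosis = "Idiopathic",
    apex_level = c("T9", "T7", "T10", "T8", "T9"),
    cobb_angle_deg = c(47, 46, 82, 50, 18),
    apex_rotation_deg = c(33, 9.7, 49.9, 22.9, 40.5),
    sacrum_angle_deg = c(-1.5, 7.3, 0.4, 2.1, 2.7),
    age = c(17, 18, 15, 16, 14))
}

#' Mirror a patient's parameters across the sagittal plane
#'
#' Negates all coronal wedges and y-tilts (and the sacrum angle), producing
#' the left-convex mirror image of a right-convex patient; used by the
#' end-to-end equivariance checks.
#'
#' @param row One row of a [generate_cohort()] tibble.
#' @return The mirrored row.
#' @export
mirror_patient <- function(row) {
  flip <- function(p) {
    vertebra_params(p$height_mm, p$r_lower_mm, p$r_upper_mm,
                    -p$wedge_top_cor_deg, -p$wedge_bot_cor_deg,
                    p$wedge_top_sag_deg, p$wedge_bot_sag_deg,
                    p$tilt_x_deg, -p$tilt_y_deg,
                    p$center_mm * c(-1, 1, 1))
  }
  row$lower[[1L]] <- flip(row$lower[[1L]])
  row$apex[[1L]] <- flip(row$apex[[1L]])
  row$upper[[1L]] <- flip(row$upper[[1L]])
  row$sacrum_angle_deg <- -row$sacrum_angle_deg
  row$coronal_wedge_deg <- -row$coronal_wedge_deg
  row
}
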