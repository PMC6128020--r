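# End-to-end pipeline: cohort -> geometry -> FEM under 15 load-states x
# material models -> response angles -> cohort statistics.

#' Configuration of a full pipeline run
#'
#' @param cohort A [cohort_spec()] or a tibble from [generate_cohort()].
#' @param materials Material set (see [default_materials()]).
#' @param models Material models to run: subset of
#'   `c("isotropic", "orthotropic")`.
#' @param mesh_size_mm Target mesh edge length; `NULL` = `min(r_lower)/5`
#'   per patient.
#' @param axial_MPa,shear_MPa Load magnitudes (MPa).
#' @param patch_radius_mm,patch_height_fraction Shear patch geometry;
#'   `NULL` radius = 0.35 x upper vertebra height.
#' @param resolution Planar-field grid resolution.
#' @param plateau_tol Focus-point plateau tolerance.
#' @param out_dir Optional output directory for CSV/VTK artefacts.
#' @param write_vtk Write one VTK file per solved load-state (default
#'   FALSE; files are large).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_spec(),
                       materials = default_materials(),
                       models = c("isotropic", "orthotropic"),
                       mesh_size_mm = NULL,
                       axial_MPa = 1, shear_MPa = 0.5,
                       patch_radius_mm = NULL, patch_height_fraction = 0.5,
                       resolution = 41L, plateau_tol = 0.02,
                       out_dir = NULL, write_vtk = FALSE) {
  models <- match.arg(models, c("isotropic", "orthotropic"),
                      several.ok = TRUE)
  if (axial_MPa <= 0 || shear_MPa <= 0) {
    stop("vertefem_config_error: load magnitudes must be > 0", call. = FALSE)
  }
  structure(list(cohort = cohort, materials = materials, models = models,
                 mesh_size_mm = mesh_size_mm, axial_MPa = axial_MPa,
                 shear_MPa = shear_MPa, patch_radius_mm = patch_radius_mm,
                 patch_height_fraction = patch_height_fraction,
                 resolution = resolution, plateau_tol = plateau_tol,
                 out_dir = out_dir, write_vtk = write_vtk),
            class = "run_config")
}

#' Simulate one patient under all load-states and material models
#'
#' Builds the segment, tags quadrants and shear patches, solves the fifteen
#' load-states per material model against one factorisation each, and
#' summarises each solution into a focus point and response angle.
#'
#' @param row One row of a [generate_cohort()] tibble.
#' @param config A [run_config()].
#' @return Tibble: one row per (state, shear, material) with `focus_x`,
#'   `focus_y`, `component_area`, `n_candidate_components`, `focus_kind`,
#'   `response_angle_deg` (NA when the focus point coincides with the
#'   centroid), `residual`.
#' @export
simulate_patient <- function(row, config = run_config()) {
  spine <- assemble_spine(row$lower[[1L]], row$apex[[1L]], row$upper[[1L]],
                          row$disc_gaps_mm[[1L]],
                          size = config$mesh_size_mm)
  spine <- top_face_quadrants(spine, row$sacrum_angle_deg)
  patch_r <- config$patch_radius_mm %||%
    (0.35 * spine$params$upper$height_mm)
  spine <- lateral_shear_patches(spine, patch_r,
                                 config$patch_height_fraction)
  states <- enumerate_load_states(config$axial_MPa, config$shear_MPa)
  purrr::map_dfr(config$models, function(model) {
    stiff <- spine_stiffness(spine, config$materials, model)
    solved <- solve_load_states(spine, stiff, states)
    purrr::map_dfr(seq_len(nrow(states)), function(i) {
      sol <- solved$solutions[[states$name[i]]]
      field <- sample_apex_plane(spine, sol, config$resolution)
      fp <- focus_point(field, config$plateau_tol)
      ang <- tryCatch(
        apex_top_response_angle(field, config$plateau_tol),
        error = function(e) NA_real_)
      tibble::tibble(patient = row$patient,
                     apex_rotation_deg = row$apex_rotation_deg,
                     sacrum_angle_deg = row$sacrum_angle_deg,
                     state = states$state[i], shear = states$shear[i],
                     material = model,
                     focus_x = fp$point[1L], focus_y = fp$point[2L],
                     component_area = fp$component_area,
                     focus_kind = fp$kind,
                     n_candidate_components = nrow(fp$candidates),
                     response_angle_deg = ang,
                     residual = sol$residual)
    })
  })
}

#' Run the full cohort pipeline
#'
#' Generates (or accepts) the cohort, simulates every patient under all
#' load-states and material models, computes the cohort statistics and,
#' when `out_dir` is set, writes `responses.csv`, `correlations.csv`,
#' `ttests.csv` and `manifest.json` (config digest, per-stage wall times,
#' output checksums).  Deterministic given the cohort spec seed.
#'
#' @param config A [run_config()].
#' @return List with `responses` (long tibble), `report`
#'   ([run_cohort()] output) and `manifest`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  cohort <- if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)
  } else {
    config$cohort
  }
  stages <- list()
  responses <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    t0 <- Sys.time()
    out <- simulate_patient(cohort[i, ], config)
    stages[[paste0("patient_", cohort$patient[i])]] <<-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  })
  t0 <- Sys.time()
  report <- run_cohort(responses)
  stages[["cohort_stats"]] <- as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("vertefem")),
    r_version = as.character(getRversion()),
    n_patients = nrow(cohort),
    models = config$models,
    n_load_states = 15L,
    config_digest = config_digest(config),
    stage_seconds = stages,
    total_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(responses = "responses.csv",
               correlations = "correlations.csv", ttests = "ttests.csv")
    utils::write.csv(responses, file.path(config$out_dir, files["responses"]),
                     row.names = FALSE)
    utils::write.csv(report$correlations,
                     file.path(config$out_dir, files["correlations"]),
                     row.names = FALSE)
    utils::write.csv(report$ttests, file.path(config$out_dir, files["ttests"]),
                     row.names = FALSE)
    manifest$files <- lapply(stats::setNames(as.list(files), names(files)),
                             function(f) {
                               path <- file.path(config$out_dir, f)
                               list(name = f, bytes = file.size(path),
                                    sha = file_digest(path))
                             })
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(responses = responses, report = report, manifest = manifest)
}

# Order-stable digest of the run configuration (31-base rolling checksum
# over the deparsed config; identification only, not cryptographic).
config_digest <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "materials")]),
               collapse = "")
  rolling_checksum(as.integer(charToRaw(txt)))
}

file_digest <- function(path) {
  rolling_checksum(as.integer(readBin(path, "raw", n = file.size(path))))
}

rolling_checksum <- function(bytes) {
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
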