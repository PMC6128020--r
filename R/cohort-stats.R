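# Cohort-level statistics: per-load-state Pearson correlation between apex
# rotation and response angle, and paired t-tests between model variants.
# The standard statistics are delegated to stats::cor / stats::t.test; this
# module owns the cohort bookkeeping (pairing order, condition completeness).

#' Sample correlation between apex rotations and response angles
#'
#' Pearson product-moment correlation of the two per-patient vectors for one
#' load-state.
#'
#' @param A,R Numeric vectors of equal length >= 2 (apex rotations and
#'   response angles).
#' @return Correlation in \[-1, 1\].
#' @export
sample_correlation <- function(A, R) {
  stopifnot(is.numeric(A), is.numeric(R))
  if (length(A) != length(R) || length(A) < 2L) {
    stop("vertefem_parameter_error: vectors must have equal length >= 2",
         call. = FALSE)
  }
  if (stats::sd(A) == 0 || stats::sd(R) == 0) {
    stop("vertefem_zero_variance_error: sample correlation undefined for a ",
         "constant vector", call. = FALSE)
  }
  stats::cor(A, R)
}

#' Two-sided paired t-test
#'
#' Tests the mean of `y - x` against zero (two-sided), the comparison used
#' between model variants (isotropic vs orthotropic, basic vs shear-added).
#'
#' @param x,y Paired numeric vectors (first and second model type).
#' @return Tibble with `t`, `p`, `n`, `mean_diff`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 2L) {
    stop("vertefem_parameter_error: vectors must have equal length >= 2",
         call. = FALSE)
  }
  d <- y - x
  if (stats::sd(d) == 0) {
    stop("vertefem_degenerate_error: all paired differences are equal; ",
         "t statistic undefined", call. = FALSE)
  }
  ht <- stats::t.test(y, x, paired = TRUE, alternative = "two.sided")
  tibble::tibble(t = unname(ht$statistic), p = ht$p.value, n = length(d),
                 mean_diff = mean(d))
}

#' Cohort report: correlations and paired comparisons
#'
#' Takes the long response table of a cohort run and emits (a) the
#' per-basic-load-state correlations between apex rotation and the
#' isotropic, shear-free response angles, (b) the four paired t-tests
#' (basic vs +cw shear, basic vs +ccw shear, ccw vs cw, isotropic vs
#' orthotropic; each over patients x basic load-states pairs), and (c) the
#' load-state with maximal |correlation|.  Pairing is patient-major,
#' load-state-minor.
#'
#' @param responses Tibble with columns `patient`, `state` (LS1..LS5),
#'   `shear` (none/cw/ccw), `material` (isotropic/orthotropic),
#'   `response_angle_deg`, `apex_rotation_deg`.
#' @return A `cohort_report`: list with `correlations`, `ttests`,
#'   `best_state`, `pairing`.
#' @export
run_cohort <- function(responses) {
  req <- c("patient", "state", "shear", "material", "response_angle_deg",
           "apex_rotation_deg")
  missing_cols <- setdiff(req, names(responses))
  if (length(missing_cols) > 0L) {
    stop("vertefem_parameter_error: responses lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  states <- paste0("LS", 1:5)
  patients <- sort(unique(responses$patient))
  need <- tidyr::expand_grid(patient = patients, state = states,
                             shear = c("none", "cw", "ccw"),
                             material = "isotropic")
  need <- dplyr::bind_rows(need,
                           tidyr::expand_grid(patient = patients,
                                              state = states, shear = "none",
                                              material = "orthotropic"))
  have <- dplyr::distinct(responses[, c("patient", "state", "shear",
                                        "material")])
  gaps <- dplyr::anti_join(need, have,
                           by = c("patient", "state", "shear", "material"))
  if (nrow(gaps) > 0L) {
    stop("vertefem_completeness_error: missing conditions, e.g. ",
         paste(utils::head(paste(gaps$patient, gaps$state, gaps$shear,
                                 gaps$material), 5L), collapse = "; "),
         call. = FALSE)
  }

  pick <- function(shear, material) {
    sub <- responses[responses$shear == shear &
                       responses$material == material &
                       responses$state %in% states, ]
    sub <- sub[order(match(sub$patient, patients),
                     match(sub$state, states)), ]
    sub
  }

  iso_basic <- pick("none", "isotropic")
  correlations <- dplyr::summarise(
    dplyr::group_by(iso_basic, .data$state),
    rho = sample_correlation(.data$apex_rotation_deg,
                             .data$response_angle_deg),
    n_patients = dplyr::n(), .groups = "drop")

  comparisons <- list(
    basic_vs_cw = list(pick("none", "isotropic"), pick("cw", "isotropic")),
    basic_vs_ccw = list(pick("none", "isotropic"), pick("ccw", "isotropic")),
    ccw_vs_cw = list(pick("ccw", "isotropic"), pick("cw", "isotropic")),
    iso_vs_ortho = list(pick("none", "isotropic"),
                        pick("none", "orthotropic")))
  ttests <- purrr::map_dfr(names(comparisons), function(nm) {
    pr <- comparisons[[nm]]
    dplyr::bind_cols(tibble::tibble(comparison = nm),
                     paired_ttest(pr[[1L]]$response_angle_deg,
                                  pr[[2L]]$response_angle_deg))
  })

  best <- correlations$state[which.max(abs(correlations$rho))]
  structure(list(correlations = correlations, ttests = ttests,
                 best_state = best,
                 pairing = "patient-major, load-state-minor"),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\nPer-load-state correlations (isotropic, no shear):\n")
  print(as.data.frame(x$correlations), row.names = FALSE)
  cat("\nPaired t-tests:\n")
  print(as.data.frame(x$ttests), row.names = FALSE)
  cat("\nLoad-state with maximal |rho|:", x$best_state, "\n")
  invisible(x)
}

#' Tidy a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return Tibble of the per-load-state correlations.
#' @export
tidy.cohort_report <- function(x, ...) x$correlations

#' One-row summary of a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return Tibble with the best load-state, its correlation, and the
#'   isotropic-vs-orthotropic p-value.
#' @export
glance.cohort_report <- function(x, ...) {
  tibble::tibble(
    best_state = x$best_state,
    best_rho = x$correlations$rho[x$correlations$state == x$best_state],
    n_correlations = nrow(x$correlations),
    n_ttests = nrow(x$ttests),
    p_iso_vs_ortho = x$ttests$p[x$ttests$comparison == "iso_vs_ortho"])
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
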