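# Published reference constants: the fitted dose-response constants of the
# thermal-neutron rat study (one row per marker) and its per-marker
# RARED/RARF table. Shipped as versioned plain-text fixtures under
# inst/extdata/ so the synthetic defaults, the reproduction check and the
# tests all draw on a single source.

ref_path <- function(file) {
  system.file("extdata", file, package = "rardose", mustWork = TRUE)
}

#' Published calibration constants
#'
#' The fitted dose-response constants for each biomarker of the reference
#' thermal-neutron rat study, as a tibble. Parameter columns `p1..p3` are
#' family-specific: linear `a, b`; exponential `A, R0, y0`; quadratic
#' `intercept, B1, B2`. `se1..se3` are the reported standard errors.
#'
#' @return A tibble with one row per marker.
#' @export
reference_constants <- function() {
  tibble::as_tibble(read.csv(ref_path("reference_constants.csv"),
                             stringsAsFactors = FALSE))
}

#' Reference calibration models
#'
#' Builds `calibration_model` objects directly from the published constants
#' (no fitting), with the acute dose domain \[0, 50\] mSv. These are the
#' generating curves of the default synthetic study and the fixtures of the
#' round-trip tests.
#'
#' @param markers Marker ids to include; default all rows of
#'   [reference_constants()].
#' @return Named list of `calibration_model` objects.
#' @export
reference_models <- function(markers = NULL) {
  tab <- reference_constants()
  if (!is.null(markers)) {
    missing <- setdiff(markers, tab$marker_id)
    if (length(missing)) {
      rd_abort(paste0("Unknown marker(s): ", paste(missing, collapse = ", ")),
               "rardose_invalid_input")
    }
    tab <- tab[match(markers, tab$marker_id), ]
  }
  models <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    domain <- c(0, 50)
    k <- switch(row$family,
      linear = list(a = row$p1, b = row$p2),
      exponential = list(A = row$p1, R0 = row$p2, y0 = row$p3),
      quadratic = list(intercept = row$p1, B1 = row$p2, B2 = row$p3)
    )
    errs <- switch(row$family,
      linear = list(a = row$se1, b = row$se2),
      exponential = list(A = row$se1, R0 = row$se2, y0 = row$se3),
      quadratic = list(intercept = row$se1, B1 = row$se2, B2 = row$se3)
    )
    vertex <- NA_real_; monotone <- TRUE; diagnostics <- character()
    if (row$family == "quadratic") {
      vertex <- -row$p2 / (2 * row$p3)
      monotone <- vertex <= domain[1] || vertex >= domain[2]
      if (!monotone) {
        diagnostics <- sprintf(
          "non-monotone on dose domain (vertex at %.4g mSv); invertible on the data-bearing branch only",
          vertex)
      }
    }
    increasing <- switch(row$family,
      linear = row$p1 >= 0,
      exponential = row$p1 * row$p2 > 0,
      quadratic = (row$p2 + 2 * row$p3 *
                     (if (monotone) mean(domain)
                      else mean(c(domain[1], vertex)))) >= 0
    )
    p <- suppressWarnings(as.numeric(row$goodness))
    new_calibration_model(
      row$marker_id, row$family, k, errs, domain,
      direction_label(increasing),
      r_value = row$r_value,
      p_value = p,
      fit_status = if (is.na(p)) row$goodness else "converged",
      n_points = 4L, rss = NA_real_, vertex = vertex,
      monotone = monotone, diagnostics = diagnostics
    )
  })
  names(models) <- tab$marker_id
  models
}

#' Published per-marker RARED/RARF table
#'
#' The reference study's per-marker RAR equivalent doses and RAR factors at
#' the two priming-plus-challenge conditions (5+50 and 10+50 mSv), as
#' printed. Inputs to [reproduce_reference_table()] and the acceptance
#' checks.
#'
#' @return A tibble with columns `marker_id`, `priming_dose_mSv`,
#'   `challenge_dose_mSv`, `rared_mSv`, `rarf`.
#' @export
table7_reference <- function() {
  tibble::as_tibble(read.csv(ref_path("table7_reference.csv"),
                             stringsAsFactors = FALSE))
}

#' Default marker-to-family map
#'
#' Which dose-response family each biomarker is calibrated with, following
#' the reference study: GSH/CAT/CA/TM/OTM/MCV exponential, SOD/EPR/DNA/Hb/RDW
#' linear, MDA/TL quadratic. HCT and MCHC carry no calibration model (their
#' dose response fluctuates) and are absent from the map.
#'
#' @return Named character vector mapping marker id to family.
#' @export
default_marker_families <- function() {
  tab <- reference_constants()
  stats::setNames(tab$family, tab$marker_id)
}
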