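#' Invert a calibration curve: reading to equivalent dose
#'
#' Maps a marker reading back to the equivalent dose through a fitted
#' calibration model — the dose-reconstruction step that turns a
#' primed-plus-challenged group's mean reading into its RAR equivalent dose.
#' Inversion is analytic per family:
#' \itemize{
#'   \item linear: `(reading - b) / a`;
#'   \item exponential: `log((reading - y0) / A) / R0`, defined only when
#'     `(reading - y0) / A > 0`;
#'   \item quadratic: the root of `B2 x^2 + B1 x + (intercept - reading)`
#'     lying on the data-bearing monotone branch; when both roots lie in the
#'     branch-extended interval the one inside the dose domain wins, ties
#'     broken toward the smaller dose.
#' }
#' Extrapolation beyond the fitted dose domain is permitted up to
#' `extrapolation_factor` times the upper bound, flagged via
#' `in_domain = FALSE`; beyond that a range error is raised rather than
#' extrapolating silently. Negative doses are returned unclamped with a
#' `negative-dose` note.
#'
#' @param model A `calibration_model`.
#' @param reading Marker reading (scalar) in the model's response units.
#' @param extrapolation_factor Multiple of the dose-domain upper bound up to
#'   which extrapolated inversions are allowed (default 2).
#' @return A tibble with columns `dose` (mSv), `in_domain` and `branch_note`.
#' @examples
#' m <- fit_linear(dose_points(c(0, 5, 10, 50), 45 + 0.153 * c(0, 5, 10, 50)))
#' invert_dose(m, 52.65)$dose  # 50
#' @export
invert_dose <- function(model, reading, extrapolation_factor = 2) {
  stopifnot(inherits(model, "calibration_model"))
  check_number(reading, "reading")
  stopifnot(length(reading) == 1L)
  k <- model$constants
  lo <- model$dose_domain[1]
  hi <- model$dose_domain[2]
  cap <- extrapolation_factor * hi
  notes <- character()

  dose <- switch(model$family,
    linear = {
      if (k$a == 0) {
        rd_abort("Flat linear model: every dose gives the same reading.",
                 "rardose_flat_model")
      }
      (reading - k$b) / k$a
    },
    exponential = {
      arg <- (reading - k$y0) / k$A
      if (arg <= 0) {
        rd_abort(sprintf(
          "Reading %.6g is beyond the exponential asymptote y0 = %.6g.",
          reading, k$y0), "rardose_domain_error")
      }
      log(arg) / k$R0
    },
    quadratic = {
      if (abs(k$B2) < .Machine$double.eps) {
        if (k$B1 == 0) {
          rd_abort("Flat quadratic model.", "rardose_flat_model")
        }
        (reading - k$intercept) / k$B1
      } else {
        disc <- k$B1^2 - 4 * k$B2 * (k$intercept - reading)
        if (disc < 0) {
          rd_abort(sprintf(
            "Reading %.6g is beyond the quadratic vertex value; unreachable.",
            reading), "rardose_unreachable_reading")
        }
        roots <- sort((-k$B1 + c(-1, 1) * sqrt(disc)) / (2 * k$B2))
        # data-bearing branch: whole domain if monotone, else the lower-dose
        # side of the vertex (doses start at the unexposed control)
        branch <- if (model$monotone) c(-Inf, Inf) else c(-Inf, model$vertex)
        in_branch <- roots >= branch[1] & roots <= branch[2]
        in_dom <- roots >= lo & roots <= hi
        ord <- order(!in_branch, !in_dom, roots)
        cand <- roots[ord]
        note_alt <- if (length(roots) == 2 && any(!in_branch)) {
          sprintf("alternative root %.6g rejected as off-branch",
                  roots[!in_branch][1])
        } else NULL
        notes <- c(notes, note_alt)
        cand[1]
      }
    },
    rd_abort(paste0("Unknown family: ", model$family), "rardose_invalid_input")
  )

  if (!is.finite(dose)) {
    rd_abort("Inversion produced a non-finite dose.", "rardose_domain_error")
  }
  if (dose > cap) {
    rd_abort(sprintf(
      "Inverted dose %.4g mSv exceeds the extrapolation cap %g mSv (%gx the fitted upper bound).",
      dose, cap, extrapolation_factor), "rardose_range_error")
  }
  tol <- 1e-9 * max(1, abs(hi))  # absorb round-trip floating error at edges
  if (dose < -tol) notes <- c(notes, "negative-dose")
  in_dom <- dose >= lo - tol && dose <= hi + tol &&
    (model$monotone || dose <= model$vertex + tol)
  if (!in_dom) notes <- c(notes, "extrapolated beyond fitted dose domain")
  tibble::tibble(
    dose = dose,
    in_domain = in_dom,
    branch_note = paste(notes, collapse = "; ")
  )
}

#' Invert a calibration curve at per-animal readings
#'
#' The per-animal alternative to inverting a single group mean: each
#' reading is inverted separately, yielding a distribution of equivalent
#' doses. Readings whose inversion fails (unreachable, beyond the
#' extrapolation cap) come back as `NA` with the error message in
#' `branch_note`.
#'
#' @inheritParams invert_dose
#' @param readings Numeric vector of per-animal readings.
#' @return A tibble with one row per reading: `reading`, `dose`,
#'   `in_domain`, `branch_note`.
#' @export
invert_readings <- function(model, readings, extrapolation_factor = 2) {
  check_number(readings, "readings")
  rows <- lapply(readings, function(r) {
    res <- tryCatch(invert_dose(model, r, extrapolation_factor),
                    rardose_error = function(e) {
                      tibble::tibble(dose = NA_real_, in_domain = NA,
                                     branch_note = conditionMessage(e))
                    })
    tibble::tibble(reading = r, res)
  })
  do.call(rbind, rows)
}
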