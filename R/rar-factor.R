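#' Dose condition for a priming-plus-challenge exposure
#'
#' Bundles the priming dose \eqn{D_p}, the challenge dose \eqn{D_c} and their
#' accumulated total \eqn{D_{p+c} = D_p + D_c}, all in mSv equivalent dose.
#' These are the dose-side arguments of the RAR factor.
#'
#' @param priming_dose Priming acute dose in mSv (non-negative).
#' @param challenge_dose Challenge dose in mSv (non-negative).
#' @return A `dose_condition` object (a named list with `priming_dose`,
#'   `challenge_dose` and `accumulated_dose`).
#' @examples
#' dose_condition(5, 50)
#' @export
dose_condition <- function(priming_dose, challenge_dose) {
  check_number(priming_dose, "priming_dose")
  check_number(challenge_dose, "challenge_dose")
  stopifnot(length(priming_dose) == 1L, length(challenge_dose) == 1L)
  if (priming_dose < 0 || challenge_dose < 0) {
    rd_abort("Doses must be non-negative.", "rardose_invalid_condition")
  }
  structure(
    list(
      priming_dose = as.numeric(priming_dose),
      challenge_dose = as.numeric(challenge_dose),
      accumulated_dose = as.numeric(priming_dose + challenge_dose)
    ),
    class = "dose_condition"
  )
}

#' @export
print.dose_condition <- function(x, ...) {
  cat(sprintf(
    "<dose_condition> priming %g mSv + challenge %g mSv (accumulated %g mSv)\n",
    x$priming_dose, x$challenge_dose, x$accumulated_dose
  ))
  invisible(x)
}

as_dose_condition <- function(x) {
  if (inherits(x, "dose_condition")) return(x)
  rd_abort("`condition` must be a dose_condition object.",
           "rardose_invalid_condition")
}

#' Radio-adaptive response factor (RARF)
#'
#' Computes the dimensionless RAR factor
#' \deqn{f_{RAR} = 1 - (D_{RAR} - D_p) / D_{p+c}}
#' from an estimated RAR equivalent dose \eqn{D_{RAR}} and a dose condition.
#' A factor of 1 means the primed-plus-challenged group reads like the
#' priming dose alone (full adaptation); smaller values mean weaker
#' adaptation. The raw value is reported without clamping: values outside
#' \[0, 1\] are possible for noisy or inconsistent inputs and are flagged via
#' `in_unit_interval` rather than hidden.
#'
#' @param d_rar RAR equivalent dose(s) in mSv, finite.
#' @param condition A [dose_condition()] with positive accumulated dose.
#' @return A tibble with one row per element of `d_rar` and columns
#'   `rared`, `factor` and `in_unit_interval`.
#' @examples
#' rar_factor(9.7, dose_condition(5, 50))$factor  # ~0.9145
#' @export
rar_factor <- function(d_rar, condition) {
  condition <- as_dose_condition(condition)
  if (condition$accumulated_dose <= 0) {
    rd_abort("accumulated_dose must be positive to compute a RAR factor.",
             "rardose_invalid_condition")
  }
  check_number(d_rar, "d_rar")
  f <- 1 - (d_rar - condition$priming_dose) / condition$accumulated_dose
  tibble::tibble(
    rared = as.numeric(d_rar),
    factor = f,
    in_unit_interval = f >= 0 & f <= 1
  )
}

#' Effective dose implied by a RAR factor
#'
#' Algebraic inverse of [rar_factor()]:
#' \eqn{D_{RAR} = D_p + (1 - f) D_{p+c}}. Used by the synthetic-study
#' generator to place a combined group's mean reading at the dose that
#' encodes a chosen adaptation strength.
#'
#' @param factor Dimensionless RAR factor(s), finite.
#' @param condition A [dose_condition()] with positive accumulated dose.
#' @return Numeric vector of effective doses in mSv.
#' @examples
#' effective_dose_from_factor(1, dose_condition(5, 50))  # 5
#' @export
effective_dose_from_factor <- function(factor, condition) {
  condition <- as_dose_condition(condition)
  if (condition$accumulated_dose <= 0) {
    rd_abort("accumulated_dose must be positive.", "rardose_invalid_condition")
  }
  check_number(factor, "factor")
  condition$priming_dose + (1 - factor) * condition$accumulated_dose
}

#' Priming-dose difference fraction
#'
#' The Yonezawa-scheme difference fraction
#' \deqn{\delta = 1 - N_{p+c} / N_c,}
#' where \eqn{N_{p+c}} is the marker reading of the primed-plus-challenged
#' group and \eqn{N_c} that of the challenge-only group. Positive when the
#' primed group reads lower than the challenge-only group; the sign is
#' meaningful and is never clamped.
#'
#' @param n_pc Reading(s) of the primed-plus-challenged group.
#' @param n_c Reading(s) of the challenge-only group; must be nonzero and in
#'   the same units as `n_pc`.
#' @return Numeric vector of difference fractions.
#' @examples
#' priming_delta(39.66, 100)  # 0.6034
#' @export
priming_delta <- function(n_pc, n_c) {
  check_number(n_pc, "n_pc")
  check_number(n_c, "n_c")
  if (any(n_c == 0)) {
    rd_abort("`n_c` must be nonzero.", "rardose_division_domain")
  }
  1 - n_pc / n_c
}

#' Signed percent change relative to a reference
#'
#' @param value Reading(s).
#' @param reference Nonzero reference reading(s) in the same units.
#' @return `100 * (value - reference) / reference`, signed.
#' @examples
#' percent_change(3, 2)  # +50
#' @export
percent_change <- function(value, reference) {
  check_number(value, "value")
  check_number(reference, "reference")
  if (any(reference == 0)) {
    rd_abort("`reference` must be nonzero.", "rardose_division_domain")
  }
  100 * (value - reference) / reference
}
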