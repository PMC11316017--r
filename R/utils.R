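# Internal condition helpers and small numeric utilities.

rd_abort <- function(message, class, call = sys.call(-1), data = list()) {
  cond <- structure(
    class = c(class, "rardose_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cond)
}

rd_warn <- function(message, class) {
  warning(structure(
    class = c(class, "rardose_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Round half away from zero
#'
#' Decimal rounding as done when reporting table values: ties go away from
#' zero (`0.485` at 2 decimals prints `0.49`, `-0.485` prints `-0.49`),
#' unlike [round()], which rounds ties to even. A tolerance of order 1e-9
#' absorbs binary representation error so that values that are exact halves
#' in decimal round upward. Used only at the reporting layer; computations
#' keep full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(0.485, 2)  # 0.49, where round() gives 0.48
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, is.finite(digits))
  scale <- 10^digits
  z <- abs(x) * scale
  out <- sign(x) * floor(z + 0.5 + 1e-9 * pmax(1, z)) / scale
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

# stopifnot-style scalar check with a classed error
check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) {
    rd_abort(sprintf("`%s` must be numeric.", name), "rardose_invalid_input")
  }
  if (finite && any(!is.finite(x))) {
    rd_abort(sprintf("`%s` must be finite.", name), "rardose_invalid_input")
  }
  invisible(x)
}
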