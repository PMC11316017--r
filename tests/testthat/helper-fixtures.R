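# Shared fixtures: noiseless dose-response points sampled from a model's
# own family, and a brute-force grid inverter used as an independent oracle.

acute_doses <- c(0, 5, 10, 50)

noiseless_points <- function(model, doses = acute_doses) {
  dose_points(doses, predict(model, doses))
}

# independent oracle: argmin |g(x) - reading| on a fine grid
grid_invert <- function(model, reading, lo = NULL, hi = NULL, by = 1e-3) {
  lo <- lo %||% model$dose_domain[1]
  hi <- hi %||% model$dose_domain[2]
  grid <- seq(lo, hi, by = by)
  grid[which.min(abs(predict(model, grid) - reading))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# relative error tolerant of zero truth
rel_err <- function(est, truth) {
  abs(est - truth) / pmax(abs(truth), .Machine$double.eps)
}
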