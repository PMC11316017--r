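# Calibration fitting: exact recovery on noiseless designs, agreement with
# independent closed-form oracles, and the correlation diagnostics.

test_that("fit_linear recovers an exact line and its correlation", {
  pts <- dose_points(acute_doses, 0.153 * acute_doses + 45)
  m <- fit_linear(pts, "EPR")
  expect_equal(m$constants$a, 0.153, tolerance = 1e-12)
  expect_equal(m$constants$b, 45, tolerance = 1e-12)
  expect_equal(m$r_value, 1)
  expect_equal(m$direction, "increasing")
  # decreasing line carries a signed (negative) r
  m2 <- fit_linear(dose_points(acute_doses, -0.0115 * acute_doses + 14.78))
  expect_equal(m2$r_value, -1)
  expect_equal(m2$direction, "decreasing")
})

test_that("fit_linear agrees with the normal-equations oracle on random fixtures", {
  set.seed(42)
  for (i in 1:20) {
    x <- sort(runif(6, 0, 50))
    y <- runif(6, 1, 10)
    m <- fit_linear(dose_points(x, y))
    # brute-force closed form
    a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    b <- mean(y) - a * mean(x)
    expect_equal(m$constants$a, a, tolerance = 1e-10)
    expect_equal(m$constants$b, b, tolerance = 1e-10)
  }
})

test_that("fit_linear flags degenerate designs", {
  expect_error(fit_linear(dose_points(c(5, 5, 5), c(1, 2, 3))),
               class = "rardose_degenerate_design")
  # horizontal line: slope 0, r undefined, flagged
  m <- suppressWarnings(fit_linear(dose_points(acute_doses, rep(7, 4))))
  expect_equal(m$constants$a, 0, tolerance = 1e-12)
  expect_true(is.na(m$r_value))
  expect_match(paste(m$diagnostics, collapse = " "), "zero response variance")
  # two points: interpolating, standard errors flagged undefined
  m2 <- suppressWarnings(fit_linear(dose_points(c(0, 10), c(1, 3))))
  expect_true(all(is.na(unlist(m2$constant_errors))))
})

test_that("fit_exponential recovers generating constants on noiseless points", {
  for (id in c("CAT", "GSH", "TM", "OTM", "MCV")) {
    gen <- reference_models(id)[[1]]
    m <- fit_exponential(noiseless_points(gen), id)
    expect_lt(rel_err(m$constants$A, gen$constants$A), 1e-6)
    expect_lt(rel_err(m$constants$R0, gen$constants$R0), 1e-6)
    expect_lt(rel_err(m$constants$y0, gen$constants$y0), 1e-6)
    expect_equal(m$fit_status, "converged")
    expect_equal(m$r_value, 1, tolerance = 1e-8)
    expect_true(is.na(m$p_value))  # nonlinear fits report status, not p
  }
})

test_that("fit_exponential stays close to truth under replicate noise", {
  gen <- reference_models("GSH")[[1]]
  truth <- unlist(gen$constants)
  set.seed(101)
  ratio <- replicate(50, {
    y <- predict(gen, acute_doses)
    y <- y * (1 + rnorm(4, 0, 0.03))
    m <- fit_exponential(dose_points(acute_doses, y))
    abs(unlist(m$constants)[names(truth)] - truth) /
      unlist(m$constant_errors)[names(truth)]
  })
  # reported-SE-standardized error: well within 3 SE in the typical run
  expect_true(all(apply(ratio, 1, median, na.rm = TRUE) <= 3))
})

test_that("fit_exponential refuses unidentifiable or degenerate input", {
  expect_error(fit_exponential(dose_points(acute_doses, rep(3, 4))),
               class = "rardose_fit_failure")
  expect_error(fit_exponential(dose_points(c(0, 5), c(1, 2))),
               class = "rardose_degenerate_design")
})

test_that("fit_quadratic recovers exact constants, vertex and monotonicity flag", {
  gen <- reference_models("TL")[[1]]
  m <- fit_quadratic(noiseless_points(gen), "TL")
  expect_equal(m$constants$intercept, 6.136, tolerance = 1e-9)
  expect_equal(m$constants$B1, 0.1886, tolerance = 1e-9)
  expect_equal(m$constants$B2, -0.0019, tolerance = 1e-9)
  expect_equal(m$vertex, 0.1886 / (2 * 0.0019), tolerance = 1e-9)  # ~49.6
  expect_false(m$monotone)  # vertex inside [0, 50]
  expect_equal(m$direction, "increasing")
  expect_match(paste(m$diagnostics, collapse = " "), "non-monotone")
})

test_that("fit_quadratic handles interpolating and collinear points", {
  m <- suppressWarnings(fit_quadratic(dose_points(c(0, 10, 20), c(1, 5, 6))))
  expect_lt(m$rss, 1e-20)  # 3 points: exact interpolation
  m2 <- fit_quadratic(dose_points(acute_doses, 2 * acute_doses + 1))
  expect_equal(m2$constants$B2, 0, tolerance = 1e-10)
  expect_error(fit_quadratic(dose_points(c(0, 5), c(1, 2))),
               class = "rardose_degenerate_design")
})

test_that("all three fitters reproduce their own family exactly (noiseless)", {
  fams <- default_marker_families()
  for (id in names(fams)) {
    gen <- reference_models(id)[[1]]
    m <- fit_calibration(noiseless_points(gen), fams[[id]], id)
    truth <- unlist(gen$constants)
    expect_true(all(rel_err(unlist(m$constants)[names(truth)], truth) < 1e-6),
                label = paste("constants recovered for", id))
  }
})

test_that("pearson_r matches a brute-force summation oracle", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    n <- length(x)
    r_brute <- (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    expect_equal(pearson_r(x, y), r_brute, tolerance = 1e-12)
  }
  expect_equal(pearson_r(1:5, 2 * (1:5) + 3), 1)
  expect_equal(pearson_r(1:5, -2 * (1:5)), -1)
  expect_error(pearson_r(1:5, rep(1, 5)),
               class = "rardose_undefined_correlation")
  expect_error(pearson_r(1:2, 1:2), class = "rardose_invalid_input")
})

test_that("correlation_pvalue reproduces the published goodness entries", {
  expect_equal(round(correlation_pvalue(-0.994, 4), 3), 0.006)
  expect_equal(signif(correlation_pvalue(0.9996, 4), 2), 4.0e-4)
  expect_equal(correlation_pvalue(0, 5), 1)
  expect_equal(correlation_pvalue(1, 4), 0)
  expect_equal(correlation_pvalue(-1, 4), 0)
  expect_error(correlation_pvalue(0.5, 2), class = "rardose_invalid_input")
})

test_that("correlation_pvalue is symmetric in sign and decreasing in |r|", {
  rs <- seq(0.05, 0.95, by = 0.1)
  for (n in c(4, 6, 10)) {
    p_pos <- vapply(rs, correlation_pvalue, 0, n = n)
    p_neg <- vapply(-rs, correlation_pvalue, 0, n = n)
    expect_equal(p_pos, p_neg)
    expect_true(all(diff(p_pos) < 0))
  }
})

test_that("linear fit p-values follow the correlation-t convention", {
  # SOD-style decreasing line with slight curvature so |r| < 1
  pts <- dose_points(acute_doses, c(0.6365, 0.6255, 0.6035, 0.5235))
  m <- fit_linear(pts, "SOD")
  expect_equal(m$p_value, correlation_pvalue(m$r_value, 4))
})

test_that("calibration models serialize to JSON and back", {
  models <- list(
    fit_linear(noiseless_points(reference_models("EPR")[[1]]), "EPR"),
    fit_exponential(noiseless_points(reference_models("CAT")[[1]]), "CAT"),
    fit_quadratic(noiseless_points(reference_models("TL")[[1]]), "TL")
  )
  path <- withr::local_tempfile(fileext = ".json")
  calibration_to_json(models, path)
  back <- calibration_from_json(path)
  expect_named(back, c("EPR", "CAT", "TL"))
  for (m in models) {
    b <- back[[m$marker_id]]
    expect_equal(unlist(b$constants), unlist(m$constants))
    expect_equal(b$family, m$family)
    expect_equal(b$dose_domain, m$dose_domain)
    # round-trips to the same inversion behaviour
    expect_equal(invert_dose(b, predict(m, 10))$dose, 10, tolerance = 1e-8)
  }
})
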