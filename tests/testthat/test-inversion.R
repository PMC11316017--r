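# Dose inversion: analytic round trips per family, quadratic branch
# selection against a grid-search oracle, extrapolation guards.

test_that("inversion round-trips forward evaluation for every family", {
  models <- reference_models()
  for (m in models) {
    hi <- if (m$monotone) m$dose_domain[2] else m$vertex - 0.5
    doses <- seq(m$dose_domain[1], hi, length.out = 12)
    for (x in doses) {
      res <- invert_dose(m, predict(m, x))
      expect_equal(res$dose, x, tolerance = 1e-6,
                   label = sprintf("%s at %.2f mSv", m$marker_id, x))
      expect_true(res$in_domain)
    }
  }
})

test_that("inversion matches worked examples from the published constants", {
  epr <- reference_models("EPR")[[1]]
  expect_equal(invert_dose(epr, 52.65)$dose, 50, tolerance = 1e-9)
  cat <- reference_models("CAT")[[1]]
  expect_equal(invert_dose(cat, predict(cat, 10))$dose, 10, tolerance = 1e-9)
  tl <- reference_models("TL")[[1]]
  res <- invert_dose(tl, 7.832)
  expect_equal(res$dose, 10, tolerance = 0.05)
  expect_match(res$branch_note, "89\\.", label = "off-branch root reported")
  # reading at dose 0 returns dose 0
  for (m in reference_models(c("GSH", "Hb", "MDA"))) {
    expect_equal(invert_dose(m, predict(m, 0))$dose, 0, tolerance = 1e-9)
  }
})

test_that("inversion is monotone in the reading, matching curve direction", {
  for (m in reference_models(c("EPR", "GSH", "TM"))) {
    hi <- if (m$monotone) m$dose_domain[2] else m$vertex - 1
    readings <- predict(m, seq(0, hi, length.out = 8))
    doses <- vapply(readings, function(r) invert_dose(m, r)$dose, 0)
    if (m$direction == "increasing") {
      expect_true(all(diff(doses[order(readings)]) > 0))
    } else {
      expect_true(all(diff(doses[order(readings)]) < 0))
    }
  }
})

test_that("quadratic branch selection agrees with a grid-search oracle", {
  for (id in c("MDA", "TL")) {
    m <- reference_models(id)[[1]]
    branch_hi <- m$vertex - 0.25
    for (x in seq(0.5, branch_hi, length.out = 9)) {
      reading <- predict(m, x)
      expect_equal(invert_dose(m, reading)$dose,
                   grid_invert(m, reading, 0, branch_hi),
                   tolerance = 2e-3,
                   label = sprintf("%s reading at %.2f mSv", id, x))
    }
  }
})

test_that("readings beyond the quadratic vertex are unreachable", {
  m <- reference_models("TL")[[1]]
  peak <- predict(m, m$vertex)
  expect_error(invert_dose(m, peak + 0.5),
               class = "rardose_unreachable_reading")
})

test_that("extrapolation is capped and flagged, not silent", {
  epr <- reference_models("EPR")[[1]]
  # beyond the fitted domain but under 2x the upper bound: flagged
  res <- invert_dose(epr, predict(epr, 75))
  expect_equal(res$dose, 75, tolerance = 1e-9)
  expect_false(res$in_domain)
  expect_match(res$branch_note, "extrapolated")
  # beyond the cap: range error
  expect_error(invert_dose(epr, predict(epr, 120)),
               class = "rardose_range_error")
  # negative doses are returned flagged, unclamped
  neg <- invert_dose(epr, predict(epr, -3))
  expect_equal(neg$dose, -3, tolerance = 1e-9)
  expect_match(neg$branch_note, "negative-dose")
})

test_that("family-specific domain guards raise classed errors", {
  flat <- rardose:::new_calibration_model(
    "flat", "linear", list(a = 0, b = 7), list(a = NA, b = NA),
    c(0, 50), "increasing", NA, NA, "converged", 4L, 0)
  expect_error(invert_dose(flat, 7), class = "rardose_flat_model")
  gsh <- reference_models("GSH")[[1]]
  # below the decay asymptote y0: log argument non-positive
  expect_error(invert_dose(gsh, gsh$constants$y0 - 1),
               class = "rardose_domain_error")
})

test_that("per-animal inversion yields a dose distribution with flagged failures", {
  epr <- reference_models("EPR")[[1]]
  set.seed(4)
  doses <- runif(5, 0, 50)
  res <- invert_readings(epr, predict(epr, doses))
  expect_equal(res$dose, doses, tolerance = 1e-9)
  gsh <- reference_models("GSH")[[1]]
  mixed <- invert_readings(gsh, c(predict(gsh, 10), gsh$constants$y0 - 1))
  expect_equal(mixed$dose[1], 10, tolerance = 1e-9)
  expect_true(is.na(mixed$dose[2]))
  expect_match(mixed$branch_note[2], "asymptote")
})
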