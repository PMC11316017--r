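# Study files, validation, and the command-line shell.

make_demo <- function(dir, seed = 42L, cv = 0.05) {
  cfg <- synthetic_config(cv = cv, seed = seed)
  st <- generate_study(cfg)
  write_study(st$readings, cfg$design, dir, ground_truth = st$ground_truth)
  cfg
}

test_that("a written study reads back field-for-field", {
  dir <- withr::local_tempdir()
  cfg <- make_demo(dir)
  study <- read_study(dir)
  expect_equal(nrow(study$design), 7)
  expect_equal(length(unique(study$readings$marker_id)), 11)
  expect_equal(sum(study$design$n_animals), 35)
  # semantic round trip
  st <- generate_study(cfg)
  expect_equal(as.data.frame(study$readings), as.data.frame(st$readings),
               tolerance = 1e-12)
  expect_equal(as.data.frame(study$design), as.data.frame(cfg$design))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})

test_that("validation lists every cross-reference violation", {
  dir <- withr::local_tempdir()
  make_demo(dir)
  study <- read_study(dir)

  bad_readings <- study$readings
  bad_readings$group_id[1] <- "G9"
  err <- tryCatch(validate_study(bad_readings, study$design),
                  error = function(e) e)
  expect_s3_class(err, "rardose_validation_error")
  expect_match(conditionMessage(err), "G9")

  bad_design <- study$design
  bad_design$role[bad_design$group_id == "G6"] <- "acute"  # has challenge dose
  err2 <- tryCatch(validate_study(study$readings, bad_design),
                   error = function(e) e)
  expect_s3_class(err2, "rardose_validation_error")
  expect_match(conditionMessage(err2), "G6")
  expect_match(conditionMessage(err2), "acute")

  # several problems reported together
  err3 <- tryCatch(validate_study(bad_readings, bad_design),
                   error = function(e) e)
  expect_match(conditionMessage(err3), "G9")
  expect_match(conditionMessage(err3), "G6")

  mixed_units <- study$readings
  mixed_units$units[mixed_units$marker_id == "GSH"][1] <- "mmol/L"
  expect_error(validate_study(mixed_units, study$design),
               regexp = "GSH", class = "rardose_validation_error")
})

test_that("cli simulate + rar compose into a full run", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  expect_equal(rar_cli(c("simulate", "--seed", "42", "--out", dir)), 0L)
  expect_true(file.exists(file.path(dir, "readings.csv")))
  expect_equal(rar_cli(c("rar", dir, "--out", out)), 0L)
  tab <- read.csv(file.path(out, "rar_table.csv"))
  est <- tab[!tab$marker_id %in% c("average", "sd"), ]
  expect_equal(nrow(est), 22)  # 2 conditions x 11 markers
  expect_equal(sum(tab$marker_id == "average"), 2)
})

test_that("cli calibrate and invert work from files", {
  dir <- withr::local_tempdir()
  make_demo(dir, cv = 0)
  json <- file.path(dir, "calibration.json")
  expect_equal(rar_cli(c("calibrate", dir, "--out", json)), 0L)
  expect_true(file.exists(json))
  models <- calibration_from_json(json)
  expect_true(all(c("GSH", "EPR", "TL") %in% names(models)))
  out <- capture.output(
    status <- rar_cli(c("invert", "--model", json, "--marker", "EPR",
                        "--reading", "52.65"))
  )
  expect_equal(status, 0L)
  expect_match(paste(out, collapse = " "), "50")
})

test_that("cli runs are byte-reproducible given the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  rar_cli(c("simulate", "--seed", "7", "--out", d1))
  rar_cli(c("simulate", "--seed", "7", "--out", d2))
  for (f in c("readings.csv", "design.yaml", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  rar_cli(c("rar", d1)); rar_cli(c("rar", d2))
  expect_identical(readLines(file.path(d1, "rar_table.csv")),
                   readLines(file.path(d2, "rar_table.csv")))
})

test_that("cli rejects unknown subcommands and bad input with nonzero status", {
  out <- capture.output(status <- rar_cli("frobnicate"))
  expect_equal(status, 1L)
  expect_match(paste(out, collapse = "\n"), "usage")
  out2 <- capture.output(status2 <- rar_cli(character()))
  expect_equal(status2, 1L)
  expect_equal(rar_cli(c("rar", tempfile())), 1L)
})

test_that("the reproduction check flags exactly the known inconsistent cell", {
  rep <- reproduce_reference_table()
  expect_equal(nrow(rep$cells), 22)
  bad <- rep$cells[!rep$cells$match, ]
  expect_equal(nrow(bad), 1)
  expect_equal(bad$marker_id, "EPR")
  expect_equal(bad$priming_dose, 5)
  expect_equal(rar_cli("reproduce-table7"), 0L)
})

test_that("an optional config file can override a marker's family", {
  dir <- withr::local_tempdir()
  make_demo(dir, cv = 0)
  yaml::write_yaml(list(families = list(DNA = "quadratic")),
                   file.path(dir, "config.yaml"))
  study <- read_study(dir)
  expect_equal(study$config$families[["DNA"]], "quadratic")
  json <- file.path(dir, "calibration.json")
  expect_equal(rar_cli(c("calibrate", dir, "--out", json)), 0L)
  models <- calibration_from_json(json)
  expect_equal(models$DNA$family, "quadratic")
  expect_equal(models$GSH$family, "exponential")  # defaults untouched
  expect_error(read_config(withr::local_tempfile(
    lines = "families:\n  DNA: cubic", fileext = ".yaml")),
    class = "rardose_validation_error")
})
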