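# Plain-text study files: readings.csv (comma-separated, UTF-8, header row,
# dot decimal separator), design.yaml and config.yaml. Doses are always in
# mSv; the unit is part of the column name.

READINGS_COLS <- c("marker_id", "group_id", "animal_index", "value", "units")
DESIGN_COLS <- c("group_id", "role", "priming_dose_mSv",
                 "challenge_dose_mSv", "interval_days", "readout_hr",
                 "n_animals")
ROLES <- c("control", "acute", "rar_control", "combined")

#' Read a per-animal readings file
#'
#' @param path CSV file with columns `marker_id`, `group_id`,
#'   `animal_index`, `value`, `units`.
#' @return Readings tibble.
#' @export
read_readings <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(READINGS_COLS, names(tab))
  if (length(missing)) {
    rd_abort(paste0("Readings file lacks column(s): ",
                    paste(missing, collapse = ", ")),
             "rardose_validation_error")
  }
  tibble::as_tibble(tab[READINGS_COLS])
}

#' Read a study-design file
#'
#' @param path YAML file with a top-level `groups` list; each group carries
#'   `group_id`, `role` (control / acute / rar_control / combined),
#'   `priming_dose_mSv`, `challenge_dose_mSv`, `interval_days`,
#'   `readout_hr`, `n_animals`. Interval fields are accepted (and ignored
#'   downstream) for single-dose groups.
#' @return Design tibble.
#' @export
read_design <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$groups)) {
    rd_abort("Design file must have a top-level `groups` list.",
             "rardose_validation_error")
  }
  rows <- lapply(raw$groups, function(g) {
    missing <- setdiff(DESIGN_COLS, names(g))
    if (length(missing)) {
      rd_abort(sprintf("Design group %s lacks field(s): %s",
                       g$group_id %||% "<unnamed>",
                       paste(missing, collapse = ", ")),
               "rardose_validation_error")
    }
    tibble::tibble(
      group_id = as.character(g$group_id), role = as.character(g$role),
      priming_dose_mSv = as.numeric(g$priming_dose_mSv),
      challenge_dose_mSv = as.numeric(g$challenge_dose_mSv),
      interval_days = as.numeric(g$interval_days),
      readout_hr = as.numeric(g$readout_hr),
      n_animals = as.integer(g$n_animals)
    )
  })
  do.call(rbind, rows)
}

#' Validate a study's cross-referencing invariants
#'
#' Checks, eagerly and collecting every violation into one error message:
#' group ids in the readings exist in the design; doses are non-negative;
#' roles are consistent with doses (combined iff both doses positive, acute
#' iff priming only, rar_control iff challenge only, control iff neither);
#' units are consistent within each marker.
#'
#' @param readings Readings tibble.
#' @param design Design tibble.
#' @return Invisibly `TRUE`; raises a `rardose_validation_error` listing
#'   all violations otherwise.
#' @export
validate_study <- function(readings, design) {
  problems <- character()
  unknown <- setdiff(unique(readings$group_id), design$group_id)
  if (length(unknown)) {
    problems <- c(problems, paste0(
      "readings reference group(s) absent from the design: ",
      paste(unknown, collapse = ", ")))
  }
  bad_dose <- design$priming_dose_mSv < 0 | design$challenge_dose_mSv < 0
  if (any(bad_dose)) {
    problems <- c(problems, paste0("negative dose for group(s): ",
                                   paste(design$group_id[bad_dose],
                                         collapse = ", ")))
  }
  bad_role <- !design$role %in% ROLES
  if (any(bad_role)) {
    problems <- c(problems, paste0("unknown role for group(s): ",
                                   paste(design$group_id[bad_role],
                                         collapse = ", ")))
  }
  for (i in seq_len(nrow(design))) {
    g <- design[i, ]
    if (!g$role %in% ROLES) next
    expected <- switch(g$role,
      control = g$priming_dose_mSv == 0 && g$challenge_dose_mSv == 0,
      acute = g$priming_dose_mSv > 0 && g$challenge_dose_mSv == 0,
      rar_control = g$priming_dose_mSv == 0 && g$challenge_dose_mSv > 0,
      combined = g$priming_dose_mSv > 0 && g$challenge_dose_mSv > 0
    )
    if (!expected) {
      problems <- c(problems, sprintf(
        "group %s: role '%s' inconsistent with doses (%g priming, %g challenge mSv)",
        g$group_id, g$role, g$priming_dose_mSv, g$challenge_dose_mSv))
    }
  }
  units_per_marker <- tapply(readings$units, readings$marker_id,
                             function(u) length(unique(u)))
  mixed <- names(units_per_marker)[units_per_marker > 1]
  if (length(mixed)) {
    problems <- c(problems, paste0("inconsistent units within marker(s): ",
                                   paste(mixed, collapse = ", ")))
  }
  if (length(problems)) {
    rd_abort(paste0("Study validation failed:\n- ",
                    paste(problems, collapse = "\n- ")),
             "rardose_validation_error")
  }
  invisible(TRUE)
}

#' Read an analysis-options file
#'
#' @param path YAML file; recognized fields are `families` (a marker-id to
#'   family map overriding [default_marker_families()]) and
#'   `control_group`.
#' @return Named list of options.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$families)) {
    fam <- unlist(cfg$families)
    bad <- setdiff(fam, c("linear", "exponential", "quadratic"))
    if (length(bad)) {
      rd_abort(paste0("Unknown calibration family: ",
                      paste(bad, collapse = ", ")),
               "rardose_validation_error")
    }
    cfg$families <- fam
  }
  cfg
}

#' Read and validate a study from disk
#'
#' @param dir Directory holding `readings.csv` and `design.yaml` (file
#'   paths may be overridden). An optional `config.yaml` with analysis
#'   options (see [read_config()]) is picked up when present.
#' @param readings_file,design_file,config_file Optional explicit paths.
#' @return List with `readings` and `design` tibbles (validated) and
#'   `config` (possibly `NULL`).
#' @export
read_study <- function(dir = NULL,
                       readings_file = file.path(dir, "readings.csv"),
                       design_file = file.path(dir, "design.yaml"),
                       config_file = file.path(dir, "config.yaml")) {
  for (p in c(readings_file, design_file)) {
    if (!file.exists(p)) {
      rd_abort(paste0("File not found: ", p), "rardose_validation_error")
    }
  }
  readings <- read_readings(readings_file)
  design <- read_design(design_file)
  validate_study(readings, design)
  config <- if (length(config_file) && file.exists(config_file)) {
    read_config(config_file)
  }
  list(readings = readings, design = design, config = config)
}

#' Write a study (and optional ground truth) to disk
#'
#' Writes `readings.csv` and `design.yaml` in the formats [read_study()]
#' reads, plus `ground_truth.json` when a generator ground truth is given.
#'
#' @param readings Readings tibble.
#' @param design Design tibble.
#' @param dir Output directory, created if absent.
#' @param ground_truth Optional ground-truth list from [generate_study()].
#' @return Invisibly, the paths written.
#' @export
write_study <- function(readings, design, dir, ground_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rp <- file.path(dir, "readings.csv")
  dp <- file.path(dir, "design.yaml")
  write.csv(readings, rp, row.names = FALSE)
  groups <- lapply(seq_len(nrow(design)), function(i) {
    as.list(design[i, DESIGN_COLS])
  })
  yaml::write_yaml(list(groups = groups), dp)
  paths <- c(rp, dp)
  if (!is.null(ground_truth)) {
    gp <- file.path(dir, "ground_truth.json")
    gt <- ground_truth
    gt$conditions <- lapply(seq_len(nrow(gt$conditions)), function(i) {
      as.list(gt$conditions[i, ])
    })
    writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), gp)
    paths <- c(paths, gp)
  }
  invisible(paths)
}
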