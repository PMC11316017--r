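# End-to-end orchestration: group summaries -> calibration on the acute
# groups -> dose inversion of the combined groups -> RARED/RARF/delta rows
# and the aggregate report.

#' Per-group marker summaries
#'
#' Mean, sample standard deviation (n - 1 denominator) and count of the
#' per-animal readings in every (marker, group) cell. The SD is `NA` (not 0)
#' for singleton cells.
#'
#' @param readings Tibble with columns `marker_id`, `group_id`, `value`
#'   (and optionally `animal_index`, `units`).
#' @return Tibble with columns `marker_id`, `group_id`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(readings) {
  need <- c("marker_id", "group_id", "value")
  if (!is.data.frame(readings) || !all(need %in% names(readings))) {
    rd_abort("`readings` must have columns marker_id, group_id, value.",
             "rardose_invalid_input")
  }
  key <- interaction(readings$marker_id, readings$group_id, drop = TRUE,
                     sep = "\r")
  parts <- split(readings$value, key)
  ids <- strsplit(names(parts), "\r", fixed = TRUE)
  out <- tibble::tibble(
    marker_id = vapply(ids, `[`, "", 1L),
    group_id = vapply(ids, `[`, "", 2L),
    n = unname(vapply(parts, length, 0L)),
    mean = unname(vapply(parts, mean, 0)),
    sd = unname(vapply(parts,
                       function(v) if (length(v) >= 2) sd(v) else NA_real_,
                       0))
  )
  out[order(out$marker_id, out$group_id), ]
}

acute_groups <- function(design) {
  design[design$challenge_dose_mSv == 0, , drop = FALSE]
}

#' Calibration points for one marker from the acute groups
#'
#' Selects the acute-exposure groups (those with no challenge dose,
#' including the unexposed control) from the design and pairs each group's
#' dose with the marker's group-mean reading. Combined
#' (priming-plus-challenge) and challenge-only groups are excluded from
#' fitting.
#'
#' @param summaries Output of [summarize_groups()].
#' @param design Study-design tibble (see [read_design()]).
#' @param marker_id Marker to extract points for.
#' @return A [dose_points()] tibble, one row per acute group.
#' @export
build_calibration_set <- function(summaries, design, marker_id) {
  ac <- acute_groups(design)
  if (nrow(ac) < 2) {
    rd_abort("Design contains fewer than 2 acute groups.",
             "rardose_incomplete_design")
  }
  if (!any(ac$priming_dose_mSv == 0)) {
    rd_warn(
      "Design has no zero-dose control group; calibration proceeds without an unexposed anchor.",
      "rardose_missing_control")
  }
  ms <- summaries[summaries$marker_id == marker_id, , drop = FALSE]
  idx <- match(ac$group_id, ms$group_id)
  if (anyNA(idx)) {
    rd_abort(sprintf(
      "No readings for marker %s in acute group(s): %s.",
      marker_id, paste(ac$group_id[is.na(idx)], collapse = ", ")),
      "rardose_missing_data")
  }
  dose_points(ac$priming_dose_mSv, ms$mean[idx])
}

group_mean <- function(summaries, marker_id, group_id) {
  hit <- summaries$marker_id == marker_id & summaries$group_id == group_id
  if (!any(hit)) {
    rd_abort(sprintf("No summary for marker %s in group %s.",
                     marker_id, group_id), "rardose_missing_data")
  }
  summaries$mean[hit][1]
}

find_group <- function(design, priming, challenge) {
  hit <- design$priming_dose_mSv == priming &
    design$challenge_dose_mSv == challenge
  if (!any(hit)) {
    rd_abort(sprintf("No design group with priming %g and challenge %g mSv.",
                     priming, challenge), "rardose_incomplete_design")
  }
  design$group_id[hit][1]
}

#' RARED, RARF and delta for one marker at one condition
#'
#' Inverts the marker's calibration curve at the combined
#' (priming-plus-challenge) group's mean reading to get the RAR equivalent
#' dose, applies the RAR-factor formula, and computes the priming-dose
#' difference fraction against the challenge-only control group.
#'
#' @param marker_id Marker label.
#' @param model Fitted `calibration_model` for the marker.
#' @param summaries Output of [summarize_groups()].
#' @param design Study-design tibble.
#' @param condition A [dose_condition()] identifying the combined group.
#' @return One-row tibble: `marker_id`, `priming_dose`, `challenge_dose`,
#'   `reading_used`, `rared`, `factor`, `in_unit_interval`, `delta`,
#'   `in_domain`, `branch_note`.
#' @export
compute_rar_row <- function(marker_id, model, summaries, design, condition) {
  condition <- as_dose_condition(condition)
  combined_id <- find_group(design, condition$priming_dose,
                            condition$challenge_dose)
  rarctl_id <- find_group(design, 0, condition$challenge_dose)
  n_pc <- group_mean(summaries, marker_id, combined_id)
  n_c <- group_mean(summaries, marker_id, rarctl_id)
  inv <- tryCatch(
    invert_dose(model, n_pc),
    rardose_error = function(e) {
      rd_abort(sprintf("Inversion failed for marker %s at %g+%g mSv: %s",
                       marker_id, condition$priming_dose,
                       condition$challenge_dose, conditionMessage(e)),
               class(e)[1])
    }
  )
  fac <- rar_factor(inv$dose, condition)
  tibble::tibble(
    marker_id = marker_id,
    priming_dose = condition$priming_dose,
    challenge_dose = condition$challenge_dose,
    reading_used = n_pc,
    rared = inv$dose,
    factor = fac$factor,
    in_unit_interval = fac$in_unit_interval,
    delta = priming_delta(n_pc, n_c),
    in_domain = inv$in_domain,
    branch_note = inv$branch_note
  )
}

#' Aggregate per-marker RAR estimates into a report table
#'
#' Per condition, the across-marker mean and sample SD (n - 1) of both the
#' RAR equivalent dose and the RAR factor — the bold average/SD columns of
#' the reference study's summary table. No rounding is applied; rendering
#' rounds half away from zero (RARED to 1 decimal, RARF to 2) at print time
#' only.
#'
#' @param estimates Row-bound output of [compute_rar_row()].
#' @return A `rar_table` object: list with `estimates` and `aggregates`
#'   tibbles.
#' @export
aggregate_rar_table <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  key <- paste(estimates$priming_dose, estimates$challenge_dose, sep = "+")
  agg <- lapply(split(estimates, key), function(d) {
    ok <- !is.na(d$rared)  # rows flagged NA (failed marker) are excluded
    tibble::tibble(
      priming_dose = d$priming_dose[1],
      challenge_dose = d$challenge_dose[1],
      n_markers = sum(ok),
      mean_rared = mean(d$rared[ok]),
      sd_rared = if (sum(ok) >= 2) sd(d$rared[ok]) else NA_real_,
      mean_factor = mean(d$factor[ok]),
      sd_factor = if (sum(ok) >= 2) sd(d$factor[ok]) else NA_real_
    )
  })
  aggregates <- do.call(rbind, agg)
  aggregates <- aggregates[order(aggregates$priming_dose), ]
  structure(list(estimates = estimates, aggregates = aggregates),
            class = "rar_table")
}

#' @export
print.rar_table <- function(x, ...) {
  cat("RAR equivalent dose (RARED, mSv) and RAR factor (RARF) per marker\n")
  for (i in seq_len(nrow(x$aggregates))) {
    a <- x$aggregates[i, ]
    d <- x$estimates[x$estimates$priming_dose == a$priming_dose &
                       x$estimates$challenge_dose == a$challenge_dose, ]
    cat(sprintf("\n(%g + %g mSv)\n", a$priming_dose, a$challenge_dose))
    cat("  marker  RARED   RARF\n")
    for (j in seq_len(nrow(d))) {
      cat(sprintf("  %-6s %6.1f  %5.2f%s\n", d$marker_id[j],
                  round_half_away(d$rared[j], 1),
                  round_half_away(d$factor[j], 2),
                  if (nzchar(d$branch_note[j])) " *" else ""))
    }
    cat(sprintf("  %-6s %6.1f  %5.2f\n", "mean",
                round_half_away(a$mean_rared, 1),
                round_half_away(a$mean_factor, 2)))
    cat(sprintf("  %-6s %6.1f  %5.2f\n", "sd",
                round_half_away(a$sd_rared, 1),
                round_half_away(a$sd_factor, 2)))
  }
  flagged <- x$estimates[nzchar(x$estimates$branch_note), ]
  if (nrow(flagged)) {
    cat("\n* ", paste(sprintf("%s (%g+%g): %s", flagged$marker_id,
                              flagged$priming_dose, flagged$challenge_dose,
                              flagged$branch_note), collapse = "\n  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Welch t-tests of every exposed group against the control
#'
#' Two-sided unequal-variance t-test of each (marker, group) cell against
#' the same marker's control-group readings, flagging p <= 0.05 as
#' significant. No multiple-testing correction is applied.
#'
#' @param readings Per-animal readings tibble.
#' @param control_group Id of the unexposed control group (default `"G1"`).
#' @return Tibble with columns `marker_id`, `group_id`, `p_value`,
#'   `significant`.
#' @export
significance_vs_control <- function(readings, control_group = "G1") {
  if (!control_group %in% readings$group_id) {
    rd_abort(sprintf("Control group %s has no readings.", control_group),
             "rardose_missing_data")
  }
  markers <- unique(readings$marker_id)
  groups <- setdiff(unique(readings$group_id), control_group)
  rows <- list()
  for (m in markers) {
    ctl <- readings$value[readings$marker_id == m &
                            readings$group_id == control_group]
    for (g in groups) {
      v <- readings$value[readings$marker_id == m & readings$group_id == g]
      if (length(v) < 2 || length(ctl) < 2) {
        rd_abort(sprintf(
          "Need at least 2 replicates per cell; marker %s group %s has %d (control %d).",
          m, g, length(v), length(ctl)), "rardose_insufficient_replicates")
      }
      # degenerate noiseless limit: both cells constant, Welch t undefined
      p <- if (stats::var(v) == 0 && stats::var(ctl) == 0) {
        if (isTRUE(all.equal(mean(v), mean(ctl)))) 1 else 0
      } else {
        t.test(v, ctl, var.equal = FALSE)$p.value
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker_id = m, group_id = g, p_value = p, significant = p <= 0.05
      )
    }
  }
  do.call(rbind, rows)
}

#' Run the full RAR analysis
#'
#' Summarizes groups, fits one calibration curve per marker over the acute
#' groups, inverts it at each combined group's mean reading, and assembles
#' the RARED/RARF/delta table plus significance tests against the control.
#' Markers without an entry in `families` (e.g. those whose dose response
#' fluctuates and supports no calibration) pass through the summaries and
#' significance tests but get no RAR row.
#'
#' @param readings Per-animal readings tibble (see [read_study()]).
#' @param design Study-design tibble.
#' @param families Named character vector mapping marker id to family;
#'   default [default_marker_families()].
#' @param control_group Id of the unexposed control group, default the
#'   design group with role `"control"`.
#' @return A `rar_analysis` object: list with `summaries`, `models`
#'   (successful fits), `fit_failures` (named messages for markers whose
#'   calibration failed; their estimate rows carry `NA` with the message in
#'   `branch_note`), `estimates`, `table`, `significance`, `design`.
#' @export
run_rar_pipeline <- function(readings, design,
                             families = default_marker_families(),
                             control_group = NULL) {
  summaries <- summarize_groups(readings)
  if (is.null(control_group)) {
    ctl <- design$group_id[design$role == "control"]
    control_group <- if (length(ctl)) ctl[1] else design$group_id[1]
  }
  markers <- intersect(unique(readings$marker_id), names(families))
  models <- list()
  fit_failures <- character()
  for (m in markers) {
    fit <- tryCatch(
      fit_calibration(build_calibration_set(summaries, design, m),
                      families[[m]], marker_id = m),
      rardose_fit_failure = function(e) conditionMessage(e)
    )
    if (is.character(fit)) fit_failures[m] <- fit else models[[m]] <- fit
  }
  combined <- design[design$role == "combined", , drop = FALSE]
  est <- list()
  failed_row <- function(m, cond, note) {
    combined_id <- find_group(design, cond$priming_dose, cond$challenge_dose)
    rarctl_id <- find_group(design, 0, cond$challenge_dose)
    tibble::tibble(
      marker_id = m,
      priming_dose = cond$priming_dose,
      challenge_dose = cond$challenge_dose,
      reading_used = group_mean(summaries, m, combined_id),
      rared = NA_real_, factor = NA_real_, in_unit_interval = NA,
      delta = priming_delta(group_mean(summaries, m, combined_id),
                            group_mean(summaries, m, rarctl_id)),
      in_domain = NA, branch_note = note
    )
  }
  for (i in seq_len(nrow(combined))) {
    cond <- dose_condition(combined$priming_dose_mSv[i],
                           combined$challenge_dose_mSv[i])
    for (m in markers) {
      est[[length(est) + 1L]] <- if (m %in% names(fit_failures)) {
        # a marker whose curve cannot be calibrated keeps its row, flagged,
        # so one fragile marker does not void the rest of the panel
        failed_row(m, cond, paste0("calibration failed: ", fit_failures[m]))
      } else {
        tryCatch(
          compute_rar_row(m, models[[m]], summaries, design, cond),
          rardose_error = function(e) failed_row(m, cond, conditionMessage(e))
        )
      }
    }
  }
  estimates <- do.call(rbind, est)
  structure(
    list(
      summaries = summaries,
      models = models,
      fit_failures = fit_failures,
      estimates = estimates,
      table = aggregate_rar_table(estimates),
      significance = significance_vs_control(readings, control_group),
      design = design
    ),
    class = "rar_analysis"
  )
}

#' @export
print.rar_analysis <- function(x, ...) {
  cat(sprintf("RAR analysis: %d markers, %d groups\n",
              length(unique(x$summaries$marker_id)), nrow(x$design)))
  if (length(x$fit_failures)) {
    cat("calibration failed for:",
        paste(names(x$fit_failures), collapse = ", "), "\n")
  }
  print(x$table)
  invisible(x)
}

#' Write the analysis outputs of a pipeline run
#'
#' Writes `summaries.csv`, `calibration.json`, `rar_table.csv` (per-marker
#' rows plus aggregate rows) and `significance.csv` into `dir`.
#'
#' @param analysis A `rar_analysis` from [run_rar_pipeline()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_rar_outputs <- function(analysis, dir) {
  stopifnot(inherits(analysis, "rar_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("summaries.csv", "calibration.json",
                            "rar_table.csv", "significance.csv"))
  write.csv(analysis$summaries, paths[1], row.names = FALSE)
  calibration_to_json(analysis$models, paths[2])
  est <- analysis$estimates
  agg <- analysis$table$aggregates
  agg_rows <- tibble::tibble(
    marker_id = rep(c("average", "sd"), times = nrow(agg)),
    priming_dose = rep(agg$priming_dose, each = 2),
    challenge_dose = rep(agg$challenge_dose, each = 2),
    reading_used = NA_real_,
    rared = as.vector(rbind(agg$mean_rared, agg$sd_rared)),
    factor = as.vector(rbind(agg$mean_factor, agg$sd_factor)),
    in_unit_interval = NA,
    delta = NA_real_,
    in_domain = NA,
    branch_note = ""
  )
  write.csv(rbind(est, agg_rows), paths[3], row.names = FALSE)
  write.csv(analysis$significance, paths[4], row.names = FALSE)
  invisible(paths)
}
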