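#' Run the full simulate -> QC -> features -> models pipeline
#'
#' Generates (or loads) a cohort, applies the seven-criterion quality check
#' and the exclusion cascade, computes the slowing features, fits the
#' requested mixed-effects models, and writes tidy CSV outputs plus a JSON
#' run manifest with content hashes. Deterministic given the seed.
#'
#' @param out_dir output directory; created if needed.
#' @param cohort a [cohort_config()] (the cohort is simulated) or a list of
#'   `tap_session` objects / a directory of session subdirectories (the
#'   cohort is loaded).
#' @param cfg a [qc_config()].
#' @param models character vector of model names to fit (see
#'   [model_spec()]); may be empty.
#' @param seed integer seed recorded in the manifest; when a
#'   `cohort_config` is supplied its own seed takes precedence.
#' @param write_sessions logical; also write every raw session directory
#'   under `out_dir/sessions/`.
#' @return invisibly, a `tap_report` list: `qc_report`, `exclusion`
#'   (an `exclusion_report`), `features`, `fits` (list of `tap_fit`),
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(out_dir, cohort = cohort_config(),
                         cfg = qc_config(),
                         models = c("max_speed", "relative_decrease",
                                    "absolute_decrease", "time_course"),
                         seed = 1L, write_sessions = FALSE) {
  if (inherits(cohort, "cohort_config")) {
    seed <- cohort$seed
    sessions <- generate_cohort(cohort)
  } else if (is.character(cohort)) {
    dirs <- list.dirs(cohort, recursive = FALSE)
    if (!length(dirs)) stop_param("no session directories under '%s'", cohort)
    sessions <- lapply(dirs, read_session)
  } else {
    sessions <- cohort
  }
  if (!length(sessions)) stop_param("empty cohort")
  # canonical participant order, independent of generation vs. disk layout
  ids <- vapply(sessions, function(s) s$participant$participant_id,
                character(1L))
  sessions <- sessions[order(ids)]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_sessions) {
    for (s in sessions) {
      write_session(s, file.path(out_dir, "sessions",
                                 s$participant$participant_id))
    }
  }
  qc_list <- lapply(sessions, evaluate_session, cfg = cfg)
  qc_report <- do.call(rbind, qc_list)
  exclusion <- exclusion_summary(qc_list, cfg)
  features <- compute_features(qc_list, cfg)
  set.seed(seed)
  fits <- stats::setNames(lapply(models, function(m) {
    d <- if (m == "time_course") time_course_table(features) else features
    fit_lmm(d, model = m)
  }), models)
  effects <- do.call(rbind, lapply(models, function(m) {
    cbind(data.frame(model = m), fits[[m]]$effects,
          n_outliers_removed = fits[[m]]$n_outliers_removed)
  }))
  contrast_tab <- do.call(rbind, lapply(models, function(m) {
    co <- fits[[m]]$contrasts
    if (is.null(co)) NULL else cbind(data.frame(model = m), co)
  }))

  wr <- function(d, f) {
    utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
    f
  }
  files <- c(wr(qc_report, "qc_report.csv"),
             wr(features, "features.csv"),
             wr(exclusion_summary_df(exclusion), "exclusion_summary.csv"))
  if (!is.null(effects)) files <- c(files, wr(effects, "effects.csv"))
  if (!is.null(contrast_tab)) files <- c(files, wr(contrast_tab,
                                                   "contrasts.csv"))
  manifest <- list(
    package = "tapfatigue",
    version = as.character(utils::packageVersion("tapfatigue")),
    seed = seed,
    n_participants = length(sessions),
    models = as.list(models),
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(list(qc_report = qc_report, exclusion = exclusion,
                           features = features, fits = fits,
                           manifest = manifest, out_dir = out_dir),
                      class = "tap_report"))
}

# Flatten an exclusion_report into one tidy CSV-friendly table.
exclusion_summary_df <- function(x) {
  rbind(
    data.frame(section = "criterion", key = as.character(1:7),
               n = x$per_criterion$n_excluded, value = x$per_criterion$pct),
    data.frame(section = "valid_participants_per_finger",
               key = x$fingers$finger, n = x$fingers$n_valid_participants,
               value = NA_real_),
    data.frame(section = "excluded_participants",
               key = x$participants$age_group, n = x$participants$n_excluded,
               value = x$participants$pct_excluded))
}

#' Render a human-readable (or JSON) summary of a pipeline run
#'
#' Prints the per-criterion exclusion table, per-finger group means and
#' standard deviations of the maximal speed and the relative/absolute
#' decreases, and the fixed-effect tables of every fitted model.
#'
#' @param report a `tap_report` from [run_pipeline()].
#' @param json logical; return a machine-readable list (and print its JSON)
#'   instead of formatted text.
#' @return the summary list, invisibly.
#' @export
render_summary <- function(report, json = FALSE) {
  stopifnot(inherits(report, "tap_report"))
  feat <- report$features
  groups <- expand.grid(finger = FINGERS_TAPPING,
                        age_group = c("young", "aged"),
                        stringsAsFactors = FALSE)
  desc <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sub <- feat[feat$finger == groups$finger[i] &
                  feat$age_group == groups$age_group[i], ]
    data.frame(groups[i, ], n = nrow(sub),
               speed_max_mean = mean(sub$speed_max),
               speed_max_sd = stats::sd(sub$speed_max),
               rel_decrease_mean = mean(sub$rel_decrease_pct),
               rel_decrease_sd = stats::sd(sub$rel_decrease_pct),
               abs_decrease_mean = mean(sub$abs_decrease_hz),
               abs_decrease_sd = stats::sd(sub$abs_decrease_hz))
  }))
  out <- list(
    exclusion = list(
      per_criterion = report$exclusion$per_criterion,
      fingers = report$exclusion$fingers,
      participants = report$exclusion$participants),
    group_means = desc,
    effects = lapply(report$fits, `[[`, "effects"),
    contrasts = lapply(report$fits, `[[`, "contrasts"))
  if (json) {
    cat(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows", na = "null"), "\n")
    return(invisible(out))
  }
  print(report$exclusion)
  cat("\nGroup means (+/- SD) per finger:\n")
  for (i in seq_len(nrow(desc))) {
    d <- desc[i, ]
    cat(sprintf(
      "  %-6s %-6s n=%3d  max speed %.2f +/- %.2f Hz  rel. decrease %.1f +/- %.1f %%  abs. decrease %.2f +/- %.2f Hz\n",
      d$age_group, d$finger, d$n, d$speed_max_mean, d$speed_max_sd,
      d$rel_decrease_mean, d$rel_decrease_sd, d$abs_decrease_mean,
      d$abs_decrease_sd))
  }
  for (m in names(report$fits)) {
    cat("\n")
    print(report$fits[[m]])
  }
  invisible(out)
}
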