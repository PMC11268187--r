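#' Write a phasic set as long-format CSV
#'
#' Columns: subject, muscle, role, angle_deg, trial, sample_index, value.
#' A JSON sidecar (`<path>.json`) records the reference angle, the
#' normalization flag and muscle roles, so the set round-trips.
#'
#' @param pset A [phasic_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phasic_csv <- function(pset, path) {
  stopifnot(inherits(pset, "phasic_set"))
  d <- dim(pset$waves)
  long <- data.frame(
    subject = rep(pset$meta$subject, times = d[2] * d[3]),
    muscle = rep(rep(pset$muscles$name, each = d[1]), times = d[3]),
    role = rep(rep(pset$muscles$role, each = d[1]), times = d[3]),
    angle_deg = rep(pset$meta$angle, times = d[2] * d[3]),
    trial = rep(pset$meta$trial, times = d[2] * d[3]),
    sample_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(pset$waves))
  utils::write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(list(reference_angle = pset$reference_angle,
                            normalized = pset$normalized,
                            muscles = pset$muscles),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a phasic set from long-format CSV
#'
#' @param path CSV written by [write_phasic_csv()] (the `.json` sidecar
#'   must sit next to it).
#' @return A [phasic_set()].
#' @export
read_phasic_csv <- function(path) {
  long <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  muscles <- as.data.frame(side$muscles)
  key <- interaction(long$subject, long$angle_deg, long$trial, drop = TRUE)
  trials <- !duplicated(key)
  meta <- data.frame(subject = long$subject[trials],
                     angle = long$angle_deg[trials],
                     trial = long$trial[trials])
  n <- nrow(meta)
  waves <- array(0, dim = c(n, nrow(muscles), max(long$sample_index)))
  row_id <- match(key, key[trials])
  mus_id <- match(long$muscle, muscles$name)
  waves[cbind(row_id, mus_id, long$sample_index)] <- long$value
  phasic_set(waves, meta, muscles,
             reference_angle = side$reference_angle,
             normalized = isTRUE(side$normalized))
}

#' Read or write a generator configuration as YAML
#'
#' Muscle specs are stored as plain lists and revalidated on read.
#'
#' @param config A [generator_config()].
#' @param path YAML file path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a validated `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$muscles <- lapply(x$muscles, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$muscles <- lapply(x$muscles, function(m) {
    do.call(muscle_spec, m)
  })
  do.call(generator_config, x)
}

#' Serialize an analysis report to JSON and CSV files
#'
#' Writes `report.json` (curves, slopes, tests, provenance; every number
#' traceable to the stored per-fold values), long-format CSVs for the
#' tuning curves and the muscle grid, and a plain-text run log. Reruns
#' with the same inputs produce byte-identical output.
#'
#' @param report An `analysis_report` from [run_full_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curve_json <- function(cu) {
    list(points = cu$points,
         fold_accuracies = lapply(cu$cv, `[[`, "fold_accuracies"),
         fold_separability = lapply(cu$cv, `[[`, "sep_values"),
         feature_spec = cu$feature_spec, seed = cu$seed)
  }
  test_json <- function(t) {
    list(method = t$method, statistic = as.list(t$statistic),
         p_value = t$p_value, effect_size = as.list(t$effect_size),
         n_per_group = as.list(t$n_per_group), mode = t$mode)
  }
  payload <- list(
    tuning = curve_json(report$tuning),
    grid = report$grid$grid,
    group_phase = list(
      slopes = report$group_phase$slopes,
      tests = lapply(report$group_phase$tests, test_json),
      control = if (!is.null(report$group_phase$control)) list(
        removed_muscle = report$group_phase$control$removed_muscle,
        slopes = report$group_phase$control$slopes,
        tests = lapply(report$group_phase$control$tests, test_json))),
    negativity = lapply(report$negativity$curves, curve_json),
    updown_comparison = test_json(report$updown_comparison),
    provenance = report$provenance)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$tuning$points,
                   file.path(dir, "tuning_curve.csv"), row.names = FALSE)
  utils::write.csv(report$grid$grid, file.path(dir, "muscle_grid.csv"),
                   row.names = FALSE)
  utils::write.csv(report$negativity$points,
                   file.path(dir, "negativity_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_phase$slopes,
                   file.path(dir, "group_phase_slopes.csv"),
                   row.names = FALSE)
  log_lines <- c(
    "phasictune run log",
    sprintf("package version: %s", report$provenance$package_version),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("classifier: %s", report$provenance$classifier$type),
    sprintf("folds: %d", report$provenance$k),
    sprintf("trials: %d", report$provenance$n_trials),
    sprintf("angles: %s", paste(report$provenance$angles, collapse = " ")))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
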