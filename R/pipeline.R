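comparison_angles <- function(pset) {
  sort(setdiff(unique(pset$meta$angle), pset$reference_angle))
}

role_muscles <- function(pset, role) {
  pset$muscles$name[pset$muscles$role == role]
}

# One cross-validated binary task with optional muscle / phase / transform
# restriction; the workhorse behind every curve and grid cell.
run_task <- function(pset, comparison_angle, muscles = NULL,
                     phase = "full",
                     transform = c("none", "negative", "binary"),
                     classifier = list(type = "lda"), k = 5L, seed = 1L) {
  transform <- match.arg(transform)
  fm <- build_binary_task(pset, comparison_angle)
  if (!is.null(muscles)) fm <- select_muscles(fm, muscles)
  if (phase != "full") fm <- select_phase(fm, phase)
  fm <- switch(transform, none = fm, negative = negative_part(fm),
               binary = binarize_negativity(fm))
  cross_validate(fm, classifier = classifier, k = k, seed = seed)
}

#' Tuning curve: separability of every direction from the horizontal
#'
#' Runs the cross-validated binary task (comparison angle vs the 90-degree
#' reference) for every non-reference angle of the dataset and collects the
#' mean accuracy, the separability index (LDA class-mean distance or SVM
#' margin width) and their standard errors across folds.
#'
#' @param pset A normalized [phasic_set()].
#' @param muscles Optional muscle subset (default: all muscles).
#' @param phase `"full"`, `"acceleration"` or `"deceleration"`.
#' @param transform `"none"`, `"negative"` ([negative_part()]) or
#'   `"binary"` ([binarize_negativity()]).
#' @param classifier Classifier spec, see [cross_validate()].
#' @param k Folds.
#' @param seed Dataset-level seed; each angle's fold seed derives from it.
#' @return A `tuning_curve`: data frame `points` (angle, delta, direction,
#'   mean_accuracy, accuracy_se, separability_index, index_se, n_folds)
#'   plus the stored per-angle `cv_result`s and the feature/classifier
#'   spec.
#' @export
run_tuning_curve <- function(pset, muscles = NULL, phase = "full",
                             transform = "none",
                             classifier = list(type = "lda"),
                             k = 5L, seed = 1L) {
  stopifnot(inherits(pset, "phasic_set"))
  angs <- comparison_angles(pset)
  if (!length(angs)) {
    pt_stop("pt_input_error", "dataset has no non-reference angles")
  }
  cv <- lapply(seq_along(angs), function(i) {
    run_task(pset, angs[i], muscles = muscles, phase = phase,
             transform = transform, classifier = classifier, k = k,
             seed = mix_seed(seed, i))
  })
  names(cv) <- as.character(angs)
  ref <- pset$reference_angle
  pts <- data.frame(
    angle = angs,
    delta = abs(angs - ref),
    direction = ifelse(angs > ref, "down", "up"),
    mean_accuracy = vapply(cv, `[[`, 0, "mean_accuracy"),
    accuracy_se = vapply(cv, function(z)
      stats::sd(z$fold_accuracies) / sqrt(k), 0),
    separability_index = vapply(cv, `[[`, 0, "separability_index"),
    index_se = vapply(cv, function(z)
      stats::sd(z$sep_values) / sqrt(k), 0),
    n_folds = k,
    row.names = NULL)
  structure(list(points = pts, cv = cv, reference_angle = ref,
                 feature_spec = list(muscles = muscles, phase = phase,
                                     transform = transform),
                 classifier = classifier, seed = seed),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  fs <- x$feature_spec
  cat(sprintf("<tuning_curve> %s | muscles: %s | phase: %s | transform: %s\n",
              x$classifier$type,
              if (is.null(fs$muscles)) "all" else
                paste(fs$muscles, collapse = ","),
              fs$phase, fs$transform))
  print(x$points, digits = 3)
  invisible(x)
}

#' Plot a tuning curve
#'
#' Mean cross-validated accuracy (with fold standard-error bars) against
#' pointing angle; the dashed line marks chance level.
#'
#' @param x A `tuning_curve`.
#' @param what `"accuracy"` or `"separability"`.
#' @param ... Passed to [plot()].
#' @export
plot.tuning_curve <- function(x, what = c("accuracy", "separability"),
                              ...) {
  what <- match.arg(what)
  p <- x$points
  yv <- if (what == "accuracy") p$mean_accuracy else p$separability_index
  se <- if (what == "accuracy") p$accuracy_se else p$index_se
  plot(p$angle, yv, type = "b", pch = 19,
       xlab = "pointing angle (deg)",
       ylab = if (what == "accuracy") "CV accuracy" else
         "separability index",
       ylim = range(c(yv - se, yv + se,
                      if (what == "accuracy") c(0.4, 1))), ...)
  graphics::arrows(p$angle, yv - se, p$angle, yv + se, angle = 90,
                   code = 3, length = 0.03)
  graphics::abline(v = x$reference_angle, lty = 3)
  if (what == "accuracy") graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Per-muscle and all-muscle classification grid
#'
#' For each muscle alone, and for all muscles concatenated ("all"), the
#' cross-validated accuracy of every comparison angle against the
#' reference.
#'
#' @inheritParams run_tuning_curve
#' @return A `muscle_grid`: long data frame `grid` (muscle, angle,
#'   mean_accuracy) and an `accuracy` matrix (muscles + "all") x angles.
#' @export
run_muscle_grid <- function(pset, classifier = list(type = "lda"),
                            k = 5L, seed = 1L) {
  stopifnot(inherits(pset, "phasic_set"))
  angs <- comparison_angles(pset)
  rows <- c(pset$muscles$name, "all")
  acc <- matrix(NA_real_, nrow = length(rows), ncol = length(angs),
                dimnames = list(rows, as.character(angs)))
  for (ri in seq_along(rows)) {
    mus <- if (rows[ri] == "all") NULL else rows[ri]
    for (ai in seq_along(angs)) {
      cvr <- run_task(pset, angs[ai], muscles = mus,
                      classifier = classifier, k = k,
                      seed = mix_seed(mix_seed(seed, ri), ai))
      acc[ri, ai] <- cvr$mean_accuracy
    }
  }
  grid <- data.frame(muscle = rep(rows, times = length(angs)),
                     angle = rep(angs, each = length(rows)),
                     mean_accuracy = as.vector(acc),
                     row.names = NULL)
  structure(list(grid = grid, accuracy = acc,
                 reference_angle = pset$reference_angle,
                 classifier = classifier, seed = seed),
            class = "muscle_grid")
}

#' @export
print.muscle_grid <- function(x, ...) {
  cat("<muscle_grid> mean CV accuracy vs", x$reference_angle, "deg\n")
  print(round(x$accuracy, 3))
  invisible(x)
}

#' Muscle-group x movement-phase tuning analysis
#'
#' Compares the direction tuning of the gravity and antigravity muscle
#' groups within the acceleration and deceleration halves of the movement:
#' a tuning curve per (group, phase); ordinary least-squares slopes of
#' accuracy against angular distance, fitted separately for upward and
#' downward directions; a Friedman test (with Kendall's W) comparing the
#' two groups across (angle, fold) blocks within each phase; and a control
#' rerun with the weakest-tuned antigravity muscle removed so both groups
#' contain the same number of channels.
#'
#' @inheritParams run_tuning_curve
#' @param equalize_control Run the equal-size control (default `TRUE`).
#' @return A `group_phase_analysis`: `curves` (named
#'   `group.phase` list), `slopes` data frame (group, phase, direction,
#'   slope, r_squared), `tests` (per phase Friedman results), and
#'   `control` (removed muscle, control slopes and tests) or `NULL`.
#' @export
run_group_phase_analysis <- function(pset,
                                     classifier = list(type = "lda"),
                                     k = 5L, seed = 1L,
                                     equalize_control = TRUE) {
  stopifnot(inherits(pset, "phasic_set"))
  groups <- list(antigravity = role_muscles(pset, "antigravity"),
                 gravity = role_muscles(pset, "gravity"))
  if (!all(lengths(groups) > 0)) {
    pt_stop("pt_input_error",
            "dataset must contain both antigravity and gravity muscles")
  }
  phases <- c("acceleration", "deceleration")
  run_set <- function(muscle_sets, seed0) {
    curves <- list()
    for (g in names(muscle_sets)) {
      for (ph in phases) {
        curves[[paste(g, ph, sep = ".")]] <-
          run_tuning_curve(pset, muscles = muscle_sets[[g]], phase = ph,
                           classifier = classifier, k = k,
                           seed = mix_seed(seed0,
                                           match(g, names(muscle_sets)) *
                                             10 + match(ph, phases)))
      }
    }
    slopes <- do.call(rbind, lapply(names(muscle_sets), function(g) {
      do.call(rbind, lapply(phases, function(ph) {
        p <- curves[[paste(g, ph, sep = ".")]]$points
        do.call(rbind, lapply(c("up", "down"), function(d) {
          pp <- p[p$direction == d, ]
          sf <- fit_slope(pp$delta, pp$mean_accuracy)
          data.frame(group = g, phase = ph, direction = d,
                     slope = sf$slope, r_squared = sf$r_squared)
        }))
      }))
    }))
    # group comparison: blocks are (comparison angle x fold) cells, the
    # two conditions are the muscle groups
    tests <- lapply(phases, function(ph) {
      fold_acc <- lapply(names(muscle_sets), function(g) {
        cvs <- curves[[paste(g, ph, sep = ".")]]$cv
        unlist(lapply(cvs, `[[`, "fold_accuracies"))
      })
      friedman_test(do.call(cbind, fold_acc))
    })
    names(tests) <- phases
    list(curves = curves, slopes = slopes, tests = tests)
  }
  main <- run_set(groups, seed)
  control <- NULL
  if (equalize_control && length(groups$antigravity) >
      length(groups$gravity)) {
    # weakest antigravity muscle = lowest mean single-muscle accuracy
    # over full-waveform tasks
    per_muscle <- vapply(seq_along(groups$antigravity), function(i) {
      m <- groups$antigravity[i]
      angs <- comparison_angles(pset)
      mean(vapply(seq_along(angs), function(ai) {
        run_task(pset, angs[ai], muscles = m, classifier = classifier,
                 k = k,
                 seed = mix_seed(mix_seed(seed, 7919L + i), ai))$mean_accuracy
      }, 0))
    }, 0)
    weakest <- groups$antigravity[which.min(per_muscle)]
    ctrl_groups <- list(
      antigravity = setdiff(groups$antigravity, weakest),
      gravity = groups$gravity)
    ctrl <- run_set(ctrl_groups, mix_seed(seed, 15485863L))
    control <- list(removed_muscle = weakest, slopes = ctrl$slopes,
                    tests = ctrl$tests, curves = ctrl$curves)
  }
  structure(list(curves = main$curves, slopes = main$slopes,
                 tests = main$tests, control = control,
                 classifier = classifier, seed = seed),
            class = "group_phase_analysis")
}

#' @export
print.group_phase_analysis <- function(x, ...) {
  cat("<group_phase_analysis> accuracy slopes per degree of angular distance:\n")
  print(x$slopes, digits = 3)
  for (ph in names(x$tests)) {
    cat(sprintf("%s phase group comparison: ", ph))
    print(x$tests[[ph]])
  }
  if (!is.null(x$control)) {
    cat("equal-size control (removed:", x$control$removed_muscle, ")\n")
  }
  invisible(x)
}

#' Tuning of the negative (deactivation) phases of antigravity muscles
#'
#' Classifies pointing direction from only the negative portions of the
#' antigravity-muscle phasic waveforms -- once keeping the negative
#' amplitudes ([negative_part()]) and once keeping only their timing
#' ([binarize_negativity()], i.e. pure negative-phase duration information)
#' -- separately for the acceleration and deceleration halves.
#'
#' @inheritParams run_tuning_curve
#' @return A `negativity_analysis`: named list of four `tuning_curve`s
#'   (`negative.acceleration`, `negative.deceleration`,
#'   `binary.acceleration`, `binary.deceleration`) plus a combined
#'   `points` data frame with `transform` and `phase` columns.
#' @export
run_negativity_analysis <- function(pset,
                                    classifier = list(type = "lda"),
                                    k = 5L, seed = 1L) {
  stopifnot(inherits(pset, "phasic_set"))
  anti <- role_muscles(pset, "antigravity")
  if (!length(anti)) {
    pt_stop("pt_input_error", "no antigravity muscles in the dataset")
  }
  out <- list()
  pts <- list()
  i <- 0L
  for (tr in c("negative", "binary")) {
    for (ph in c("acceleration", "deceleration")) {
      i <- i + 1L
      cu <- run_tuning_curve(pset, muscles = anti, phase = ph,
                             transform = tr, classifier = classifier,
                             k = k, seed = mix_seed(seed, 100L + i))
      out[[paste(tr, ph, sep = ".")]] <- cu
      pts[[i]] <- cbind(transform = tr, phase = ph, cu$points)
    }
  }
  structure(list(curves = out, points = do.call(rbind, pts),
                 classifier = classifier, seed = seed),
            class = "negativity_analysis")
}

#' @export
print.negativity_analysis <- function(x, ...) {
  cat("<negativity_analysis> antigravity muscles, negative-phase features\n")
  print(x$points, digits = 3)
  invisible(x)
}

#' Run the complete direction-tuning analysis
#'
#' Orchestrates every analysis stage over one dataset: the per-muscle /
#' all-muscle accuracy grid, the all-muscle tuning curve with its
#' separability index, the muscle-group x movement-phase slopes with the
#' group Friedman comparison, the negative-phase analyses, and the
#' upward/downward asymmetry test (exact Wilcoxon rank sum on the fold
#' separability indices of the two extreme directions).
#'
#' @param pset A normalized [phasic_set()], or a [generator_config()]
#'   (a phasic dataset is then generated from it).
#' @inheritParams run_tuning_curve
#' @return An `analysis_report` with components `grid`, `tuning`,
#'   `group_phase`, `negativity`, `updown_comparison` and `provenance`.
#' @export
run_full_report <- function(pset, classifier = list(type = "lda"),
                            k = 5L, seed = 1L) {
  if (inherits(pset, "generator_config")) {
    pset <- generate_dataset(pset, level = "phasic")
  }
  stopifnot(inherits(pset, "phasic_set"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pt_stop("pt_stage_error", "stage '%s' failed: %s", name,
              conditionMessage(e))
    })
  }
  grid <- stage("muscle_grid",
                run_muscle_grid(pset, classifier, k, mix_seed(seed, 1L)))
  tuning <- stage("tuning_curve",
                  run_tuning_curve(pset, classifier = classifier, k = k,
                                   seed = mix_seed(seed, 2L)))
  gp <- stage("group_phase",
              run_group_phase_analysis(pset, classifier, k,
                                       mix_seed(seed, 3L)))
  neg <- stage("negativity",
               run_negativity_analysis(pset, classifier, k,
                                       mix_seed(seed, 4L)))
  angs <- comparison_angles(pset)
  up_ext <- as.character(min(angs))
  down_ext <- as.character(max(angs))
  updown <- stage("updown_comparison", wilcoxon_rank_sum(
    tuning$cv[[up_ext]]$sep_values,
    tuning$cv[[down_ext]]$sep_values))
  structure(list(
    grid = grid, tuning = tuning, group_phase = gp, negativity = neg,
    updown_comparison = updown,
    provenance = list(seed = seed, classifier = classifier, k = k,
                      n_trials = nrow(pset$meta),
                      angles = sort(unique(pset$meta$angle)),
                      reference_angle = pset$reference_angle,
                      package_version =
                        as.character(utils::packageVersion("phasictune")))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n== all-muscle tuning ==\n")
  print(x$tuning$points, digits = 3)
  cat("== group x phase slopes ==\n")
  print(x$group_phase$slopes, digits = 3)
  cat("== up/down separability asymmetry (",
      min(x$provenance$angles), "vs", max(x$provenance$angles), "deg) ==\n")
  print(x$updown_comparison)
  invisible(x)
}
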