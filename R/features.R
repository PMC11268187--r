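new_feature_matrix <- function(x, y, map, meta, angles) {
  stopifnot(nrow(x) == length(y), ncol(x) == nrow(map),
            nrow(meta) == nrow(x))
  structure(list(x = x, y = as.integer(y), map = map, meta = meta,
                 angles = angles),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d trials x %d features (%d muscles), classes 0 (%g deg, n=%d) / 1 (%g deg, n=%d)\n",
    nrow(x$x), ncol(x$x), length(unique(x$map$muscle)),
    x$angles[1], sum(x$y == 0), x$angles[2], sum(x$y == 1)))
  invisible(x)
}

#' Concatenate the muscle waveforms of one trial into a feature vector
#'
#' Builds the classifier input for one trial: the 1000-point waveforms of
#' the listed muscles, concatenated block-wise in the given order (nine
#' muscles give a 9000-point vector). The returned vector carries a
#' `feature_map` attribute recording the (muscle, time point) provenance of
#' every element.
#'
#' @param trial Matrix muscles x 1000 with muscle names as rownames
#'   (one slice of a [phasic_set()], or a [preprocess_trial()] output).
#' @param muscle_order Character vector of muscle names; all must be
#'   present.
#' @return Numeric vector of length `1000 * length(muscle_order)`.
#' @export
concat_muscles <- function(trial, muscle_order = rownames(trial)) {
  missing <- setdiff(muscle_order, rownames(trial))
  if (length(missing)) {
    pt_stop("pt_input_error", "muscle(s) not present: %s",
            paste(missing, collapse = ", "))
  }
  v <- as.numeric(t(trial[muscle_order, , drop = FALSE]))
  attr(v, "feature_map") <- data.frame(
    muscle = rep(muscle_order, each = ncol(trial)),
    time = rep(seq_len(ncol(trial)), times = length(muscle_order)),
    stringsAsFactors = FALSE)
  v
}

#' Assemble the binary classification task for one comparison angle
#'
#' Rows are all trials (across subjects) of the reference direction and of
#' one comparison direction; features are the concatenated multi-muscle
#' waveforms; labels are 0 for the reference (horizontal, gravity-neutral)
#' class and 1 for the comparison class.
#'
#' @param pset A [phasic_set()].
#' @param comparison_angle Degrees; must differ from the reference and be
#'   present in the set.
#' @param reference_angle Degrees (defaults to the set's reference, 90).
#' @param muscle_order Block order (defaults to the set's muscle order).
#' @return A `feature_matrix`.
#' @export
build_binary_task <- function(pset, comparison_angle,
                              reference_angle = pset$reference_angle,
                              muscle_order = pset$muscles$name) {
  stopifnot(inherits(pset, "phasic_set"))
  if (comparison_angle == reference_angle) {
    pt_stop("pt_input_error",
            "comparison angle equals the reference angle (%g)",
            reference_angle)
  }
  present <- unique(pset$meta$angle)
  for (a in c(reference_angle, comparison_angle)) {
    if (!a %in% present) {
      pt_stop("pt_input_error", "angle %g not present in the dataset", a)
    }
  }
  rows <- which(pset$meta$angle %in% c(reference_angle, comparison_angle))
  midx <- match(muscle_order, pset$muscles$name)
  if (anyNA(midx)) {
    pt_stop("pt_input_error", "unknown muscle in muscle_order")
  }
  npts <- dim(pset$waves)[3]
  x <- do.call(cbind, lapply(midx, function(j) pset$waves[rows, j, ]))
  map <- data.frame(muscle = rep(muscle_order, each = npts),
                    time = rep(seq_len(npts), times = length(midx)),
                    stringsAsFactors = FALSE)
  y <- as.integer(pset$meta$angle[rows] == comparison_angle)
  new_feature_matrix(x, y, map, pset$meta[rows, , drop = FALSE],
                     angles = c(reference_angle, comparison_angle))
}

#' Restrict a feature matrix to a muscle subset
#'
#' @param fm A `feature_matrix`.
#' @param subset Character vector of muscle names (non-empty, all present).
#' @return The restricted `feature_matrix`; labels unchanged.
#' @export
select_muscles <- function(fm, subset) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(subset) == 0) {
    pt_stop("pt_input_error", "empty muscle subset")
  }
  missing <- setdiff(subset, unique(fm$map$muscle))
  if (length(missing)) {
    pt_stop("pt_input_error", "muscle(s) not in feature matrix: %s",
            paste(missing, collapse = ", "))
  }
  keep <- fm$map$muscle %in% subset
  new_feature_matrix(fm$x[, keep, drop = FALSE], fm$y,
                     fm$map[keep, , drop = FALSE], fm$meta, fm$angles)
}

#' Restrict a feature matrix to a movement phase
#'
#' Keeps, within every muscle block, the acceleration half (normalized time
#' points up to `floor(1000 * split_fraction)`) or the deceleration half
#' (the remainder). With no velocity trace available, the midpoint split
#' reflects the near-symmetric velocity profile of rapid point-to-point
#' movements.
#'
#' @param fm A `feature_matrix` built from full waveforms.
#' @param phase `"full"`, `"acceleration"` or `"deceleration"`.
#' @param split_fraction Phase boundary in (0, 1), default 0.5.
#' @return The restricted `feature_matrix`.
#' @export
select_phase <- function(fm, phase = c("full", "acceleration",
                                       "deceleration"),
                         split_fraction = 0.5) {
  phase <- match.arg(phase)
  stopifnot(inherits(fm, "feature_matrix"))
  if (phase == "full") return(fm)
  if (split_fraction <= 0 || split_fraction >= 1) {
    pt_stop("pt_input_error", "split_fraction must lie in (0, 1)")
  }
  npts <- max(fm$map$time)
  cut <- floor(npts * split_fraction)
  keep <- if (phase == "acceleration") fm$map$time <= cut else
    fm$map$time > cut
  new_feature_matrix(fm$x[, keep, drop = FALSE], fm$y,
                     fm$map[keep, , drop = FALSE], fm$meta, fm$angles)
}

#' Keep only the negative (deactivation) part of the features
#'
#' Positive values are replaced by zero; negative values are kept unchanged,
#' preserving the vector length so rows stay commensurable.
#'
#' @param fm A `feature_matrix` of signed phasic values.
#' @return A `feature_matrix` of the same shape.
#' @export
negative_part <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  fm$x[fm$x > 0] <- 0
  fm
}

#' Binarize negativity: 1 where negative, 0 elsewhere
#'
#' Removes all amplitude information: strictly negative values map to 1 and
#' nonnegative values (zeros included) to 0, so a row sum equals the
#' duration of the negative phases in normalized time points.
#'
#' @param fm A `feature_matrix` of signed phasic values.
#' @return A `feature_matrix` of 0/1 values, same shape.
#' @export
binarize_negativity <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  fm$x <- (fm$x < 0) * 1
  fm
}
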