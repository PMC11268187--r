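#' Describe one simulated muscle channel
#'
#' A muscle is characterized by its functional role with respect to the
#' gravity torque at the shoulder and by a positive triphasic burst template
#' (agonist -- antagonist -- agonist), modeled as a sum of Gaussian bursts
#' over normalized movement time.
#'
#' @param name Channel label.
#' @param role One of `"antigravity"` (action opposes gravity torque;
#'   deactivation lobes appear when gravity assists the motion), `"gravity"`
#'   (action assisted by gravity; weak positive-burst tuning only) or
#'   `"neutral"` (untuned).
#' @param burst_peaks Burst centers as fractions of movement duration.
#' @param burst_widths Gaussian SDs of the bursts (movement fraction).
#' @param burst_amps Nonnegative burst amplitudes (dimensionless).
#' @param directions Directions in which this muscle is tuned: subset of
#'   `c("up", "down")`. Both by default; restricting it builds channels tuned
#'   for only one pointing direction.
#' @return A `muscle_spec` list.
#' @export
#' @examples
#' muscle_spec("anterior_deltoid", "antigravity")
muscle_spec <- function(name, role = c("antigravity", "gravity", "neutral"),
                        burst_peaks = c(0.15, 0.50, 0.85),
                        burst_widths = c(0.06, 0.08, 0.06),
                        burst_amps = c(1.0, 0.8, 0.6),
                        directions = c("up", "down")) {
  role <- match.arg(role)
  if (any(burst_amps < 0)) {
    pt_stop("pt_config_error", "burst amplitudes must be nonnegative")
  }
  stopifnot(length(burst_peaks) == length(burst_widths),
            length(burst_peaks) == length(burst_amps),
            all(directions %in% c("up", "down")))
  structure(list(name = name, role = role,
                 burst_peaks = burst_peaks, burst_widths = burst_widths,
                 burst_amps = burst_amps, directions = directions),
            class = "muscle_spec")
}

#' Default nine-channel shoulder muscle set
#'
#' Four antigravity muscles (anterior deltoid, medial deltoid, trapezius,
#' biceps brachii), three gravity muscles (posterior deltoid, latissimus
#' dorsi, long triceps) and two neutral channels (short triceps plus a
#' brachioradialis placeholder for the unidentified ninth channel). Burst
#' templates differ slightly per muscle so channels are not collinear.
#'
#' @return List of nine [muscle_spec()] objects.
#' @export
default_muscles <- function() {
  list(
    muscle_spec("anterior_deltoid",  "antigravity",
                burst_peaks = c(0.13, 0.50, 0.84),
                burst_amps  = c(1.00, 0.75, 0.60)),
    muscle_spec("medial_deltoid",    "antigravity",
                burst_peaks = c(0.16, 0.52, 0.86),
                burst_amps  = c(0.90, 0.80, 0.55)),
    muscle_spec("trapezius",         "antigravity",
                burst_peaks = c(0.15, 0.48, 0.83),
                burst_amps  = c(0.80, 0.70, 0.65)),
    muscle_spec("biceps_brachii",    "antigravity",
                burst_peaks = c(0.18, 0.51, 0.87),
                burst_amps  = c(0.70, 0.60, 0.45)),
    muscle_spec("posterior_deltoid", "gravity",
                burst_peaks = c(0.14, 0.49, 0.85),
                burst_amps  = c(0.95, 0.70, 0.55)),
    muscle_spec("latissimus_dorsi",  "gravity",
                burst_peaks = c(0.17, 0.52, 0.84),
                burst_amps  = c(0.85, 0.75, 0.50)),
    muscle_spec("long_triceps",      "gravity",
                burst_peaks = c(0.15, 0.50, 0.86),
                burst_amps  = c(0.75, 0.65, 0.55)),
    muscle_spec("short_triceps",     "neutral",
                burst_peaks = c(0.16, 0.50, 0.85),
                burst_amps  = c(0.60, 0.55, 0.45)),
    muscle_spec("brachioradialis",   "neutral",
                burst_peaks = c(0.14, 0.51, 0.84),
                burst_amps  = c(0.55, 0.50, 0.40))
  )
}

#' Configuration of the synthetic pointing-EMG generator
#'
#' Defines a full factorial recording campaign: `n_subjects` subjects point
#' in each direction of `angles` (degrees; 90 is the gravity-neutral
#' horizontal reference) `n_trials` times while the listed muscles are
#' recorded. Direction tuning is linear in the angular distance from the
#' reference: antigravity channels acquire a deactivation (negative) lobe of
#' depth `negativity_base_depth + negativity_depth_gain * |angle - 90|` and
#' duration `negativity_duration_gain * |angle - 90|` (fraction of movement
#' time), placed in the acceleration half for downward pointing
#' (angle > 90) and the deceleration half for upward pointing (angle < 90);
#' their first/last burst amplitudes are additionally reshaped with gain
#' `antigravity_burst_gain`. Gravity channels get only the analogous
#' (weaker) positive burst reshaping with gain `gravity_tuning_gain`.
#' All downward effects are multiplied by `updown_asymmetry`.
#'
#' @param n_subjects,n_trials Counts (each >= 1).
#' @param angles Direction labels in degrees; must contain `reference_angle`.
#' @param reference_angle Horizontal reference (degrees), default 90.
#' @param muscles List of [muscle_spec()] objects.
#' @param negativity_depth_gain Lobe depth per degree of angular distance.
#' @param negativity_base_depth Depth offset of the lobe (applies whenever
#'   the lobe has nonzero duration); lets duration-only tuning exist.
#' @param negativity_duration_gain Lobe duration (movement fraction) per
#'   degree; the total lobe duration is capped at 0.45 so it stays inside
#'   its movement half.
#' @param gravity_tuning_gain Burst-reshaping gain per degree for gravity
#'   muscles (weak).
#' @param antigravity_burst_gain Burst-reshaping gain per degree for
#'   antigravity muscles.
#' @param updown_asymmetry Multiplier (> 0, typically > 1) applied to all
#'   effects for downward directions (angle > reference).
#' @param noise_sd Additive white-noise SD at the phasic-waveform level; for
#'   raw signals, the relative amplitude of the activity-modulated broadband
#'   interference.
#' @param burst_jitter_sd,amp_jitter_sd Trial-to-trial SD of burst-center
#'   jitter (movement fraction) and of the log amplitude factor.
#' @param subject_scale_sd SD of the per-(subject, muscle) log amplitude
#'   scale (removed downstream by the Z-score normalization).
#' @param tonic_level Constant baseline amplitude of raw signals.
#' @param trial_duration_s,movement_duration_s,sampling_rate_hz Raw-trial
#'   geometry; quiet margins of at least 1 s must fit on both sides of the
#'   movement.
#' @param seed Integer master seed; every trial's random stream derives from
#'   it deterministically.
#' @return A validated `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 2, n_trials = 3,
#'                         angles = c(30, 90, 150), seed = 7)
generator_config <- function(n_subjects = 11,
                             n_trials = 10,
                             angles = seq(0, 240, by = 15),
                             reference_angle = 90,
                             muscles = default_muscles(),
                             negativity_depth_gain = 0.008,
                             negativity_base_depth = 0.3,
                             negativity_duration_gain = 0.003,
                             gravity_tuning_gain = 0.0015,
                             antigravity_burst_gain = 0.003,
                             updown_asymmetry = 1.3,
                             noise_sd = 1.0,
                             burst_jitter_sd = 0.05,
                             amp_jitter_sd = 0.25,
                             subject_scale_sd = 0.3,
                             tonic_level = 1.0,
                             trial_duration_s = 3.5,
                             movement_duration_s = 1.0,
                             sampling_rate_hz = 1000,
                             seed = 1L) {
  gains <- c(negativity_depth_gain, negativity_base_depth,
             negativity_duration_gain, gravity_tuning_gain,
             antigravity_burst_gain, noise_sd, burst_jitter_sd,
             amp_jitter_sd, subject_scale_sd)
  if (any(gains < 0)) pt_stop("pt_config_error", "all gains must be >= 0")
  if (n_subjects < 1 || n_trials < 1) {
    pt_stop("pt_config_error", "n_subjects and n_trials must be >= 1")
  }
  if (!reference_angle %in% angles) {
    pt_stop("pt_config_error",
            "angles must contain the reference angle (%g)", reference_angle)
  }
  if (sampling_rate_hz <= 600) {
    pt_stop("pt_config_error",
            "sampling_rate_hz must exceed 600 so a 20-300 Hz band-pass is valid")
  }
  if (updown_asymmetry <= 0) {
    pt_stop("pt_config_error", "updown_asymmetry must be positive")
  }
  if (trial_duration_s < movement_duration_s + 2) {
    pt_stop("pt_config_error",
            "trial_duration_s too short for 1 s quiet margins around a %g s movement",
            movement_duration_s)
  }
  nm <- vapply(muscles, function(m) m$name, "")
  if (anyDuplicated(nm)) pt_stop("pt_config_error", "duplicate muscle names")
  structure(list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    angles = as.numeric(angles), reference_angle = reference_angle,
    muscles = muscles,
    negativity_depth_gain = negativity_depth_gain,
    negativity_base_depth = negativity_base_depth,
    negativity_duration_gain = negativity_duration_gain,
    gravity_tuning_gain = gravity_tuning_gain,
    antigravity_burst_gain = antigravity_burst_gain,
    updown_asymmetry = updown_asymmetry,
    noise_sd = noise_sd, burst_jitter_sd = burst_jitter_sd,
    amp_jitter_sd = amp_jitter_sd, subject_scale_sd = subject_scale_sd,
    tonic_level = tonic_level,
    trial_duration_s = trial_duration_s,
    movement_duration_s = movement_duration_s,
    sampling_rate_hz = sampling_rate_hz,
    seed = as.integer(seed)
  ), class = "generator_config")
}

muscle_names <- function(config) vapply(config$muscles, `[[`, "", "name")
muscle_roles <- function(config) vapply(config$muscles, `[[`, "", "role")

# Per-(subject, muscle) log-normal amplitude scales; deterministic in the
# master seed and removed downstream by the Z-score normalization.
subject_scales <- function(config) {
  with_seed(mix_seed(config$seed, 104729L), {
    matrix(exp(stats::rnorm(config$n_subjects * length(config$muscles),
                            0, config$subject_scale_sd)),
           nrow = config$n_subjects)
  })
}

# Direction-dependent waveform parameters for one muscle at one angle.
tuning_params <- function(config, muscle, angle) {
  ref <- config$reference_angle
  delta <- abs(angle - ref)
  down <- angle > ref
  dir_label <- if (down) "down" else "up"
  tuned <- delta > 0 && dir_label %in% muscle$directions
  asym <- if (down) config$updown_asymmetry else 1
  g <- switch(muscle$role,
              antigravity = config$antigravity_burst_gain,
              gravity = config$gravity_tuning_gain,
              neutral = 0)
  burst_factor <- if (tuned) 1 + g * delta * asym else 1
  if (muscle$role == "antigravity" && tuned) {
    duration <- min(config$negativity_duration_gain * delta * asym, 0.45)
    depth <- if (duration > 0) {
      (config$negativity_base_depth +
         config$negativity_depth_gain * delta) * asym
    } else 0
  } else {
    duration <- 0
    depth <- 0
  }
  list(delta = delta, down = down, burst_factor = burst_factor,
       lobe_depth = depth, lobe_duration = duration,
       lobe_center = if (down) 0.25 else 0.75)
}

#' Generate one phasic EMG waveform
#'
#' Produces the 1000-point noise-free (or noisy) phasic waveform of one
#' muscle for one pointing angle: a positive triphasic Gaussian-burst
#' pattern, reshaped with angular distance from the reference, plus -- for
#' antigravity muscles -- a compactly supported deactivation lobe in the
#' movement half where gravity assists the motion (acceleration half for
#' downward pointing, deceleration half for upward pointing).
#'
#' @param config A [generator_config()].
#' @param muscle A [muscle_spec()] (typically one of `config$muscles`).
#' @param angle Pointing direction in degrees; must be in `config$angles`.
#' @param noise If `TRUE`, add trial-level burst jitter, amplitude jitter
#'   and white noise, drawn from the current RNG state (or from `seed`).
#' @param seed Optional integer seed for the noise draw.
#' @return Numeric vector of length 1000 (dimensionless phasic amplitude;
#'   negative values are deactivation below the tonic level).
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 1, n_trials = 1)
#' w <- generate_phasic_waveform(cfg, cfg$muscles[[1]], angle = 180)
#' min(w[1:500]) < 0   # deactivation during the acceleration half
generate_phasic_waveform <- function(config, muscle, angle,
                                     noise = FALSE, seed = NULL) {
  if (!angle %in% config$angles) {
    pt_stop("pt_input_error", "angle %g is not in config$angles", angle)
  }
  p <- tuning_params(config, muscle, angle)
  npts <- 1000L
  t <- (seq_len(npts) - 0.5) / npts

  draw <- function() {
    centers <- muscle$burst_peaks
    amps <- muscle$burst_amps
    if (noise) {
      centers <- centers + stats::rnorm(length(centers), 0,
                                        config$burst_jitter_sd)
      amps <- amps * exp(stats::rnorm(1, 0, config$amp_jitter_sd))
    }
    # burst reshaping: first burst scaled up, last burst scaled down, so the
    # waveform SHAPE changes with angle (a uniform gain would be erased by
    # the per-angle Z-score normalization)
    amps[1] <- amps[1] * p$burst_factor
    amps[length(amps)] <- amps[length(amps)] / p$burst_factor
    w <- numeric(npts)
    for (i in seq_along(centers)) {
      w <- w + amps[i] * exp(-(t - centers[i])^2 /
                               (2 * muscle$burst_widths[i]^2))
    }
    if (p$lobe_depth > 0 && p$lobe_duration > 0) {
      half <- p$lobe_duration / 2
      inside <- abs(t - p$lobe_center) < half
      w[inside] <- w[inside] - p$lobe_depth *
        cos(pi * (t[inside] - p$lobe_center) / p$lobe_duration)^2
    }
    if (noise && config$noise_sd > 0) {
      w <- w + stats::rnorm(npts, 0, config$noise_sd)
    }
    w
  }
  if (!is.null(seed)) with_seed(seed, draw()) else draw()
}

#' Generate one raw multi-muscle trial
#'
#' Builds the sampled signals of all muscles for one (subject, angle, trial)
#' cell. The activity envelope is `tonic_level` everywhere, plus the phasic
#' waveform mapped onto the movement interval (floored at zero: a muscle
#' cannot be less than silent). The observed signal is the envelope plus
#' broadband interference whose amplitude is proportional to the
#' instantaneous envelope (`noise_sd` sets the relative level), the standard
#' amplitude-modulation model of surface EMG; with `noise_sd = 0` the signal
#' equals the envelope exactly. Quiet margins of at least 1 s surround the
#' movement so the tonic-estimation windows exist.
#'
#' @param config A [generator_config()].
#' @param subject Subject index (1-based).
#' @param angle Pointing direction (degrees, in `config$angles`).
#' @param trial Trial index (1-based).
#' @return A `raw_trial`: list with `signals` (muscles x samples matrix,
#'   muscle names as rownames), `sampling_rate`, `onset`/`offset` sample
#'   indices, and `subject`/`angle`/`trial` labels.
#' @export
generate_raw_trial <- function(config, subject, angle, trial = 1L) {
  if (!angle %in% config$angles) {
    pt_stop("pt_input_error", "angle %g is not in config$angles", angle)
  }
  fs <- config$sampling_rate_hz
  n <- round(config$trial_duration_s * fs)
  n_mov <- round(config$movement_duration_s * fs)
  onset <- round((n - n_mov) / 2)
  offset <- onset + n_mov - 1L
  if (onset < fs || (n - offset) < fs) {
    pt_stop("pt_config_error",
            "trial too short for 1 s quiet margins around the movement")
  }
  a_idx <- match(angle, config$angles)
  trial_seed <- mix_seed(mix_seed(mix_seed(config$seed, subject),
                                  a_idx), trial)
  mus <- config$muscles
  scales <- subject_scales(config)
  sig <- with_seed(trial_seed, {
    m <- matrix(0, nrow = length(mus), ncol = n)
    for (j in seq_along(mus)) {
      subj_scale <- scales[subject, j]
      wave <- generate_phasic_waveform(config, mus[[j]], angle,
                                       noise = config$noise_sd > 0 ||
                                         config$burst_jitter_sd > 0)
      env <- rep(config$tonic_level, n)
      env[onset:offset] <- env[onset:offset] +
        stats::approx(seq_len(1000), wave,
                      xout = seq(1, 1000, length.out = n_mov))$y
      env <- pmax(env, 0)
      x <- env
      if (config$noise_sd > 0) {
        x <- env + config$noise_sd * env * stats::rnorm(n)
      }
      m[j, ] <- subj_scale * x
    }
    rownames(m) <- muscle_names(config)
    m
  })
  structure(list(signals = sig, sampling_rate = fs,
                 onset = as.integer(onset), offset = as.integer(offset),
                 subject = as.integer(subject), angle = angle,
                 trial = as.integer(trial)),
            class = "raw_trial")
}

#' Generate a full factorial synthetic recording set
#'
#' Runs the generator over every (subject, angle, trial) cell of the
#' configuration. `level = "raw"` returns sampled raw trials for the
#' preprocessing chain; `level = "phasic"` skips the raw stage and returns
#' duration-normalized 1000-point phasic waveforms directly (optionally
#' Z-score normalized), which is the natural input of the classification
#' pipeline.
#'
#' @param config A [generator_config()].
#' @param level `"raw"` or `"phasic"`.
#' @param normalize For `level = "phasic"`: apply the per
#'   (subject, muscle, angle) Z-score normalization (default `TRUE`).
#' @return For `"raw"`, a `raw_recording_set` (list of [generate_raw_trial()]
#'   outputs plus the config); for `"phasic"`, a [phasic_set()].
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 2, n_trials = 2,
#'                         angles = c(60, 90, 120), seed = 3)
#' ps <- generate_dataset(cfg, level = "phasic")
#' dim(ps$waves)
generate_dataset <- function(config, level = c("raw", "phasic"),
                             normalize = TRUE) {
  level <- match.arg(level)
  grid <- expand.grid(trial = seq_len(config$n_trials),
                      angle = config$angles,
                      subject = seq_len(config$n_subjects))
  if (level == "raw") {
    trials <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      trials[[i]] <- generate_raw_trial(config, grid$subject[i],
                                        grid$angle[i], grid$trial[i])
    }
    return(structure(list(trials = trials, config = config),
                     class = "raw_recording_set"))
  }
  mus <- config$muscles
  nm <- muscle_names(config)
  waves <- array(0, dim = c(nrow(grid), length(mus), 1000L))
  scales <- subject_scales(config)
  for (i in seq_len(nrow(grid))) {
    a_idx <- match(grid$angle[i], config$angles)
    trial_seed <- mix_seed(mix_seed(mix_seed(config$seed, grid$subject[i]),
                                    a_idx), grid$trial[i])
    waves[i, , ] <- with_seed(trial_seed, {
      t(vapply(seq_along(mus), function(j) {
        scales[grid$subject[i], j] *
          generate_phasic_waveform(config, mus[[j]], grid$angle[i],
                                   noise = TRUE)
      }, numeric(1000L)))
    })
  }
  ps <- phasic_set(waves,
                   meta = data.frame(subject = grid$subject,
                                     angle = grid$angle,
                                     trial = grid$trial),
                   muscles = data.frame(name = nm,
                                        role = muscle_roles(config),
                                        stringsAsFactors = FALSE),
                   reference_angle = config$reference_angle,
                   normalized = FALSE)
  if (normalize) ps <- zscore_normalize(ps)
  ps
}

#' Number of muscle-level recordings in a raw recording set
#'
#' One recording is one muscle's signal in one trial, so the count equals
#' trials x muscles (subjects x angles x trials x muscles overall).
#'
#' @param x A `raw_recording_set`.
#' @return Integer count.
#' @export
n_recordings <- function(x) {
  stopifnot(inherits(x, "raw_recording_set"))
  length(x$trials) * length(x$config$muscles)
}

#' @export
print.raw_recording_set <- function(x, ...) {
  cat(sprintf(
    "<raw_recording_set> %d trials (%d subjects x %d angles x %d trials), %d muscles, %d recordings\n",
    length(x$trials), x$config$n_subjects, length(x$config$angles),
    x$config$n_trials, length(x$config$muscles), n_recordings(x)))
  invisible(x)
}

#' Container for duration-normalized phasic trials
#'
#' @param waves 3-d array `(trial rows) x (muscles) x 1000` of phasic
#'   waveforms.
#' @param meta Data frame with one row per trial: `subject`, `angle`,
#'   `trial`.
#' @param muscles Data frame with `name` and `role` per channel, in the
#'   order of the array's second dimension.
#' @param reference_angle Degrees (default 90).
#' @param normalized Logical: have the waveforms been Z-scored per
#'   (subject, muscle, angle) cell?
#' @return A `phasic_set` object.
#' @export
phasic_set <- function(waves, meta, muscles, reference_angle = 90,
                       normalized = FALSE) {
  stopifnot(length(dim(waves)) == 3, dim(waves)[3] == 1000L,
            dim(waves)[1] == nrow(meta), dim(waves)[2] == nrow(muscles),
            all(c("subject", "angle", "trial") %in% names(meta)),
            all(c("name", "role") %in% names(muscles)))
  structure(list(waves = waves, meta = meta, muscles = muscles,
                 reference_angle = reference_angle,
                 normalized = isTRUE(normalized)),
            class = "phasic_set")
}

#' @export
print.phasic_set <- function(x, ...) {
  cat(sprintf(
    "<phasic_set> %d trials x %d muscles x 1000 points (%d subjects, %d angles)%s\n",
    dim(x$waves)[1], dim(x$waves)[2], length(unique(x$meta$subject)),
    length(unique(x$meta$angle)),
    if (x$normalized) ", Z-scored" else ""))
  invisible(x)
}
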