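#' Rectify and band-pass filter a raw EMG signal
#'
#' Full-wave rectification followed by a zero-phase (forward-backward)
#' third-order Butterworth band-pass, 20-300 Hz by default. The order of the
#' two steps is configurable; rectify-first is the default.
#'
#' @param x Numeric sampled signal.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the upper
#'   band edge.
#' @param band Pass band in Hz, default `c(20, 300)`.
#' @param order Filter order (applied forward and backward), default 3.
#' @param rectify_first If `TRUE` (default), rectify then filter; otherwise
#'   filter then rectify.
#' @return Filtered series, same length as `x`.
#' @export
rectify_and_filter <- function(x, sampling_rate, band = c(20, 300),
                               order = 3, rectify_first = TRUE) {
  if (sampling_rate <= 2 * band[2]) {
    pt_stop("pt_input_error",
            "sampling rate %g Hz too low for a %g-%g Hz band-pass",
            sampling_rate, band[1], band[2])
  }
  bf <- signal::butter(order, band / (sampling_rate / 2), type = "pass")
  if (rectify_first) {
    as.numeric(signal::filtfilt(bf, abs(x)))
  } else {
    abs(as.numeric(signal::filtfilt(bf, x)))
  }
}

#' Sliding-window integration envelope
#'
#' Trapezoidal integration over a centered 5 ms sliding window, normalized
#' by the window length so a constant input maps to itself. The window
#' shrinks at the edges rather than padding with fabricated samples. With
#' `mode = "rms"` the square of the signal is integrated and the square root
#' taken (a proper root-mean-square envelope); the default `"trapz"`
#' integrates the signal as given.
#'
#' @param x Numeric series (typically rectified-filtered EMG).
#' @param sampling_rate Hz.
#' @param window_s Window length in seconds (default 0.005).
#' @param mode `"trapz"` or `"rms"`.
#' @return Envelope series, same length as `x`.
#' @export
rms_integrate <- function(x, sampling_rate, window_s = 0.005,
                          mode = c("trapz", "rms")) {
  mode <- match.arg(mode)
  if (window_s * sampling_rate < 2) {
    pt_stop("pt_input_error", "window shorter than two samples")
  }
  n <- length(x)
  half <- max(1L, floor(window_s * sampling_rate / 2))
  v <- if (mode == "rms") x^2 else x
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs <- cumsum(v)
  seg_sum <- cs[hi] - c(0, cs)[lo]
  # trapezoid rule over [lo, hi] with unit spacing = sum - (ends)/2,
  # normalized by the window length in samples
  trap <- (seg_sum - (v[lo] + v[hi]) / 2) / (hi - lo)
  if (mode == "rms") sqrt(pmax(trap, 0)) else trap
}

#' Estimate tonic activity across the movement
#'
#' Averages the envelope from 1 to 0.5 s before movement onset and from
#' 0.5 to 1 s after movement stop, then linearly interpolates between the
#' two values across the movement interval (pre-value anchored at the onset
#' sample, post-value at the offset sample).
#'
#' @param envelope Numeric envelope series.
#' @param sampling_rate Hz.
#' @param onset,offset Movement start/stop sample indices.
#' @return Numeric tonic estimate of length `offset - onset + 1`, with
#'   attributes `pre` and `post` (the two window means).
#' @export
estimate_tonic <- function(envelope, sampling_rate, onset, offset) {
  fs <- sampling_rate
  i1 <- round(onset - fs); i2 <- round(onset - 0.5 * fs)
  j1 <- round(offset + 0.5 * fs); j2 <- round(offset + fs)
  if (i1 < 1 || j2 > length(envelope) || onset >= offset) {
    pt_stop("pt_input_error",
            "tonic windows [onset-1s, onset-0.5s] / [offset+0.5s, offset+1s] out of range")
  }
  pre <- mean(envelope[i1:i2])
  post <- mean(envelope[j1:j2])
  tonic <- seq(pre, post, length.out = offset - onset + 1)
  attr(tonic, "pre") <- pre
  attr(tonic, "post") <- post
  tonic
}

#' Extract the phasic component over the movement interval
#'
#' Subtracts the tonic estimate from the envelope on `[onset, offset]`.
#' Negative values -- activity below what gravity compensation requires --
#' are preserved, never clipped.
#'
#' @param envelope Envelope series.
#' @param tonic Tonic estimate over the movement interval
#'   (see [estimate_tonic()]).
#' @param onset,offset Movement sample indices.
#' @return Phasic series of length `offset - onset + 1`.
#' @export
extract_phasic <- function(envelope, tonic, onset, offset) {
  seg <- envelope[onset:offset]
  if (length(seg) != length(tonic)) {
    pt_stop("pt_input_error", "tonic and movement interval lengths differ")
  }
  seg - tonic
}

#' Normalize a movement-interval series to 1000 points
#'
#' Linear interpolation onto 1000 equally spaced points spanning the input;
#' the first and last values are preserved exactly.
#'
#' @param x Numeric series of length >= 2.
#' @param n_points Output length (default 1000).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, n_points = 1000L) {
  if (length(x) < 2) {
    pt_stop("pt_input_error", "need at least 2 samples to time-normalize")
  }
  stats::approx(seq_along(x), x,
                xout = seq(1, length(x), length.out = n_points))$y
}

#' Z-score phasic waveforms per (subject, muscle, angle) cell
#'
#' Pools all time points of all trials within each (subject, muscle, angle)
#' cell and transforms them to zero mean and unit standard deviation. Done
#' separately per subject (removes inter-individual amplitude differences),
#' per muscle (keeps small-amplitude muscles in play) and per angle (removes
#' direction-dependent amplitude information, so classification must rely on
#' waveform shape). Zero-variance cells are set to zero with a warning.
#'
#' @param pset A [phasic_set()].
#' @return The normalized `phasic_set` (`normalized = TRUE`).
#' @export
zscore_normalize <- function(pset) {
  stopifnot(inherits(pset, "phasic_set"))
  waves <- pset$waves
  meta <- pset$meta
  cells <- interaction(meta$subject, meta$angle, drop = TRUE)
  degenerate <- 0L
  for (cell in levels(cells)) {
    rows <- which(cells == cell)
    for (m in seq_len(dim(waves)[2])) {
      vals <- waves[rows, m, , drop = FALSE]
      mu <- mean(vals)
      sdv <- stats::sd(as.vector(vals))
      if (!is.finite(sdv) || sdv == 0) {
        waves[rows, m, ] <- 0
        degenerate <- degenerate + 1L
      } else {
        waves[rows, m, ] <- (vals - mu) / sdv
      }
    }
  }
  if (degenerate > 0) {
    pt_warn("pt_degenerate_cell",
            "%d zero-variance (subject, muscle, angle) cells set to 0",
            degenerate)
  }
  pset$waves <- waves
  pset$normalized <- TRUE
  pset
}

#' Preprocess one raw trial into 1000-point phasic waveforms
#'
#' Runs the full per-trial chain: rectification and 20-300 Hz zero-phase
#' band-pass, 5 ms sliding-window integration, tonic estimation from the
#' quiet windows, tonic subtraction over the movement interval, and
#' duration normalization to 1000 points.
#'
#' @param trial A `raw_trial` (see [generate_raw_trial()]).
#' @param band,order,rectify_first Passed to [rectify_and_filter()].
#' @param window_s,mode Passed to [rms_integrate()].
#' @return Matrix muscles x 1000 of phasic waveforms (muscle rownames kept).
#' @export
preprocess_trial <- function(trial, band = c(20, 300), order = 3,
                             rectify_first = TRUE, window_s = 0.005,
                             mode = c("trapz", "rms")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trial, "raw_trial"))
  out <- t(apply(trial$signals, 1, function(x) {
    filt <- rectify_and_filter(x, trial$sampling_rate, band = band,
                               order = order,
                               rectify_first = rectify_first)
    env <- rms_integrate(filt, trial$sampling_rate, window_s = window_s,
                         mode = mode)
    tonic <- estimate_tonic(env, trial$sampling_rate, trial$onset,
                            trial$offset)
    time_normalize(extract_phasic(env, tonic, trial$onset, trial$offset))
  }))
  rownames(out) <- rownames(trial$signals)
  out
}

#' Preprocess a raw recording set into a phasic set
#'
#' Applies [preprocess_trial()] to every trial and (by default) the
#' per-(subject, muscle, angle) Z-score normalization.
#'
#' @param rset A `raw_recording_set` from [generate_dataset()].
#' @param normalize Apply [zscore_normalize()] (default `TRUE`).
#' @inheritParams preprocess_trial
#' @return A [phasic_set()].
#' @export
preprocess_dataset <- function(rset, normalize = TRUE, band = c(20, 300),
                               order = 3, rectify_first = TRUE,
                               window_s = 0.005, mode = c("trapz", "rms")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rset, "raw_recording_set"))
  cfg <- rset$config
  nt <- length(rset$trials)
  waves <- array(0, dim = c(nt, length(cfg$muscles), 1000L))
  meta <- data.frame(subject = integer(nt), angle = numeric(nt),
                     trial = integer(nt))
  for (i in seq_len(nt)) {
    tr <- rset$trials[[i]]
    waves[i, , ] <- preprocess_trial(tr, band = band, order = order,
                                     rectify_first = rectify_first,
                                     window_s = window_s, mode = mode)
    meta$subject[i] <- tr$subject
    meta$angle[i] <- tr$angle
    meta$trial[i] <- tr$trial
  }
  ps <- phasic_set(waves, meta,
                   muscles = data.frame(name = muscle_names(cfg),
                                        role = muscle_roles(cfg),
                                        stringsAsFactors = FALSE),
                   reference_angle = cfg$reference_angle,
                   normalized = FALSE)
  if (normalize) ps <- zscore_normalize(ps)
  ps
}
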