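# Synthetic sensorimotor EEG: montage, class profiles, session protocol,
# 1/f background, narrowband rhythms with ERD/ERS amplitude modulation.

#' Electrode montage specification
#'
#' The pipeline uses a six-channel scalp montage over frontal, central and
#' parieto-occipital sites, referenced at the vertex with a mastoid ground.
#' Channel order is meaningful: it fixes the row order of every recording.
#'
#' @param channel_labels character vector of exactly six 10-10 position
#'   names; default `c("Fz","C5","C3","C4","C6","POz")`.
#' @param reference_label reference electrode name (default `"Cz"`).
#' @param ground_label ground electrode name (default `"mastoid"`).
#' @return an object of class `montage_spec`.
#' @export
montage_spec <- function(channel_labels = c("Fz", "C5", "C3", "C4", "C6", "POz"),
                         reference_label = "Cz",
                         ground_label = "mastoid") {
  if (length(channel_labels) != 6L)
    stop_invalid("montage must have exactly 6 recording channels, got ",
                 length(channel_labels))
  if (anyDuplicated(channel_labels))
    stop_invalid("montage channel labels must be unique")
  structure(list(channel_labels = as.character(channel_labels),
                 reference_label = reference_label,
                 ground_label = ground_label),
            class = "montage_spec")
}

#' Frequency bands used throughout the pipeline
#'
#' mu and beta are the sensorimotor rhythms modulated by motor imagery;
#' alpha is the posterior rhythm prominent with eyes closed.
#' @return named list of `c(low, high)` Hz intervals.
#' @export
default_bands <- function() {
  list(mu = c(8, 12), beta = c(18, 26), alpha = c(8, 13))
}

#' Class names used by the four-class paradigm
#' @return character vector (left hand, right hand, feet motor imagery, and
#'   the eyes-closed alpha "null" class).
#' @export
mi_classes <- function() c("left_hand", "right_hand", "feet", "eyes_closed")

#' Per-class band-power modulation profile
#'
#' A profile maps each (channel, band) pair to a dimensionless amplitude
#' multiplier applied while the class is active: 1 is baseline, values < 1
#' are event-related desynchronization (ERD), values > 1 are event-related
#' synchronization (ERS). Multipliers apply to the oscillation's amplitude;
#' band power scales with the square.
#'
#' @param class_id one of [mi_classes()].
#' @param montage a [montage_spec()].
#' @param modulation named list like `list(C4 = c(mu = 0.6))`; unnamed
#'   (channel, band) pairs default to 1.
#' @param bands band definition list, see [default_bands()].
#' @return object of class `class_profile` with a channels x bands
#'   multiplier matrix.
#' @export
class_profile <- function(class_id, montage, modulation = list(),
                          bands = default_bands()) {
  if (!class_id %in% mi_classes())
    stop_invalid("unknown class_id: ", class_id)
  mult <- matrix(1, nrow = length(montage$channel_labels), ncol = length(bands),
                 dimnames = list(montage$channel_labels, names(bands)))
  for (ch in names(modulation)) {
    if (!ch %in% rownames(mult)) stop_invalid("profile channel not in montage: ", ch)
    v <- modulation[[ch]]
    if (any(v <= 0)) stop_invalid("multipliers must be > 0")
    mult[ch, names(v)] <- v
  }
  structure(list(class_id = class_id, modulation = mult, bands = bands),
            class = "class_profile")
}

#' Default somatotopic modulation profiles
#'
#' Standard sensorimotor somatotopy: hand imagery desynchronizes mu/beta
#' over the contralateral central electrodes, foot imagery over the midline
#' (with mild bilateral involvement), and eyes closure synchronizes the
#' posterior alpha rhythm.
#'
#' @param montage a [montage_spec()].
#' @param erd ERD amplitude multiplier (< 1), default 0.6.
#' @param ers eyes-closed alpha ERS multiplier (> 1), default 2.5.
#' @return named list of [class_profile()] objects, one per class.
#' @export
default_profiles <- function(montage = montage_spec(), erd = 0.6, ers = 2.5) {
  if (erd >= 1) stop_invalid("erd multiplier must be < 1")
  if (ers <= 1) stop_invalid("ers multiplier must be > 1")
  mild <- 1 - (1 - erd) / 2.5   # mild bilateral ERD accompanying foot imagery
  list(
    left_hand = class_profile("left_hand", montage, list(
      C4 = c(mu = erd, beta = erd), C6 = c(mu = erd, beta = erd))),
    right_hand = class_profile("right_hand", montage, list(
      C3 = c(mu = erd, beta = erd), C5 = c(mu = erd, beta = erd))),
    feet = class_profile("feet", montage, list(
      Fz = c(mu = erd, beta = erd),
      C3 = c(mu = mild), C4 = c(mu = mild),
      C5 = c(mu = mild), C6 = c(mu = mild))),
    eyes_closed = class_profile("eyes_closed", montage, list(
      POz = c(alpha = ers)))
  )
}

#' Session protocol: ordered class segments
#'
#' One trial is a continuous recording of every class in order, one minute
#' each by default; the first two seconds after each class onset are marked
#' for discard downstream (reaction time to the cue). The default order
#' starts with eyes closed.
#'
#' @param trials number of trials (recordings) per subject, default 5.
#' @param class_order character vector of class ids; default
#'   eyes_closed, left_hand, right_hand, feet.
#' @param segment_s duration of each class segment in seconds (default 60).
#' @param discard_s seconds discarded at each class onset (default 2).
#' @param subjects number of subjects the session covers (default 4).
#' @return object of class `protocol_schedule`: a segments data frame
#'   (trial, class_id, start, duration; start is within-trial seconds) plus
#'   the protocol parameters.
#' @export
make_protocol <- function(trials = 5,
                          class_order = c("eyes_closed", "left_hand",
                                          "right_hand", "feet"),
                          segment_s = 60, discard_s = 2, subjects = 4) {
  if (!is.numeric(trials) || trials < 1) stop_invalid("trials must be >= 1")
  if (segment_s <= 0 || discard_s < 0 || segment_s <= discard_s)
    stop_invalid("need segment_s > discard_s >= 0 and positive durations")
  if (!all(class_order %in% mi_classes()))
    stop_invalid("unknown class in class_order")
  k <- length(class_order)
  seg <- data.frame(
    trial = rep(seq_len(trials), each = k),
    class_id = rep(class_order, times = trials),
    start = rep((seq_len(k) - 1) * segment_s, times = trials),
    duration = segment_s,
    stringsAsFactors = FALSE
  )
  structure(list(segments = seg, discard_s = discard_s, trials = as.integer(trials),
                 subjects = as.integer(subjects), segment_s = segment_s,
                 class_order = class_order, trial_s = k * segment_s),
            class = "protocol_schedule")
}

#' 1/f ("pink") background noise
#'
#' Spectrally shaped Gaussian noise with power spectral density
#' proportional to `f^(-exponent)`, synthesized by FFT amplitude shaping
#' and normalized to the requested RMS amplitude.
#'
#' @param duration seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param exponent spectral slope in [0, 2]; 0 gives white noise.
#' @param scale RMS amplitude in microvolts.
#' @param seed integer seed; identical seeds give identical signals.
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
pink_noise <- function(duration, fs, exponent = 1, scale = 1, seed = NULL) {
  stopifnot_scalar_num(duration, "duration", lower = 1e-9)
  stopifnot_scalar_num(exponent, "exponent", lower = 0, upper = 2)
  n <- round(duration * fs)
  with_seed(seed, {
    w <- stats::rnorm(n)
    sp <- stats::fft(w)
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f[f > fs / 2] <- fs - f[f > fs / 2]   # fold to physical frequencies
    shape <- c(0, f[-1]^(-exponent / 2))  # kill DC
    x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s > 0) x <- x * (scale / s)
    x
  })
}

# Unit-RMS narrowband noise: band-filtered white noise. Zero-phase filtering
# avoids an onset transient in the synthesized rhythm.
narrowband_noise <- function(n, fs, band, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  pad <- min(4 * fs, n)
  x <- stats::rnorm(n + 2 * pad)
  y <- signal::filtfilt(bf, x)[(pad + 1):(pad + n)]
  y / stats::sd(y)
}


#' Simulation configuration
#'
#' Collects everything that defines a synthetic subject/session: montage,
#' per-class modulation profiles, sampling rate, background spectrum, and
#' per-band baseline oscillation amplitudes. Two background terms are
#' simulated: an independent pink-noise process per channel and a shared
#' ("common-mode") pink-noise process added to every channel, standing in
#' for volume-conducted background activity that a spatial filter can
#' cancel but a per-channel method cannot.
#'
#' @param montage a [montage_spec()].
#' @param profiles named list of [class_profile()]s covering every class in
#'   the protocol; default [default_profiles()].
#' @param fs sampling rate, Hz (default 500).
#' @param background_exponent 1/f slope of the background (default 1).
#' @param oscillation_amplitudes named numeric vector, baseline RMS
#'   amplitude in microvolts of each band's rhythm on every channel.
#' @param noise_scale RMS of the per-channel pink background, microvolts.
#' @param common_scale RMS of the shared pink background, microvolts.
#' @param common_alpha_amp RMS of a shared, class-independent alpha-band
#'   (8-13 Hz) process added to every channel, microvolts: volume-conducted
#'   posterior alpha that sits on top of the local mu rhythms.
#' @param leakage volume-conduction mixing coefficient in [0, 1): each
#'   channel records its local oscillation plus `leakage` times every other
#'   channel's oscillation. Per-channel band-power contrasts are diluted
#'   (sign preserved) while the mixture stays linearly separable, so
#'   learned spatial filters recover the local sources that per-channel
#'   methods see only through the mixture.
#' @param line_noise_hz optional mains frequency (NULL disables).
#' @param line_noise_amp mains amplitude in microvolts.
#' @param seed master integer seed; with the subject and trial ids it fixes
#'   the recording bit-for-bit.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(montage = montage_spec(),
                       profiles = default_profiles(montage),
                       fs = 500,
                       background_exponent = 1,
                       oscillation_amplitudes = c(mu = 6, beta = 4, alpha = 5),
                       noise_scale = 10,
                       common_scale = 8,
                       common_alpha_amp = 0,
                       leakage = 0.55,
                       line_noise_hz = NULL,
                       line_noise_amp = 0,
                       seed = 1L) {
  bands <- profiles[[1]]$bands
  if (fs <= 2 * max(unlist(bands)))
    stop_invalid("fs must exceed twice the highest simulated frequency")
  if (!all(names(bands) %in% names(oscillation_amplitudes)))
    stop_invalid("oscillation_amplitudes must name every band")
  structure(list(montage = montage, profiles = profiles, fs = fs,
                 background_exponent = background_exponent,
                 oscillation_amplitudes = oscillation_amplitudes,
                 noise_scale = noise_scale, common_scale = common_scale,
                 common_alpha_amp = common_alpha_amp, leakage = leakage,
                 line_noise_hz = line_noise_hz, line_noise_amp = line_noise_amp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Piecewise-constant per-sample multiplier trace for one (channel, band),
# cross-faded at segment boundaries with a raised-cosine kernel.
modulation_trace <- function(segments, mult_by_class, n, fs, fade_s = 0.5) {
  m <- rep(1, n)
  for (i in seq_len(nrow(segments))) {
    a <- round(segments$start[i] * fs) + 1L
    b <- min(n, round((segments$start[i] + segments$duration[i]) * fs))
    m[a:b] <- mult_by_class[[segments$class_id[i]]]
  }
  L <- round(fade_s * fs)
  if (L >= 2) {
    k <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
    k <- k / sum(k)
    padded <- c(rep(m[1], L), m, rep(m[n], L))
    sm <- stats::filter(padded, k, sides = 2)
    m <- as.numeric(sm[(L + 1):(L + n)])
  }
  m
}

#' Simulate one EEG recording (one trial)
#'
#' Each channel is the sum of: an independent 1/f background, a shared 1/f
#' background common to all channels, one unit-RMS narrowband noise process
#' per frequency band scaled by its baseline amplitude and by the active
#' class's (channel, band) multiplier (amplitude envelopes cross-fade over
#' 0.5 s at class boundaries), and optionally a mains sinusoid.
#'
#' @param config a [sim_config()].
#' @param protocol a [make_protocol()] schedule.
#' @param subject_id integer subject index (seeds the channel noise).
#' @param trial_id integer trial index within the protocol.
#' @param return_components if TRUE, attach the noise-free oscillation
#'   component per channel as attribute `"components"` (used by power
#'   oracles in tests).
#' @return object of class `eeg_recording`: `data` (channels x samples
#'   matrix, microvolts), `fs`, `montage`, `annotations` (data frame with
#'   start, end, class_id; half-open seconds), `subject_id`, `trial_id`.
#' @export
simulate_recording <- function(config, protocol, subject_id = 1L, trial_id = 1L,
                               return_components = FALSE) {
  seg <- protocol$segments[protocol$segments$trial == trial_id, , drop = FALSE]
  if (nrow(seg) == 0) stop_invalid("protocol has no segments for trial ", trial_id)
  missing <- setdiff(unique(seg$class_id), names(config$profiles))
  if (length(missing))
    stop(errorCondition(paste("no class profile for:", paste(missing, collapse = ", ")),
                        class = c("mibmi_config_error", "error")))
  fs <- config$fs
  chs <- config$montage$channel_labels
  bands <- config$profiles[[1]]$bands
  dur <- sum(seg$duration)
  n <- round(dur * fs)

  seed <- derive_seed(config$seed, subject_id, trial_id)
  rec_data <- matrix(0, nrow = length(chs), ncol = n,
                     dimnames = list(chs, NULL))
  osc_part <- if (return_components) rec_data else NULL

  with_seed(seed, {
    common <- if (config$common_scale > 0)
      pink_noise(dur, fs, config$background_exponent, config$common_scale)
    else 0
    if (!is.null(config$common_alpha_amp) && config$common_alpha_amp > 0)
      common <- common +
        config$common_alpha_amp * narrowband_noise(n, fs, c(8, 13))

    # local class-modulated oscillations, one set per channel
    osc <- matrix(0, nrow = length(chs), ncol = n)
    for (ci in seq_along(chs)) {
      for (b in names(bands)) {
        mult_by_class <- lapply(config$profiles, function(p)
          p$modulation[chs[ci], b])
        names(mult_by_class) <- names(config$profiles)
        env <- config$oscillation_amplitudes[[b]] *
          modulation_trace(seg, mult_by_class, n, fs)
        osc[ci, ] <- osc[ci, ] + env * narrowband_noise(n, fs, bands[[b]])
      }
    }
    # volume conduction: every channel also sees the other channels' sources
    lam <- if (is.null(config$leakage)) 0 else config$leakage
    if (lam > 0) {
      mix <- matrix(lam, length(chs), length(chs))
      diag(mix) <- 1
      osc <- mix %*% osc
    }

    for (ci in seq_along(chs)) {
      x <- pink_noise(dur, fs, config$background_exponent, config$noise_scale) +
        common
      if (!is.null(config$line_noise_hz) && config$line_noise_amp > 0) {
        t <- (seq_len(n) - 1) / fs
        x <- x + config$line_noise_amp *
          sin(2 * pi * config$line_noise_hz * t + stats::runif(1, 0, 2 * pi))
      }
      rec_data[ci, ] <- x + osc[ci, ]
      if (return_components) osc_part[ci, ] <- osc[ci, ]
    }
  })

  ann <- data.frame(start = seg$start, end = seg$start + seg$duration,
                    class_id = seg$class_id, stringsAsFactors = FALSE)
  rec <- structure(list(data = rec_data, fs = fs, montage = config$montage,
                        annotations = ann, subject_id = subject_id,
                        trial_id = trial_id),
                   class = "eeg_recording")
  if (return_components) attr(rec, "components") <- osc_part
  rec
}

#' Simulate all trials of one subject
#'
#' @inheritParams simulate_recording
#' @return list of [simulate_recording()] results, one per protocol trial.
#' @export
simulate_subject <- function(config, protocol, subject_id = 1L) {
  lapply(seq_len(protocol$trials), function(tr)
    simulate_recording(config, protocol, subject_id, tr))
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s trial %s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  cat("  channels:", paste(rownames(x$data), collapse = ", "), "\n")
  cat("  annotations:", nrow(x$annotations), "segments\n")
  invisible(x)
}

# duration in seconds
rec_duration <- function(rec) ncol(rec$data) / rec$fs
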