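# Signal conditioning: decimation, Butterworth filtering, windowing with
# overlap and onset discards, global amplitude rescaling.

#' Window specification for epoching
#'
#' @param length_s window length in seconds (1, 2 or 4 in this pipeline).
#' @param overlap_frac fractional overlap between consecutive windows,
#'   default 0.5.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(length_s = 4, overlap_frac = 0.5) {
  stopifnot_scalar_num(length_s, "length_s", lower = 1e-9)
  if (!is.numeric(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1)
    stop_invalid("overlap_frac must be in [0, 1)")
  structure(list(length_s = length_s, overlap_frac = overlap_frac),
            class = "window_spec")
}

# Apply a filter causally (forward only) or zero-phase to each row of a
# channels x samples matrix.
filter_rows <- function(x, flt, zero_phase = FALSE) {
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- if (zero_phase) signal::filtfilt(flt, x[i, ])
                else as.numeric(signal::filter(flt, x[i, ]))
  }
  out
}

#' Downsample a recording by an integer factor
#'
#' Applies a causal order-8 Butterworth anti-alias low-pass (cutoff at a
#' quarter of the target rate, comfortably above the 4-33 Hz analysis band)
#' and then keeps every q-th sample. Only integer decimation is supported;
#' the pipeline's single conversion is 500 to 250 Hz. Annotations are in
#' seconds and are unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs target sampling rate; must divide `rec$fs`.
#' @return the decimated `eeg_recording`.
#' @export
resample_to <- function(rec, target_fs) {
  if (rec$fs == target_fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop_invalid("target_fs must divide fs (integer decimation only); fs = ",
                 rec$fs, ", target = ", target_fs)
  q <- as.integer(round(q))
  aa <- signal::butter(8, (0.25 * target_fs) / (rec$fs / 2), type = "low")
  y <- filter_rows(rec$data, aa)
  rec$data <- y[, seq(1, ncol(y), by = q), drop = FALSE]
  rec$fs <- target_fs
  rec
}

#' Butterworth band-pass filter
#'
#' Order-3 4-33 Hz by default, matching the classification preprocessing.
#' Filtering is causal (forward only) by default so that offline results
#' estimate what the streaming path computes; a zero-phase option exists.
#'
#' @param rec an `eeg_recording`.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order (default 3).
#' @param zero_phase apply forward-backward filtering (default FALSE).
#' @return the filtered `eeg_recording`.
#' @export
bandpass <- function(rec, low = 4, high = 33, order = 3, zero_phase = FALSE) {
  if (!(low > 0 && high > low && high < rec$fs / 2))
    stop_invalid("need 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  rec$data <- filter_rows(rec$data, bf, zero_phase)
  rec
}

#' Butterworth high-pass filter
#'
#' Order-3 with 4 Hz cutoff by default (the SNR preprocessing).
#'
#' @inheritParams bandpass
#' @param cutoff cutoff frequency in Hz.
#' @return the filtered `eeg_recording`.
#' @export
highpass <- function(rec, cutoff = 4, order = 3, zero_phase = FALSE) {
  if (!(cutoff > 0 && cutoff < rec$fs / 2))
    stop_invalid("need 0 < cutoff < fs/2")
  hf <- signal::butter(order, cutoff / (rec$fs / 2), type = "high")
  rec$data <- filter_rows(rec$data, hf, zero_phase)
  rec
}

#' Analytic magnitude response of a Butterworth design
#'
#' Evaluates |H(e^{j 2 pi f / fs})| of the digital filter that [bandpass()]
#' or [highpass()] applies, as an independent oracle for gain tests.
#'
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param type "pass" or "high".
#' @param band band edges (pass) or cutoff (high), Hz.
#' @param order filter order.
#' @return numeric vector of magnitudes.
#' @export
butter_gain <- function(f, fs, type = c("pass", "high"), band, order = 3) {
  type <- match.arg(type)
  flt <- signal::butter(order, band / (fs / 2), type = type)
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(flt$b * zz^(seq_along(flt$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(flt$a * zz^(seq_along(flt$a) - 1)), complex(1))
  Mod(num / den)
}

#' Segment an annotated recording into labeled windows
#'
#' Within each annotated class segment the first `discard_s` seconds are
#' dropped (cue reaction time); windows then start at the usable-segment
#' start and advance by `length * (1 - overlap)`; windows that would cross
#' the segment end are dropped. With 60 s segments, 2 s discards, 4 s
#' windows and 50% overlap this yields 28 windows per segment and 112 per
#' four-class trial.
#'
#' @param rec an `eeg_recording` (annotated).
#' @param spec a [window_spec()].
#' @param discard_s seconds discarded at each segment onset (default 2).
#' @return object of class `epoch_set`: `windows` array (channels x samples
#'   x n), `labels` factor, `window_spec`, `fs`, `provenance` data frame
#'   (subject_id, trial_id, start).
#' @export
segment <- function(rec, spec, discard_s = 2) {
  fs <- rec$fs
  len <- round(spec$length_s * fs)
  stride_s <- spec$length_s * (1 - spec$overlap_frac)
  wins <- list(); labs <- character(0); starts <- numeric(0)
  for (i in seq_len(nrow(rec$annotations))) {
    a <- rec$annotations[i, ]
    usable_start <- a$start + discard_s
    usable <- a$end - usable_start
    if (usable < spec$length_s - 1e-9) {
      warning("segment of class ", a$class_id,
              " shorter than one window after discard; skipped")
      next
    }
    n_win <- floor((usable - spec$length_s) / stride_s + 1e-9) + 1
    for (k in seq_len(n_win)) {
      t0 <- usable_start + (k - 1) * stride_s
      s0 <- round(t0 * fs)
      if (s0 + len > ncol(rec$data)) break
      wins[[length(wins) + 1L]] <- rec$data[, (s0 + 1):(s0 + len), drop = FALSE]
      labs <- c(labs, a$class_id)
      starts <- c(starts, t0)
    }
  }
  n <- length(wins)
  arr <- array(0, dim = c(nrow(rec$data), len, n),
               dimnames = list(rownames(rec$data), NULL, NULL))
  for (k in seq_len(n)) arr[, , k] <- wins[[k]]
  structure(list(
    windows = arr,
    labels = factor(labs, levels = mi_classes()),
    window_spec = spec, fs = fs,
    provenance = data.frame(subject_id = rep(rec$subject_id, n),
                            trial_id = rep(rec$trial_id, n),
                            start = starts)),
    class = "epoch_set")
}

#' Combine epoch sets (same window spec and rate)
#' @param ... `epoch_set` objects.
#' @return a single `epoch_set`.
#' @export
bind_epochs <- function(...) {
  es <- list(...)
  if (length(es) == 1L && is.list(es[[1]]) && !inherits(es[[1]], "epoch_set"))
    es <- es[[1]]
  fs <- unique(vapply(es, function(e) e$fs, numeric(1)))
  lens <- unique(vapply(es, function(e) dim(e$windows)[2], numeric(1)))
  if (length(fs) != 1L || length(lens) != 1L)
    stop_invalid("epoch sets must share fs and window length")
  arr <- array(unlist(lapply(es, function(e) e$windows)),
               dim = c(dim(es[[1]]$windows)[1], lens,
                       sum(vapply(es, function(e) dim(e$windows)[3], numeric(1)))))
  dimnames(arr)[[1]] <- dimnames(es[[1]]$windows)[[1]]
  structure(list(windows = arr,
                 labels = factor(unlist(lapply(es, function(e) as.character(e$labels))),
                                 levels = mi_classes()),
                 window_spec = es[[1]]$window_spec, fs = fs[1],
                 provenance = do.call(rbind, lapply(es, function(e) e$provenance))),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<epoch_set> %d windows of %d ch x %d samples @ %g Hz (%g s, %.0f%% overlap)\n",
              d[3], d[1], d[2], x$fs, x$window_spec$length_s,
              100 * x$window_spec$overlap_frac))
  print(table(x$labels))
  invisible(x)
}

#' Closed-form window count per segment
#'
#' `floor((usable - length)/stride) + 1` with `stride = length * (1 -
#' overlap)`; the bookkeeping oracle for [segment()].
#'
#' @param usable_s usable segment seconds (after discard).
#' @param length_s window seconds.
#' @param overlap_frac fractional overlap.
#' @return integer count (0 if the window does not fit).
#' @export
window_count <- function(usable_s, length_s, overlap_frac = 0.5) {
  if (usable_s < length_s - 1e-9) return(0L)
  stride <- length_s * (1 - overlap_frac)
  as.integer(floor((usable_s - length_s) / stride + 1e-9) + 1)
}

#' Global amplitude rescale to [-1, 1]
#'
#' Affine map over all channels jointly sending the global minimum to -1
#' and the global maximum to +1 (inter-channel amplitude ratios are
#' preserved, which the spatial classifier exploits). With `extrema` given,
#' the same affine map (fitted elsewhere, e.g. on training recordings) is
#' applied instead; values may then exceed [-1, 1].
#'
#' @param x an `eeg_recording` or `epoch_set`.
#' @param extrema optional `c(min, max)` to freeze the map.
#' @return the rescaled object, with attribute `"extrema"` recording the
#'   map that was applied. Applying [rescale()] to its own output is the
#'   identity.
#' @export
rescale <- function(x, extrema = NULL) {
  vals <- if (inherits(x, "eeg_recording")) x$data else x$windows
  if (is.null(extrema)) extrema <- range(vals)
  if (!(extrema[2] > extrema[1]))
    stop(errorCondition("constant input: max equals min, rescale undefined",
                        class = c("mibmi_degenerate_input", "error")))
  out <- 2 * (vals - extrema[1]) / (extrema[2] - extrema[1]) - 1
  if (inherits(x, "eeg_recording")) x$data <- out else x$windows <- out
  attr(x, "extrema") <- extrema
  x
}

#' Pooled extrema across recordings (for fold-safe rescaling)
#' @param recordings list of `eeg_recording`s.
#' @return `c(min, max)` over all channels of all recordings.
#' @export
rescale_extrema <- function(recordings) {
  range(vapply(recordings, function(r) range(r$data), numeric(2)))
}
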