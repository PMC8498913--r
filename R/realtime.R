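# Online BMI replay: sliding-window classification at a fixed cadence,
# two-consecutive-agreement confirmation, and scoring against the cued
# game schedule.

#' Streaming configuration
#'
#' @param window_s classification window seconds (default 4).
#' @param tick_s classification cadence seconds (default 0.16).
#' @param agreement_n consecutive agreeing classifications required to
#'   confirm a command (default 2).
#' @return object of class `stream_config`.
#' @export
stream_config <- function(window_s = 4, tick_s = 0.16, agreement_n = 2) {
  if (tick_s <= 0) stop_invalid("tick_s must be > 0")
  if (agreement_n < 1) stop_invalid("agreement_n must be >= 1")
  structure(list(window_s = window_s, tick_s = tick_s,
                 agreement_n = as.integer(agreement_n)),
            class = "stream_config")
}

#' Sliding-window classification of a raw recording
#'
#' Replays the online path: the raw recording is decimated to the model's
#' rate and band-pass filtered with the causal (forward-only) filters, then
#' rescaled with the extrema frozen at training time (no lookahead) —
#' because these are causal time-invariant operations applied with
#' persistent state, filtering the whole recording once is sample-for-sample
#' identical to filtering tick by tick. At every tick `t = window_s,
#' window_s + tick_s, ...` (quantized to whole samples) the trailing
#' `window_s` seconds are classified.
#'
#' @param rec a raw `eeg_recording` (e.g. at 500 Hz).
#' @param clf a `trained_classifier`.
#' @param cfg a [stream_config()].
#' @param extrema rescale extrema frozen from the training recordings.
#' @param target_fs analysis rate (default 250).
#' @param band band-pass edges (default 4-33 Hz, order 3, causal).
#' @return data frame (class `command_stream_raw`) with columns `time`
#'   (seconds, end of window) and `class` (character); empty with a warning
#'   if the recording is shorter than one window.
#' @export
stream_classify <- function(rec, clf, cfg = stream_config(), extrema,
                            target_fs = 250, band = c(4, 33)) {
  pre <- bandpass(resample_to(rec, target_fs), band[1], band[2], order = 3)
  pre <- rescale(pre, extrema)
  fs <- pre$fs
  len <- round(cfg$window_s * fs)
  n <- ncol(pre$data)
  if (n < len) {
    warning("recording shorter than one window; empty stream")
    return(structure(data.frame(time = numeric(0), class = character(0)),
                     class = c("command_stream_raw", "data.frame")))
  }
  n_ticks <- floor((n / fs - cfg$window_s) / cfg$tick_s + 1e-9) + 1
  times <- cfg$window_s + (seq_len(n_ticks) - 1) * cfg$tick_s
  ends <- round(times * fs)
  arr <- array(0, dim = c(nrow(pre$data), len, n_ticks),
               dimnames = list(rownames(pre$data), NULL, NULL))
  for (k in seq_len(n_ticks))
    arr[, , k] <- pre$data[, (ends[k] - len + 1):ends[k], drop = FALSE]
  eps <- structure(list(windows = arr,
                        labels = factor(rep(NA_character_, n_ticks),
                                        levels = mi_classes()),
                        window_spec = window_spec(cfg$window_s, 0), fs = fs,
                        provenance = data.frame(subject_id = rec$subject_id,
                                                trial_id = rec$trial_id,
                                                start = times - cfg$window_s)),
                   class = "epoch_set")
  pred <- predict(clf, eps)
  structure(data.frame(time = times, class = as.character(pred$labels),
                       stringsAsFactors = FALSE),
            class = c("command_stream_raw", "data.frame"))
}

#' Confirm commands by consecutive agreement
#'
#' A command is confirmed at tick k when the last `agreement_n` raw
#' classifications (since the previous confirmation) all agree;
#' confirmations consume their ticks, so agreeing runs re-confirm every
#' `agreement_n` ticks (non-overlapping pairs for the default n = 2:
#' A,A,A,A confirms twice).
#'
#' @param raw a [stream_classify()] result (time-ordered).
#' @param cfg a [stream_config()].
#' @return data frame (class `command_stream_confirmed`) with `time` and
#'   `class` of each confirmed command.
#' @export
confirm_commands <- function(raw, cfg = stream_config()) {
  if (is.unsorted(raw$time, strictly = TRUE))
    stop_invalid("raw stream times must be strictly increasing")
  n_req <- cfg$agreement_n
  times <- numeric(0); classes <- character(0)
  run_class <- NA_character_; run_len <- 0L
  for (i in seq_len(nrow(raw))) {
    if (identical(raw$class[i], run_class)) run_len <- run_len + 1L
    else { run_class <- raw$class[i]; run_len <- 1L }
    if (run_len == n_req) {
      times <- c(times, raw$time[i]); classes <- c(classes, run_class)
      run_len <- 0L; run_class <- NA_character_  # ticks consumed
    }
  }
  structure(data.frame(time = times, class = classes, stringsAsFactors = FALSE),
            class = c("command_stream_confirmed", "data.frame"))
}

#' Cued game schedule
#'
#' A 240 s session by default: after an initial 1 s delay a colored cube
#' spawns every 4 s; each color demands one action (Blue: feet, Green: left
#' hand, Red: right hand, Yellow: eyes closed). Colors are drawn uniformly.
#'
#' @param total_s session length in seconds (default 240).
#' @param initial_delay_s delay before the first cue (default 1).
#' @param spawn_interval_s seconds between cues (default 4).
#' @param seed integer seed for the color sequence.
#' @return object of class `game_schedule`: data frame `cues` (spawn,
#'   color, class) plus the timing parameters.
#' @export
make_schedule <- function(total_s = 240, initial_delay_s = 1,
                          spawn_interval_s = 4, seed = 1L) {
  if (total_s <= 0 || initial_delay_s < 0 || spawn_interval_s <= 0)
    stop_invalid("durations must be positive")
  color_map <- c(Blue = "feet", Green = "left_hand",
                 Red = "right_hand", Yellow = "eyes_closed")
  spawn <- seq(initial_delay_s, total_s - 1e-9, by = spawn_interval_s)
  colors <- with_seed(seed, sample(names(color_map), length(spawn), replace = TRUE))
  structure(list(cues = data.frame(spawn = spawn, color = colors,
                                   class = unname(color_map[colors]),
                                   stringsAsFactors = FALSE),
                 total_s = total_s, initial_delay_s = initial_delay_s,
                 spawn_interval_s = spawn_interval_s, color_map = color_map),
            class = "game_schedule")
}

#' Score a confirmed command stream against a game schedule
#'
#' Each cue accepts responses from its spawn until the next spawn (or the
#' session end for the last cue). The first confirmed command matching the
#' cue's required class clears it and scores one point; its latency is
#' recorded. A cue with commands but no match is wrong; a cue with no
#' commands in its window is missed. Commands arriving after a cue is
#' cleared are ignored, as are mismatching commands (the game shows
#' feedback but the cue stays active) — with a sliding analysis window the
#' first commands after a cue change necessarily still carry the previous
#' class, so a mismatch must not consume the cue.
#'
#' @param confirmed a [confirm_commands()] result.
#' @param schedule a [make_schedule()].
#' @return object of class `game_score`: `points`, per-cue `outcomes` data
#'   frame (spawn, class, outcome, latency).
#' @export
run_game <- function(confirmed, schedule) {
  cues <- schedule$cues
  k <- nrow(cues)
  ends <- c(cues$spawn[-1], schedule$total_s)
  outcome <- character(k); latency <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    in_win <- confirmed$time >= cues$spawn[i] & confirmed$time < ends[i]
    cmds <- confirmed[in_win, , drop = FALSE]
    if (nrow(cmds) == 0) { outcome[i] <- "missed"; next }
    hit <- which(cmds$class == cues$class[i])
    if (length(hit)) {
      outcome[i] <- "correct"
      latency[i] <- cmds$time[hit[1]] - cues$spawn[i]
    } else outcome[i] <- "wrong"
  }
  structure(list(points = sum(outcome == "correct"),
                 n_cues = k,
                 outcomes = data.frame(spawn = cues$spawn, class = cues$class,
                                       outcome = outcome, latency = latency,
                                       stringsAsFactors = FALSE)),
            class = "game_score")
}

#' @export
print.game_score <- function(x, ...) {
  tb <- table(factor(x$outcomes$outcome, levels = c("correct", "wrong", "missed")))
  cat(sprintf("<game_score> %d / %d points (%s)\n", x$points, x$n_cues,
              paste(names(tb), tb, sep = ": ", collapse = ", ")))
  invisible(x)
}
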