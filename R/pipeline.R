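# End-to-end orchestration: simulate -> preprocess -> train -> crossvalidate
# -> stream -> game, with a manifest for reproducibility.

#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline; it round-trips losslessly
#' through JSON. Every stochastic step derives its seed from `seed`.
#'
#' @param seed master integer seed.
#' @param subjects,trials session size (defaults 4 subjects, 5 trials).
#' @param segment_s class-segment seconds (default 60).
#' @param discard_s onset discard seconds (default 2).
#' @param window_s classification window seconds (default 4).
#' @param family classifier family (default `"psda_svm"`, the fastest).
#' @param target_fs analysis rate (default 250).
#' @param band band-pass edges in Hz (default 4-33).
#' @param cnn extra arguments for the CNN builders (list).
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, subjects = 4L, trials = 5L,
                           segment_s = 60, discard_s = 2, window_s = 4,
                           family = "psda_svm", target_fs = 250,
                           band = c(4, 33), cnn = list()) {
  list(seed = as.integer(seed),
       protocol = list(trials = as.integer(trials), segment_s = segment_s,
                       discard_s = discard_s, subjects = as.integer(subjects)),
       sim = list(fs = 500, background_exponent = 1,
                  oscillation_amplitudes = list(mu = 6, beta = 4, alpha = 5),
                  noise_scale = 10, common_scale = 8, common_alpha_amp = 0,
                  leakage = 0.55, erd = 0.6, ers = 2.5),
       preprocess = list(target_fs = target_fs, band = band, order = 3,
                         window_s = window_s, overlap = 0.5),
       classifier = c(list(family = family), cnn),
       stream = list(window_s = window_s, tick_s = 0.16, agreement_n = 2),
       game = list(total_s = 240, initial_delay_s = 1, spawn_interval_s = 4))
}

#' Read / write a pipeline configuration
#' @param path JSON file path.
#' @return the configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$sim$oscillation_amplitudes <- as.list(cfg$sim$oscillation_amplitudes)
  cfg
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sim_config_from <- function(config) {
  m <- montage_spec()
  sim_config(montage = m,
             profiles = default_profiles(m, erd = config$sim$erd,
                                         ers = config$sim$ers),
             fs = config$sim$fs,
             background_exponent = config$sim$background_exponent,
             oscillation_amplitudes = unlist(config$sim$oscillation_amplitudes),
             noise_scale = config$sim$noise_scale,
             common_scale = config$sim$common_scale,
             common_alpha_amp = config$sim$common_alpha_amp,
             leakage = config$sim$leakage,
             seed = config$seed)
}

#' Protocol schedule matching a game session
#'
#' Builds the segment list a compliant subject would produce while playing:
#' eyes closed during the initial delay, then each cue's class held until
#' the next cue spawns.
#'
#' @param schedule a [make_schedule()].
#' @param trial trial number to stamp on the segments (lets the game
#'   recording draw a noise realization distinct from the training trials).
#' @return a `protocol_schedule` usable with [simulate_recording()].
#' @export
game_protocol <- function(schedule, trial = 99L) {
  cues <- schedule$cues
  ends <- c(cues$spawn[-1], schedule$total_s)
  seg <- data.frame(trial = as.integer(trial),
                    class_id = c("eyes_closed", cues$class),
                    start = c(0, cues$spawn),
                    duration = c(cues$spawn[1], ends - cues$spawn),
                    stringsAsFactors = FALSE)
  structure(list(segments = seg, discard_s = 0, trials = 1L, subjects = 1L,
                 segment_s = NA_real_, class_order = unique(seg$class_id),
                 trial_s = schedule$total_s),
            class = "protocol_schedule")
}

#' Fit a classifier for online streaming
#'
#' Trains on all but one of a subject's recordings (the held-out one is the
#' CNN's early-stopping set) and freezes the preprocessing state the
#' streaming path needs: the rescale extrema of the training recordings.
#'
#' @param recordings a subject's recordings (list of `eeg_recording`).
#' @param family classifier family.
#' @param wspec a [window_spec()].
#' @param seed integer seed.
#' @param val_idx index of the held-out recording (default the last).
#' @param target_fs,band,discard_s preprocessing parameters.
#' @param ... passed to the model builder or SVM trainer.
#' @return list with `clf` (trained classifier) and `extrema`.
#' @export
fit_online_classifier <- function(recordings, family = "psda_svm",
                                  wspec = window_spec(4, 0.5), seed = 1L,
                                  val_idx = length(recordings),
                                  target_fs = 250, band = c(4, 33),
                                  discard_s = 2, ...) {
  pre <- lapply(recordings, function(r)
    bandpass(resample_to(r, target_fs), band[1], band[2], order = 3))
  tr_idx <- setdiff(seq_along(pre), val_idx)
  ext <- rescale_extrema(pre[tr_idx])
  train_eps <- bind_epochs(lapply(pre[tr_idx], function(r)
    segment(rescale(r, ext), wspec, discard_s)))
  if (family == "psda_svm") {
    clf <- train_svm_psda(psda_features(train_eps, band = band), ...)
  } else {
    val_eps <- segment(rescale(pre[[val_idx]], ext), wspec, discard_s)
    builder <- if (family == "spatial_cnn") build_spatial_cnn else build_standard_cnn
    spec <- builder(channels = dim(train_eps$windows)[1],
                    samples = dim(train_eps$windows)[2], n_classes = 4, ...)
    clf <- train_cnn(spec, train_eps, val_eps, seed = seed)
  }
  list(clf = clf, extrema = ext)
}

#' Run the full pipeline
#'
#' Simulates the session, cross-validates the configured classifier per
#' subject, computes the information transfer rate from the pooled
#' accuracy, replays one online game session, and writes recordings,
#' results and a manifest under `out_dir`.
#'
#' @param config a [default_config()]-shaped list, or a JSON path.
#' @param out_dir output directory (created if missing).
#' @return results bundle: per-subject `cv_result`s, pooled accuracy, ITR
#'   (bits/min), the game score, and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("mibmi_")) {
  if (is.character(config)) config <- read_config(config)
  for (need in c("seed", "protocol", "sim", "preprocess", "classifier",
                 "stream", "game"))
    if (is.null(config[[need]]))
      stop_invalid("missing config section: ", need)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec_dir <- file.path(out_dir, "recordings")
  dir.create(rec_dir, showWarnings = FALSE)

  scfg <- sim_config_from(config)
  proto <- make_protocol(config$protocol$trials,
                         segment_s = config$protocol$segment_s,
                         discard_s = config$protocol$discard_s,
                         subjects = config$protocol$subjects)
  wspec <- window_spec(config$preprocess$window_s, config$preprocess$overlap)
  family <- config$classifier$family

  message("[simulate] ", config$protocol$subjects, " subjects x ",
          proto$trials, " trials")
  subjects <- lapply(seq_len(config$protocol$subjects), function(s)
    simulate_subject(scfg, proto, s))
  rec_paths <- character(0)
  for (s in seq_along(subjects)) for (tr in seq_along(subjects[[s]])) {
    p <- file.path(rec_dir, sprintf("subject%02d_trial%02d.csv", s, tr))
    write_recording(subjects[[s]][[tr]], p)
    rec_paths <- c(rec_paths, p, paste0(p, ".json"))
  }

  message("[crossvalidate] family = ", family, ", window = ",
          wspec$length_s, " s")
  cv <- lapply(seq_along(subjects), function(s)
    crossvalidate(subjects[[s]], family, wspec,
                  seed = derive_seed(config$seed, 900, s),
                  target_fs = config$preprocess$target_fs,
                  band = config$preprocess$band,
                  discard_s = config$protocol$discard_s))
  pooled_cm <- Reduce("+", lapply(cv, function(x) x$pooled_cm))
  pooled_acc <- sum(diag(pooled_cm)) / sum(pooled_cm)
  subject_acc <- vapply(cv, function(x) x$pooled_accuracy, numeric(1))
  rate <- itr(4, pooled_acc, wspec$length_s)
  message(sprintf("[evaluate] pooled accuracy %.4f -> ITR %.2f bits/min",
                  pooled_acc, rate))

  message("[stream] replaying one game session")
  schedule <- make_schedule(config$game$total_s, config$game$initial_delay_s,
                            config$game$spawn_interval_s,
                            seed = derive_seed(config$seed, 77))
  fit <- fit_online_classifier(subjects[[1]], family, wspec,
                               seed = derive_seed(config$seed, 901),
                               target_fs = config$preprocess$target_fs,
                               band = config$preprocess$band,
                               discard_s = config$protocol$discard_s)
  game_rec <- simulate_recording(scfg, game_protocol(schedule, trial = 99L),
                                 subject_id = 1L, trial_id = 99L)
  raw <- stream_classify(game_rec, fit$clf,
                         stream_config(config$stream$window_s,
                                       config$stream$tick_s,
                                       config$stream$agreement_n),
                         extrema = fit$extrema,
                         target_fs = config$preprocess$target_fs,
                         band = config$preprocess$band)
  confirmed <- confirm_commands(raw, stream_config(config$stream$window_s,
                                                   config$stream$tick_s,
                                                   config$stream$agreement_n))
  score <- run_game(confirmed, schedule)
  message(sprintf("[game] %d / %d points", score$points, score$n_cues))

  manifest <- list(seed = config$seed,
                   seeds = list(cv = vapply(seq_along(subjects), function(s)
                                  derive_seed(config$seed, 900, s), integer(1)),
                                schedule = derive_seed(config$seed, 77),
                                online = derive_seed(config$seed, 901)),
                   n_recordings = length(rec_paths) / 2,
                   windows_per_subject = vapply(cv, function(x)
                     sum(x$pooled_cm), numeric(1)),
                   file_md5 = as.list(tools::md5sum(rec_paths)))
  results <- list(subject_accuracy = subject_acc, pooled_accuracy = pooled_acc,
                  itr_bits_per_min = rate, game_points = score$points,
                  game_cues = score$n_cues)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cv = cv, pooled_cm = pooled_cm, results = results,
                 score = score, manifest = manifest, out_dir = out_dir))
}
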