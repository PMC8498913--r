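# Shared fixtures. Simulated data is cached per session so several test
# files can reuse one subject without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small synthetic subject: default generator, shortened class segments
small_subject <- function(seed = 11, segment_s = 30) {
  cached(sprintf("subject_%d_%g", seed, segment_s), {
    cfg <- sim_config(seed = seed)
    proto <- make_protocol(trials = 5, segment_s = segment_s, discard_s = 2)
    simulate_subject(cfg, proto, 1)
  })
}

# a full-protocol subject (60 s class segments), cached across test files
fullsize_subject <- function(seed, subject_id = 1L) {
  cached(sprintf("full_%d_%d", seed, subject_id), {
    cfg <- sim_config(seed = seed)
    proto <- make_protocol(trials = 5, segment_s = 60, discard_s = 2)
    simulate_subject(cfg, proto, subject_id)
  })
}

# preprocessed + segmented train/test split of the small subject
small_split <- function(seed = 11, window_s = 2, segment_s = 30) {
  cached(sprintf("split_%d_%g_%g", seed, window_s, segment_s), {
    recs <- small_subject(seed, segment_s)
    pre <- lapply(recs, function(r) bandpass(resample_to(r, 250)))
    ext <- rescale_extrema(pre[1:4])
    wspec <- window_spec(window_s, 0.5)
    list(train = bind_epochs(lapply(pre[1:4], function(r)
           segment(rescale(r, ext), wspec, 2))),
         test = segment(rescale(pre[[5]], ext), wspec, 2),
         extrema = ext)
  })
}

# an annotated recording with deterministic (zero) data, for windowing
# bookkeeping tests that need no signal content
blank_recording <- function(segments_s, fs = 250, classes = mi_classes()) {
  k <- length(segments_s)
  starts <- cumsum(c(0, segments_s))[seq_len(k)]
  n <- round(sum(segments_s) * fs)
  structure(list(
    data = matrix(0, 6, n, dimnames = list(montage_spec()$channel_labels, NULL)),
    fs = fs, montage = montage_spec(),
    annotations = data.frame(start = starts, end = starts + segments_s,
                             class_id = rep_len(classes, k),
                             stringsAsFactors = FALSE),
    subject_id = 1L, trial_id = 1L), class = "eeg_recording")
}

# epoch_set built directly from an array (bypasses segmentation)
epochs_from_array <- function(arr, labels, fs = 250, window_s = dim(arr)[2] / fs) {
  structure(list(windows = arr,
                 labels = factor(labels, levels = mi_classes()),
                 window_spec = window_spec(window_s, 0.5), fs = fs,
                 provenance = data.frame(subject_id = rep(1L, dim(arr)[3]),
                                         trial_id = rep(1L, dim(arr)[3]),
                                         start = seq_len(dim(arr)[3]))),
            class = "epoch_set")
}
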