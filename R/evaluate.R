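# Fivefold leave-one-recording-out cross-validation, confusion matrices,
# Wolpaw information transfer rate, and alpha-rhythm spectral SNR.

#' Confusion matrix
#'
#' @param y_true,y_pred vectors of equal length; values must be in
#'   `class_order`.
#' @param class_order character vector fixing row/column order.
#' @return K x K integer matrix of class `confusion_matrix`; rows are true
#'   classes, columns predicted.
#' @export
confusion <- function(y_true, y_pred, class_order = mi_classes()) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop_invalid("length mismatch")
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad)) stop_invalid("labels outside class_order: ",
                                paste(bad, collapse = ", "))
  m <- table(factor(y_true, levels = class_order),
             factor(y_pred, levels = class_order))
  structure(unclass(as.matrix(m)), dimnames = list(true = class_order,
                                                   predicted = class_order),
            class = c("confusion_matrix", "matrix"))
}

#' Accuracy of a confusion matrix
#' @param cm a [confusion()] matrix.
#' @return trace / total.
#' @export
cm_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Mean and standard error of the mean
#'
#' @param values numeric vector, `n >= 2`.
#' @return list with `mean`, `sem` (= sd/sqrt(n)) and `n`.
#' @export
summarize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop_invalid("need n >= 2 values")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)),
       n = length(values))
}

#' Wolpaw information transfer rate
#'
#' `ITR = (log2 N + A log2 A + (1 - A) log2((1 - A)/(N - 1))) * 60/w` in
#' bits per minute, with the limits `0 * log2(0) = 0` at A = 0 and A = 1.
#' The value is returned as the formula gives it (it is negative below
#' chance; no clipping at zero).
#'
#' @param N number of targets (classes), >= 2.
#' @param A accuracy, fraction in [0, 1].
#' @param w seconds per command, including latencies (> 0).
#' @return bits per minute.
#' @export
itr <- function(N, A, w) {
  if (!is.numeric(N) || any(N < 2)) stop_invalid("N must be >= 2")
  if (any(A < 0 | A > 1)) stop_invalid("A must be in [0, 1]")
  if (any(w <= 0)) stop_invalid("w must be > 0")
  xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)
  bits <- log2(N) + xlogx(A) + ifelse(A < 1, (1 - A) * log2((1 - A) / (N - 1)), 0)
  out <- bits * 60 / w
  out + 0   # normalize -0 to 0
}

#' Fivefold leave-one-recording-out cross-validation
#'
#' The five recordings of one subject define the folds: in fold i,
#' recording i is held out and the remaining four train the model. All
#' data-dependent preprocessing is fitted on the training recordings only:
#' the global rescale extrema are pooled over the four training recordings
#' and applied unchanged to the held-out one, and the SVM's feature
#' standardization is fitted on training windows. For the CNN families the
#' held-out fold also serves as the early-stopping validation set, matching
#' the training protocol.
#'
#' @param recordings list of exactly 5 annotated `eeg_recording`s (one
#'   subject).
#' @param family `"spatial_cnn"`, `"standard_cnn"` or `"psda_svm"`.
#' @param wspec a [window_spec()].
#' @param seed integer seed (CNN training).
#' @param target_fs analysis rate (default 250).
#' @param band band-pass edges (default 4-33 Hz, order 3).
#' @param discard_s onset discard in seconds (default 2).
#' @param classifier_fn optional diagnostic hook: a
#'   `function(train_epochs, test_epochs)` returning predicted labels for
#'   the test windows, used in place of the model families (e.g. an oracle
#'   or a constant classifier when testing the fold bookkeeping itself).
#' @param ... extra arguments passed to the model builder
#'   ([build_spatial_cnn()], [build_standard_cnn()]) or to
#'   [train_svm_psda()].
#' @return object of class `cv_result`: per-fold confusion matrices and
#'   accuracies, the pooled confusion matrix and accuracy, and mean +/- SEM
#'   across folds.
#' @export
crossvalidate <- function(recordings, family = c("spatial_cnn", "standard_cnn",
                                                 "psda_svm"),
                          wspec = window_spec(4, 0.5), seed = 1L,
                          target_fs = 250, band = c(4, 33), discard_s = 2,
                          classifier_fn = NULL, ...) {
  family <- if (is.null(classifier_fn)) match.arg(family) else "custom"
  if (length(recordings) != 5)
    stop_invalid("fivefold scheme needs exactly 5 recordings, got ",
                 length(recordings))
  pre <- lapply(recordings, function(r)
    bandpass(resample_to(r, target_fs), band[1], band[2], order = 3))
  folds <- vector("list", 5)
  for (i in 1:5) {
    tr_idx <- setdiff(1:5, i)
    ext <- rescale_extrema(pre[tr_idx])
    train_eps <- bind_epochs(lapply(pre[tr_idx], function(r)
      segment(rescale(r, ext), wspec, discard_s)))
    test_eps <- segment(rescale(pre[[i]], ext), wspec, discard_s)
    if (!is.null(classifier_fn)) {
      pred <- list(labels = classifier_fn(train_eps, test_eps))
    } else if (family == "psda_svm") {
      clf <- train_svm_psda(psda_features(train_eps, band = band), ...)
      pred <- predict(clf, psda_features(test_eps, band = band))
    } else {
      builder <- if (family == "spatial_cnn") build_spatial_cnn else build_standard_cnn
      spec <- builder(channels = dim(train_eps$windows)[1],
                      samples = dim(train_eps$windows)[2], n_classes = 4, ...)
      clf <- train_cnn(spec, train_eps, test_eps, seed = derive_seed(seed, i))
      pred <- predict(clf, test_eps)
    }
    folds[[i]] <- confusion(test_eps$labels, pred$labels)
  }
  pooled <- Reduce("+", folds)
  class(pooled) <- class(folds[[1]])
  accs <- vapply(folds, cm_accuracy, numeric(1))
  structure(list(fold_cms = folds, pooled_cm = pooled,
                 fold_accuracy = accs, pooled_accuracy = cm_accuracy(pooled),
                 across_folds = summarize(accs), family = family,
                 window_s = wspec$length_s),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %g s windows: pooled accuracy %.4f (folds %.4f +/- %.4f SEM)\n",
              x$family, x$window_s, x$pooled_accuracy,
              x$across_folds$mean, x$across_folds$sem))
  invisible(x)
}

#' Alpha-rhythm spectral SNR
#'
#' The recording (high-pass filtered at 4 Hz beforehand) is cut into
#' consecutive windows of `window_s` seconds; each window's amplitude
#' spectrum is the square root of a Welch estimate (Hann taper over the
#' full window, zero-padded to `nfft`). The signal amplitude is the largest
#' spectral amplitude inside the alpha band; the noise amplitude is the
#' largest amplitude in `noise_band` outside an exclusion zone of
#' `exclusion_hz` around the detected peak; per window,
#' `SNR = 10 log10((A_signal/A_noise)^2)` dB.
#'
#' @param rec an `eeg_recording` (expected already high-pass filtered).
#' @param channel channel label or index (default "POz").
#' @param alpha_band Hz interval, default `c(8, 13)`.
#' @param window_s window seconds (default 5).
#' @param exclusion_hz half-width of the peak exclusion zone (default 2).
#' @param noise_band where noise peaks are searched (default `c(4, 40)`).
#' @param nfft FFT length (default 4096).
#' @param seg_len Welch taper length; default the full window
#'   (zero-padding to `nfft` then reduces bias). Set e.g. `seg_len = 1024`
#'   to average several shorter segments instead.
#' @return list with `per_window` (dB vector), `mean`, `sd`, `n`.
#' @export
snr_alpha <- function(rec, channel = "POz", alpha_band = c(8, 13), window_s = 5,
                      exclusion_hz = 2, noise_band = c(4, 40), nfft = 4096,
                      seg_len = NULL) {
  x <- if (is.character(channel)) rec$data[channel, ] else rec$data[channel, ]
  n_win <- floor(length(x) / (window_s * rec$fs))
  if (n_win < 1) stop_invalid("recording shorter than one SNR window")
  wlen <- round(window_s * rec$fs)
  out <- numeric(0)
  for (k in seq_len(n_win)) {
    seg <- x[((k - 1) * wlen + 1):(k * wlen)]
    sl <- if (is.null(seg_len)) wlen else min(seg_len, wlen)
    psd <- welch_psd(seg, rec$fs, seg_len = sl, nfft = max(nfft, sl))
    amp <- sqrt(psd$power[1, ])
    in_alpha <- psd$freqs >= alpha_band[1] & psd$freqs <= alpha_band[2]
    if (!any(in_alpha) || all(!is.finite(amp[in_alpha])) ||
        max(amp[in_alpha]) <= 0) {
      warning("window ", k, ": no detectable alpha peak; skipped")
      next
    }
    a_sig <- max(amp[in_alpha])
    f_peak <- psd$freqs[in_alpha][which.max(amp[in_alpha])]
    in_noise <- psd$freqs >= noise_band[1] & psd$freqs <= noise_band[2] &
      abs(psd$freqs - f_peak) > exclusion_hz
    a_noise <- max(amp[in_noise])
    out <- c(out, 10 * log10((a_sig / a_noise)^2))
  }
  list(per_window = out, mean = mean(out), sd = stats::sd(out), n = length(out))
}
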