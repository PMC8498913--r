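# Welch power spectral density, band power, PSDA feature vectors for the
# SVM route, and ERD/ERS maps.

# periodic Hann taper (matches the convention of common scientific stacks)
hann_taper <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is split into `seg_len`-sample
#' segments advanced by `seg_len * (1 - overlap_frac)`, each segment is
#' demeaned, tapered (Hann by default), zero-padded to `nfft` and
#' transformed; one-sided density scaling is used, so the integral of the
#' estimate over frequency approximates the signal variance.
#'
#' @param x numeric vector, or channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param seg_len segment length in samples (default `min(512, n)`).
#' @param taper `"hann"` or `"rectangular"`.
#' @param overlap_frac fractional overlap between segments (default 0.5).
#' @param nfft FFT length, `>= seg_len` (zero padding allowed); default
#'   `seg_len`.
#' @return object of class `psd_estimate`: `freqs` (Hz, 0..fs/2 inclusive
#'   on a uniform grid), `power` (channels x freqs, power per Hz), `fs`,
#'   and method metadata.
#' @export
welch_psd <- function(x, fs, seg_len = NULL, taper = c("hann", "rectangular"),
                      overlap_frac = 0.5, nfft = NULL) {
  taper <- match.arg(taper)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (is.null(seg_len)) seg_len <- min(512L, n)
  if (seg_len > n)
    stop_invalid("signal shorter than seg_len (", n, " < ", seg_len, ")")
  if (is.null(nfft)) nfft <- seg_len
  if (nfft < seg_len) stop_invalid("nfft must be >= seg_len")
  w <- if (taper == "hann") hann_taper(seg_len) else rep(1, seg_len)
  u <- sum(w^2)
  step <- max(1L, round(seg_len * (1 - overlap_frac)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  nb <- nfft %/% 2 + 1L
  freqs <- (0:(nb - 1L)) * fs / nfft
  pow <- matrix(0, nrow = nrow(x), ncol = nb)
  for (ci in seq_len(nrow(x))) {
    acc <- numeric(nb)
    for (s0 in starts) {
      seg <- x[ci, s0:(s0 + seg_len - 1L)]
      seg <- (seg - mean(seg)) * w
      X <- stats::fft(c(seg, numeric(nfft - seg_len)))
      p <- Mod(X[seq_len(nb)])^2 / (fs * u)
      # one-sided: double all bins except DC (and Nyquist when nfft is even)
      dbl <- rep(2, nb); dbl[1] <- 1
      if (nfft %% 2 == 0) dbl[nb] <- 1
      acc <- acc + p * dbl
    }
    pow[ci, ] <- acc / length(starts)
  }
  rownames(pow) <- rownames(x)
  structure(list(freqs = freqs, power = pow, fs = fs,
                 meta = list(seg_len = seg_len, taper = taper,
                             overlap_frac = overlap_frac, nfft = nfft,
                             n_segments = length(starts))),
            class = "psd_estimate")
}

#' Integrated band power from a PSD estimate
#'
#' Trapezoidal integral of the density over the grid points falling inside
#' the band, per channel.
#'
#' @param psd a [welch_psd()] result.
#' @param band `c(low, high)` in Hz, inside `[0, fs/2]`.
#' @return named numeric vector, one value per channel (power units).
#' @export
band_power <- function(psd, band) {
  if (band[1] < 0 || band[2] > psd$fs / 2 || band[2] <= band[1])
    stop_invalid("band must lie within [0, fs/2]")
  idx <- which(psd$freqs >= band[1] - 1e-9 & psd$freqs <= band[2] + 1e-9)
  if (length(idx) < 2L)
    stop_invalid("band [", band[1], ", ", band[2], "] covers fewer than two grid points")
  f <- psd$freqs[idx]
  apply(psd$power[, idx, drop = FALSE], 1, function(p)
    sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2))
}

# frequency-bin indices of the PSDA analysis band on the Welch grid
psda_band_bins <- function(fs, nfft, band) {
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
}

#' PSDA feature matrix for the SVM route
#'
#' Per window: Welch PSD of every channel (512-point Hann segments by
#' default; for windows shorter than 512 samples the segment length is
#' clipped to the window and zero-padded to `nfft`, keeping the frequency
#' grid identical across window sizes), restricted to the analysis band and
#' concatenated channel-wise.
#'
#' @param epochs an `epoch_set` (expected at 250 Hz).
#' @param band analysis band in Hz, default `c(4, 33)`.
#' @param seg_len Welch segment length (default 512, clipped to the window).
#' @param nfft FFT length (default 512).
#' @param overlap_frac Welch overlap (default 0.5).
#' @return object of class `feature_matrix`: numeric matrix rows = windows,
#'   columns = channels x in-band bins, with `labels` and method metadata
#'   attached as attributes.
#' @export
psda_features <- function(epochs, band = c(4, 33), seg_len = 512L, nfft = 512L,
                          overlap_frac = 0.5) {
  d <- dim(epochs$windows)
  sl <- min(seg_len, d[2])
  bins <- psda_band_bins(epochs$fs, nfft, band)
  out <- matrix(0, nrow = d[3], ncol = d[1] * length(bins))
  for (k in seq_len(d[3])) {
    psd <- welch_psd(epochs$windows[, , k, drop = TRUE], epochs$fs,
                     seg_len = sl, overlap_frac = overlap_frac, nfft = nfft)
    out[k, ] <- as.numeric(t(psd$power[, bins, drop = FALSE]))
  }
  chs <- dimnames(epochs$windows)[[1]]
  freqs <- (0:(nfft %/% 2)) * epochs$fs / nfft
  colnames(out) <- as.vector(t(outer(chs, sprintf("%.2fHz", freqs[bins]), paste, sep = "_")))
  structure(out, labels = epochs$labels,
            meta = list(band = band, seg_len = sl, nfft = nfft,
                        overlap_frac = overlap_frac, fs = epochs$fs,
                        window_samples = d[2], channels = chs),
            class = c("feature_matrix", "matrix"))
}

#' ERD/ERS map: relative band-power change per class
#'
#' For every (class, channel, band), the relative change of mean band power
#' against a reference condition: negative values are event-related
#' desynchronization, positive are synchronization. By default the
#' reference for each class is the pooled mean over the other classes
#' (there is no explicit rest condition in the protocol).
#'
#' @param epochs an `epoch_set`.
#' @param reference_class a class id to use as the common reference, or
#'   NULL (default) for the pooled-others reference.
#' @param bands named list of Hz intervals, default [default_bands()].
#' @return 3-d array class x channel x band of relative changes (class
#'   `erd_ers_map`); entries where the reference power is zero are NA.
#' @export
erd_ers_map <- function(epochs, reference_class = NULL, bands = default_bands()) {
  if (!is.null(reference_class) && !reference_class %in% epochs$labels)
    stop_invalid("reference class not present in epochs")
  d <- dim(epochs$windows)
  chs <- dimnames(epochs$windows)[[1]]
  classes <- levels(droplevels(epochs$labels))
  # per-window band power, channels x bands x windows
  bp <- array(0, dim = c(d[1], length(bands), d[3]))
  sl <- min(512L, d[2])
  for (k in seq_len(d[3])) {
    psd <- welch_psd(epochs$windows[, , k, drop = TRUE], epochs$fs,
                     seg_len = sl, nfft = max(512L, sl))
    for (bi in seq_along(bands)) bp[, bi, k] <- band_power(psd, bands[[bi]])
  }
  out <- array(NA_real_, dim = c(length(classes), length(chs), length(bands)),
               dimnames = list(classes, chs, names(bands)))
  for (cl in classes) {
    in_cl <- epochs$labels == cl
    ref <- if (is.null(reference_class)) !in_cl else epochs$labels == reference_class
    m_cl <- apply(bp[, , in_cl, drop = FALSE], c(1, 2), mean)
    m_rf <- apply(bp[, , ref, drop = FALSE], c(1, 2), mean)
    rel <- (m_cl - m_rf) / m_rf
    rel[m_rf <= 0] <- NA_real_
    out[cl, , ] <- rel
  }
  structure(out, class = c("erd_ers_map", "array"))
}
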