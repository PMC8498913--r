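# Confusion matrices, cross-validation bookkeeping, Wolpaw ITR, alpha SNR,
# mean +/- SEM summaries.

test_that("confusion matrices tally correctly", {
  cls <- mi_classes()
  y <- cls[c(1, 1, 2, 3, 4, 2, 2, 1)]
  expect_equal(unname(diag(confusion(y, y))), c(3, 3, 1, 1))

  all_first <- confusion(y, rep(cls[1], 8))
  expect_equal(unname(colSums(all_first)), c(8, 0, 0, 0))

  # hand-enumerated 8-item tally
  p <- cls[c(1, 2, 2, 3, 4, 2, 1, 1)]
  cm <- confusion(y, p)
  manual <- matrix(0, 4, 4, dimnames = dimnames(cm))
  for (i in 1:8) manual[y[i], p[i]] <- manual[y[i], p[i]] + 1
  expect_equal(unclass(cm), manual, ignore_attr = TRUE)
  expect_equal(sum(cm), 8)
  expect_equal(cm_accuracy(cm), sum(y == p) / 8)

  expect_error(confusion(y, p[1:3]), class = "mibmi_invalid_argument")
  expect_error(confusion(c(y, "blink"), c(p, "blink")),
               class = "mibmi_invalid_argument")
})

test_that("cross-validation folds are leave-one-recording-out", {
  # tiny recordings; classifiers replaced by diagnostic hooks
  cfg <- sim_config(seed = 5)
  proto <- make_protocol(5, segment_s = 6, discard_s = 1)
  recs <- simulate_subject(cfg, proto, 1)

  oracle <- crossvalidate(recs, wspec = window_spec(2, 0.5), discard_s = 1,
                          classifier_fn = function(tr, te) te$labels)
  expect_equal(oracle$pooled_accuracy, 1)
  expect_true(all(oracle$pooled_cm[upper.tri(oracle$pooled_cm)] == 0))
  expect_length(oracle$fold_cms, 5)
  # pooling conserves counts
  expect_equal(sum(oracle$pooled_cm),
               sum(vapply(oracle$fold_cms, sum, numeric(1))))

  constant <- crossvalidate(recs, wspec = window_spec(2, 0.5), discard_s = 1,
                            classifier_fn = function(tr, te)
                              factor(rep("feet", dim(te$windows)[3]),
                                     levels = mi_classes()))
  expect_equal(constant$pooled_accuracy, 0.25)

  expect_error(crossvalidate(recs[1:4], "psda_svm"),
               class = "mibmi_invalid_argument")
})

test_that("ITR reproduces the published table and its limiting cases", {
  table1 <- list(list(4, 0.9322, 4, 23.02),
                 list(4, 0.83,   4, 16.09),
                 list(2, 0.8641, 3,  8.53),
                 list(2, 0.776,  2,  6.98),
                 list(2, 0.84,   2, 10.97),
                 list(4, 0.954,  2, 49.74),
                 list(4, 0.84,   4, 16.68))
  for (row in table1)
    expect_equal(round(itr(row[[1]], row[[2]], row[[3]]), 2), row[[4]])

  expect_equal(itr(4, 1, 4), 30)        # log2(4) * 60/4
  expect_equal(itr(4, 0.25, 4), 0)      # chance: exactly zero bits
  expect_identical(sign(1 / itr(4, 0.25, 4)), 1)  # never negative zero
  expect_equal(itr(4, 0, 4), (2 + log2(1 / 3)) * 15)  # 0*log0 limit

  expect_error(itr(1, 0.9, 4), class = "mibmi_invalid_argument")
  expect_error(itr(4, 1.2, 4), class = "mibmi_invalid_argument")
  expect_error(itr(4, 0.9, 0), class = "mibmi_invalid_argument")
})

test_that("ITR is strictly increasing in accuracy and proportional to 1/w", {
  a <- seq(0.26, 1, by = 0.02)
  v <- itr(4, a, 4)
  expect_true(all(diff(v) > 0))
  w <- c(1, 2, 4, 8)
  expect_equal(itr(4, 0.9, w) * w, rep(itr(4, 0.9, 1), 4))
})

test_that("summarize returns mean and standard error", {
  expect_equal(summarize(c(1, 1, 1)), list(mean = 1, sem = 0, n = 3))
  expect_equal(summarize(c(0, 2)), list(mean = 1, sem = 1, n = 2))
  expect_equal(summarize(c(3, 1, 2)), summarize(c(1, 2, 3)))
  expect_error(summarize(5), class = "mibmi_invalid_argument")
})

# recording with known spectral content for SNR checks
tone_recording <- function(freqs, amps, fs = 500, dur = 10, noise_sd = 0) {
  t <- (seq_len(fs * dur) - 1) / fs
  x <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  if (noise_sd > 0) x <- x + rnorm(length(x), sd = noise_sd)
  structure(list(data = matrix(rep(x, each = 6), nrow = 6,
                               dimnames = list(montage_spec()$channel_labels, NULL)),
                 fs = fs, montage = montage_spec(),
                 annotations = data.frame(start = 0, end = dur,
                                          class_id = "eyes_closed"),
                 subject_id = 1L, trial_id = 1L),
            class = "eeg_recording")
}

test_that("alpha SNR matches analytic cases and the component oracle", {
  # on-bin frequencies for nfft 4096 at 500 Hz
  f_alpha <- 82 * 500 / 4096    # ~10.01 Hz
  f_out <- 164 * 500 / 4096     # ~20.02 Hz

  equal_amp <- snr_alpha(tone_recording(c(f_alpha, f_out), c(1, 1)))
  expect_equal(equal_amp$mean, 0, tolerance = 0.5)

  ratio10 <- snr_alpha(tone_recording(c(f_alpha, f_out), c(10, 1)))
  expect_equal(ratio10$mean, 20, tolerance = 0.5)

  # oracle: amplitude spectra of the two components computed separately
  set.seed(31)
  t <- (seq_len(5000) - 1) / 500
  sig <- 5 * sin(2 * pi * f_alpha * t)
  noise <- rnorm(5000)
  spec_amp <- function(x) {
    ps <- welch_psd(x, 500, seg_len = 2500, nfft = 4096)
    list(freqs = ps$freqs, amp = sqrt(ps$power[1, ]))
  }
  s <- spec_amp(sig); nz <- spec_amp(noise)
  a_sig <- max(s$amp[s$freqs >= 8 & s$freqs <= 13])
  f_pk <- s$freqs[s$freqs >= 8 & s$freqs <= 13][
    which.max(s$amp[s$freqs >= 8 & s$freqs <= 13])]
  a_noise <- max(nz$amp[nz$freqs >= 4 & nz$freqs <= 40 &
                          abs(nz$freqs - f_pk) > 2])
  oracle_db <- 20 * log10(a_sig / a_noise)

  rec <- tone_recording(f_alpha, 5, dur = 10)
  rec$data <- rec$data + matrix(rep(noise, each = 6), nrow = 6)
  measured <- snr_alpha(rec)
  expect_equal(measured$mean, oracle_db, tolerance = 2)
  expect_equal(measured$n, 2)
})
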