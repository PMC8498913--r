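# Synthetic EEG generator: protocol arithmetic, background spectrum,
# determinism, and the ERD/ERS modulation semantics.

test_that("protocol schedules have the documented segment bookkeeping", {
  p <- make_protocol(5, segment_s = 60, discard_s = 2)
  expect_equal(nrow(p$segments), 20)
  expect_equal(p$trial_s, 240)

  p1 <- make_protocol(1, class_order = "eyes_closed", segment_s = 60,
                      discard_s = 0)
  expect_equal(nrow(p1$segments), 1)
  expect_equal(p1$segments$duration, 60)

  p2 <- make_protocol(2, segment_s = 10, discard_s = 2)
  expect_equal(nrow(p2$segments), 8)
  expect_equal(unique(p2$segments$duration - p2$discard_s), 8)

  expect_error(make_protocol(0), class = "mibmi_invalid_argument")
  expect_error(make_protocol(2, segment_s = -5), class = "mibmi_invalid_argument")
  expect_error(make_protocol(2, segment_s = 2, discard_s = 2),
               class = "mibmi_invalid_argument")
})

test_that("pink noise has the requested spectral slope and is seeded", {
  expect_identical(pink_noise(2, 250, 1, 5, seed = 42),
                   pink_noise(2, 250, 1, 5, seed = 42))
  expect_equal(length(pink_noise(2.5, 250, 1)), 625)

  # exponent 0: flat spectrum within estimation error
  x <- pink_noise(60, 250, 0, 1, seed = 1)
  ps <- welch_psd(x, 250, seg_len = 512)
  lo <- mean(ps$power[1, ps$freqs >= 2 & ps$freqs < 20])
  hi <- mean(ps$power[1, ps$freqs >= 80 & ps$freqs < 120])
  expect_lt(abs(log10(lo / hi)), 0.15)

  # exponent 1: fitted log-log slope in [-1.3, -0.7] over 50 realizations
  slopes <- vapply(1:50, function(s) {
    ps <- welch_psd(pink_noise(60, 250, 1, 1, seed = s), 250, seg_len = 1024)
    sel <- ps$freqs >= 2 & ps$freqs <= 40
    unname(coef(lm(log10(ps$power[1, sel]) ~ log10(ps$freqs[sel])))[2])
  }, numeric(1))
  expect_gt(mean(slopes), -1.3)
  expect_lt(mean(slopes), -0.7)
})

test_that("recordings are bit-reproducible and annotation-conserving", {
  cfg <- sim_config(seed = 3)
  proto <- make_protocol(1, segment_s = 8, discard_s = 2)
  r1 <- simulate_recording(cfg, proto, 1, 1)
  r2 <- simulate_recording(cfg, proto, 1, 1)
  expect_identical(r1$data, r2$data)
  # different trial or subject gives a different realization
  expect_false(identical(r1$data,
                         simulate_recording(cfg, make_protocol(2, segment_s = 8,
                                                               discard_s = 2),
                                            1, 2)$data))
  # annotated segment durations sum to the recording duration
  expect_equal(sum(r1$annotations$end - r1$annotations$start),
               ncol(r1$data) / r1$fs)
  # missing profile is a configuration error
  cfg2 <- cfg
  cfg2$profiles <- cfg$profiles[c("left_hand", "right_hand", "feet")]
  expect_error(simulate_recording(cfg2, proto, 1, 1),
               class = "mibmi_config_error")
})

test_that("band modulation scales oscillation power as the multiplier squared", {
  # leakage off so channel power reflects its own sources only
  mont <- montage_spec()
  profiles <- default_profiles(mont)
  profiles$left_hand <- class_profile("left_hand", mont, list(C4 = c(mu = 0.5)))
  mk_cfg <- function(amps) sim_config(
    montage = mont, profiles = profiles, fs = 250,
    oscillation_amplitudes = amps, noise_scale = 1, common_scale = 0,
    leakage = 0, seed = 9)
  proto <- make_protocol(1, class_order = c("eyes_closed", "left_hand"),
                         segment_s = 20, discard_s = 2)
  band_pow <- function(rec, ch, t0, t1) {
    osc <- attr(rec, "components")
    seg <- osc[ch, (round(t0 * rec$fs) + 1):round(t1 * rec$fs)]
    ps <- welch_psd(seg, rec$fs, seg_len = 1024)
    band_power(ps, c(8, 12))
  }
  # alpha amplitude 0: the 8-13 Hz alpha process overlaps the mu band and
  # would otherwise add class-independent power to both segments
  rec <- simulate_recording(mk_cfg(c(mu = 6, beta = 4, alpha = 0)), proto, 1, 1,
                            return_components = TRUE)
  # mu multiplier 0.5 on C4 -> mu power during left_hand ~ 0.25 x baseline
  p_base <- band_pow(rec, "C4", 4, 18)    # eyes_closed segment, away from fades
  p_mod <- band_pow(rec, "C4", 24, 38)    # left_hand segment
  expect_equal(p_mod / p_base, 0.25, tolerance = 0.15)

  # doubling the baseline amplitude quadruples the band's power contribution
  rec2 <- simulate_recording(mk_cfg(c(mu = 12, beta = 4, alpha = 0)), proto, 1, 1,
                             return_components = TRUE)
  expect_equal(band_pow(rec2, "C4", 4, 18) / p_base, 4, tolerance = 0.1)
})

test_that("null profiles give statistically identical band power across segments", {
  mont <- montage_spec()
  null_profiles <- lapply(mi_classes(), function(cl) class_profile(cl, mont))
  names(null_profiles) <- mi_classes()
  proto <- make_protocol(1, class_order = c("eyes_closed", "feet"),
                         segment_s = 9, discard_s = 1)
  rejections <- vapply(1:100, function(s) {
    cfg <- sim_config(montage = mont, profiles = null_profiles, fs = 250,
                      seed = s)
    rec <- simulate_recording(cfg, proto, 1, 1)
    eps <- segment(rec, window_spec(2, 0.5), 1)
    bp <- vapply(seq_len(dim(eps$windows)[3]), function(k)
      band_power(welch_psd(eps$windows[3, , k], eps$fs, seg_len = 256),
                 c(8, 12)), numeric(1))
    a <- bp[eps$labels == "eyes_closed"]
    b <- bp[eps$labels == "feet"]
    stats::t.test(log(a), log(b))$p.value < 0.01
  }, logical(1))
  expect_gte(mean(!rejections), 0.95)
})

test_that("eyes-closed alpha synchronization dominates POz alpha power", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s)
    proto <- make_protocol(1, segment_s = 12, discard_s = 2)
    rec <- simulate_recording(cfg, proto, 1, 1)
    eps <- segment(rec, window_spec(4, 0.5), 2)
    bp <- vapply(seq_len(dim(eps$windows)[3]), function(k)
      band_power(welch_psd(eps$windows["POz", , k], eps$fs, seg_len = 512),
                 c(8, 13)), numeric(1))
    means <- tapply(bp, eps$labels, mean)
    means["eyes_closed"] > max(means[c("left_hand", "right_hand", "feet")])
  }, logical(1))
  expect_true(all(hits))
})

test_that("montage and profile validation reject malformed inputs", {
  expect_error(montage_spec(c("Fz", "C3")), class = "mibmi_invalid_argument")
  expect_error(montage_spec(rep("Fz", 6)), class = "mibmi_invalid_argument")
  expect_error(class_profile("left_hand", montage_spec(),
                             list(C4 = c(mu = -1))),
               class = "mibmi_invalid_argument")
  expect_error(class_profile("jump", montage_spec()),
               class = "mibmi_invalid_argument")
  expect_error(default_profiles(erd = 1.2), class = "mibmi_invalid_argument")
})
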