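# Online control scheme: tick grid, agreement confirmation, game scoring.

raw_stream <- function(classes, tick_s = 0.16, window_s = 4) {
  structure(data.frame(time = window_s + (seq_along(classes) - 1) * tick_s,
                       class = classes, stringsAsFactors = FALSE),
            class = c("command_stream_raw", "data.frame"))
}

test_that("two-agreement confirmation pairs ticks without overlap", {
  cfg <- stream_config()
  expect_equal(nrow(confirm_commands(raw_stream(c("feet", "feet")), cfg)), 1)
  expect_equal(confirm_commands(raw_stream(c("feet", "feet")), cfg)$time, 4.16)

  alt <- raw_stream(rep(c("feet", "left_hand"), length.out = 5))
  expect_equal(nrow(confirm_commands(alt, cfg)), 0)

  four <- confirm_commands(raw_stream(rep("feet", 4)), cfg)
  expect_equal(nrow(four), 2)          # non-overlapping pairs 1-2 and 3-4
  expect_equal(four$time, c(4.16, 4.48))

  # a confirmation never contradicts its defining raw pair
  set.seed(12)
  rnd <- raw_stream(sample(mi_classes(), 200, replace = TRUE))
  conf <- confirm_commands(rnd, cfg)
  for (i in seq_len(nrow(conf))) {
    k <- match(conf$time[i], rnd$time)
    expect_identical(rnd$class[k], conf$class[i])
    expect_identical(rnd$class[k - 1], conf$class[i])
  }

  # general agreement_n
  cfg3 <- stream_config(agreement_n = 3)
  expect_equal(nrow(confirm_commands(raw_stream(rep("feet", 8)), cfg3)), 2)
  expect_error(stream_config(tick_s = 0), class = "mibmi_invalid_argument")
})

test_that("the tick grid is arithmetic and handles short recordings", {
  split <- small_split(window_s = 2)
  clf <- train_svm_psda(psda_features(split$train))
  rec10 <- small_subject()[[5]]
  rec10$data <- rec10$data[, 1:(10 * rec10$fs)]
  cfg <- stream_config(window_s = 2, tick_s = 0.16)
  raw <- stream_classify(rec10, clf, cfg, extrema = split$extrema)
  # floor((10 - 2)/0.16) + 1 = 51 classifications
  expect_equal(nrow(raw), 51)
  expect_equal(raw$time, 2 + 0.16 * (0:50))

  short <- rec10
  short$data <- short$data[, 1:(1 * short$fs)]
  expect_warning(empty <- stream_classify(short, clf, cfg,
                                          extrema = split$extrema),
                 "shorter than one window")
  expect_equal(nrow(empty), 0)
})

test_that("a 4 s window at 0.16 s ticks gives 38 classifications over 10 s", {
  # pure arithmetic of the tick grid
  expect_equal(floor((10 - 4) / 0.16) + 1, 38)
  split4 <- small_split(window_s = 4)
  clf <- train_svm_psda(psda_features(split4$train))
  rec10 <- small_subject()[[4]]
  rec10$data <- rec10$data[, 1:(10 * rec10$fs)]
  raw <- stream_classify(rec10, clf, stream_config(), extrema = split4$extrema)
  expect_equal(nrow(raw), 38)
})

test_that("confirmed labels do not switch to a new class before it starts", {
  # high-separability configuration: strong modulation, low noise
  mont <- montage_spec()
  cfg <- sim_config(montage = mont,
                    profiles = default_profiles(mont, erd = 0.2, ers = 4),
                    noise_scale = 2, common_scale = 0, leakage = 0, seed = 8)
  proto <- make_protocol(9, class_order = c("eyes_closed", "left_hand"),
                         segment_s = 12, discard_s = 2)
  recs <- lapply(1:5, function(tr)
    simulate_recording(cfg, make_protocol(5, class_order = c("eyes_closed",
                                                             "left_hand"),
                                          segment_s = 12, discard_s = 2),
                       1, tr))
  pre <- lapply(recs[1:4], function(r) bandpass(resample_to(r, 250)))
  ext <- rescale_extrema(pre)
  tr_eps <- bind_epochs(lapply(pre, function(r)
    segment(rescale(r, ext), window_spec(4, 0.5), 2)))
  clf <- train_svm_psda(psda_features(tr_eps))
  step_rec <- simulate_recording(cfg, proto, 1, 9)   # change at t = 12 s
  raw <- stream_classify(step_rec, clf, stream_config(), extrema = ext)
  conf <- confirm_commands(raw, stream_config())
  first_flip <- conf$time[conf$class == "left_hand"][1]
  expect_gte(first_flip, 12)
})

test_that("game schedules have the documented cue grid", {
  s <- make_schedule(240, 1, 4, seed = 2)
  expect_equal(nrow(s$cues), 60)
  expect_equal(s$cues$spawn, seq(1, 237, by = 4))
  expect_true(all(s$cues$class %in% mi_classes()))
  # color -> action mapping is fixed
  expect_equal(unname(s$color_map["Green"]), "left_hand")
  expect_equal(unname(s$color_map["Blue"]), "feet")

  expect_equal(nrow(make_schedule(9, 1, 4)$cues), 2)
  expect_identical(make_schedule(240, 1, 4, seed = 7)$cues$color,
                   make_schedule(240, 1, 4, seed = 7)$cues$color)
  expect_error(make_schedule(-1), class = "mibmi_invalid_argument")
})

test_that("game scoring matches a brute-force replay", {
  sched <- make_schedule(60, 1, 4, seed = 3)

  # perfect responder: a matching command shortly after each spawn
  perfect <- structure(data.frame(time = sched$cues$spawn + 0.5,
                                  class = sched$cues$class,
                                  stringsAsFactors = FALSE),
                       class = c("command_stream_confirmed", "data.frame"))
  expect_equal(run_game(perfect, sched)$points, nrow(sched$cues))

  none <- structure(data.frame(time = numeric(0), class = character(0)),
                    class = c("command_stream_confirmed", "data.frame"))
  g0 <- run_game(none, sched)
  expect_equal(g0$points, 0)
  expect_true(all(g0$outcomes$outcome == "missed"))

  # random command streams: independent replay gives the same score
  replay <- function(cmds, sched) {
    ends <- c(sched$cues$spawn[-1], sched$total_s)
    pts <- 0
    for (i in seq_len(nrow(sched$cues))) {
      for (j in seq_len(nrow(cmds))) {
        if (cmds$time[j] >= sched$cues$spawn[i] && cmds$time[j] < ends[i] &&
            cmds$class[j] == sched$cues$class[i]) { pts <- pts + 1; break }
      }
    }
    pts
  }
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    cmds <- structure(data.frame(
      time = sort(runif(n, 0, 60)),
      class = sample(mi_classes(), n, replace = TRUE),
      stringsAsFactors = FALSE),
      class = c("command_stream_confirmed", "data.frame"))
    expect_equal(run_game(cmds, sched)$points, replay(cmds, sched))
  }
})
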