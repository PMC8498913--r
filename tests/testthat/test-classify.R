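# Classifier families: architecture contracts, gradient correctness,
# training behavior, prediction semantics.

tiny_arch <- function(type = 0L) {
  list(type = type, dw_trunk = if (type == 1L) 1L else 0L,
       channels = 3L, samples = 64L, n_classes = 3L,
       F1 = if (type == 1L) 6L else 4L, L1 = if (type == 1L) 5L else 1L,
       F2 = if (type == 1L) 6L else 4L, L2 = 5L,
       F3 = if (type == 1L) 6L else 4L, L3 = 5L,
       p1 = 2L, p2 = 2L, p3 = 2L, dropout = 0)
}

test_that("model specs encode the spatial-vs-temporal layer-1 contrast", {
  sp <- build_spatial_cnn(6, 1000, 4)
  expect_equal(sp$arch$type, 0L)
  expect_equal(sp$arch$L1, 1L)          # layer-1 kernel: all channels x 1
  expect_lt(sp$n_params, 1e6)

  st <- build_standard_cnn(6, 1000, 4)
  expect_equal(st$arch$type, 1L)        # layer-1 spatial extent 1
  expect_gt(st$arch$L1, 1L)
  expect_lt(st$n_params, 1e6)

  # 1 s windows leave a non-empty time axis after pooling
  expect_s3_class(build_spatial_cnn(6, 250, 4), "model_spec")
  expect_error(build_spatial_cnn(6, 32, 4), class = "mibmi_invalid_argument")
  expect_error(build_spatial_cnn(6, 128, 4, pools = c(8, 8, 8)),
               class = "mibmi_invalid_argument")
})

test_that("forward pass emits a probability simplex, ties break low", {
  for (builder in list(build_spatial_cnn, build_standard_cnn)) {
    spec <- builder(6, 250, 4)
    X <- array(0, dim = c(6, 250, 3))
    # quick fit on noise to obtain parameters
    eps <- epochs_from_array(array(rnorm(6 * 250 * 24), dim = c(6, 250, 24)),
                             rep(mi_classes(), 6))
    spec$train$max_epochs <- 2L
    clf <- train_cnn(spec, eps, eps, seed = 1)
    probs <- mibmi:::cnn_predict_cpp(clf$params, spec$arch, X)
    expect_equal(colSums(probs), rep(1, 3), tolerance = 1e-9)
    expect_true(all(probs >= 0))
    # duplicated windows give identical predictions
    pr <- predict(clf, epochs_from_array(array(eps$windows[, , c(1, 1)],
                                               dim = c(6, 250, 2)),
                                         c("feet", "feet")))
    expect_equal(pr$labels[1], pr$labels[2])
    expect_equal(pr$scores[1, ], pr$scores[2, ])
  }
})

test_that("analytic gradients match finite differences in both variants", {
  set.seed(42)
  X <- array(rnorm(3 * 64 * 6), dim = c(3, 64, 6))
  y <- as.integer(c(0, 1, 2, 0, 1, 2))
  for (type in c(0L, 1L)) {
    arch <- tiny_arch(type)
    fit <- mibmi:::cnn_train_cpp(X, y, X, y, arch,
                                 list(lr = 1e-3, batch = 6L, max_epochs = 1L,
                                      patience = 1L), 1L)
    p <- fit$params
    lg <- mibmi:::cnn_loss_grad_cpp(p, arch, X, y)
    for (nm in c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2",
                 "W3", "b3", "g3", "be3", "Wd", "bd")) {
      for (r in 1:3) {
        idx <- sample(length(p[[nm]]), 1)
        eps <- 1e-5
        pp <- p; pp[[nm]][idx] <- pp[[nm]][idx] + eps
        pm <- p; pm[[nm]][idx] <- pm[[nm]][idx] - eps
        num <- (mibmi:::cnn_loss_cpp(pp, arch, X, y) -
                  mibmi:::cnn_loss_cpp(pm, arch, X, y)) / (2 * eps)
        ana <- lg$grads[[nm]][idx]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3,
                  label = sprintf("type %d grad %s[%d]", type, nm, idx))
      }
    }
  }
})

# easy synthetic task: class determined by one channel's 10 Hz band power
easy_epochs <- function(n_per_class, samples = 250, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  arr <- array(rnorm(6 * samples * n, sd = 0.3), dim = c(6, samples, n))
  t <- (seq_len(samples) - 1) / 250
  for (k in seq_len(n_per_class))
    arr[1, , k] <- arr[1, , k] + sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
  if (n > 0) arr <- arr / max(abs(arr))
  epochs_from_array(arr, rep(c("left_hand", "feet"), each = n_per_class))
}

test_that("training separates an easy task, stays at chance on shuffled labels", {
  tr <- easy_epochs(60, seed = 1)
  va <- easy_epochs(30, seed = 2)
  spec <- build_spatial_cnn(6, 250, 2, max_epochs = 60, patience = 15)
  clf <- train_cnn(spec, tr, va, seed = 3)
  expect_gt(clf$best_val_acc, 0.9)
  # determinism given seed
  clf2 <- train_cnn(spec, tr, va, seed = 3)
  expect_identical(clf$params$Wd, clf2$params$Wd)

  # label permutation: accuracy near chance (2 classes -> ~0.5)
  trs <- tr
  set.seed(9)
  trs$labels <- sample(trs$labels)
  vas <- va
  vas$labels <- sample(vas$labels)
  spec0 <- build_spatial_cnn(6, 250, 2, max_epochs = 20, patience = 5)
  clf0 <- train_cnn(spec0, trs, vas, seed = 4)
  expect_gt(clf0$best_val_acc, 0.3)
  expect_lt(clf0$best_val_acc, 0.7)

  # early stopping: training halts within patience of the best epoch
  expect_lte(length(clf0$history), clf0$best_epoch + spec0$train$patience)
  expect_error(train_cnn(spec, tr, easy_epochs(0)),
               class = "mibmi_invalid_argument")
})

test_that("cubic SVM route fits, is deterministic, and predicts consistently", {
  set.seed(7)
  x <- rbind(matrix(rnorm(50 * 4, 0), 50), matrix(rnorm(50 * 4, 4), 50))
  labs <- factor(rep(c("feet", "left_hand"), each = 50), levels = mi_classes())
  clf <- train_svm_psda(x, labs)
  pr <- predict(clf, x)
  expect_equal(mean(as.character(pr$labels) == as.character(labs)), 1)
  clf2 <- train_svm_psda(x, labs)
  expect_identical(clf$model$tot.nSV, clf2$model$tot.nSV)
  expect_error(train_svm_psda(x, factor(rep("feet", 100))),
               class = "mibmi_invalid_argument")
})

test_that("4-class PSDA + SVM beats 0.5 held out on default synthetic data", {
  split <- cached("svm_fullsize_2", {
    recs <- fullsize_subject(2)
    pre <- lapply(recs, function(r) bandpass(resample_to(r, 250)))
    ext <- rescale_extrema(pre[1:4])
    list(train = bind_epochs(lapply(pre[1:4], function(r)
           segment(rescale(r, ext), window_spec(4, 0.5), 2))),
         test = segment(rescale(pre[[5]], ext), window_spec(4, 0.5), 2))
  })
  clf <- train_svm_psda(psda_features(split$train))
  acc <- mean(predict(clf, psda_features(split$test))$labels ==
                split$test$labels)
  expect_gt(acc, 0.5)
})

test_that("prediction refuses fingerprint mismatches and is rescale-stable", {
  split <- small_split(window_s = 2)
  clf <- train_svm_psda(psda_features(split$train))
  wrong <- epochs_from_array(array(0, dim = c(6, 123, 1)), "feet")
  expect_error(predict(clf, wrong), class = "mibmi_contract_error")

  # re-applying the affine map of already-rescaled data (extrema -1, 1) is
  # the identity, so predictions are unchanged
  pr1 <- predict(clf, split$test)
  again <- rescale(split$test, c(-1, 1))
  pr2 <- predict(clf, again)
  expect_identical(pr1$labels, pr2$labels)
})
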