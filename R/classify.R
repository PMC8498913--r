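# The three classifier families: spatial-first CNN, temporal-first
# ("standard") CNN, and cubic-kernel SVM on Welch spectral features.

#' Spatial-first CNN model specification
#'
#' Layer 1 is a spatial convolution whose kernel spans all input channels
#' (temporal extent 1), producing `F1` virtual channels — the network
#' learns spatial filters before any temporal processing. Two temporal
#' convolution blocks follow (convolution, batch normalization, ELU,
#' average pooling, dropout), then a dense softmax over the classes. The
#' layer sizes are compact (well under a million parameters) so that the
#' model trains quickly on the window counts a single subject produces.
#'
#' @param channels input channels (6 in this montage).
#' @param samples samples per window (>= 64).
#' @param n_classes number of classes (default 4).
#' @param F1 spatial filters in layer 1 (default 12).
#' @param F2,F3 trunk convolution maps (defaults 16, 16).
#' @param L temporal kernel length of the trunk convolutions (default 9).
#' @param pools average-pool widths for layer 1 and the two blocks
#'   (default `c(4, 4, 4)`).
#' @param dropout dropout probability in the trunk blocks (default 0.5).
#' @param batch,max_epochs,patience,lr training hyperparameters: minibatch
#'   size 64, at most 200 epochs, early stop after 20 epochs without
#'   validation-accuracy improvement, Adam step size 5e-3.
#' @return object of class `model_spec`.
#' @export
build_spatial_cnn <- function(channels = 6, samples, n_classes = 4,
                              F1 = 12, F2 = 16, F3 = 16, L = 9,
                              pools = c(4, 4, 4), dropout = 0.5,
                              batch = 64, max_epochs = 200, patience = 20,
                              lr = 5e-3) {
  if (samples < 64) stop_invalid("need at least 64 samples per window")
  spec <- list(family = "spatial_cnn",
               arch = list(type = 0L, dw_trunk = 0L,
                           channels = as.integer(channels),
                           samples = as.integer(samples),
                           n_classes = as.integer(n_classes),
                           F1 = as.integer(F1), L1 = 1L,
                           F2 = as.integer(F2), L2 = as.integer(L),
                           F3 = as.integer(F3), L3 = as.integer(L),
                           p1 = as.integer(pools[1]), p2 = as.integer(pools[2]),
                           p3 = as.integer(pools[3]), dropout = dropout),
               train = list(batch = as.integer(batch),
                            max_epochs = as.integer(max_epochs),
                            patience = as.integer(patience), lr = lr))
  validate_model_spec(spec)
}

#' Temporal-first ("standard") CNN model specification
#'
#' The generic-CNN baseline: no spatial kernel spans the channels anywhere
#' in the convolutional stack. Layer 1 filters each input channel
#' temporally on its own (a depthwise convolution with `k1` kernels per
#' channel), the trunk blocks stay per-map (temporal-only), and channels
#' only meet at the final dense layer — i.e. the network can weigh
#' channels but never learns a spatial filter over raw amplitudes. This
#' isolates learned spatial filtering as the experimental variable between
#' the two CNN families; the training protocol and budget match the
#' spatial variant.
#'
#' @inheritParams build_spatial_cnn
#' @param k1 temporal kernels per input channel in layer 1 (default 2, so
#'   the layer-1 map count is comparable to the spatial variant's `F1`).
#' @param L1 layer-1 temporal kernel length (default 9).
#' @return object of class `model_spec`.
#' @export
build_standard_cnn <- function(channels = 6, samples, n_classes = 4,
                               k1 = 2, L1 = 9, L = 9,
                               pools = c(4, 4, 4), dropout = 0.5,
                               batch = 64, max_epochs = 200, patience = 20,
                               lr = 5e-3) {
  if (samples < 64) stop_invalid("need at least 64 samples per window")
  F1 <- as.integer(k1 * channels)
  spec <- list(family = "standard_cnn",
               arch = list(type = 1L, dw_trunk = 1L,
                           channels = as.integer(channels),
                           samples = as.integer(samples),
                           n_classes = as.integer(n_classes),
                           F1 = F1, L1 = as.integer(L1),
                           F2 = F1, L2 = as.integer(L),
                           F3 = F1, L3 = as.integer(L),
                           p1 = as.integer(pools[1]), p2 = as.integer(pools[2]),
                           p3 = as.integer(pools[3]), dropout = dropout),
               train = list(batch = as.integer(batch),
                            max_epochs = as.integer(max_epochs),
                            patience = as.integer(patience), lr = lr))
  validate_model_spec(spec)
}

# shape propagation and parameter-count sanity
validate_model_spec <- function(spec) {
  a <- spec$arch
  t1 <- a$samples %/% a$p1
  t2 <- t1 %/% a$p2
  t3 <- t2 %/% a$p3
  if (t3 < 1) stop_invalid("pooling exhausts the time axis for ", a$samples,
                           " samples; reduce pool widths")
  n_par <- length_params(a)
  if (n_par >= 1e6) stop_invalid("parameter budget exceeded: ", n_par)
  spec$arch$feat <- a$F3 * t3
  spec$n_params <- n_par
  structure(spec, class = "model_spec")
}

length_params <- function(a) {
  w1 <- if (a$type == 0L) a$F1 * a$channels else a$F1 * a$L1
  in2 <- if (a$dw_trunk == 1L) 1L else a$F1
  in3 <- if (a$dw_trunk == 1L) 1L else a$F2
  w1 + a$F1 * 3 +
    in2 * a$L2 * a$F2 + a$F2 * 3 +
    in3 * a$L3 * a$F3 + a$F3 * 3 +
    a$n_classes * (a$F3 * ((a$samples %/% a$p1 %/% a$p2) %/% a$p3)) + a$n_classes
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d ch x %d samples -> %d classes (%d parameters)\n",
              x$family, x$arch$channels, x$arch$samples, x$arch$n_classes,
              x$n_params))
  invisible(x)
}

# preprocessing fingerprint that a trained model refuses to violate
make_fingerprint <- function(fs, channels, samples, rescaled, band = c(4, 33),
                             extrema = NULL) {
  list(fs = fs, channels = channels, samples = samples,
       rescaled = isTRUE(rescaled), band = band, extrema = extrema)
}

check_fingerprint <- function(clf, epochs) {
  fp <- clf$fingerprint
  d <- dim(epochs$windows)
  if (epochs$fs != fp$fs || d[1] != fp$channels || d[2] != fp$samples)
    stop(errorCondition(
      sprintf("fingerprint mismatch: model expects %d ch x %d samples @ %g Hz, got %d x %d @ %g",
              fp$channels, fp$samples, fp$fs, d[1], d[2], epochs$fs),
      class = c("mibmi_contract_error", "error")))
  invisible(TRUE)
}

#' Train a CNN classifier
#'
#' Minibatch Adam on categorical cross-entropy; training stops at
#' `max_epochs` or as soon as validation accuracy has not improved for
#' `patience` consecutive epochs, and the parameters of the best validation
#' epoch are kept. Deterministic given `seed`.
#'
#' @param spec a [build_spatial_cnn()] / [build_standard_cnn()] spec.
#' @param train,val `epoch_set`s with identical label sets, rescaled to
#'   roughly `[-1, 1]`.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param fingerprint optional preprocessing fingerprint to store.
#' @return object of class `trained_classifier`.
#' @export
train_cnn <- function(spec, train, val, seed = 1L, fingerprint = NULL) {
  if (!inherits(spec, "model_spec")) stop_invalid("spec must be a model_spec")
  if (dim(train$windows)[3] == 0 || dim(val$windows)[3] == 0)
    stop_invalid("empty training or validation set")
  lv <- levels(droplevels(train$labels))
  if (!setequal(lv, levels(droplevels(val$labels))))
    stop_invalid("train/val label sets differ")
  if (length(lv) != spec$arch$n_classes)
    stop_invalid("spec expects ", spec$arch$n_classes, " classes, data has ",
                 length(lv))
  ytr <- as.integer(factor(train$labels, levels = lv)) - 1L
  yva <- as.integer(factor(val$labels, levels = lv)) - 1L
  fit <- cnn_train_cpp(train$windows, ytr, val$windows, yva,
                       spec$arch, spec$train, as.integer(seed))
  if (is.null(fingerprint))
    fingerprint <- make_fingerprint(train$fs, dim(train$windows)[1],
                                    dim(train$windows)[2], rescaled = TRUE)
  structure(list(family = spec$family, spec = spec, params = fit$params,
                 label_map = lv,
                 history = as.numeric(fit$history),
                 best_epoch = fit$best_epoch,
                 best_val_acc = fit$best_val_acc,
                 fingerprint = fingerprint, seed = as.integer(seed)),
            class = "trained_classifier")
}

#' Train the PSDA + cubic-SVM classifier
#'
#' Features are standardized column-wise with statistics fitted on the
#' training rows only, then a multiclass support vector machine with a
#' degree-3 polynomial kernel (one-vs-one reduction) is fitted.
#'
#' @param features a [psda_features()] matrix (or plain matrix).
#' @param labels factor of class labels, one per row; defaults to the
#'   labels attached to `features`.
#' @param cost SVM regularization constant (default 1).
#' @param degree polynomial degree (default 3, the cubic kernel).
#' @param fingerprint optional preprocessing fingerprint to store.
#' @return object of class `trained_classifier`.
#' @export
train_svm_psda <- function(features, labels = attr(features, "labels"),
                           cost = 1, degree = 3, fingerprint = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop_invalid("need at least 2 classes")
  x <- unclass(features)
  attr(x, "labels") <- NULL; attr(x, "meta") <- NULL
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  model <- e1071::svm(xs, labels, kernel = "polynomial", degree = degree,
                      coef0 = 1, cost = cost, scale = FALSE)
  meta <- attr(features, "meta")
  if (is.null(fingerprint) && !is.null(meta))
    fingerprint <- make_fingerprint(meta$fs, length(meta$channels),
                                    meta$window_samples, rescaled = TRUE,
                                    band = meta$band)
  structure(list(family = "psda_svm", model = model,
                 scaling = list(mean = mu, sd = sdv),
                 psda = meta, label_map = levels(labels),
                 fingerprint = fingerprint),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> %s over classes {%s}\n", x$family,
              paste(x$label_map, collapse = ", ")))
  if (!is.null(x$best_epoch))
    cat(sprintf("  best epoch %d, validation accuracy %.3f\n",
                x$best_epoch, x$best_val_acc))
  invisible(x)
}

#' Predict window labels
#'
#' For CNN families `newdata` is an `epoch_set` whose preprocessing
#' fingerprint must match the model's; scores are softmax probabilities
#' (ties broken toward the lowest class index). For the SVM family the
#' stored spectral-feature recipe is applied first; scores are one-vs-one
#' decision values.
#'
#' @param object a `trained_classifier`.
#' @param newdata an `epoch_set` (any family) or `feature_matrix` (SVM).
#' @param ... unused.
#' @return list with `labels` (factor) and `scores` (matrix, one row per
#'   window).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  if (object$family %in% c("spatial_cnn", "standard_cnn")) {
    check_fingerprint(object, newdata)
    probs <- t(cnn_predict_cpp(object$params, object$spec$arch, newdata$windows))
    colnames(probs) <- object$label_map
    idx <- apply(probs, 1, which.max)   # first max = lowest class index
    labels <- factor(object$label_map[idx], levels = levels(newdata$labels))
    return(list(labels = labels, scores = probs))
  }
  # SVM route
  x <- if (inherits(newdata, "epoch_set")) {
    check_fingerprint(object, newdata)
    p <- object$psda
    unclass(psda_features(newdata, band = p$band, seg_len = p$seg_len,
                          nfft = p$nfft, overlap_frac = p$overlap_frac))
  } else unclass(newdata)
  attr(x, "labels") <- NULL; attr(x, "meta") <- NULL
  xs <- sweep(sweep(x, 2, object$scaling$mean), 2, object$scaling$sd, "/")
  pred <- predict(object$model, xs, decision.values = TRUE)
  lv <- if (inherits(newdata, "epoch_set")) levels(newdata$labels) else object$label_map
  list(labels = factor(as.character(pred), levels = lv),
       scores = attr(pred, "decision.values"))
}
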