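#' Stratified train/validation/test split
#'
#' Shuffles each class independently (seeded) and partitions it
#' according to `ratios`, so per-class proportions are preserved to
#' within rounding.  The three index sets are disjoint and exhaustive.
#'
#' @param labels Factor or character vector of class labels.
#' @param ratios Length-3 proportions summing to 1 (default 6:2:2).
#' @param seed Integer seed.
#' @return List with sorted integer index vectors `train`, `val`,
#'   `test`.
#' @export
stratified_split <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stopf("ratios must be three proportions summing to 1")
  labels <- as.factor(labels)
  if (any(table(labels) == 0L))
    stopf("every class must have at least one sample")
  tr <- va <- te <- integer()
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_tr <- round(n * ratios[1])
      n_va <- round(n * (ratios[1] + ratios[2])) - n_tr
      tr <- c(tr, idx[seq_len(n_tr)])
      va <- c(va, idx[seq_len(n_va) + n_tr])
      te <- c(te, idx[seq(n_tr + n_va + 1L, length.out = n - n_tr - n_va)])
    }
  })
  list(train = sort(tr), val = sort(va), test = sort(te))
}

#' Image augmentation primitives
#'
#' `hflip()` mirrors an image horizontally (an involution);
#' `center_crop()` extracts the central `size` x `size` window (the
#' identity when the image is already that size); and
#' `normalize_channels()` standardizes each channel with the given mean
#' and standard deviation.
#'
#' @param image H x W x C numeric array.
#' @param size Crop side length.
#' @param mean,sd Length-C channel statistics.
#' @return The transformed array.
#' @export
hflip <- function(image) image[, dim(image)[2]:1, , drop = FALSE]

#' @rdname hflip
#' @export
center_crop <- function(image, size) {
  d <- dim(image)
  if (d[1] < size || d[2] < size) stopf("image smaller than crop size")
  y0 <- (d[1] - size) %/% 2L
  x0 <- (d[2] - size) %/% 2L
  image[(y0 + 1L):(y0 + size), (x0 + 1L):(x0 + size), , drop = FALSE]
}

#' @rdname hflip
#' @export
normalize_channels <- function(image, mean, sd) {
  for (ch in seq_len(dim(image)[3]))
    image[, , ch] <- (image[, , ch] - mean[ch]) / sd[ch]
  image
}

#' Training-time / evaluation-time augmentation
#'
#' The training path applies a random horizontal flip (probability
#' 0.5, drawn from the current RNG), a center crop to the model input
#' size and per-channel normalization.  The evaluation path applies
#' only the deterministic steps (crop and normalization), so repeated
#' evaluation of the same inputs is bit-identical.
#'
#' @param image H x W x 3 array scaled to `[0, 1]`.
#' @param config List with `input_size`, `flip` (logical), `mean`, `sd`.
#' @param train Logical: use the stochastic training path?
#' @return Augmented array.
#' @export
augment <- function(image, config, train = TRUE) {
  if (train && isTRUE(config$flip) && runif(1) < 0.5) image <- hflip(image)
  if (dim(image)[1] != config$input_size || dim(image)[2] != config$input_size)
    image <- center_crop(image, config$input_size)
  normalize_channels(image, config$mean, config$sd)
}

#' Training configuration
#'
#' Defaults mirror the operating protocol: 50 epochs, batch size 16,
#' Adam at its default learning rate 0.001, cross-entropy loss, and a
#' 6:2:2 stratified split.
#'
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param split Length-3 split ratios summing to 1.
#' @param flip Enable random horizontal flips during training.
#' @param normalize Standardize channels with training-split statistics.
#' @param early_stop_accuracy Optional validation-accuracy level at
#'   which training stops before `epochs` is reached (NULL disables).
#' @param seed Integer seed controlling the split, shuffling and
#'   augmentation.
#' @return An object of class `"candle_config"`.
#' @export
candle_config <- function(epochs = 50L, batch_size = 16L,
                          learning_rate = 0.001, split = c(0.6, 0.2, 0.2),
                          flip = TRUE, normalize = TRUE,
                          early_stop_accuracy = NULL, seed = 1L) {
  if (epochs < 1L || batch_size < 1L) stopf("epochs and batch_size must be >= 1")
  if (length(split) != 3L || abs(sum(split) - 1) > 1e-8)
    stopf("split ratios must sum to 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, split = split,
                 flip = isTRUE(flip), normalize = isTRUE(normalize),
                 early_stop_accuracy = early_stop_accuracy,
                 seed = as.integer(seed)),
            class = "candle_config")
}

# per-channel mean/sd of a list of [0,1]-scaled arrays
channel_stats <- function(xs) {
  sums <- numeric(3); sqs <- numeric(3); n <- 0
  for (a in xs) {
    for (ch in 1:3) {
      v <- a[, , ch]
      sums[ch] <- sums[ch] + sum(v)
      sqs[ch] <- sqs[ch] + sum(v * v)
    }
    n <- n + length(a[, , 1])
  }
  mean <- sums / n
  sd <- sqrt(pmax(sqs / n - mean^2, 1e-12))
  list(mean = mean, sd = pmax(sd, 1e-6))
}

#' Train a classifier with mini-batch Adam and cross-entropy loss
#'
#' Runs `config$epochs` epochs of seeded mini-batch training and
#' records, per epoch, the mean training cross-entropy and the full
#' validation accuracy (evaluation-mode forward pass).  Data order,
#' augmentation draws and weight updates are all derived from
#' `config$seed`, so identical inputs give identical epoch records.
#'
#' @param model A [build_classifier()] model (modified in place).
#' @param x_train,x_val Lists of H x W x 3 arrays with values 0--255.
#' @param y_train,y_val Integer class indices (1-based).
#' @param config A [candle_config()].
#' @param norm Optional precomputed `list(mean, sd)`; computed from the
#'   training inputs when NULL and `config$normalize` is TRUE.
#' @return List with `records` (data frame of epoch, train_loss,
#'   val_accuracy), `norm`, and `steps` (total optimizer steps).
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val,
                        config = candle_config(), norm = NULL) {
  if (length(x_train) == 0L) stopf("empty training set")
  size <- model$spec$input_size
  xs_tr <- lapply(x_train, function(a) a / 255)
  xs_va <- lapply(x_val, function(a) a / 255)
  if (is.null(norm))
    norm <- if (config$normalize) channel_stats(xs_tr) else
      list(mean = c(0, 0, 0), sd = c(1, 1, 1))
  aug <- list(input_size = size, flip = config$flip,
              mean = norm$mean, sd = norm$sd)
  layers <- walk_layers(model)
  xs_va_eval <- lapply(xs_va, augment, config = aug, train = FALSE)
  records <- vector("list", config$epochs)
  steps <- 0L
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(xs_tr))
      losses <- c()
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + config$batch_size - 1L, length(ord))
        idx <- ord[i:j]
        batch <- lapply(xs_tr[idx], augment, config = aug, train = TRUE)
        x <- stack_inputs(batch)
        logits <- model$fwd(x, training = TRUE)
        ls <- softmax_xent(logits, y_train[idx])
        model$bwd(ls$dlogits)
        steps <- steps + 1L
        adam_step(layers, steps, lr = config$learning_rate)
        zero_grads(layers)
        losses <- c(losses, ls$loss)
        i <- j + 1L
      }
      val_acc <- if (length(xs_va_eval)) {
        pred <- max.col(model_logits(model, xs_va_eval, config$batch_size),
                        ties.method = "first")
        mean(pred == y_val)
      } else NA_real_
      records[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                  val_accuracy = val_acc)
      if (!is.null(config$early_stop_accuracy) && !is.na(val_acc) &&
          val_acc >= config$early_stop_accuracy) break
    }
  })
  list(records = do.call(rbind, records), norm = norm, steps = steps)
}

#' Stability statistics of a per-epoch accuracy sequence
#'
#' Summarizes a validation-accuracy trajectory with its mean, overall
#' population standard deviation and variance, and the population
#' variances of the first and last `window` epochs — the convergence /
#' stability profile used to compare attention variants.
#'
#' @param records Numeric accuracy vector, or a data frame with a
#'   `val_accuracy` column.
#' @param window Window length for the head/tail variances (default
#'   10); `NULL` skips the windowed statistics.
#' @return Object of class `"stability_report"`.
#' @export
stability_metrics <- function(records, window = 10L) {
  acc <- if (is.data.frame(records)) records$val_accuracy else as.numeric(records)
  if (any(is.na(acc))) stopf("accuracy sequence contains NA")
  pvar <- function(v) mean((v - mean(v))^2)
  out <- list(mean_accuracy = mean(acc),
              overall_std = sqrt(pvar(acc)),
              overall_variance = pvar(acc),
              first10_variance = NA_real_,
              last10_variance = NA_real_,
              n_epochs = length(acc), window = window)
  if (!is.null(window) && window > 0L) {
    if (length(acc) < 2L * window)
      stopf("need at least %d epochs for window %d", 2L * window, window)
    out$first10_variance <- pvar(acc[seq_len(window)])
    out$last10_variance <- pvar(acc[seq(length(acc) - window + 1L, length(acc))])
  }
  structure(out, class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("<stability_report> mean acc %.4f, sd %.4f, var %.6f",
                     " | first-%d var %.6f | last-%d var %.6f (%d epochs)\n"),
              x$mean_accuracy, x$overall_std, x$overall_variance,
              x$window %||% 0, x$first10_variance,
              x$window %||% 0, x$last10_variance, x$n_epochs))
  invisible(x)
}

# macro-averaged precision / recall / F1 from a confusion matrix with
# true classes in rows and predictions in columns
macro_metrics <- function(cm) {
  k <- nrow(cm)
  prec <- rec <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec[i] <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       per_class = data.frame(class = rownames(cm) %||% seq_len(k),
                              precision = prec, recall = rec, f1 = f1))
}
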