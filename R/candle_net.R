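#' Fit a candling-image classifier
#'
#' The package's main modelling function.  Takes a prepared dataset
#' (model-input-sized images plus class labels), performs a seeded
#' stratified 6:2:2 split, computes channel normalization statistics on
#' the training split, builds the 34-layer residual network with the
#' requested attention module and trains it with mini-batch Adam under
#' cross-entropy loss, recording per-epoch training loss and
#' validation accuracy.
#'
#' @param x A `"prepared_dataset"` (see [prepare_dataset()]) or a list
#'   of H x W x 3 arrays with values 0--255.
#' @param y Class labels (factor or character); taken from `x` when it
#'   is a prepared dataset.
#' @param attention Attention variant: `"cbam"` (default), `"se"`,
#'   `"ca"` or `"none"`.
#' @param spec A [model_spec()]; its `attention` field is overridden by
#'   the `attention` argument when both are supplied.
#' @param config A [candle_config()].
#' @param split Optional precomputed split (list with `train`, `val`,
#'   `test` indices), e.g. to share one partition across variants.
#' @return An object of class `"candle_net"` with components `model`,
#'   `spec`, `config`, `split`, `records` (per-epoch data frame),
#'   `norm`, `levels` and `stability` (when enough epochs ran).
#' @seealso [predict.candle_net()], [evaluate_model()],
#'   [compare_attention_variants()]
#' @examples
#' \donttest{
#' ds <- generate_dataset(c(unfertilized = 6, live = 6, abnormal = 6),
#'                        generator_params(seed = 7))
#' prep <- prepare_dataset(ds, preprocess_config(input_size = 32))
#' fit <- candle_net(prep, attention = "none",
#'                   spec = model_spec(width_factor = 1 / 8, input_size = 32),
#'                   config = candle_config(epochs = 1, seed = 1))
#' print(fit)
#' }
#' @export
candle_net <- function(x, y = NULL, attention = NULL,
                       spec = model_spec(), config = candle_config(),
                       split = NULL) {
  if (inherits(x, "prepared_dataset")) {
    y <- x$y
    x <- x$x
  }
  if (is.null(y)) stopf("class labels are required")
  y <- factor(y)
  if (length(y) != length(x)) stopf("x and y lengths differ")
  if (!is.null(attention)) {
    spec$attention <- match.arg(attention, c("cbam", "none", "se", "ca"))
  }
  if (spec$num_classes != nlevels(y))
    spec$num_classes <- nlevels(y)
  d <- dim(x[[1]])
  if (d[1] != spec$input_size || d[2] != spec$input_size)
    stopf("inputs are %dx%d but the spec expects %dx%d",
          d[1], d[2], spec$input_size, spec$input_size)
  if (is.null(split))
    split <- stratified_split(y, config$split, config$seed)
  yi <- as.integer(y)
  model <- build_classifier(spec, seed = config$seed)
  tr <- train_model(model, x[split$train], yi[split$train],
                    x[split$val], yi[split$val], config)
  stab <- if (nrow(tr$records) >= 20L) stability_metrics(tr$records) else NULL
  structure(list(model = model, spec = spec, config = config, split = split,
                 records = tr$records, norm = tr$norm, steps = tr$steps,
                 levels = levels(y), stability = stab,
                 call = match.call()),
            class = "candle_net")
}

#' @export
print.candle_net <- function(x, ...) {
  cat(sprintf("Candling classifier: ResNet%d + %s (%s parameters)\n",
              x$spec$depth, x$spec$attention,
              format(n_parameters(x$model), big.mark = ",")))
  cat(sprintf("  classes: %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  trained %d epochs (%d optimizer steps), final val accuracy %.4f\n",
              nrow(x$records), x$steps,
              x$records$val_accuracy[nrow(x$records)]))
  invisible(x)
}

#' @export
summary.candle_net <- function(object, ...) {
  out <- list(fit = object,
              stability = object$stability %||%
                stability_metrics(object$records, window = NULL))
  class(out) <- "summary.candle_net"
  out
}

#' @export
print.summary.candle_net <- function(x, ...) {
  print(x$fit)
  cat("Per-epoch validation-accuracy stability:\n")
  print(x$stability)
  invisible(x)
}

#' @export
coef.candle_net <- function(object, ...) {
  layers <- walk_layers(object$model)
  out <- list()
  for (i in seq_along(layers))
    for (nm in names(layers[[i]]$par))
      out[[sprintf("%s%d.%s", layers[[i]]$type, i, nm)]] <- layers[[i]]$par[[nm]]
  out
}

#' Predict hatching classes for new candling inputs
#'
#' Applies the deterministic evaluation path (center crop plus the
#' stored training-split normalization) and an evaluation-mode forward
#' pass.
#'
#' @param object A [candle_net()] fit.
#' @param newdata A `"prepared_dataset"` or list of H x W x 3 arrays
#'   (values 0--255) at the model input size.
#' @param type `"class"` (default), `"prob"` or `"logit"`.
#' @param ... Unused.
#' @return Factor of classes, or a numeric matrix for `"prob"` /
#'   `"logit"`.
#' @export
predict.candle_net <- function(object, newdata, type = c("class", "prob", "logit"),
                               ...) {
  type <- match.arg(type)
  if (inherits(newdata, "prepared_dataset")) newdata <- newdata$x
  aug <- list(input_size = object$spec$input_size, flip = FALSE,
              mean = object$norm$mean, sd = object$norm$sd)
  xs <- lapply(newdata, function(a) augment(a / 255, aug, train = FALSE))
  logits <- model_logits(object$model, xs, object$config$batch_size)
  colnames(logits) <- object$levels
  if (type == "logit") return(logits)
  e <- exp(logits - apply(logits, 1, max))
  p <- e / rowSums(e)
  if (type == "prob") return(p)
  factor(object$levels[max.col(logits, ties.method = "first")],
         levels = object$levels)
}

#' @export
plot.candle_net <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$records$epoch, x$records$train_loss, type = "l", col = "firebrick",
       xlab = "epoch", ylab = "training loss", main = "loss")
  plot(x$records$epoch, x$records$val_accuracy, type = "l", col = "navy",
       ylim = c(0, 1), xlab = "epoch", ylab = "validation accuracy",
       main = "accuracy")
  invisible(x)
}

#' Evaluate a fitted classifier on a held-out test set
#'
#' Computes the aggregate confusion matrix (true classes in rows),
#' accuracy and macro-averaged precision/recall/F1 from one
#' deterministic evaluation pass, then estimates the round-to-round
#' accuracy variance over `rounds` repetitions.  Because the evaluation
#' path is fully deterministic, rounds are made to differ by seeded
#' bootstrap resampling of the test set, and the report is labelled
#' with `mode = "bootstrap"`; with `rounds = 0` no resampling is done
#' and the variance is 0 over identical rounds.
#'
#' @param fit A [candle_net()] object.
#' @param x Test inputs (list of arrays or `"prepared_dataset"`).
#' @param y True labels; taken from `x` when it is a prepared dataset.
#'   When `x` is NULL, the fit's own held-out test split is used.
#' @param rounds Number of test rounds (default 10).
#' @param seed Seed for the round resampling.
#' @param resample Vary rounds by bootstrap resampling (default).  With
#'   `FALSE` every round is the same deterministic pass, so the
#'   round-to-round variance is exactly 0.
#' @return Object of class `"eval_report"`: accuracy, macro_precision,
#'   macro_recall, macro_f1, confusion, round_accuracies,
#'   mean_variance, rounds, mode.
#' @export
evaluate_model <- function(fit, x = NULL, y = NULL, rounds = 10L, seed = 1L,
                           resample = TRUE) {
  stopifnot(inherits(fit, "candle_net"))
  if (inherits(x, "prepared_dataset")) {
    y <- x$y[fit$split$test]
    x <- x$x[fit$split$test]
  }
  if (is.null(x)) stopf("test inputs are required")
  if (length(x) == 0L) stopf("empty test set")
  y <- factor(y, levels = fit$levels)
  pred <- predict(fit, x)
  cm <- table(true = y, predicted = pred)
  cm <- matrix(cm, nrow(cm), dimnames = dimnames(cm))
  acc <- sum(diag(cm)) / sum(cm)
  mm <- macro_metrics(cm)
  n <- length(y)
  accs <- if (resample) {
    with_seed(seed, {
      vapply(seq_len(max(rounds, 0L)), function(r) {
        idx <- sample.int(n, n, replace = TRUE)
        mean(pred[idx] == y[idx])
      }, numeric(1))
    })
  } else rep(acc, max(rounds, 0L))
  mv <- if (length(accs) > 0) mean((accs - mean(accs))^2) else 0
  structure(list(accuracy = acc, macro_precision = mm$precision,
                 macro_recall = mm$recall, macro_f1 = mm$f1,
                 per_class = mm$per_class, confusion = cm,
                 round_accuracies = accs, mean_variance = mv,
                 rounds = as.integer(rounds),
                 mode = if (resample) "bootstrap" else "deterministic"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> accuracy %.4f | macro P %.4f R %.4f F1",
                     " %.4f | %d-round variance %.6f (%s)\n"),
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$rounds, x$mean_variance, x$mode))
  cat("confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Compare attention variants under a shared data partition
#'
#' Trains one classifier per requested attention variant on the same
#' stratified split with the same seeds, and tabulates the per-epoch
#' stability statistics together with held-out test metrics, giving a
#' paired comparison of the fusion variants.
#'
#' @param x A `"prepared_dataset"` (or list of input arrays).
#' @param y Labels when `x` is a plain list.
#' @param attentions Character vector of variants to fit.
#' @param spec Base [model_spec()] (attention field replaced per
#'   variant).
#' @param config A [candle_config()].
#' @param rounds Test rounds passed to [evaluate_model()].
#' @return Object of class `"attention_comparison"`: list with `table`
#'   (one row per variant) and `fits`.
#' @export
compare_attention_variants <- function(x, y = NULL,
                                       attentions = c("none", "se", "ca", "cbam"),
                                       spec = model_spec(),
                                       config = candle_config(),
                                       rounds = 10L) {
  if (inherits(x, "prepared_dataset")) {
    y <- x$y
    xs <- x$x
  } else xs <- x
  y <- factor(y)
  split <- stratified_split(y, config$split, config$seed)
  win <- if (nrow_records_possible(config) >= 20L) 10L else NULL
  fits <- list()
  rows <- list()
  for (att in attentions) {
    fit <- candle_net(xs, y, attention = att, spec = spec, config = config,
                      split = split)
    ev <- evaluate_model(fit, xs[split$test], y[split$test], rounds = rounds,
                         seed = config$seed)
    st <- stability_metrics(fit$records,
                            window = if (nrow(fit$records) >= 20L) 10L else NULL)
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      attention = att,
      mean_accuracy = st$mean_accuracy,
      overall_std = st$overall_std,
      overall_variance = st$overall_variance,
      first10_variance = st$first10_variance,
      last10_variance = st$last10_variance,
      test_accuracy = ev$accuracy,
      macro_precision = ev$macro_precision,
      macro_recall = ev$macro_recall,
      macro_f1 = ev$macro_f1,
      mean_variance = ev$mean_variance)
  }
  names(fits) <- make.unique(attentions)
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 fits = fits, split = split),
            class = "attention_comparison")
}

nrow_records_possible <- function(config) config$epochs

#' @export
print.attention_comparison <- function(x, ...) {
  cat("Attention-variant comparison (shared split):\n")
  print(x$table, digits = 4)
  invisible(x)
}
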