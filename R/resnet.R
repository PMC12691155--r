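# Residual network assembly: basic blocks y = F(x, {Wi}) + Ws x with
# post-addition ReLU, stacked 3/4/6/3 (the canonical 34-layer layout),
# with an optional attention module inserted in every block after the
# convolution stack and before the shortcut addition.

#' Residual block
#'
#' Builds one basic residual block: two 3x3 convolutions with batch
#' normalization and a ReLU between them, an optional attention module
#' applied to the residual branch output, and a shortcut that is the
#' identity when shapes match or a 1x1 strided projection (with batch
#' norm) when they do not.  The block output is
#' `ReLU(attn(F(x)) + Ws x)`.  With all residual-branch weights zeroed
#' the block degenerates to `ReLU(Ws x)` — a (projected) identity on
#' nonnegative inputs — which is what protects deep stacks from
#' degradation.
#'
#' @param in_channels,out_channels Channel counts.
#' @param stride Stride of the first convolution (2 halves the spatial
#'   extent and triggers the projection shortcut).
#' @param attention One of `"none"`, `"se"`, `"ca"`, `"cbam"`.
#' @param reduction Bottleneck reduction ratio of the attention MLPs.
#' @param spatial_kernel CBAM spatial kernel size (default 7).
#' @return An internal layer object with `fwd(x, training)` and
#'   `bwd(dy)`; see [residual_block_forward()] for the array interface.
#' @export
residual_block <- function(in_channels, out_channels, stride = 1L,
                           attention = "none", reduction = 16L,
                           spatial_kernel = 7L) {
  self <- new_layer("residual_block")
  self$children$conv1 <- nn_conv2d(in_channels, out_channels, 3L, stride)
  self$children$bn1 <- nn_batchnorm(out_channels)
  self$children$conv2 <- nn_conv2d(out_channels, out_channels, 3L, 1L)
  self$children$bn2 <- nn_batchnorm(out_channels)
  self$children$attn <- make_attention(attention, out_channels,
                                       reduction = reduction,
                                       spatial_kernel = spatial_kernel)
  self$project <- (stride != 1L || in_channels != out_channels)
  if (self$project) {
    self$children$conv_s <- nn_conv2d(in_channels, out_channels, 1L, stride,
                                      pad = 0L)
    self$children$bn_s <- nn_batchnorm(out_channels)
  }
  self$fwd <- function(x, training = FALSE) {
    ch <- self$children
    h <- ch$bn1$fwd(ch$conv1$fwd(x, training), training)
    relu1 <- h$mat > 0
    h$mat <- h$mat * relu1
    h <- ch$bn2$fwd(ch$conv2$fwd(h, training), training)
    if (!is.null(ch$attn)) h <- ch$attn$fwd(h, training)
    sc <- if (self$project)
      ch$bn_s$fwd(ch$conv_s$fwd(x, training), training) else x
    s <- h$mat + sc$mat
    relu2 <- s > 0
    if (training) self$cache <- list(relu1 = relu1, relu2 = relu2)
    nn_tensor(s * relu2, h$H, h$W, h$N)
  }
  self$bwd <- function(dy) {
    ch <- self$children
    cc <- self$cache
    d <- nn_tensor(dy$mat * cc$relu2, dy$H, dy$W, dy$N)
    db <- d
    if (!is.null(ch$attn)) db <- ch$attn$bwd(db)
    db <- ch$bn2$bwd(db)
    db <- ch$conv2$bwd(db)
    db$mat <- db$mat * cc$relu1
    db <- ch$conv1$bwd(ch$bn1$bwd(db))
    dsc <- if (self$project) ch$conv_s$bwd(ch$bn_s$bwd(d)) else d
    self$cache <- NULL
    nn_tensor(db$mat + dsc$mat, db$H, db$W, db$N)
  }
  self
}

#' Forward pass of a residual block on a single feature map
#'
#' @param block A [residual_block()].
#' @param x C x H x W numeric array.
#' @param training Use batch statistics (TRUE) or running statistics
#'   (FALSE) in the batch-norm layers.
#' @return The output C' x H' x W' array.
#' @export
residual_block_forward <- function(block, x, training = FALSE) {
  out <- block$fwd(fmap_to_tensor(x), training)
  tensor_to_fmap(out)
}

#' Classifier architecture specification
#'
#' The production depth is 34 layers (stage block counts 3/4/6/3 of
#' basic blocks); `width_factor` scales all channel widths for
#' desk-scale experiments (1 gives the canonical 64/128/256/512).
#'
#' @param depth Network depth; only 34 is supported.
#' @param attention Attention module inserted in every residual block:
#'   `"none"`, `"se"`, `"ca"` or `"cbam"`.
#' @param num_classes Number of output classes (default 3).
#' @param reduction Channel-attention MLP reduction ratio (default 16).
#' @param ca_reduction Coordinate-attention reduction ratio (default 32).
#' @param spatial_kernel CBAM spatial kernel (default, and per the
#'   module definition, 7).
#' @param width_factor Multiplier on the canonical channel widths.
#' @param input_size Expected square input side (pixels).
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(depth = 34L, attention = c("cbam", "none", "se", "ca"),
                       num_classes = 3L, reduction = 16L, ca_reduction = 32L,
                       spatial_kernel = 7L, width_factor = 1,
                       input_size = 224L) {
  attention <- match.arg(attention)
  if (depth != 34L) stopf("only the 34-layer configuration is supported")
  if (num_classes < 2L) stopf("num_classes must be >= 2")
  if (spatial_kernel %% 2L == 0L) stopf("spatial_kernel must be odd")
  widths <- as.integer(round(c(64, 128, 256, 512) * width_factor))
  if (any(widths < 4L)) stopf("width_factor too small")
  if (input_size < 32L || input_size %% 32L != 0L)
    stopf("input_size must be a positive multiple of 32")
  structure(list(depth = 34L, attention = attention,
                 num_classes = as.integer(num_classes),
                 reduction = as.integer(reduction),
                 ca_reduction = as.integer(ca_reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 width_factor = width_factor, widths = widths,
                 blocks = c(3L, 4L, 6L, 3L),
                 input_size = as.integer(input_size)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> ResNet%d (+%s), widths %s, input %dx%d, %d classes\n",
              x$depth, x$attention, paste(x$widths, collapse = "/"),
              x$input_size, x$input_size, x$num_classes))
  invisible(x)
}

#' Build the residual-network classifier
#'
#' Assembles the 34-layer network: a 7x7 stride-2 stem convolution with
#' batch norm, ReLU and 3x3 stride-2 max pooling, four stages of basic
#' residual blocks (3/4/6/3) with the configured attention module in
#' every block, global average pooling and a linear classification
#' head.  Weight initialization is seeded Kaiming-style; attention
#' biases start at zero.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `"candle_model"`.
#' @export
build_classifier <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    self <- new_layer("candle_model")
    self$spec <- spec
    self$seed <- as.integer(seed)
    w <- spec$widths
    self$children$stem_conv <- nn_conv2d(3L, w[1], 7L, 2L, pad = 3L)
    self$children$stem_bn <- nn_batchnorm(w[1])
    self$children$stem_pool <- nn_maxpool(3L, 2L, pad = 1L)
    blocks <- list()
    in_c <- w[1]
    for (st in 1:4) {
      for (bl in seq_len(spec$blocks[st])) {
        stride <- if (st > 1L && bl == 1L) 2L else 1L
        blocks[[length(blocks) + 1L]] <-
          residual_block(in_c, w[st], stride, spec$attention,
                         spec$reduction, spec$spatial_kernel)
        in_c <- w[st]
      }
    }
    self$children$blocks <- NULL
    for (i in seq_along(blocks)) self$children[[paste0("block", i)]] <- blocks[[i]]
    self$blocks <- blocks
    self$children$fc <- nn_linear(w[4], spec$num_classes)
    self$fwd <- function(x, training = FALSE) {
      ch <- self$children
      h <- ch$stem_bn$fwd(ch$stem_conv$fwd(x, training), training)
      relu0 <- h$mat > 0
      h$mat <- h$mat * relu0
      if (training)
        self$cache <- list(relu0 = relu0, stem_geom = h[c("H", "W", "N")])
      h <- ch$stem_pool$fwd(h, training)
      for (b in self$blocks) h <- b$fwd(h, training)
      g <- sample_groups(h)
      feat <- rowsum(h$mat, g, reorder = TRUE) / (h$H * h$W)
      if (training) self$cache$gap_geom <- h[c("H", "W", "N")]
      ch$fc$fwd(feat, training)
    }
    self$bwd <- function(dlogits) {
      ch <- self$children
      cc <- self$cache
      dfeat <- ch$fc$bwd(dlogits)
      gg <- cc$gap_geom
      dmat <- dfeat[sample_groups(gg), , drop = FALSE] / (gg$H * gg$W)
      d <- nn_tensor(dmat, gg$H, gg$W, gg$N)
      for (b in rev(self$blocks)) d <- b$bwd(d)
      dpool <- ch$stem_pool$bwd(d)
      sg <- cc$stem_geom
      d <- nn_tensor(dpool * cc$relu0, sg$H, sg$W, sg$N)
      d <- ch$stem_conv$bwd(ch$stem_bn$bwd(d))
      self$cache <- NULL
      d
    }
    class(self) <- c("candle_model", "nn_layer")
    self
  })
}

#' @export
print.candle_model <- function(x, ...) {
  cat(sprintf("<candle_model> ResNet%d (+%s), %s parameters, seed %d\n",
              x$spec$depth, x$spec$attention,
              format(n_parameters(x), big.mark = ","), x$seed))
  invisible(x)
}

# forward a list of (H x W x 3, values 0..1 normalized) arrays through
# the model in evaluation mode, returning the logit matrix
model_logits <- function(model, xs, batch_size = 16L) {
  n <- length(xs)
  out <- matrix(0, n, model$spec$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- stack_inputs(xs[i:j])
    out[i:j, ] <- model$fwd(x, training = FALSE)
    i <- j + 1L
  }
  out
}

# list of H x W x 3 arrays -> input tensor (values already scaled)
stack_inputs <- function(xs) {
  H <- dim(xs[[1]])[1]; W <- dim(xs[[1]])[2]
  mat <- do.call(rbind, lapply(xs, function(a) matrix(a, H * W, 3L)))
  nn_tensor(mat, H, W, length(xs))
}
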