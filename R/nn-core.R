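# Minimal seeded neural-network engine.
#
# Feature maps flow as "tensors": a list(mat, H, W, N) where mat is a
# (H*W*N) x C matrix with row index r = h + H*(w-1) + H*W*(n-1).  This
# keeps channels in columns so per-channel operations (batch norm,
# channel gating) are plain column arithmetic, and convolutions become
# a single GEMM against im2col patches (cpp_im2col / cpp_col2im).
# Layers are mutable environments exposing fwd(x, training) and
# bwd(dy); each stores its parameters in $par, gradients in $grad and
# Adam state in $opt.

nn_tensor <- function(mat, H, W, N) list(mat = mat, H = H, W = W, N = N)

sigmoid <- function(x) 1 / (1 + exp(-x))

new_layer <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$par <- list()
  self$grad <- list()
  self$opt <- list()
  self$children <- list()
  class(self) <- "nn_layer"
  self
}

# Kaiming-style init for a fan_in of incoming connections
kaiming <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

# spatial-position group index: one group per sample
sample_groups <- function(x) rep(seq_len(x$N), each = x$H * x$W)

# expand an N x C matrix to (H*W*N) x C by repeating rows per sample
expand_samples <- function(m, x) m[sample_groups(x), , drop = FALSE]

nn_conv2d <- function(C_in, C_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      bias = FALSE) {
  self <- new_layer("conv2d")
  self$C_in <- C_in; self$C_out <- C_out
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)
  fan_in <- C_in * k * k
  self$par$W <- matrix(kaiming(fan_in * C_out, fan_in), fan_in, C_out)
  if (bias) self$par$b <- numeric(C_out)
  self$fwd <- function(x, training = FALSE) {
    cols <- cpp_im2col(x$mat, x$H, x$W, x$N, self$C_in,
                       self$k, self$stride, self$pad)
    y <- cols %*% self$par$W
    if (!is.null(self$par$b)) y <- y + rep(self$par$b, each = nrow(y))
    if (training) self$cache <- list(cols = cols, H = x$H, W = x$W, N = x$N)
    Ho <- (x$H + 2L * self$pad - self$k) %/% self$stride + 1L
    Wo <- (x$W + 2L * self$pad - self$k) %/% self$stride + 1L
    nn_tensor(y, Ho, Wo, x$N)
  }
  self$bwd <- function(dy) {
    cc <- self$cache
    self$grad$W <- crossprod(cc$cols, dy$mat)
    if (!is.null(self$par$b)) self$grad$b <- colSums(dy$mat)
    dcols <- dy$mat %*% t(self$par$W)
    dx <- cpp_col2im(dcols, cc$H, cc$W, cc$N, self$C_in,
                     self$k, self$stride, self$pad)
    self$cache <- NULL
    nn_tensor(dx, cc$H, cc$W, cc$N)
  }
  self
}

nn_batchnorm <- function(C, eps = 1e-5, momentum = 0.1) {
  self <- new_layer("batchnorm")
  self$eps <- eps; self$momentum <- momentum
  self$par$gamma <- rep(1, C)
  self$par$beta <- rep(0, C)
  self$running_mean <- rep(0, C)
  self$running_var <- rep(1, C)
  self$fwd <- function(x, training = FALSE) {
    if (training) {
      mu <- colMeans(x$mat)
      xc <- sweep(x$mat, 2L, mu)
      v <- colMeans(xc * xc) # population variance over the batch
      invstd <- 1 / sqrt(v + self$eps)
      xhat <- sweep(xc, 2L, invstd, "*")
      self$running_mean <- (1 - self$momentum) * self$running_mean +
        self$momentum * mu
      self$running_var <- (1 - self$momentum) * self$running_var +
        self$momentum * v
      self$cache <- list(xhat = xhat, invstd = invstd)
    } else {
      xhat <- sweep(sweep(x$mat, 2L, self$running_mean), 2L,
                    1 / sqrt(self$running_var + self$eps), "*")
    }
    y <- sweep(sweep(xhat, 2L, self$par$gamma, "*"), 2L, self$par$beta, "+")
    nn_tensor(y, x$H, x$W, x$N)
  }
  self$bwd <- function(dy) {
    xhat <- self$cache$xhat; invstd <- self$cache$invstd
    self$grad$gamma <- colSums(dy$mat * xhat)
    self$grad$beta <- colSums(dy$mat)
    dxhat <- sweep(dy$mat, 2L, self$par$gamma, "*")
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*")
    dx <- sweep(dx, 2L, invstd, "*")
    self$cache <- NULL
    nn_tensor(dx, dy$H, dy$W, dy$N)
  }
  self
}

nn_maxpool <- function(k, stride, pad = 0L) {
  self <- new_layer("maxpool")
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)
  self$fwd <- function(x, training = FALSE) {
    C <- ncol(x$mat)
    res <- cpp_maxpool(x$mat, x$H, x$W, x$N, C, self$k, self$stride, self$pad)
    if (training) self$cache <- list(argmax = res$argmax, nrow_x = nrow(x$mat))
    Ho <- (x$H + 2L * self$pad - self$k) %/% self$stride + 1L
    Wo <- (x$W + 2L * self$pad - self$k) %/% self$stride + 1L
    nn_tensor(res$y, Ho, Wo, x$N)
  }
  self$bwd <- function(dy) {
    dx <- cpp_maxpool_bwd(dy$mat, self$cache$argmax, self$cache$nrow_x)
    self$cache <- NULL
    # caller knows the input geometry; return matrix wrapped lazily
    dx
  }
  self
}

nn_linear <- function(C_in, C_out) {
  self <- new_layer("linear")
  self$par$W <- matrix(kaiming(C_in * C_out, C_in), C_in, C_out)
  self$par$b <- numeric(C_out)
  self$fwd <- function(x, training = FALSE) {
    if (training) self$cache <- list(x = x)
    x %*% self$par$W + rep(self$par$b, each = nrow(x))
  }
  self$bwd <- function(dy) {
    self$grad$W <- crossprod(self$cache$x, dy)
    self$grad$b <- colSums(dy)
    dx <- dy %*% t(self$par$W)
    self$cache <- NULL
    dx
  }
  self
}

# Softmax cross-entropy over K classes; y is an integer vector in 1..K.
# Returns mean loss and the gradient wrt the logits.
softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, prob = p)
}

# ---- parameter walking and Adam -------------------------------------------

walk_layers <- function(layer) {
  out <- list(layer)
  for (ch in layer$children)
    if (!is.null(ch)) out <- c(out, walk_layers(ch))
  out
}

zero_grads <- function(layers) {
  for (l in layers) l$grad <- list()
  invisible(NULL)
}

adam_step <- function(layers, t, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in layers) {
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      if (is.null(g)) next
      st <- l$opt[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      l$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$par[[nm]] <- l$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

# count of trainable parameter values in a module tree
n_parameters <- function(layer) {
  sum(vapply(walk_layers(layer),
             function(l) sum(vapply(l$par, length, integer(1))), numeric(1)))
}
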