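# Attention modules: channel + spatial (CBAM), squeeze-and-excitation
# and coordinate attention.  All gates are sigmoid outputs in (0, 1)
# applied multiplicatively, so a gated feature map never exceeds its
# input in magnitude and zeroed sub-networks give gates of exactly 0.5.

# per-(sample, channel) mean over spatial positions -> N x C
spatial_mean <- function(x) {
  g <- sample_groups(x)
  rowsum(x$mat, g, reorder = TRUE) / (x$H * x$W)
}

# per-(sample, channel) max over spatial positions, with absolute row
# indices of the maxima for gradient scatter
spatial_max <- function(x) {
  HW <- x$H * x$W
  C <- ncol(x$mat)
  mx <- matrix(0, x$N, C)
  am <- matrix(0L, x$N, C)
  for (n in seq_len(x$N)) {
    rows <- ((n - 1L) * HW + 1L):(n * HW)
    blk <- x$mat[rows, , drop = FALSE]
    j <- max.col(t(blk), ties.method = "first")
    mx[n, ] <- blk[cbind(j, seq_len(C))]
    am[n, ] <- j + (n - 1L) * HW
  }
  list(max = mx, argmax = am)
}

attention_hidden <- function(C, reduction) max(2L, C %/% as.integer(reduction))

# Channel attention: Mc = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))
# with a two-layer MLP shared between the two pooled branches.
nn_channel_attention <- function(C, reduction = 16L) {
  self <- new_layer("channel_attention")
  h <- attention_hidden(C, reduction)
  self$C <- C
  self$par$W1 <- matrix(kaiming(C * h, C), C, h)
  self$par$b1 <- numeric(h)
  self$par$W2 <- matrix(kaiming(h * C, h), h, C)
  self$par$b2 <- numeric(C)
  mlp1 <- function(s) s %*% self$par$W1 + rep(self$par$b1, each = nrow(s))
  self$fwd <- function(x, training = FALSE) {
    if (ncol(x$mat) != self$C) stopf("channel attention expects %d channels", self$C)
    sa <- spatial_mean(x)
    sm <- spatial_max(x)
    za <- mlp1(sa); zm <- mlp1(sm$max)
    ra <- pmax(za, 0); rm <- pmax(zm, 0)
    pre <- (ra %*% self$par$W2 + rep(self$par$b2, each = nrow(ra))) +
           (rm %*% self$par$W2 + rep(self$par$b2, each = nrow(rm)))
    Mc <- sigmoid(pre)
    self$last_gate <- Mc
    y <- x$mat * expand_samples(Mc, x)
    if (training)
      self$cache <- list(x = x, sa = sa, sm = sm, za = za, zm = zm,
                         ra = ra, rm = rm, Mc = Mc)
    nn_tensor(y, x$H, x$W, x$N)
  }
  self$bwd <- function(dy) {
    cc <- self$cache
    x <- cc$x
    g <- sample_groups(x)
    dMc <- rowsum(dy$mat * x$mat, g, reorder = TRUE)
    dxm <- dy$mat * expand_samples(cc$Mc, x)
    dpre <- dMc * cc$Mc * (1 - cc$Mc)
    # shared second layer: both branches contribute
    self$grad$W2 <- crossprod(cc$ra, dpre) + crossprod(cc$rm, dpre)
    self$grad$b2 <- 2 * colSums(dpre)
    dra <- dpre %*% t(self$par$W2)
    drm <- dra # same upstream gradient for both branch relu outputs
    dza <- dra * (cc$za > 0)
    dzm <- drm * (cc$zm > 0)
    self$grad$W1 <- crossprod(cc$sa, dza) + crossprod(cc$sm$max, dzm)
    self$grad$b1 <- colSums(dza) + colSums(dzm)
    dsa <- dza %*% t(self$par$W1)
    dsm <- dzm %*% t(self$par$W1)
    dxm <- dxm + expand_samples(dsa, x) / (x$H * x$W)
    idx <- cbind(as.vector(cc$sm$argmax), rep(seq_len(ncol(dxm)), each = x$N))
    dxm[idx] <- dxm[idx] + as.vector(dsm)
    self$cache <- NULL
    nn_tensor(dxm, x$H, x$W, x$N)
  }
  self
}

# Spatial attention: Ms = sigmoid(conv7x7([AvgPool_c(F'); MaxPool_c(F')]))
nn_spatial_attention <- function(spatial_kernel = 7L) {
  self <- new_layer("spatial_attention")
  k <- as.integer(spatial_kernel)
  if (k %% 2L == 0L) stopf("spatial kernel must be odd")
  self$children$conv <- nn_conv2d(2L, 1L, k, stride = 1L, pad = (k - 1L) %/% 2L,
                                  bias = TRUE)
  self$fwd <- function(x, training = FALSE) {
    av <- rowMeans(x$mat)
    rm <- cpp_row_max(x$mat)
    m2 <- nn_tensor(cbind(av, rm$max), x$H, x$W, x$N)
    z <- self$children$conv$fwd(m2, training)
    Ms <- sigmoid(z$mat)
    self$last_gate <- Ms
    y <- x$mat * as.vector(Ms)
    if (training) self$cache <- list(x = x, rm = rm, Ms = Ms)
    nn_tensor(y, x$H, x$W, x$N)
  }
  self$bwd <- function(dy) {
    cc <- self$cache
    x <- cc$x
    C <- ncol(x$mat)
    dMs <- rowSums(dy$mat * x$mat)
    dxm <- dy$mat * as.vector(cc$Ms)
    dz <- dMs * cc$Ms * (1 - cc$Ms)
    dm2 <- self$children$conv$bwd(nn_tensor(matrix(dz, ncol = 1L),
                                            dy$H, dy$W, dy$N))
    dxm <- dxm + dm2$mat[, 1L] / C # mean-pool branch spreads evenly
    idx <- cbind(seq_len(nrow(dxm)), cc$rm$argmax)
    dxm[idx] <- dxm[idx] + dm2$mat[, 2L]
    self$cache <- NULL
    nn_tensor(dxm, x$H, x$W, x$N)
  }
  self
}

# CBAM: channel gate then spatial gate, both multiplicative.
nn_cbam <- function(C, reduction = 16L, spatial_kernel = 7L) {
  self <- new_layer("cbam")
  self$children$channel <- nn_channel_attention(C, reduction)
  self$children$spatial <- nn_spatial_attention(spatial_kernel)
  self$fwd <- function(x, training = FALSE) {
    f1 <- self$children$channel$fwd(x, training)
    self$children$spatial$fwd(f1, training)
  }
  self$bwd <- function(dy) {
    self$children$channel$bwd(self$children$spatial$bwd(dy))
  }
  self
}

# Squeeze-and-excitation: global average pool -> bottleneck MLP ->
# sigmoid channel gate.
nn_se <- function(C, reduction = 16L) {
  self <- new_layer("se")
  h <- attention_hidden(C, reduction)
  self$par$W1 <- matrix(kaiming(C * h, C), C, h)
  self$par$b1 <- numeric(h)
  self$par$W2 <- matrix(kaiming(h * C, h), h, C)
  self$par$b2 <- numeric(C)
  self$fwd <- function(x, training = FALSE) {
    s <- spatial_mean(x)
    z <- s %*% self$par$W1 + rep(self$par$b1, each = nrow(s))
    r <- pmax(z, 0)
    g <- sigmoid(r %*% self$par$W2 + rep(self$par$b2, each = nrow(r)))
    self$last_gate <- g
    y <- x$mat * expand_samples(g, x)
    if (training) self$cache <- list(x = x, s = s, z = z, r = r, g = g)
    nn_tensor(y, x$H, x$W, x$N)
  }
  self$bwd <- function(dy) {
    cc <- self$cache
    x <- cc$x
    g <- sample_groups(x)
    dg <- rowsum(dy$mat * x$mat, g, reorder = TRUE)
    dxm <- dy$mat * expand_samples(cc$g, x)
    dpre <- dg * cc$g * (1 - cc$g)
    self$grad$W2 <- crossprod(cc$r, dpre)
    self$grad$b2 <- colSums(dpre)
    dr <- dpre %*% t(self$par$W2)
    dz <- dr * (cc$z > 0)
    self$grad$W1 <- crossprod(cc$s, dz)
    self$grad$b1 <- colSums(dz)
    ds <- dz %*% t(self$par$W1)
    dxm <- dxm + expand_samples(ds, x) / (x$H * x$W)
    self$cache <- NULL
    nn_tensor(dxm, x$H, x$W, x$N)
  }
  self
}

# Coordinate attention: directional (height / width) average pools pass
# through a shared bottleneck, then split into per-height and per-width
# sigmoid gates.  Follows the published design with a ReLU bottleneck.
nn_coord_attention <- function(C, reduction = 32L) {
  self <- new_layer("coord_attention")
  h <- attention_hidden(C, reduction)
  self$par$W1 <- matrix(kaiming(C * h, C), C, h)
  self$par$b1 <- numeric(h)
  self$par$Wh <- matrix(kaiming(h * C, h), h, C)
  self$par$bh <- numeric(C)
  self$par$Ww <- matrix(kaiming(h * C, h), h, C)
  self$par$bw <- numeric(C)
  idx_hw <- function(x) {
    r <- seq_len(nrow(x$mat)) - 1L
    hh <- r %% x$H + 1L
    ww <- (r %/% x$H) %% x$W + 1L
    nn <- r %/% (x$H * x$W) + 1L
    list(ih = hh + x$H * (nn - 1L), iw = ww + x$W * (nn - 1L))
  }
  self$fwd <- function(x, training = FALSE) {
    id <- idx_hw(x)
    zh <- rowsum(x$mat, id$ih, reorder = TRUE) / x$W # (H*N) x C
    zw <- rowsum(x$mat, id$iw, reorder = TRUE) / x$H # (W*N) x C
    z <- rbind(zh, zw)
    u <- z %*% self$par$W1 + rep(self$par$b1, each = nrow(z))
    t_ <- pmax(u, 0)
    nh <- nrow(zh)
    th <- t_[seq_len(nh), , drop = FALSE]
    tw <- t_[-seq_len(nh), , drop = FALSE]
    ah <- sigmoid(th %*% self$par$Wh + rep(self$par$bh, each = nrow(th)))
    aw <- sigmoid(tw %*% self$par$Ww + rep(self$par$bw, each = nrow(tw)))
    self$last_gate <- list(h = ah, w = aw)
    y <- x$mat * ah[id$ih, , drop = FALSE] * aw[id$iw, , drop = FALSE]
    if (training)
      self$cache <- list(x = x, id = id, z = z, u = u, th = th, tw = tw,
                         ah = ah, aw = aw, nh = nh)
    nn_tensor(y, x$H, x$W, x$N)
  }
  self$bwd <- function(dy) {
    cc <- self$cache
    x <- cc$x; id <- cc$id
    A <- cc$ah[id$ih, , drop = FALSE]
    B <- cc$aw[id$iw, , drop = FALSE]
    dxm <- dy$mat * A * B
    dAh <- rowsum(dy$mat * x$mat * B, id$ih, reorder = TRUE)
    dAw <- rowsum(dy$mat * x$mat * A, id$iw, reorder = TRUE)
    dph <- dAh * cc$ah * (1 - cc$ah)
    dpw <- dAw * cc$aw * (1 - cc$aw)
    self$grad$Wh <- crossprod(cc$th, dph)
    self$grad$bh <- colSums(dph)
    self$grad$Ww <- crossprod(cc$tw, dpw)
    self$grad$bw <- colSums(dpw)
    dth <- dph %*% t(self$par$Wh)
    dtw <- dpw %*% t(self$par$Ww)
    dt <- rbind(dth, dtw) * (cc$u > 0)
    self$grad$W1 <- crossprod(cc$z, dt)
    self$grad$b1 <- colSums(dt)
    dz <- dt %*% t(self$par$W1)
    dzh <- dz[seq_len(cc$nh), , drop = FALSE]
    dzw <- dz[-seq_len(cc$nh), , drop = FALSE]
    dxm <- dxm + dzh[id$ih, , drop = FALSE] / x$W +
      dzw[id$iw, , drop = FALSE] / x$H
    self$cache <- NULL
    nn_tensor(dxm, x$H, x$W, x$N)
  }
  self
}

make_attention <- function(kind, C, reduction = 16L, spatial_kernel = 7L,
                           ca_reduction = 32L) {
  switch(kind,
         none = NULL,
         cbam = nn_cbam(C, reduction, spatial_kernel),
         se = nn_se(C, reduction),
         ca = nn_coord_attention(C, ca_reduction),
         stopf("unknown attention kind '%s'", kind))
}

# ---- exported functional views (single feature map) -----------------------

# convert a C x H x W array to the internal tensor layout and back
fmap_to_tensor <- function(f) {
  d <- dim(f)
  if (length(d) != 3L) stopf("feature map must be a C x H x W array")
  nn_tensor(t(matrix(f, d[1], d[2] * d[3])), d[2], d[3], 1L)
}

tensor_to_fmap <- function(x, C = ncol(x$mat)) {
  array(t(x$mat), dim = c(C, x$H, x$W))
}

#' Reshape a spatial convolution kernel to the internal weight matrix
#'
#' The convolution engine stores weights as a `(C_in * k * k) x C_out`
#' matrix whose row index is `c + C_in * ((kh - 1) + k * (kw - 1))`.
#' This helper converts a `k x k x C_in` (single output channel) or
#' `k x k x C_in x C_out` kernel array to that layout, which is what
#' the hand-written oracles in the tests use.
#'
#' @param karr Kernel array.
#' @return Weight matrix.
#' @export
kernel_to_mat <- function(karr) {
  d <- dim(karr)
  if (length(d) == 3L) { karr <- array(karr, c(d, 1L)); d <- dim(karr) }
  k <- d[1]; C_in <- d[3]; C_out <- d[4]
  W <- matrix(0, C_in * k * k, C_out)
  for (co in seq_len(C_out))
    for (kw in seq_len(k))
      for (kh in seq_len(k))
        for (ci in seq_len(C_in))
          W[ci + C_in * ((kh - 1L) + k * (kw - 1L)), co] <- karr[kh, kw, ci, co]
  W
}

#' Channel attention weights of a feature map
#'
#' Computes the per-channel sigmoid gate
#' `sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))`, where both pools act
#' over the spatial dimensions and the two-layer MLP (weights `W1`,
#' `b1`, `W2`, `b2`) is shared between the branches.
#'
#' @param f C x H x W numeric array.
#' @param W1,b1,W2,b2 MLP parameters: `W1` is `C x hidden`, `W2` is
#'   `hidden x C`; biases default to zero.
#' @return Length-C vector of gates in (0, 1).
#' @export
channel_attention <- function(f, W1, b1 = numeric(ncol(W1)), W2,
                              b2 = numeric(ncol(W2))) {
  C <- dim(f)[1]
  if (nrow(W1) != C) stopf("W1 must have %d rows to match the channels", C)
  lay <- nn_channel_attention(C, reduction = max(1L, C %/% ncol(W1)))
  lay$par <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  lay$fwd(fmap_to_tensor(f), training = FALSE)
  as.vector(lay$last_gate)
}

#' Spatial attention weights of a feature map
#'
#' Computes the per-position sigmoid gate
#' `sigmoid(conv([AvgPool_c(F); MaxPool_c(F)]))` where the pools act
#' over channels and the convolution (default 7 x 7, same-size padding)
#' maps the 2-channel pooled stack to one channel.
#'
#' @param f C x H x W numeric array.
#' @param kernel `k x k x 2` kernel array (channel 1 weights the
#'   average-pool map, channel 2 the max-pool map).
#' @param bias Scalar bias.
#' @return H x W matrix of gates in (0, 1).
#' @export
spatial_attention <- function(f, kernel, bias = 0) {
  d <- dim(kernel)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 2L)
    stopf("kernel must be a k x k x 2 array")
  lay <- nn_spatial_attention(d[1])
  lay$children$conv$par$W <- kernel_to_mat(kernel)
  lay$children$conv$par$b <- bias
  lay$fwd(fmap_to_tensor(f), training = FALSE)
  matrix(lay$last_gate, dim(f)[2], dim(f)[3])
}

#' Apply the convolutional block attention module to a feature map
#'
#' Cascades channel then spatial attention:
#' `F' = Mc(F) * F` (channel gate broadcast over space) and
#' `F'' = Ms(F') * F'` (spatial gate broadcast over channels), both
#' multiplications element-wise.
#'
#' @param f C x H x W numeric array.
#' @param params List with MLP parameters `W1, b1, W2, b2` (see
#'   [channel_attention()]) and spatial parameters `kernel, bias` (see
#'   [spatial_attention()]).
#' @return C x H x W array of the same shape.
#' @export
cbam <- function(f, params) {
  C <- dim(f)[1]
  lay <- nn_cbam(C, reduction = max(1L, C %/% ncol(params$W1)),
                 spatial_kernel = dim(params$kernel)[1])
  lay$children$channel$par <- params[c("W1", "b1", "W2", "b2")]
  if (is.null(lay$children$channel$par$b1))
    lay$children$channel$par$b1 <- numeric(ncol(params$W1))
  if (is.null(lay$children$channel$par$b2))
    lay$children$channel$par$b2 <- numeric(C)
  lay$children$spatial$children$conv$par$W <- kernel_to_mat(params$kernel)
  lay$children$spatial$children$conv$par$b <- params$bias %||% 0
  out <- lay$fwd(fmap_to_tensor(f), training = FALSE)
  tensor_to_fmap(out, C)
}
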