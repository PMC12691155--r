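# Independent brute-force oracles.  These deliberately avoid the code
# paths they are used to check: plain loops, direct sums, no shared
# helpers.

# median filter with symmetric (edge-duplicating) reflection padding
oracle_median <- function(img, k) {
  H <- nrow(img); W <- ncol(img); p <- (k - 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- img
  for (h in 1:H) for (w in 1:W) {
    vals <- numeric(0)
    for (dh in -p:p) for (dw in -p:p)
      vals <- c(vals, img[refl(h + dh, H), refl(w + dw, W)])
    out[h, w] <- median(vals)
  }
  out
}

# exhaustive 256-threshold Otsu scan with direct per-threshold sums
oracle_otsu <- function(gray) {
  v <- as.vector(gray)
  n <- length(v)
  best_T <- NA_integer_; best_s <- -1
  sigmas <- numeric(256)
  for (T in 0:255) {
    c0 <- v[v <= T]; c1 <- v[v > T]
    s <- if (length(c0) == 0 || length(c1) == 0) 0 else
      (length(c0) / n) * (length(c1) / n) * (mean(c0) - mean(c1))^2
    sigmas[T + 1] <- s
    if (s > best_s) { best_s <- s; best_T <- T }
  }
  list(T = best_T, sigma = best_s, curve = sigmas)
}

# 8-connected labeling by breadth-first flood fill over a pixel queue
oracle_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (w in 1:W) for (h in 1:H) {
    if (!mask[h, w] || lab[h, w] > 0L) next
    cur <- cur + 1L
    queue <- list(c(h, w)); lab[h, w] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dh in -1:1) for (dw in -1:1) {
        nh <- q[1] + dh; nw <- q[2] + dw
        if (nh >= 1 && nh <= H && nw >= 1 && nw <= W &&
            mask[nh, nw] && lab[nh, nw] == 0L) {
          lab[nh, nw] <- cur
          queue <- c(queue, list(c(nh, nw)))
        }
      }
    }
  }
  lab
}

# direct 2-D convolution (zero padding) of an H x W x Cin array with a
# k x k x Cin x Cout kernel
oracle_conv2d <- function(x, kern, stride = 1L, pad = 0L, bias = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(kern)[1]; Cout <- dim(kern)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout))
  for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- if (is.null(bias)) 0 else bias[co]
    for (kh in 1:k) for (kw in 1:k) for (ci in 1:Cin) {
      hi <- (ho - 1) * stride + kh - pad
      wi <- (wo - 1) * stride + kw - pad
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci] * kern[kh, kw, ci, co]
    }
    out[ho, wo, co] <- acc
  }
  out
}

# macro precision/recall/F1 per class from a confusion matrix (rows =
# true), computed one class at a time
oracle_macro <- function(cm) {
  k <- nrow(cm)
  p <- r <- f <- numeric(k)
  for (i in 1:k) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    p[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    r[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f[i] <- if (p[i] + r[i] > 0) 2 * p[i] * r[i] / (p[i] + r[i]) else 0
  }
  list(precision = mean(p), recall = mean(r), f1 = mean(f))
}

# compact generator settings for fast property loops
small_gen_params <- function(...) {
  generator_params(image_width = 160L, image_height = 96L,
                   egg_axes_range = list(major = c(28, 34),
                                         minor = c(20, 24)),
                   vessel_step = 25L, ...)
}

# random H x W x 3 integer image
rand_rgb <- function(H, W, seed = 1) {
  set.seed(seed)
  array(sample(0:255, H * W * 3, replace = TRUE), c(H, W, 3))
}
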