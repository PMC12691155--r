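# Finite-difference gradient checking for layer environments.  Uses the
# smooth surrogate loss sum(R * forward(x)) with a fixed random R, so
# the only nondifferentiable points are the layer's own kinks (ReLU,
# max pooling); seeds are fixed so inputs sit away from them.
check_grads <- function(layer, x, n_each = 4, eps = 1e-5, seed = 99) {
  fwd_mat <- function() {
    o <- layer$fwd(x, training = TRUE)
    if (is.list(o)) o$mat else o
  }
  m0 <- fwd_mat()
  set.seed(seed)
  R <- matrix(rnorm(length(m0)), nrow(m0))
  o <- layer$fwd(x, training = TRUE)
  dy <- if (is.list(o)) { o$mat <- R; o } else R
  dx <- layer$bwd(dy)
  dxm <- if (is.list(dx)) dx$mat else dx
  loss <- function() sum(R * fwd_mat())
  max_err <- 0
  for (l in eggcandler:::walk_layers(layer)) {
    for (nm in names(l$par)) {
      ks <- unique(round(seq(1, length(l$par[[nm]]), length.out = n_each)))
      for (k in ks) {
        p0 <- l$par[[nm]][k]
        l$par[[nm]][k] <- p0 + eps; lp <- loss()
        l$par[[nm]][k] <- p0 - eps; lm <- loss()
        l$par[[nm]][k] <- p0
        gn <- (lp - lm) / (2 * eps)
        max_err <- max(max_err, abs(l$grad[[nm]][k] - gn) / max(1, abs(gn)))
      }
    }
  }
  xm <- if (is.list(x)) x$mat else x
  ks <- unique(round(seq(1, length(xm), length.out = n_each)))
  for (k in ks) {
    p0 <- xm[k]
    assign_x <- function(v) {
      if (is.list(x)) x$mat[k] <<- v else x[k] <<- v
    }
    assign_x(p0 + eps); lp <- loss()
    assign_x(p0 - eps); lm <- loss()
    assign_x(p0)
    gn <- (lp - lm) / (2 * eps)
    max_err <- max(max_err, abs(dxm[k] - gn) / max(1, abs(gn)))
  }
  max_err
}

rand_tensor <- function(C, H, W, N, seed = 5) {
  set.seed(seed)
  eggcandler:::nn_tensor(matrix(rnorm(H * W * N * C), H * W * N, C), H, W, N)
}
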