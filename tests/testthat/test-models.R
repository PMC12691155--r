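test_that("zeroed attention sub-networks gate at exactly 0.5 and CBAM scales by 0.25", {
  set.seed(1)
  C <- 4; H <- 5; W <- 6
  f <- array(rnorm(C * H * W), c(C, H, W))
  W1 <- matrix(0, C, 2); W2 <- matrix(0, 2, C)
  expect_equal(channel_attention(f, W1, W2 = W2), rep(0.5, C))
  kern <- array(0, c(7, 7, 2))
  expect_equal(spatial_attention(f, kern), matrix(0.5, H, W))
  out <- cbam(f, list(W1 = W1, W2 = W2, kernel = kern, bias = 0))
  expect_lt(max(abs(out - 0.25 * f)), 1e-6)
  expect_equal(dim(out), dim(f))
})

test_that("average and max pooling coincide on per-channel-constant maps", {
  set.seed(2)
  C <- 3
  v <- c(1.5, -0.7, 0.3)
  f <- array(rep(v, 4 * 4), c(C, 4, 4)) # channel c constant at v[c]
  W1 <- matrix(rnorm(C * 2), C, 2); b1 <- rnorm(2)
  W2 <- matrix(rnorm(2 * C), 2, C); b2 <- rnorm(C)
  mlp <- function(s) pmax(s %*% W1 + rep(b1, each = 1), 0) %*% W2 + b2
  expected <- 1 / (1 + exp(-2 * mlp(matrix(v, 1))))
  expect_equal(channel_attention(f, W1, b1, W2, b2), as.vector(expected),
               tolerance = 1e-12)
})

test_that("channel attention matches a step-by-step scalar oracle on a tiny map", {
  f <- array(c(1, -2, 0.5, 3, -1, 4, 2, 0), c(2, 2, 2))
  W1 <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  b1 <- c(0.05, -0.1)
  W2 <- matrix(c(0.4, 0.2, -0.3, 0.6), 2, 2)
  b2 <- c(0.1, -0.2)
  # oracle: explicit pooling then two-layer MLP, each step by hand
  avg <- c(mean(f[1, , ]), mean(f[2, , ]))
  mx <- c(max(f[1, , ]), max(f[2, , ]))
  branch <- function(s) {
    z <- c(s[1] * W1[1, 1] + s[2] * W1[2, 1] + b1[1],
           s[1] * W1[1, 2] + s[2] * W1[2, 2] + b1[2])
    r <- pmax(z, 0)
    c(r[1] * W2[1, 1] + r[2] * W2[2, 1] + b2[1],
      r[1] * W2[1, 2] + r[2] * W2[2, 2] + b2[2])
  }
  expected <- 1 / (1 + exp(-(branch(avg) + branch(mx))))
  expect_equal(channel_attention(f, W1, b1, W2, b2), expected,
               tolerance = 1e-12)
})

test_that("spatial attention equals a direct 7x7 convolution oracle", {
  set.seed(3)
  f <- array(rnorm(8 * 8), c(1, 8, 8))
  kern <- array(rnorm(7 * 7 * 2) / 10, c(7, 7, 2))
  bias <- 0.2
  ms <- spatial_attention(f, kern, bias)
  expect_equal(dim(ms), c(8, 8))
  # with one channel, both channel-pools return the map itself
  m2 <- array(0, c(8, 8, 2))
  m2[, , 1] <- f[1, , ]; m2[, , 2] <- f[1, , ]
  z <- oracle_conv2d(m2, array(kern, c(7, 7, 2, 1)), stride = 1, pad = 3,
                     bias = bias)
  expect_equal(ms, 1 / (1 + exp(-z[, , 1])), tolerance = 1e-10)
  expect_error(spatial_attention(f, array(0, c(7, 7, 3))), "k x k x 2")
})

test_that("attention gates lie in (0,1) and CBAM never amplifies a feature map", {
  for (seed in 1:3) {
    set.seed(seed)
    C <- 8; H <- 5; W <- 7
    f <- array(rnorm(C * H * W), c(C, H, W))
    params <- list(W1 = matrix(rnorm(C * 2) / 2, C, 2), b1 = rnorm(2) / 2,
                   W2 = matrix(rnorm(2 * C) / 2, 2, C), b2 = rnorm(C) / 2,
                   kernel = array(rnorm(7 * 7 * 2) / 4, c(7, 7, 2)),
                   bias = rnorm(1) / 2)
    gates_c <- channel_attention(f, params$W1, params$b1, params$W2, params$b2)
    expect_true(all(gates_c > 0 & gates_c < 1))
    out <- cbam(f, params)
    expect_true(all(abs(out) <= abs(f)))
    expect_equal(dim(out), dim(f))
  }
})

test_that("zeroed residual branches reduce blocks to (projected) identity plus activation", {
  for (att in c("none", "cbam")) {
    blk <- residual_block(4, 4, stride = 1, attention = att)
    blk$children$conv1$par$W[] <- 0
    blk$children$conv2$par$W[] <- 0
    set.seed(4)
    x_pos <- array(abs(rnorm(4 * 6 * 5)), c(4, 6, 5))
    expect_equal(residual_block_forward(blk, x_pos, training = TRUE), x_pos,
                 tolerance = 1e-12)
    x_mix <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
    expect_equal(residual_block_forward(blk, x_mix, training = TRUE),
                 pmax(x_mix, 0), tolerance = 1e-12)
  }
})

test_that("stride-2 blocks halve the spatial extent and project channels", {
  blk <- residual_block(4, 8, stride = 2, attention = "se")
  set.seed(5)
  x <- array(rnorm(4 * 8 * 6), c(4, 8, 6))
  y <- residual_block_forward(blk, x, training = TRUE)
  expect_equal(dim(y), c(8, 4, 3))
})

test_that("a hand-computed scalar residual block agrees with the implementation", {
  blk <- residual_block(1, 1, stride = 1, attention = "none")
  w1 <- 0.7; w2 <- -0.3
  blk$children$conv1$par$W[] <- 0; blk$children$conv1$par$W[5, 1] <- w1
  blk$children$conv2$par$W[] <- 0; blk$children$conv2$par$W[5, 1] <- w2
  # make eval-mode batch norm an exact identity
  for (bn in list(blk$children$bn1, blk$children$bn2)) {
    bn$running_mean[] <- 0; bn$running_var[] <- 1
    bn$par$gamma[] <- sqrt(1 + bn$eps)
  }
  x <- array(2, c(1, 1, 1))
  # y = relu(w2 * relu(w1 * x) + x) = relu(-0.42 + 2)
  expect_equal(as.vector(residual_block_forward(blk, x)), 1.58,
               tolerance = 1e-12)
  x2 <- array(0.1, c(1, 1, 1))
  # residual sum 0.1 - 0.021 = 0.079
  expect_equal(as.vector(residual_block_forward(blk, x2)), 0.079,
               tolerance = 1e-12)
})

test_that("the classifier emits one 3-logit row per sample and is seed-reproducible", {
  spec <- model_spec(attention = "cbam", width_factor = 1 / 8, input_size = 32)
  m1 <- build_classifier(spec, seed = 11)
  m2 <- build_classifier(spec, seed = 11)
  m3 <- build_classifier(spec, seed = 12)
  expect_identical(m1$children$stem_conv$par$W, m2$children$stem_conv$par$W)
  expect_identical(m1$children$fc$par$W, m2$children$fc$par$W)
  expect_false(identical(m1$children$stem_conv$par$W,
                         m3$children$stem_conv$par$W))
  set.seed(6)
  xs <- lapply(1:2, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  lg <- eggcandler:::model_logits(m1, xs)
  expect_equal(dim(lg), c(2, 3))
  expect_true(all(is.finite(lg)))
  expect_equal(eggcandler:::model_logits(m2, xs), lg)
})

test_that("saturating every CBAM gate reproduces the attention-free network exactly", {
  spec_c <- model_spec(attention = "cbam", width_factor = 1 / 8, input_size = 32)
  spec_n <- model_spec(attention = "none", width_factor = 1 / 8, input_size = 32)
  mc <- build_classifier(spec_c, seed = 21)
  mn <- build_classifier(spec_n, seed = 22)
  # share all non-attention weights, then force the multiplicative gates
  # to 1 so the fusion becomes a no-op
  copy <- function(from, to) {
    for (nm in names(from$par)) to$par[[nm]] <- from$par[[nm]]
    if (!is.null(from$running_mean)) {
      to$running_mean <- from$running_mean
      to$running_var <- from$running_var
    }
  }
  copy(mc$children$stem_conv, mn$children$stem_conv)
  copy(mc$children$stem_bn, mn$children$stem_bn)
  copy(mc$children$fc, mn$children$fc)
  for (i in seq_along(mc$blocks)) {
    bc <- mc$blocks[[i]]; bn <- mn$blocks[[i]]
    for (nm in c("conv1", "bn1", "conv2", "bn2", "conv_s", "bn_s"))
      if (!is.null(bc$children[[nm]])) copy(bc$children[[nm]], bn$children[[nm]])
    att <- bc$children$attn
    att$children$channel$par$W1[] <- 0
    att$children$channel$par$W2[] <- 0
    att$children$channel$par$b1[] <- 0
    att$children$channel$par$b2[] <- 1e3 # sigmoid(2e3) == 1 in doubles
    att$children$spatial$children$conv$par$W[] <- 0
    att$children$spatial$children$conv$par$b[] <- 1e3
  }
  set.seed(7)
  xs <- lapply(1:2, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_equal(eggcandler:::model_logits(mc, xs),
               eggcandler:::model_logits(mn, xs), tolerance = 1e-10)
})

test_that("analytic gradients match central differences for every layer type", {
  x <- rand_tensor(3, 6, 5, 2, seed = 31)
  expect_lt(check_grads(eggcandler:::nn_conv2d(3, 4, 3, stride = 2, bias = TRUE), x),
            1e-5)
  expect_lt(check_grads(eggcandler:::nn_batchnorm(3), x), 1e-5)
  expect_lt(check_grads(eggcandler:::nn_maxpool(3, 2, 1), x), 1e-5)
  set.seed(32)
  expect_lt(check_grads(eggcandler:::nn_se(3, reduction = 1), x), 1e-4)
  set.seed(33)
  expect_lt(check_grads(eggcandler:::nn_channel_attention(3, reduction = 1), x),
            1e-4)
  set.seed(34)
  expect_lt(check_grads(eggcandler:::nn_spatial_attention(7), x), 1e-4)
  set.seed(35)
  expect_lt(check_grads(eggcandler:::nn_coord_attention(3, reduction = 1), x),
            1e-4)
  set.seed(36)
  expect_lt(check_grads(eggcandler:::nn_cbam(3, 1, 7), x), 1e-4)
  set.seed(37)
  xm <- matrix(rnorm(8), 2, 4)
  expect_lt(check_grads(eggcandler:::nn_linear(4, 3), xm), 1e-6)
  set.seed(38)
  expect_lt(check_grads(residual_block(3, 4, 2, attention = "cbam"), x), 1e-3)
})

test_that("unsupported specifications are rejected", {
  expect_error(model_spec(depth = 50), "34")
  expect_error(model_spec(num_classes = 1), "num_classes")
  expect_error(model_spec(input_size = 100), "multiple of 32")
  expect_error(model_spec(spatial_kernel = 4), "odd")
})
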