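test_that("stratified splitting preserves class proportions and partitions exactly", {
  y <- rep("a", 100)
  sp <- stratified_split(y, c(0.6, 0.2, 0.2), seed = 1)
  expect_length(sp$train, 60)
  expect_length(sp$val, 20)
  expect_length(sp$test, 20)

  y3 <- rep(c("a", "b", "c"), each = 50)
  sp3 <- stratified_split(y3, seed = 2)
  all_idx <- c(sp3$train, sp3$val, sp3$test)
  expect_setequal(all_idx, seq_along(y3))
  expect_equal(length(all_idx), length(unique(all_idx))) # pairwise disjoint
  for (cl in c("a", "b", "c")) {
    expect_lte(abs(sum(y3[sp3$train] == cl) - 30), 1)
    expect_lte(abs(sum(y3[sp3$val] == cl) - 10), 1)
    expect_lte(abs(sum(y3[sp3$test] == cl) - 10), 1)
  }

  expect_identical(stratified_split(y3, seed = 2), sp3)
  expect_false(identical(stratified_split(y3, seed = 3), sp3))
  expect_error(stratified_split(factor(c("a"), levels = c("a", "b"))),
               "at least one")
  expect_error(stratified_split(y3, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("augmentation primitives behave as documented", {
  set.seed(8)
  img <- array(runif(10 * 12 * 3), c(10, 12, 3))
  expect_equal(hflip(hflip(img)), img) # involution
  cc <- center_crop(img, 8)
  expect_equal(dim(cc), c(8, 8, 3))
  expect_equal(cc[1, 1, ], img[2, 3, ]) # central window

  m <- vapply(1:3, function(ch) mean(img[, , ch]), numeric(1))
  s <- vapply(1:3, function(ch) sd(as.vector(img[, , ch])), numeric(1))
  z <- normalize_channels(img, m, s)
  for (ch in 1:3) {
    expect_equal(mean(z[, , ch]), 0, tolerance = 1e-12)
    expect_equal(sd(as.vector(z[, , ch])), 1, tolerance = 1e-12)
  }

  cfg <- list(input_size = 10, flip = TRUE, mean = m, sd = s)
  sq <- img[1:10, 1:10, , drop = FALSE]
  e1 <- augment(sq, cfg, train = FALSE)
  e2 <- augment(sq, cfg, train = FALSE)
  expect_identical(e1, e2) # evaluation path is deterministic
})

test_that("cross-entropy of uniform logits over 3 classes is ln 3", {
  lg <- matrix(0, 4, 3)
  ls <- eggcandler:::softmax_xent(lg, c(1L, 2L, 3L, 1L))
  expect_equal(ls$loss, log(3), tolerance = 1e-12)
  lg2 <- matrix(rep(c(2.2, 2.2, 2.2), each = 2), 2, 3)
  expect_equal(eggcandler:::softmax_xent(lg2, c(1L, 3L))$loss, log(3),
               tolerance = 1e-12)
})

test_that("training performs ceiling(n/batch) optimizer steps per epoch and is seed-deterministic", {
  spec <- model_spec(attention = "none", width_factor = 1 / 16, input_size = 32)
  set.seed(9)
  xs <- lapply(1:10, function(i) array(runif(32 * 32 * 3) * 255, c(32, 32, 3)))
  y <- rep(1:2, 5)
  cfg <- candle_config(epochs = 2, batch_size = 4, seed = 5, split = c(0.6, 0.2, 0.2))
  m1 <- build_classifier(model_spec(attention = "none", width_factor = 1 / 16,
                                    input_size = 32, num_classes = 2), seed = 5)
  r1 <- train_model(m1, xs, y, xs[1:4], y[1:4], cfg)
  expect_equal(r1$steps, 2L * ceiling(10 / 4))
  expect_equal(nrow(r1$records), 2)
  expect_true(all(r1$records$train_loss >= 0))
  expect_true(all(r1$records$val_accuracy >= 0 & r1$records$val_accuracy <= 1))

  m2 <- build_classifier(model_spec(attention = "none", width_factor = 1 / 16,
                                    input_size = 32, num_classes = 2), seed = 5)
  r2 <- train_model(m2, xs, y, xs[1:4], y[1:4], cfg)
  expect_identical(r1$records, r2$records)
  expect_error(train_model(m1, list(), integer(), xs, y, cfg), "empty training")
})

test_that("stability metrics match hand arithmetic and definitional identities", {
  const <- rep(0.9, 25)
  st <- stability_metrics(const, window = 10)
  expect_equal(st$mean_accuracy, 0.9)
  expect_equal(st$overall_variance, 0)
  expect_equal(st$first10_variance, 0)
  expect_equal(st$last10_variance, 0)

  st2 <- stability_metrics(c(0.8, 1.0), window = NULL)
  expect_equal(st2$mean_accuracy, 0.9)
  expect_equal(st2$overall_variance, 0.01) # population variance
  expect_equal(st2$overall_std, 0.1)

  set.seed(10)
  acc <- runif(30, 0.5, 1)
  st3 <- stability_metrics(acc, window = 10)
  expect_equal(st3$overall_variance, st3$overall_std^2, tolerance = 1e-14)
  expect_equal(st3$mean_accuracy, mean(acc))
  expect_equal(st3$first10_variance, mean((acc[1:10] - mean(acc[1:10]))^2))
  expect_equal(st3$last10_variance, mean((acc[21:30] - mean(acc[21:30]))^2))

  expect_error(stability_metrics(runif(15), window = 10), "at least 20")
})

test_that("macro metrics match a per-class brute-force oracle", {
  cm <- matrix(c(8, 1, 1,
                 0, 9, 1,
                 2, 0, 8), 3, 3, byrow = TRUE)
  mm <- eggcandler:::macro_metrics(cm)
  orc <- oracle_macro(cm)
  expect_equal(mm$precision, orc$precision, tolerance = 1e-14)
  expect_equal(mm$recall, orc$recall, tolerance = 1e-14)
  expect_equal(mm$f1, orc$f1, tolerance = 1e-14)
  # degenerate column (class never predicted) yields zero precision
  cm0 <- matrix(c(5, 0, 5,
                  0, 4, 6,
                  0, 0, 10), 3, 3, byrow = TRUE)
  expect_equal(eggcandler:::macro_metrics(cm0)$precision,
               oracle_macro(cm0)$precision)
  # a perfectly diagonal confusion matrix scores 1 everywhere
  mm1 <- eggcandler:::macro_metrics(diag(c(5, 3, 4)))
  expect_equal(mm1$precision, 1)
  expect_equal(mm1$recall, 1)
  expect_equal(mm1$f1, 1)
})

test_that("end-to-end fits are reproducible and evaluation accounting is exact", {
  p <- small_gen_params()
  ds <- generate_dataset(c(unfertilized = 5, live = 5, abnormal = 5), p, seed = 14)
  prep <- prepare_dataset(ds, preprocess_config(input_size = 32))
  spec <- model_spec(attention = "none", width_factor = 1 / 16, input_size = 32)
  cfg <- candle_config(epochs = 2, batch_size = 8, seed = 3)
  fit1 <- candle_net(prep, spec = spec, config = cfg)
  fit2 <- candle_net(prep, spec = spec, config = cfg)
  expect_identical(fit1$records, fit2$records)
  expect_identical(fit1$split, fit2$split)

  ev <- evaluate_model(fit1, prep$x[fit1$split$test], prep$y[fit1$split$test],
                       rounds = 10, seed = 4)
  cm <- ev$confusion
  expect_equal(sum(diag(cm)) / sum(cm), ev$accuracy)
  expect_equal(unname(rowSums(cm)),
               unname(as.vector(table(prep$y[fit1$split$test]))))
  ev2 <- evaluate_model(fit1, prep$x[fit1$split$test], prep$y[fit1$split$test],
                        rounds = 10, seed = 4)
  expect_identical(ev$round_accuracies, ev2$round_accuracies)
  # fully deterministic rounds collapse the round-to-round variance to 0
  ev3 <- evaluate_model(fit1, prep$x[fit1$split$test], prep$y[fit1$split$test],
                        rounds = 10, resample = FALSE)
  expect_equal(ev3$mean_variance, 0)
  expect_equal(ev3$mode, "deterministic")

  # scoring predictions against themselves leaves no off-diagonal mass
  yhat <- predict(fit1, prep$x[fit1$split$test])
  ev4 <- evaluate_model(fit1, prep$x[fit1$split$test], yhat, rounds = 5)
  expect_equal(ev4$accuracy, 1)
  expect_true(all(ev4$confusion[upper.tri(ev4$confusion)] == 0) &&
              all(ev4$confusion[lower.tri(ev4$confusion)] == 0))

  s <- summary(fit1)
  expect_s3_class(s$stability, "stability_report")
  cf <- coef(fit1)
  expect_true(length(cf) > 10)
})

test_that("attention variants are compared on one shared partition", {
  p <- small_gen_params()
  ds <- generate_dataset(c(unfertilized = 4, live = 4, abnormal = 4), p, seed = 15)
  prep <- prepare_dataset(ds, preprocess_config(input_size = 32))
  spec <- model_spec(width_factor = 1 / 16, input_size = 32)
  cfg <- candle_config(epochs = 1, batch_size = 8, seed = 6)
  cmp1 <- compare_attention_variants(prep, attentions = "none", spec = spec,
                                     config = cfg, rounds = 3)
  expect_equal(nrow(cmp1$table), 1)
  cmp2 <- compare_attention_variants(prep, attentions = c("none", "none"),
                                     spec = spec, config = cfg, rounds = 3)
  expect_equal(cmp2$table$test_accuracy[1], cmp2$table$test_accuracy[2])
  expect_equal(cmp2$table$mean_accuracy[1], cmp2$table$mean_accuracy[2])
  expect_identical(cmp1$split, cmp2$split)
})
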