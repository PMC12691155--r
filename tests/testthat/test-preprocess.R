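test_that("grayscale conversion uses BT.601 weights and validates input", {
  white <- array(255, c(4, 5, 3))
  expect_true(all(to_grayscale(white) == 255))
  black <- array(0, c(4, 5, 3))
  expect_true(all(to_grayscale(black) == 0))
  red <- array(0, c(3, 3, 3)); red[, , 1] <- 255
  expect_true(all(to_grayscale(red) == round(255 * 0.299)))
  expect_error(to_grayscale(matrix(0, 3, 3)), "H x W x 3")
  expect_error(to_grayscale(array(300, c(2, 2, 3))), "\\[0, 255\\]")
})

test_that("median filter matches the brute-force neighbourhood oracle", {
  const <- matrix(7L, 9, 11)
  expect_identical(median_filter(const, 3), const)
  expect_identical(median_filter(const, 5), const)

  spike <- matrix(0L, 7, 7); spike[4, 4] <- 255L
  out <- median_filter(spike, 3)
  expect_equal(out[4, 4], 0L)
  expect_true(all(out == 0L))

  set.seed(42)
  img <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
  for (k in c(3, 5))
    expect_equal(median_filter(img, k), oracle_median(img, k))

  expect_error(median_filter(img, 4), "odd")
  expect_error(median_filter(img, 1), "odd")
})

test_that("between-class variance follows the two-class closed form", {
  # single-valued histogram: one class is always empty or means collapse
  h <- integer(256); h[101] <- 50
  for (T in c(0, 99, 100, 200, 255))
    expect_equal(between_class_variance(h, T), 0)

  # two-point histogram at levels a < b with proportions p, 1-p
  cases <- list(c(a = 50, b = 200, na = 30, nb = 10),
                c(a = 10, b = 240, na = 5, nb = 95),
                c(a = 0, b = 255, na = 50, nb = 50))
  for (cs in cases) {
    h <- integer(256)
    h[cs["a"] + 1] <- cs["na"]; h[cs["b"] + 1] <- cs["nb"]
    p <- cs["na"] / (cs["na"] + cs["nb"])
    expected <- p * (1 - p) * (cs["a"] - cs["b"])^2
    for (T in c(cs["a"], floor((cs["a"] + cs["b"]) / 2), cs["b"] - 1))
      expect_equal(unname(between_class_variance(h, T)), unname(expected))
  }
  expect_error(between_class_variance(h, 300), "T must")
})

test_that("total variance decomposes into between- plus within-class variance at every threshold", {
  set.seed(7)
  lev <- 0:255
  for (rep in 1:20) {
    counts <- rpois(256, lambda = runif(1, 0.1, 3))
    if (sum(counts) == 0) counts[sample(256, 1)] <- 5
    n <- sum(counts)
    mu <- sum(counts * lev) / n
    sigma_tot <- sum(counts * (lev - mu)^2) / n
    for (T in c(0, 17, 63, 128, 200, 255)) {
      i0 <- lev <= T
      n0 <- sum(counts[i0]); n1 <- n - n0
      within <- 0
      if (n0 > 0) {
        mu0 <- sum(counts[i0] * lev[i0]) / n0
        within <- within + n0 / n * sum(counts[i0] * (lev[i0] - mu0)^2) / n0
      }
      if (n1 > 0) {
        mu1 <- sum(counts[!i0] * lev[!i0]) / n1
        within <- within + n1 / n * sum(counts[!i0] * (lev[!i0] - mu1)^2) / n1
      }
      sb <- between_class_variance(counts, T)
      expect_equal(sb + within, sigma_tot, tolerance = 1e-9)
    }
  }
})

test_that("otsu_threshold maximizes between-class variance with the documented tie-break and offset", {
  # clean bimodal image: half at 50, half at 200
  img <- matrix(c(rep(50L, 32), rep(200L, 32)), 8, 8)
  th <- otsu_threshold(img, offset = 0)
  expect_equal(th$sigma_b2, 0.25 * 150^2) # = 5625
  expect_gte(th$T_otsu, 50)
  expect_lt(th$T_otsu, 200)
  orc <- oracle_otsu(img)
  expect_equal(th$T_otsu, orc$T)

  th100 <- otsu_threshold(img, offset = 100)
  expect_equal(th100$T_effective, min(th100$T_otsu + 100L, 255L))
  # offset is capped at the gray-scale ceiling
  expect_equal(otsu_threshold(img, offset = 250)$T_effective, 255L)

  expect_error(otsu_threshold(matrix(9L, 4, 4)), "degenerate")

  set.seed(11)
  for (rep in 1:20) {
    img <- matrix(sample(0:255, 12 * 12, replace = TRUE), 12, 12)
    th <- otsu_threshold(img, offset = 100)
    orc <- oracle_otsu(img)
    expect_equal(th$T_otsu, orc$T)
    expect_equal(th$sigma_b2, orc$sigma, tolerance = 1e-12)
  }
})

test_that("largest foreground component selection is 8-connected and oracle-exact", {
  m <- matrix(FALSE, 10, 12)
  m[2:4, 2:5] <- TRUE # 12 pixels
  r <- largest_foreground_region(m)
  expect_equal(r$n_components, 1)
  expect_equal(unclass(r$box)[c("x", "y", "w", "h")],
               list(x = 1, y = 1, w = 4, h = 3))

  m[6:10, 7:12] <- TRUE # 30 pixels, larger blob wins
  r <- largest_foreground_region(m)
  expect_equal(r$n_components, 2)
  expect_equal(unclass(r$box)[c("x", "y", "w", "h")],
               list(x = 6, y = 5, w = 6, h = 5))
  expect_equal(sum(r$mask), 30)

  # a purely diagonal chain is one component under 8-connectivity
  d <- matrix(FALSE, 6, 6); for (i in 1:6) d[i, i] <- TRUE
  r <- largest_foreground_region(d)
  expect_equal(r$n_components, 1)
  expect_equal(sum(r$mask), 6)

  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(runif(15 * 15) < 0.35, 15, 15)
    if (!any(m)) next
    lab_o <- oracle_components8(m)
    r <- largest_foreground_region(m)
    sizes <- tabulate(lab_o[lab_o > 0])
    expect_equal(r$n_components, length(sizes))
    expect_equal(sum(r$mask), max(sizes))
    comp_o <- lab_o == which.max(sizes)
    expect_equal(r$mask, comp_o)
  }

  expect_error(largest_foreground_region(matrix(FALSE, 3, 3)), "foreground")
})

test_that("bounding boxes scale about their centre and clamp to the image", {
  b <- region_box(100, 100, 200, 100)
  expect_equal(unclass(scale_and_clamp_bbox(b, 1.0, 1000, 1000)),
               unclass(b))
  s <- scale_and_clamp_bbox(b, 1.1, 1000, 1000)
  expect_equal(unclass(s)[c("x", "y", "w", "h")],
               list(x = 90, y = 95, w = 220, h = 110))
  # near the border the box is clamped, never out of range
  nb <- scale_and_clamp_bbox(region_box(0, 0, 50, 40), 1.5, 60, 45)
  expect_gte(nb$x, 0); expect_gte(nb$y, 0)
  expect_lte(nb$x + nb$w, 60); expect_lte(nb$y + nb$h, 45)
  expect_error(scale_and_clamp_bbox(b, 0.5, 100, 100), ">= 1")
})

test_that("the full localisation chain crops a region containing the true egg box", {
  p <- small_gen_params()
  cfg <- preprocess_config(input_size = 32)
  for (cl in egg_classes()) {
    s <- render_egg_image(class_label(cl), p, 77)
    out <- preprocess_egg(s$image, cfg)
    expect_equal(dim(out$image), c(32, 32, 3))
    bb <- s$egg_bbox; cb <- out$box
    expect_lte(cb$x, bb$x); expect_lte(cb$y, bb$y)
    expect_gte(cb$x + cb$w, bb$x + bb$w)
    expect_gte(cb$y + cb$h, bb$y + bb$h)
    expect_s3_class(out$threshold, "threshold_result")
  }
})

test_that("an image with only a sub-threshold reflection patch raises a no-egg error", {
  img <- array(10, c(60, 80, 3))
  img[20:35, 10:25, ] <- 190 # wall reflection gray, no egg
  expect_error(preprocess_egg(img, preprocess_config(otsu_offset = 250)),
               "no foreground")
})

test_that("prepare_dataset audits thresholds and drops failed samples", {
  p <- small_gen_params()
  ds <- generate_dataset(c(live = 2, abnormal = 1, unfertilized = 1), p, seed = 5)
  # inject an undetectable sample: uniform black image
  bad <- ds$samples[[1]]
  bad$image <- array(0L, dim(bad$image))
  ds$samples <- c(ds$samples, list(bad))
  prep <- prepare_dataset(ds$samples, preprocess_config(input_size = 32))
  expect_equal(nrow(prep$audit), 5)
  expect_equal(sum(prep$audit$ok), 4)
  expect_length(prep$x, 4)
  expect_true(all(prep$audit$otsu_offset == 100))
})
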