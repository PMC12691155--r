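#' Convert an RGB candling image to grayscale
#'
#' Uses ITU-R BT.601 luma weights (0.299, 0.587, 0.114) and rounds to
#' integer gray levels.
#'
#' @param image H x W x 3 numeric array with values 0--255.
#' @return H x W integer matrix of gray levels.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stopf("to_grayscale expects an H x W x 3 array")
  if (min(image) < 0 || max(image) > 255)
    stopf("intensities must lie in [0, 255]")
  g <- LUMA_WEIGHTS[1] * image[, , 1] + LUMA_WEIGHTS[2] * image[, , 2] +
    LUMA_WEIGHTS[3] * image[, , 3]
  g <- round(g)
  storage.mode(g) <- "integer"
  g
}

#' Median filter a grayscale image
#'
#' Each output pixel is the median of its `kernel` x `kernel`
#' neighbourhood; edges are handled by symmetric reflection (edge row
#' and column duplicated).  Median filtering removes isolated impulse
#' noise while preserving edges, which is why it precedes threshold
#' segmentation here.
#'
#' @param image H x W numeric matrix of gray levels.
#' @param kernel Odd window size >= 3 (default 5).
#' @return Filtered matrix of the same size.
#' @export
median_filter <- function(image, kernel = 5L) {
  if (!is.matrix(image)) stopf("median_filter expects a matrix")
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    stopf("kernel must be an odd integer >= 3")
  out <- cpp_median_filter(matrix(as.numeric(image), nrow(image)), kernel)
  if (is.integer(image)) storage.mode(out) <- "integer"
  out
}

#' Gray-level histogram with 256 bins
#'
#' @param image Matrix of integer gray levels in 0--255.
#' @return Object of class `"histogram256"`: list with `counts`
#'   (length 256, bin `i` holds level `i - 1`) and `total`.
#' @export
hist256 <- function(image) {
  v <- as.integer(round(image))
  if (length(v) == 0) stopf("empty image")
  if (min(v) < 0 || max(v) > 255) stopf("gray levels must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)), class = "histogram256")
}

#' Between-class variance of a threshold
#'
#' For threshold `T`, pixels with level `<= T` form class 0 and the rest
#' class 1; the criterion is `w0 * w1 * (mu0 - mu1)^2` with `w` the
#' class proportions and `mu` the class mean gray levels.  Returns 0
#' when either class is empty.  The Otsu threshold maximizes this
#' quantity.
#'
#' @param hist A [hist256()] object (or a length-256 count vector).
#' @param T Gray level in 0--255.
#' @return The between-class variance (numeric scalar).
#' @export
between_class_variance <- function(hist, T) {
  if (inherits(hist, "histogram256")) hist <- hist$counts
  if (length(hist) != 256L) stopf("hist must have 256 bins")
  if (T < 0 || T > 255) stopf("T must lie in [0, 255]")
  total <- sum(hist)
  if (total <= 0) stopf("histogram is empty")
  lev <- 0:255
  i0 <- lev <= T
  n0 <- sum(hist[i0]); n1 <- total - n0
  if (n0 == 0 || n1 == 0) return(0)
  mu0 <- sum(hist[i0] * lev[i0]) / n0
  mu1 <- sum(hist[!i0] * lev[!i0]) / n1
  (n0 / total) * (n1 / total) * (mu0 - mu1)^2
}

# between-class variance for all T = 0..255 at once (cumulative sums)
bcv_curve <- function(counts) {
  lev <- 0:255
  total <- sum(counts)
  n0 <- cumsum(counts)
  s0 <- cumsum(counts * lev)
  n1 <- total - n0
  s1 <- s0[256] - s0
  w0 <- n0 / total
  w1 <- n1 / total
  mu0 <- ifelse(n0 > 0, s0 / n0, 0)
  mu1 <- ifelse(n1 > 0, s1 / n1, 0)
  out <- w0 * w1 * (mu0 - mu1)^2
  out[n0 == 0 | n1 == 0] <- 0
  out
}

#' Otsu threshold with a manual offset
#'
#' Finds the gray level maximizing the between-class variance (smallest
#' maximizer on ties), then raises it by `offset` (capped at 255) to
#' obtain the effective segmentation threshold.  The offset compensates
#' for near-saturated shell light leakage dragging the adaptive
#' threshold toward mid-range values while wall reflections (gray
#' 180--200) must stay out of the foreground association with the egg;
#' the operating default is +100.  Foreground is defined as pixels
#' strictly greater than the effective threshold.
#'
#' @param image Matrix of gray levels 0--255 (typically median
#'   filtered).
#' @param offset Integer added to the Otsu optimum (default 100).
#' @return Object of class `"threshold_result"`: list with `T_otsu`,
#'   `sigma_b2` (the maximized between-class variance), `offset` and
#'   `T_effective = min(T_otsu + offset, 255)`.
#' @export
otsu_threshold <- function(image, offset = 100L) {
  h <- hist256(image)
  if (sum(h$counts > 0) < 2L)
    stopf("degenerate image: a single gray level has no contrast to threshold")
  curve <- bcv_curve(h$counts)
  T_otsu <- which.max(curve) - 1L # first maximum = smallest maximizing T
  structure(list(T_otsu = T_otsu,
                 sigma_b2 = curve[T_otsu + 1L],
                 offset = as.integer(offset),
                 T_effective = min(T_otsu + as.integer(offset), 255L)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> T_otsu=%d sigma_b2=%.3f offset=%+d T_effective=%d\n",
              x$T_otsu, x$sigma_b2, x$offset, x$T_effective))
  invisible(x)
}

#' Largest foreground connected component
#'
#' Labels the foreground with 8-connectivity and returns the component
#' with the largest pixel count (smallest label on ties) together with
#' its tight bounding box.
#'
#' @param mask Logical H x W matrix.
#' @return List with `box` (a [region_box()]), `mask` (logical matrix of
#'   the selected component) and `n_components`.
#' @export
largest_foreground_region <- function(mask) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  mask <- mask > 0
  if (!any(mask)) stopf("no foreground: egg not detected")
  lab <- cpp_label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  comp <- lab == best
  rows <- range(which(rowSums(comp) > 0))
  cols <- range(which(colSums(comp) > 0))
  list(box = region_box(x = cols[1] - 1, y = rows[1] - 1,
                        w = cols[2] - cols[1] + 1, h = rows[2] - rows[1] + 1),
       mask = comp,
       n_components = length(sizes))
}

#' Scale a bounding box about its centre and clamp to the image
#'
#' @param box A [region_box()].
#' @param factor Scale factor >= 1 (the cropping default is 1.1, which
#'   guards against truncating the egg).
#' @param image_w,image_h Image extent used for clamping.
#' @return The scaled, clamped [region_box()].
#' @export
scale_and_clamp_bbox <- function(box, factor, image_w, image_h) {
  if (factor < 1) stopf("factor must be >= 1")
  cx <- box$x + box$w / 2
  cy <- box$y + box$h / 2
  w2 <- round(box$w * factor)
  h2 <- round(box$h * factor)
  x2 <- round(cx - w2 / 2)
  y2 <- round(cy - h2 / 2)
  x2 <- max(0, x2); y2 <- max(0, y2)
  w2 <- min(w2, image_w - x2)
  h2 <- min(h2, image_h - y2)
  region_box(x2, y2, w2, h2)
}

#' Preprocessing configuration
#'
#' @param median_kernel Median filter window (odd, default 5).
#' @param otsu_offset Manual threshold offset (default +100).
#' @param bbox_scale Crop box scale factor (default 1.1).
#' @param input_size Model input side length (default 224; the capture
#'   pipeline downstream model expects square inputs).
#' @return A validated list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(median_kernel = 5L, otsu_offset = 100L,
                              bbox_scale = 1.1, input_size = 224L) {
  p <- structure(list(median_kernel = as.integer(median_kernel),
                      otsu_offset = as.integer(otsu_offset),
                      bbox_scale = bbox_scale,
                      input_size = as.integer(input_size)),
                 class = "preprocess_config")
  if (p$median_kernel < 3L || p$median_kernel %% 2L == 0L)
    stopf("median_kernel must be odd and >= 3")
  if (p$bbox_scale < 1) stopf("bbox_scale must be >= 1")
  if (p$input_size < 16L) stopf("input_size too small")
  p
}

# bilinear resize of an H x W x 3 array to size x size, via EBImage
resize_rgb <- function(image, size) {
  img <- EBImage::Image(aperm(image / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = size, h = size)
  aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
}

#' Locate and crop the egg in a candling image
#'
#' Runs the full localisation chain: grayscale conversion, median
#' filtering, Otsu thresholding with the manual offset, largest
#' 8-connected foreground component, bounding box scaled by
#' `bbox_scale` and clamped, crop of the original colour image, and
#' bilinear resize to the model input size.  The intermediate threshold
#' and crop box are returned for auditing.
#'
#' @param image H x W x 3 array, values 0--255.
#' @param config A [preprocess_config()].
#' @return Object of class `"preprocessed_egg"`: list with `image`
#'   (input_size x input_size x 3 numeric array, 0--255), `threshold`
#'   (a `"threshold_result"`) and `box` (the crop [region_box()]).
#' @export
preprocess_egg <- function(image, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  g <- to_grayscale(image)
  f <- median_filter(g, config$median_kernel)
  th <- otsu_threshold(f, config$otsu_offset)
  mask <- f > th$T_effective
  if (!any(mask))
    stopf("no foreground: egg not detected (all pixels below threshold %d)",
          th$T_effective)
  region <- largest_foreground_region(mask)
  H <- nrow(g); W <- ncol(g)
  box <- scale_and_clamp_bbox(region$box, config$bbox_scale, W, H)
  crop <- image[(box$y + 1):(box$y + box$h), (box$x + 1):(box$x + box$w), ,
                drop = FALSE]
  out <- resize_rgb(crop, config$input_size)
  structure(list(image = out, threshold = th, box = box), class = "preprocessed_egg")
}

#' Preprocess a whole dataset for training
#'
#' Applies [preprocess_egg()] to every sample and collects model inputs,
#' labels and an audit table.  Failures (e.g. no egg found) are recorded
#' in the audit table and the sample is dropped.
#'
#' @param dataset An `"egg_dataset"` (or list of `"egg_sample"`).
#' @param config A [preprocess_config()].
#' @return Object of class `"prepared_dataset"`: list with `x` (list of
#'   input arrays), `y` (factor of classes), `audit` (data frame with
#'   `T_otsu`, `otsu_offset`, `T_effective` and crop box per sample).
#' @export
prepare_dataset <- function(dataset, config = preprocess_config()) {
  samples <- if (inherits(dataset, "egg_dataset")) dataset$samples else dataset
  xs <- list(); ys <- character(); rows <- list(); kept <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    res <- tryCatch(preprocess_egg(s$image, config), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(index = i, class = s$label$value, ok = FALSE,
                              T_otsu = NA, otsu_offset = config$otsu_offset,
                              T_effective = NA, x = NA, y = NA, w = NA, h = NA)
      next
    }
    kept <- kept + 1L
    xs[[kept]] <- res$image
    ys[kept] <- s$label$value
    rows[[i]] <- data.frame(index = i, class = s$label$value, ok = TRUE,
                            T_otsu = res$threshold$T_otsu,
                            otsu_offset = config$otsu_offset,
                            T_effective = res$threshold$T_effective,
                            x = res$box$x, y = res$box$y,
                            w = res$box$w, h = res$box$h)
  }
  structure(list(x = xs, y = factor(ys, levels = egg_classes()),
                 audit = do.call(rbind, rows), config = config),
            class = "prepared_dataset")
}
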