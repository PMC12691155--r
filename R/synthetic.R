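#' Class labels for candling images
#'
#' A candling image belongs to one of three hatching-status classes:
#' `"unfertilized"` (pale amber-yellow interior, light leakage through
#' the shell), `"live"` (dark red interior with black blood vessels at
#' 12-day embryo age) and `"abnormal"` (non-viable).  Abnormal eggs come
#' in three subtypes: `"dead_early"` (small deep red/black foci within
#' the yolk), `"dead_late"` (a large blackened region) and
#' `"yolk_dispersed"` (uniform yellow, no embryo).  Subtypes are only
#' valid for the abnormal class.
#'
#' @param value One of `"unfertilized"`, `"live"`, `"abnormal"`.
#' @param subtype One of `"none"`, `"dead_early"`, `"dead_late"`,
#'   `"yolk_dispersed"`; must be `"none"` unless `value = "abnormal"`.
#' @return An object of class `"class_label"`.
#' @examples
#' class_label("abnormal", "dead_early")
#' @export
class_label <- function(value, subtype = "none") {
  value <- match.arg(value, egg_classes())
  subtype <- match.arg(subtype, c("none", abnormal_subtypes()))
  if (subtype != "none" && value != "abnormal")
    stopf("subtype '%s' is only valid for the abnormal class", subtype)
  structure(list(value = value, subtype = subtype), class = "class_label")
}

#' @export
print.class_label <- function(x, ...) {
  cat("<class_label> ", x$value,
      if (x$subtype != "none") paste0(" (", x$subtype, ")"), "\n", sep = "")
  invisible(x)
}

#' @rdname class_label
#' @export
egg_classes <- function() c("unfertilized", "live", "abnormal")

#' @rdname class_label
#' @export
abnormal_subtypes <- function() c("dead_early", "dead_late", "yolk_dispersed")

#' Parameters of the synthetic candling-image generator
#'
#' Controls the rendered scene: a dark-box background, one elliptical
#' transilluminated egg with a class-specific interior palette, a wall
#' reflection patch on the opposite side of the frame, shell light
#' leakage for unfertilized eggs, class-specific overlays (vessels,
#' foci, blackened region) and pixel noise.  Defaults emulate the
#' capture conditions described for the real rig: reflections at gray
#' 180--200, light leakage at gray 254--255, and a 16:9 canvas at 1/8 of
#' the 3840 x 2160 capture resolution.
#'
#' All interior palettes are kept bright (transillumination) but with
#' disjoint per-class mean-luminance intervals ordered
#' live < abnormal < unfertilized; overlay features (vessels, embryo,
#' foci, blackened areas) are near-background dark so that the
#' threshold-plus-offset segmentation treats them like background
#' rather than shifting the Otsu optimum into mid-gray.
#'
#' @param image_width,image_height Canvas size in pixels (each >= 64).
#' @param egg_axes_range List with `major` and `minor` ranges (pixels)
#'   for the egg semi-axes.
#' @param class_palettes Per-class interior color ranges: a named list
#'   of 2 x 3 matrices (rows lo/hi, columns R,G,B, values 0--255).  The
#'   `yolk_dispersed` entry is the abnormal subtype palette.
#' @param background_gray_range Dark-box gray interval.
#' @param falloff Radial brightness falloff coefficient (interior is
#'   scaled by `1 - falloff * r^2` with `r` the normalised ellipse
#'   radius), mimicking transillumination.
#' @param reflection_gray_range Wall-reflection gray interval, default
#'   `c(180, 200)`.
#' @param leakage_gray_range Shell light-leakage gray interval, default
#'   `c(254, 255)`.
#' @param leakage_fraction Fraction of rim-band pixels receiving
#'   leakage (unfertilized eggs only).
#' @param vessel_count,vessel_step,vessel_width Vasculature controls
#'   for live embryos (number of seeded branching random walks, steps
#'   per walk, stroke radius in pixels).
#' @param spot_count,spot_radius Dead-embryo foci controls (count, and
#'   radius range in pixels).
#' @param noise_sigma Gaussian intensity noise (gray levels).
#' @param salt_pepper_fraction Fraction of impulse-noise pixels, in
#'   `[0, 0.05]`.
#' @param min_contrast Required minimum luminance gap between the
#'   dimmest interior (at the rim) and the brightest background.
#' @param seed Default master seed used by [generate_dataset()].
#' @return An object of class `"generator_params"` (a validated list).
#' @export
generator_params <- function(image_width = 480L,
                             image_height = 270L,
                             egg_axes_range = list(major = c(88, 108),
                                                   minor = c(60, 76)),
                             class_palettes = default_palettes(),
                             background_gray_range = c(8, 16),
                             falloff = 0.08,
                             reflection_gray_range = c(180, 200),
                             leakage_gray_range = c(254, 255),
                             leakage_fraction = 0.35,
                             vessel_count = 6L,
                             vessel_step = 60L,
                             vessel_width = 1L,
                             spot_count = 5L,
                             spot_radius = c(2, 5),
                             noise_sigma = 4,
                             salt_pepper_fraction = 0.002,
                             min_contrast = 60,
                             seed = 1L) {
  p <- structure(as.list(environment()), class = "generator_params")
  validate_generator_params(p)
  p
}

# Interior palettes (lo/hi per channel).  Chosen so the class
# mean-luminance intervals are disjoint and ordered
# live < abnormal < unfertilized, with every interior bright enough to
# survive the +100 threshold offset (see vignette).
default_palettes <- function() {
  pal <- function(r, g, b) {
    m <- rbind(lo = c(r[1], g[1], b[1]), hi = c(r[2], g[2], b[2]))
    colnames(m) <- c("R", "G", "B")
    m
  }
  list(
    unfertilized   = pal(c(250, 255), c(225, 240), c(160, 185)),
    live           = pal(c(250, 255), c(135, 150), c(60, 80)),
    abnormal       = pal(c(235, 255), c(165, 185), c(85, 110)),
    yolk_dispersed = pal(c(245, 255), c(200, 220), c(50, 75))
  )
}

validate_generator_params <- function(p) {
  if (!is_count(p$image_width) || !is_count(p$image_height) ||
      p$image_width < 64 || p$image_height < 64)
    stopf("image dimensions must be integers >= 64")
  rng_ok <- function(r) is.numeric(r) && length(r) == 2L && r[1] <= r[2] &&
    r[1] >= 0 && r[2] <= 255
  for (nm in c("background_gray_range", "reflection_gray_range",
               "leakage_gray_range"))
    if (!rng_ok(p[[nm]])) stopf("%s must be an interval within [0, 255]", nm)
  for (nm in names(p$class_palettes)) {
    m <- p$class_palettes[[nm]]
    if (!is.matrix(m) || any(m < 0) || any(m > 255) || any(m[1, ] > m[2, ]))
      stopf("palette '%s' must be a lo/hi matrix within [0, 255]", nm)
  }
  if (!all(egg_classes() %in% names(p$class_palettes)))
    stopf("class_palettes must cover %s", paste(egg_classes(), collapse = ", "))
  if (p$salt_pepper_fraction < 0 || p$salt_pepper_fraction > 0.05)
    stopf("salt_pepper_fraction must lie in [0, 0.05]")
  if (p$falloff < 0 || p$falloff >= 0.5) stopf("falloff must lie in [0, 0.5)")
  if (2 * max(p$egg_axes_range$major) > 0.6 * p$image_width ||
      2 * max(p$egg_axes_range$minor) > 0.85 * p$image_height)
    stopf("egg axes too large for the canvas")
  # contrast guarantee: dimmest rim interior vs brightest background
  lum <- class_luminance_intervals(p)
  rim_min <- min(lum[, "lo"]) * (1 - p$falloff)
  if (rim_min - p$background_gray_range[2] < p$min_contrast)
    stopf("palettes violate the minimum interior/background contrast (%g < %g)",
          rim_min - p$background_gray_range[2], p$min_contrast)
  invisible(p)
}

#' Mean-luminance intervals implied by the generator palettes
#'
#' Returns, for each top-level class, the interval of possible interior
#' base luminances (BT.601 weights applied to the palette lo/hi
#' corners).  With `noise_sigma = 0` these intervals are the separability
#' knob: the defaults are pairwise disjoint.
#'
#' @param params A [generator_params()] object.
#' @return Matrix with rows per class and columns `lo`, `hi`.
#' @export
class_luminance_intervals <- function(params) {
  cls <- egg_classes()
  out <- t(vapply(cls, function(cl) {
    m <- params$class_palettes[[cl]]
    lo <- sum(LUMA_WEIGHTS * m["lo", ])
    hi <- sum(LUMA_WEIGHTS * m["hi", ])
    if (cl == "abnormal") { # class interval covers the subtype palette too
      y <- params$class_palettes[["yolk_dispersed"]]
      lo <- min(lo, sum(LUMA_WEIGHTS * y["lo", ]))
      hi <- max(hi, sum(LUMA_WEIGHTS * y["hi", ]))
    }
    c(lo = lo, hi = hi)
  }, numeric(2)))
  out
}

#' Rectangular image region
#'
#' Regions use 0-based, half-open pixel coordinates: a box covers
#' columns `[x, x + w)` and rows `[y, y + h)`.
#'
#' @param x,y Top-left corner (0-based).
#' @param w,h Extent in pixels (> 0).
#' @return An object of class `"region_box"`.
#' @export
region_box <- function(x, y, w, h) {
  x <- as.numeric(x); y <- as.numeric(y)
  w <- as.numeric(w); h <- as.numeric(h)
  if (w <= 0 || h <= 0) stopf("region_box extents must be positive")
  structure(list(x = x, y = y, w = w, h = h), class = "region_box")
}

#' @export
print.region_box <- function(x, ...) {
  cat(sprintf("<region_box> x=%g y=%g w=%g h=%g\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

# ---- rendering ------------------------------------------------------------

# linear (column-major) pixel indices of a disk, optionally restricted
# to an inclusion mask; painting is deferred so rendering loops never
# copy the full image
disk_indices <- function(cx, cy, rad, H, W, inside = NULL) {
  h0 <- max(1L, floor(cy - rad)); h1 <- min(H, ceiling(cy + rad))
  w0 <- max(1L, floor(cx - rad)); w1 <- min(W, ceiling(cx + rad))
  if (h0 > h1 || w0 > w1) return(integer())
  hh <- h0:h1; ww <- w0:w1
  m <- outer((hh - cy)^2, (ww - cx)^2, "+") <= rad^2
  if (!is.null(inside)) m <- m & inside[hh, ww]
  idx <- which(m)
  (rep.int(ww, rep.int(length(hh), length(ww)))[idx] - 1L) * H +
    rep.int(hh, length(ww))[idx]
}

# apply deferred paint operations (list of list(idx, col)) to the image
apply_paint <- function(img, ops) {
  if (!length(ops)) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    for (op in ops) if (length(op$idx)) plane[op$idx] <- op$col[ch]
    img[, , ch] <- plane
  }
  img
}

#' Render one synthetic candling image
#'
#' Draws a dark-box background, one elliptical egg filled from the
#' class palette with a radial transillumination falloff, class-specific
#' overlays (branching vessel walks and an embryo focus for live eggs;
#' dark foci or a blackened region for dead embryos; nothing for
#' yolk-dispersed), shell light leakage along the rim for unfertilized
#' eggs, a wall-reflection patch on the opposite side of the frame, and
#' finally Gaussian plus impulse noise.  The output is fully determined
#' by `(label, params, seed)`.
#'
#' @param label A [class_label()].
#' @param params A [generator_params()] object.
#' @param seed Integer seed.
#' @return An object of class `"egg_sample"`: a list with `image`
#'   (H x W x 3 integer array, 0--255), `label`, `egg_bbox` (ground-truth
#'   tight [region_box()] of the rendered ellipse), `seed` and
#'   `geometry` (ellipse centre and semi-axes, for testing).
#' @export
render_egg_image <- function(label, params, seed) {
  if (!inherits(label, "class_label")) label <- do.call(class_label, as.list(label))
  if (!inherits(params, "generator_params"))
    stopf("params must be a generator_params object")
  validate_generator_params(params)
  H <- as.integer(params$image_height); W <- as.integer(params$image_width)

  with_seed(seed, {
    bg <- runif(1, params$background_gray_range[1], params$background_gray_range[2])
    img <- array(bg, dim = c(H, W, 3))

    # egg geometry
    a <- runif(1, params$egg_axes_range$major[1], params$egg_axes_range$major[2])
    b <- runif(1, params$egg_axes_range$minor[1], params$egg_axes_range$minor[2])
    cx <- runif(1, 0.35 * W, 0.65 * W)
    cy <- runif(1, 0.45 * H, 0.55 * H)
    xs <- matrix(rep(seq_len(W), each = H), H)
    ys <- matrix(rep(seq_len(H), times = W), H)
    r2 <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
    egg <- r2 <= 1

    pal_name <- if (label$subtype == "yolk_dispersed") "yolk_dispersed" else label$value
    pm <- params$class_palettes[[pal_name]]
    base <- runif(3, pm["lo", ], pm["hi", ])
    shade <- 1 - params$falloff * pmin(r2, 1)
    sel <- which(egg)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- base[ch] * shade[sel]
      img[, , ch] <- plane
    }

    ops <- list()
    if (label$value == "live") {
      # embryo focus + branching random-walk vessels, near-background dark
      fx <- cx + runif(1, -0.3, 0.3) * a
      fy <- cy + runif(1, -0.3, 0.3) * b
      ops[[length(ops) + 1L]] <- list(
        idx = disk_indices(fx, fy, 0.15 * min(a, b), H, W, egg),
        col = c(55, 8, 8))
      vidx <- integer()
      queue <- lapply(seq_len(params$vessel_count), function(i)
        c(fx, fy, runif(1, 0, 2 * pi)))
      walks <- 0L
      while (length(queue) > 0 && walks < 3L * params$vessel_count) {
        st <- queue[[1]]; queue <- queue[-1]; walks <- walks + 1L
        px <- st[1]; py <- st[2]; ang <- st[3]
        for (s in seq_len(params$vessel_step)) {
          ang <- ang + rnorm(1, 0, 0.35)
          px <- px + 2 * cos(ang); py <- py + 2 * sin(ang)
          if (((px - cx) / a)^2 + ((py - cy) / b)^2 > 0.85) break
          vidx <- c(vidx, disk_indices(px, py, params$vessel_width, H, W, egg))
          if (runif(1) < 0.12 && length(queue) < 2L * params$vessel_count)
            queue <- c(queue, list(c(px, py, ang + runif(1, -1.2, 1.2))))
        }
      }
      ops[[length(ops) + 1L]] <- list(idx = unique(vidx), col = c(52, 10, 10))
    } else if (label$value == "abnormal") {
      if (label$subtype %in% c("none", "dead_early", "dead_late")) {
        # prominent brown regions on the tan-brown base
        bidx <- integer()
        for (i in 1:2) {
          bx <- cx + runif(1, -0.35, 0.35) * a
          by <- cy + runif(1, -0.35, 0.35) * b
          bidx <- c(bidx, disk_indices(bx, by, runif(1, 0.15, 0.25) * min(a, b),
                                       H, W, egg))
        }
        ops[[length(ops) + 1L]] <- list(idx = unique(bidx), col = base * 0.88)
      }
      if (label$subtype == "dead_early") {
        sidx <- integer()
        for (i in seq_len(params$spot_count)) {
          sx <- cx + runif(1, -0.5, 0.5) * a
          sy <- cy + runif(1, -0.5, 0.5) * b
          sidx <- c(sidx, disk_indices(
            sx, sy, runif(1, params$spot_radius[1], params$spot_radius[2]),
            H, W, egg))
        }
        ops[[length(ops) + 1L]] <- list(idx = unique(sidx), col = c(45, 10, 10))
      } else if (label$subtype == "dead_late") {
        dx <- cx + runif(1, -0.25, 0.25) * a
        dy <- cy + runif(1, -0.25, 0.25) * b
        dr2 <- ((xs - dx) / (0.35 * a))^2 + ((ys - dy) / (0.35 * b))^2
        ops[[length(ops) + 1L]] <- list(idx = which(dr2 <= 1 & egg),
                                        col = c(45, 25, 18))
      }
    } else if (label$value == "unfertilized") {
      # shell light leakage: near-saturated pixels along the rim band
      band <- which(r2 >= 0.82 & r2 <= 1)
      keep <- band[runif(length(band)) < params$leakage_fraction]
      if (length(keep) == 0) keep <- band[1]
      v <- sample(seq(params$leakage_gray_range[1], params$leakage_gray_range[2]),
                  length(keep), replace = TRUE)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[keep] <- v
        img[, , ch] <- plane
      }
    }

    img <- apply_paint(img, ops)

    # wall-reflection patch, opposite side of the frame from the egg
    rcx <- if (cx <= W / 2) 0.85 * W else 0.15 * W
    rcx <- rcx + runif(1, -0.02, 0.02) * W
    rcy <- cy + runif(1, -0.08, 0.08) * H
    ra <- 0.40 * a; rb <- 0.40 * b # area <= 16% of the egg's
    rr2 <- ((xs - rcx) / ra)^2 + ((ys - rcy) / rb)^2
    rsel <- which(rr2 <= 1 & r2 > 1.3)
    g <- sample(seq(params$reflection_gray_range[1], params$reflection_gray_range[2]),
                length(rsel), replace = TRUE)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[rsel] <- g
      img[, , ch] <- plane
    }

    if (params$noise_sigma > 0)
      img <- img + array(rnorm(length(img), 0, params$noise_sigma), dim(img))
    if (params$salt_pepper_fraction > 0) {
      nsp <- round(params$salt_pepper_fraction * H * W)
      if (nsp > 0) {
        pix <- sample.int(H * W, nsp)
        val <- sample(c(0, 255), nsp, replace = TRUE)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[pix] <- val
          img[, , ch] <- plane
        }
      }
    }
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"

    rows <- range(which(rowSums(egg) > 0))
    cols <- range(which(colSums(egg) > 0))
    bbox <- region_box(x = cols[1] - 1, y = rows[1] - 1,
                       w = cols[2] - cols[1] + 1, h = rows[2] - rows[1] + 1)
    structure(list(image = img, label = label, egg_bbox = bbox,
                   seed = as.integer(seed),
                   geometry = list(cx = cx, cy = cy, a = a, b = b,
                                   refl = c(cx = rcx, cy = rcy,
                                            a = ra, b = rb))),
              class = "egg_sample")
  })
}

#' @export
print.egg_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<egg_sample> %s%s, %dx%d, seed %d\n", x$label$value,
              if (x$label$subtype != "none") paste0("/", x$label$subtype) else "",
              d[2], d[1], x$seed))
  invisible(x)
}

#' Generate a labelled synthetic candling dataset
#'
#' Renders `n_per_class` images per class with per-sample seeds derived
#' deterministically from the master seed.  Abnormal samples cycle
#' through the three subtypes (dead_early, dead_late, yolk_dispersed).
#'
#' @param n_per_class Named counts, e.g.
#'   `c(unfertilized = 10, live = 10, abnormal = 10)`.
#' @param params A [generator_params()] object.
#' @param seed Master seed; defaults to `params$seed`.
#' @return An object of class `"egg_dataset"`: list with `samples` (list
#'   of [render_egg_image()] outputs) and `manifest` (data frame with
#'   columns `path, class, subtype, seed, x, y, w, h`).
#' @export
generate_dataset <- function(n_per_class, params = generator_params(),
                             seed = params$seed) {
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% egg_classes()))
    stopf("n_per_class must be named with classes %s",
          paste(egg_classes(), collapse = ", "))
  if (!all(vapply(n_per_class, is_count, logical(1))))
    stopf("counts must be nonnegative integers")
  counts <- vapply(egg_classes(), function(cl)
    as.integer(n_per_class[cl] %||% 0L), integer(1))
  counts[is.na(counts)] <- 0L

  subs <- abnormal_subtypes()
  rows <- list(); samples <- list(); i <- 0L
  for (cl in egg_classes()) {
    for (j in seq_len(counts[[cl]])) {
      i <- i + 1L
      subtype <- if (cl == "abnormal") subs[(j - 1L) %% 3L + 1L] else "none"
      s_i <- derive_seed(seed, i)
      smp <- render_egg_image(class_label(cl, subtype), params, s_i)
      samples[[i]] <- smp
      bb <- smp$egg_bbox
      rows[[i]] <- data.frame(
        path = sprintf("%s/%s_%04d.png", cl, cl, j),
        class = cl, subtype = subtype, seed = s_i,
        x = bb$x, y = bb$y, w = bb$w, h = bb$h,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), class = character(), subtype = character(),
               seed = integer(), x = numeric(), y = numeric(),
               w = numeric(), h = numeric())
  structure(list(samples = samples, manifest = manifest,
                 params = params, seed = as.integer(seed)),
            class = "egg_dataset")
}

#' @export
print.egg_dataset <- function(x, ...) {
  cat(sprintf("<egg_dataset> %d samples (%s)\n", length(x$samples),
              paste(sprintf("%s=%d", egg_classes(),
                            table(factor(x$manifest$class, egg_classes()))),
                    collapse = ", ")))
  invisible(x)
}

#' Write a dataset to disk as PNG files plus a CSV manifest
#'
#' @param dataset An [generate_dataset()] result.
#' @param dir Output directory; class subdirectories are created.
#' @return Invisibly, the manifest with paths resolved against `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "egg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in unique(dataset$manifest$class))
    dir.create(file.path(dir, cl), showWarnings = FALSE)
  for (i in seq_along(dataset$samples)) {
    img <- dataset$samples[[i]]$image
    png::writePNG(aperm(array(img / 255, dim(img)), c(1, 2, 3)),
                  file.path(dir, dataset$manifest$path[i]))
  }
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dataset$manifest)
}

#' Read a candling image written by [write_dataset()]
#'
#' @param path PNG file path.
#' @return H x W x 3 integer array with values 0--255.
#' @export
read_candling_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  img <- round(a[, , 1:3] * 255)
  storage.mode(img) <- "integer"
  img
}
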