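# Synthetic four-class wound-image generator, right-angle augmentation
# operators, and the split + minority-class augmentation bookkeeping of the
# study's data regime.
#
# The generator emulates the coarse visual structure of close-up wound
# photographs: a skin-toned textured background with class-specific lesions.
# Classes are separable by construction (distinct hue/structure parameters);
# the generator makes no attempt at photorealism.

#' Published class-wise dataset statistics (before augmentation)
#'
#' The per-class train/validation/test image counts of the labelled DFUC-2021
#' data, used as input to the augmentation bookkeeping.  These printed totals
#' (3672 + 1190 + 1193 = 6055) slightly exceed the stated 5,955 labelled
#' images; the per-class column is taken as ground truth for the arithmetic.
#'
#' @return data.frame with columns `class`, `train`, `val`, `test`.
#' @export
dfuc2021_class_counts <- function() {
  data.frame(class = dfu_classes,
             train = c(1631L, 1533L, 136L, 372L),
             val = c(510L, 511L, 45L, 124L),
             test = c(511L, 511L, 46L, 125L))
}

# Deterministic per-class appearance parameters: base skin tone plus lesion
# structure. Hue/texture ranges are disjoint enough that a small classifier
# separates the classes.
synthetic_class_specs <- function() {
  list(
    none = list(blobs = 0L, rim = FALSE,
                base = c(0.80, 0.62, 0.52), lesion = NULL, tex_freq = 2),
    infection = list(blobs = 3L, rim = FALSE,
                     base = c(0.78, 0.58, 0.48), lesion = c(0.75, 0.12, 0.10),
                     tex_freq = 5),
    ischemia = list(blobs = 2L, rim = TRUE,
                    base = c(0.75, 0.60, 0.52), lesion = c(0.55, 0.55, 0.60),
                    tex_freq = 3),
    both = list(blobs = 4L, rim = TRUE,
                base = c(0.76, 0.56, 0.47), lesion = c(0.65, 0.20, 0.25),
                tex_freq = 7))
}

synth_one <- function(class, size) {
  spec <- synthetic_class_specs()[[class]]
  H <- size; W <- size
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- array(0, dim = c(H, W, 3))
  # low-frequency skin texture
  ph <- stats::runif(4, 0, 2 * pi)
  fr <- spec$tex_freq
  tex <- 0.05 * (sin(2 * pi * fr * yy / H + ph[1]) * cos(2 * pi * fr * xx / W + ph[2]) +
                 0.5 * sin(2 * pi * (fr + 1) * (yy + xx) / (H + W) + ph[3]))
  noise <- array(stats::rnorm(H * W, 0, 0.02), dim = c(H, W))
  for (c in 1:3) img[, , c] <- spec$base[c] + tex + noise
  # lesion blobs
  if (spec$blobs > 0) {
    for (b in seq_len(spec$blobs)) {
      cy <- stats::runif(1, 0.25 * H, 0.75 * H)
      cx <- stats::runif(1, 0.25 * W, 0.75 * W)
      r <- stats::runif(1, 0.08, 0.18) * size
      d2 <- ((yy - cy)^2 + (xx - cx)^2) / r^2
      mask <- exp(-d2)
      for (c in 1:3)
        img[, , c] <- img[, , c] * (1 - mask) + spec$lesion[c] * mask
      if (spec$rim) {
        rim <- exp(-(sqrt(d2) - 1.4)^2 / 0.08) * 0.8
        rim_col <- c(0.85, 0.82, 0.75)      # pale, poorly perfused margin
        for (c in 1:3)
          img[, , c] <- img[, , c] * (1 - rim) + rim_col[c] * rim
      }
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic four-class image dataset
#'
#' Seeded and fully reproducible: the same seed yields bit-identical images.
#'
#' @param class_counts named integer vector / list over [dfu_classes]
#'   (e.g. `c(none = 40, infection = 40, ischemia = 12, both = 12)`).
#' @param seed RNG seed.
#' @param size image side in pixels (default 224).
#' @return list with `images` (list of `(size, size, 3)` arrays in `[0,1]`),
#'   `labels` (integer class indices), `classes` (label names), `ids`.
#' @export
generate_synthetic_dataset <- function(class_counts, seed = 1L, size = 224L) {
  cls <- dfu_classes
  if (is.null(names(class_counts)) || !all(cls %in% names(class_counts)))
    stop("class_counts must be named with all of: ", paste(cls, collapse = ", "))
  if (any(unlist(class_counts) < 1)) stop("class_counts must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  images <- list(); labels <- integer(0); ids <- character(0)
  for (k in seq_along(cls)) {
    n <- as.integer(class_counts[[cls[k]]])
    for (i in seq_len(n)) {
      images[[length(images) + 1L]] <- synth_one(cls[k], size)
      labels <- c(labels, k)
      ids <- c(ids, sprintf("%s_%04d", cls[k], i))
    }
  }
  list(images = images, labels = labels, classes = cls[labels], ids = ids)
}

#' Write a dataset to class-named PNG folders
#' @param ds a dataset from [generate_synthetic_dataset()].
#' @param dir output directory (one sub-directory per class).
#' @return invisibly, the written file paths.
#' @export
save_dataset_png <- function(ds, dir) {
  paths <- character(length(ds$images))
  for (i in seq_along(ds$images)) {
    d <- file.path(dir, ds$classes[i])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(d, paste0(ds$ids[i], ".png"))
    png::writePNG(ds$images[[i]], paths[i])
  }
  invisible(paths)
}

# ----------------------------------------------------------- augmentation --

#' Apply a deterministic right-angle augmentation
#'
#' @param img `(H, W, 3)` array (square for rotations).
#' @param vflip,hflip logical flips.
#' @param rot rotation angle, one of 0, 90, 270 (counter-clockwise).
#' @return augmented array of identical size; all operations are lossless.
#' @export
apply_augment <- function(img, vflip = FALSE, hflip = FALSE, rot = 0L) {
  if (!rot %in% c(0L, 90L, 270L))
    stop("apply_augment: rotation must be one of 0, 90, 270")
  d <- dim(img)
  if (rot != 0L && d[1] != d[2])
    stop("apply_augment: 90/270 degree rotation of a non-square image would change its shape")
  if (vflip) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  if (hflip) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (rot == 90L) img <- aperm(img, c(2, 1, 3))[rev(seq_len(d[2])), , , drop = FALSE]
  if (rot == 270L) img <- aperm(img, c(2, 1, 3))[, rev(seq_len(d[1])), , drop = FALSE]
  img
}

#' Randomly augment an image
#'
#' Samples an independent vertical flip, horizontal flip, and a rotation from
#' {0, 90, 270} degrees using R's RNG (seed for reproducibility).
#'
#' @param img square `(H, H, 3)` array.
#' @return list with `image` and the sampled `ops`.
#' @export
augment_image <- function(img) {
  ops <- list(vflip = stats::runif(1) < 0.5,
              hflip = stats::runif(1) < 0.5,
              rot = sample(c(0L, 90L, 270L), 1L))
  list(image = apply_augment(img, ops$vflip, ops$hflip, ops$rot), ops = ops)
}

# ----------------------------------------------------- splits + balancing --

#' Stratified split with minority-class augmentation bookkeeping
#'
#' Splits labelled images 60/20/20 (stratified, seeded shuffle per class),
#' then adds `aug_copies` augmented entries for every *train and validation*
#' original of the minority classes (ischemia and both); the test set is never
#' augmented.  Augmentation operations are sampled per copy; duplicates among
#' copies are allowed.
#'
#' @param labels integer class indices (1-based into [dfu_classes]) or class
#'   name vector.
#' @param seed RNG seed for the shuffle and the sampled operations.
#' @param train_frac,val_frac split fractions (test takes the remainder).
#' @param aug_copies augmented copies per minority original (default 4, the
#'   x5 expansion).
#' @param minority classes receiving augmentation.
#' @return data.frame manifest with columns `id` (index into the input),
#'   `class`, `split`, `provenance` (`"original"` or
#'   `"augmented-from:<id>"`), `vflip`, `hflip`, `rot`.
#' @export
make_splits_and_balance <- function(labels, seed = 1L, train_frac = 0.6,
                                    val_frac = 0.2, aug_copies = 4L,
                                    minority = c("ischemia", "both")) {
  if (is.character(labels)) labels <- match(labels, dfu_classes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- list()
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    if (length(idx) < 5)
      warning("class '", dfu_classes[k], "' has fewer than 5 images; ",
              "splits will be tiny")
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    ntr <- round(train_frac * n)
    nva <- round(val_frac * n)
    split <- c(rep("train", ntr), rep("val", nva), rep("test", n - ntr - nva))
    rows[[length(rows) + 1L]] <-
      data.frame(id = idx, class = dfu_classes[k], split = split,
                 provenance = "original", vflip = FALSE, hflip = FALSE,
                 rot = 0L, stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  if (aug_copies > 0L) {
    aug_rows <- man[man$class %in% minority & man$split %in% c("train", "val"), ]
    if (nrow(aug_rows)) {
      ex <- aug_rows[rep(seq_len(nrow(aug_rows)), each = aug_copies), ]
      ex$provenance <- paste0("augmented-from:", ex$id)
      ex$vflip <- stats::runif(nrow(ex)) < 0.5
      ex$hflip <- stats::runif(nrow(ex)) < 0.5
      ex$rot <- sample(c(0L, 90L, 270L), nrow(ex), replace = TRUE)
      man <- rbind(man, ex)
    }
  }
  rownames(man) <- NULL
  man
}

#' Minority-class augmentation arithmetic
#'
#' Applies the x(1 + copies) expansion to a before-augmentation count table:
#' train and validation cells of the minority classes are multiplied by
#' `1 + copies`; all other cells (and every test cell) are unchanged.
#'
#' @param before data.frame with columns `class`, `train`, `val`, `test`
#'   (e.g. [dfuc2021_class_counts()]).
#' @param copies augmented copies per original (default 4).
#' @param minority classes to expand.
#' @return data.frame of after-augmentation counts.
#' @export
augmentation_bookkeeping <- function(before = dfuc2021_class_counts(),
                                     copies = 4L,
                                     minority = c("ischemia", "both")) {
  after <- before
  f <- 1L + as.integer(copies)
  sel <- after$class %in% minority
  after$train[sel] <- after$train[sel] * f
  after$val[sel] <- after$val[sel] * f
  after
}

#' Materialize a split manifest into training arrays
#'
#' Resolves a manifest against a generated dataset, applying the recorded
#' augmentation operations, and stacks each split into `(H, W, 3, N)` arrays.
#'
#' @param ds dataset from [generate_synthetic_dataset()].
#' @param manifest manifest from [make_splits_and_balance()].
#' @param normalize standardize each channel using train-split statistics?
#' @return list of splits, each with `x` array, `y` integer labels, and the
#'   normalization statistics under `$norm`.
#' @export
materialize_splits <- function(ds, manifest, normalize = TRUE) {
  build <- function(rows) {
    n <- nrow(rows)
    sz <- dim(ds$images[[1]])
    x <- array(0, dim = c(sz[1], sz[2], 3, n))
    y <- integer(n)
    for (i in seq_len(n)) {
      img <- ds$images[[rows$id[i]]]
      if (rows$provenance[i] != "original")
        img <- apply_augment(img, rows$vflip[i], rows$hflip[i], rows$rot[i])
      x[, , , i] <- img
      y[i] <- ds$labels[rows$id[i]]
    }
    list(x = x, y = y)
  }
  out <- list(train = build(manifest[manifest$split == "train", ]),
              val = build(manifest[manifest$split == "val", ]),
              test = build(manifest[manifest$split == "test", ]))
  if (normalize) {
    mu <- apply(out$train$x, 3, mean)
    sdv <- apply(out$train$x, 3, stats::sd)
    sdv[sdv < 1e-8] <- 1
    for (s in names(out)) {
      for (c in 1:3)
        out[[s]]$x[, , c, ] <- (out[[s]]$x[, , c, ] - mu[c]) / sdv[c]
      out[[s]]$norm <- list(mean = mu, sd = sdv)
    }
  }
  out
}
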