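# Grad-CAM saliency over the network's final convolutional representation.

#' Bilinear resize of a matrix
#'
#' Align-corners bilinear interpolation used to upsample saliency grids to
#' the input resolution.
#'
#' @param m numeric matrix.
#' @param H,W target size.
#' @return `H x W` matrix.
#' @export
bilinear_resize <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  if (h == 1) { y0 <- rep(1, H); fy <- rep(0, H) } else {
    ry <- if (H == 1) 1 else 1 + (seq_len(H) - 1) * (h - 1) / (H - 1)
    y0 <- pmin(floor(ry), h - 1); fy <- ry - y0
  }
  if (w == 1) { x0 <- rep(1, W); fx <- rep(0, W) } else {
    rx <- if (W == 1) 1 else 1 + (seq_len(W) - 1) * (w - 1) / (W - 1)
    x0 <- pmin(floor(rx), w - 1); fx <- rx - x0
  }
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  FY <- matrix(fy, H, W); FX <- matrix(fx, H, W, byrow = TRUE)
  m00 * (1 - FY) * (1 - FX) + m01 * (1 - FY) * FX +
    m10 * FY * (1 - FX) + m11 * FY * FX
}

#' Grad-CAM saliency map
#'
#' Computes the gradient of the target class's logit with respect to the
#' activations of a named intermediate representation (default: the shuffle
#' attention output), weights each activation channel by the spatial mean of
#' its gradient, and forms `ReLU(sum_k w_k A_k)`, bilinearly upsampled to the
#' input resolution and min-max normalized to `[0, 1]`.  If every
#' pre-normalization value is non-positive the map is defined as all zeros.
#' Model weights are not modified.
#'
#' @param model a model whose forward populates `model$cache` (e.g.
#'   [dfu_model()]; cached layers: `"sa"`, `"fused"`, `"swin"`, `"emadn"`,
#'   and `"emadn_mid"`, the middle EMADN stage, which retains more spatial
#'   resolution).
#' @param img a single image `(H, W, 3)` or `(H, W, 3, 1)` array.
#' @param target_class class index (1-based) or name from [dfu_classes].
#' @param layer name of the cached representation to attribute.
#' @return an object of class `dfu_heatmap`: list with `map` (input-resolution
#'   `[0,1]` matrix), `raw` (low-resolution unnormalized map), `class`,
#'   `logits`.
#' @export
grad_cam <- function(model, img, target_class, layer = "sa") {
  if (is.character(target_class)) {
    target_class <- match(target_class, dfu_classes)
    if (is.na(target_class)) stop("grad_cam: unknown class name")
  }
  img <- dt_value(img)
  if (length(dim(img)) == 3) dim(img) <- c(dim(img), 1L)
  if (dim(img)[4] != 1) stop("grad_cam: one image at a time")
  was_training <- model$training
  set_train(model, FALSE)
  on.exit(set_train(model, was_training))
  dt_tape_reset()
  x <- dt_tensor(img, requires_grad = TRUE)   # grad flows through activations
  logits <- forward(model, x)
  K <- dim(logits$v)[1]
  if (target_class < 1 || target_class > K) stop("grad_cam: invalid class")
  act <- model$cache[[layer]]
  if (is.null(act)) stop("grad_cam: no cached layer '", layer, "'")
  score <- dt_take(dt_reshape(logits, c(K, 1L)), target_class, 1L)
  dt_backward(score)
  A <- act$v; G <- act$grad
  d <- dim(A)
  w <- apply(G, 3, mean)                      # spatial mean of d score / d A_k
  cam <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) cam <- cam + w[k] * A[, , k, 1]
  cam <- pmax(cam, 0)
  up <- bilinear_resize(cam, dim(img)[1], dim(img)[2])
  mx <- max(up); mn <- min(up)
  map <- if (mx <= 0) matrix(0, dim(img)[1], dim(img)[2])
         else if (mx - mn < .Machine$double.eps) matrix(1, dim(img)[1], dim(img)[2])
         else (up - mn) / (mx - mn)
  structure(list(map = map, raw = cam, class = target_class,
                 logits = as.numeric(logits$v)),
            class = "dfu_heatmap")
}

#' Write a heat-map overlay PNG
#'
#' Renders the saliency map with a blue-to-red colormap (blue = low, red =
#' high activation), optionally blended over the source image, with a color
#' bar strip on the right edge.
#'
#' @param hm a `dfu_heatmap` (or plain `[0,1]` matrix).
#' @param file output PNG path.
#' @param img optional source image `(H, W, 3)` in `[0,1]` to blend under the
#'   map.
#' @param alpha blend weight of the heat map.
#' @export
save_heatmap_png <- function(hm, file, img = NULL, alpha = 0.5) {
  map <- if (inherits(hm, "dfu_heatmap")) hm$map else hm
  H <- nrow(map); W <- ncol(map)
  colmap <- function(v) {
    # blue (0) -> cyan -> yellow -> red (1)
    r <- pmin(pmax(2 * v - 0.5, 0), 1)
    g <- pmin(pmax(1.5 - abs(2 * v - 1) * 2, 0), 1)
    b <- pmin(pmax(1.5 - 2 * v, 0), 1)
    array(c(r, g, b), dim = c(length(v), 3))
  }
  rgbm <- colmap(as.vector(map))
  out <- array(rgbm, dim = c(H, W, 3))
  if (!is.null(img)) out <- (1 - alpha) * img[, , 1:3, drop = FALSE] + alpha * out
  bar_w <- max(4L, W %/% 24L)
  bar <- colmap(rev(seq(0, 1, length.out = H)))
  bar <- aperm(array(bar, dim = c(H, 3, bar_w)), c(1, 3, 2))
  gap <- array(1, dim = c(H, max(2L, bar_w %/% 2L), 3))
  canvas <- array(0, dim = c(H, W + dim(gap)[2] + bar_w, 3))
  canvas[, seq_len(W), ] <- out
  canvas[, W + seq_len(dim(gap)[2]), ] <- gap
  canvas[, W + dim(gap)[2] + seq_len(bar_w), ] <- bar
  png::writePNG(pmin(pmax(canvas, 0), 1), file)
  invisible(file)
}

#' Write a raw saliency grid as a delimited text file
#' @param hm a `dfu_heatmap`.
#' @param file output path (tab-separated values of the `[0,1]` map).
#' @export
save_heatmap_grid <- function(hm, file) {
  utils::write.table(hm$map, file, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
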