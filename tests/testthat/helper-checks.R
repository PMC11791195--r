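# Shared test utilities: finite-difference gradient checking, parameter
# copying between layers, and a small in-memory training set builder.

fd_gradient_check <- function(fn, tensors, eps = 1e-6, tol = 3e-4,
                              n_probe = 4) {
  loss <- fn()
  dt_backward(loss)
  for (t in tensors) {
    g <- dt_grad(t)
    if (is.null(g)) return("a tensor received no gradient")
    for (i in sample(length(t$v), min(n_probe, length(t$v)))) {
      v0 <- t$v[i]
      t$v[i] <- v0 + eps
      lp <- sum(dt_value(dt_no_grad(fn())))
      t$v[i] <- v0 - eps
      lm <- sum(dt_value(dt_no_grad(fn())))
      t$v[i] <- v0
      num <- (lp - lm) / (2 * eps)
      if (abs(num - g[i]) > tol * max(1, abs(num)))
        return(sprintf("gradient mismatch: numeric %.6g vs analytic %.6g",
                       num, g[i]))
    }
    dt_zero_grad(t)
  }
  TRUE
}

copy_layer_params <- function(from, to) {
  pf <- parameters(from); pt <- parameters(to)
  stopifnot(identical(names(pf), names(pt)))
  for (nm in names(pf)) pt[[nm]]$v <- pf[[nm]]$v
  invisible(to)
}

# Small normalized synthetic training set at 32x32.
tiny_training_data <- function(n_per_class = 4, seed = 11) {
  counts <- stats::setNames(rep(n_per_class, 4), dfu_classes)
  ds <- generate_synthetic_dataset(counts, seed = seed, size = 32)
  n <- length(ds$images)
  x <- array(0, c(32, 32, 3, n))
  for (i in seq_len(n)) x[, , , i] <- ds$images[[i]]
  mu <- apply(x, 3, mean); sdv <- apply(x, 3, stats::sd)
  for (c in 1:3) x[, , c, ] <- (x[, , c, ] - mu[c]) / sdv[c]
  list(x = x, y = ds$labels)
}

quiet_loss <- function(model, x, y) {
  as.numeric(dt_value(dt_cross_entropy(dt_no_grad(forward(model, x)), y)))
}

# A minimal Grad-CAM test model with one non-negative activation channel,
# global average pooling, and a single linear weight; its saliency map has a
# closed form (the min-max normalized activation when w > 0).
make_toy_cam_model <- function(w) {
  dfunet:::new_layer("toy_cam_model", w = w, cache = list())
}

forward.toy_cam_model <- function(layer, x, ...) {
  x <- dfunet:::as_dt(x)
  A <- dt_take(dt_relu(x), 1L, 3L)
  layer$cache <- list(sa = A)
  pooled <- dt_mean_axes(A, c(1, 2))
  s <- dt_scale(dt_reshape(pooled, c(1L, dim(dt_value(x))[4])), layer$w)
  dt_concat(list(s, dt_scale(s, 0)), 1L)
}
registerS3method("forward", "toy_cam_model", forward.toy_cam_model,
                 envir = asNamespace("dfunet"))
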