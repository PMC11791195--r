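# Layer library on top of the autograd core.
#
# A layer is an environment with class attributes, a named list `params` of
# dt_tensor parameters, a named list `children` of sub-layers, and optional
# buffers (e.g. batch-norm running statistics).  `forward()` dispatches on the
# layer class; feature maps are arrays with dims (H, W, C, N).

new_layer <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$params)) e$params <- list()
  if (is.null(e$children)) e$children <- list()
  e$training <- TRUE
  class(e) <- c(class, "nn_layer")
  e
}

#' Forward pass through a layer
#' @param layer a layer object.
#' @param x input (`dt_tensor` or plain array with dims `(H, W, C, N)`).
#' @param ... passed to methods.
#' @return a `dt_tensor`.
#' @export
forward <- function(layer, x, ...) UseMethod("forward")

#' Collect the trainable parameters of a layer tree
#' @param layer a layer.
#' @return named list of `dt_tensor`s.
#' @export
parameters <- function(layer) {
  out <- layer$params
  for (nm in names(layer$children)) {
    sub <- parameters(layer$children[[nm]])
    if (length(sub)) names(sub) <- paste(nm, names(sub), sep = ".")
    out <- c(out, sub)
  }
  out
}

#' Count trainable parameters
#'
#' @param model a layer (or any object with `parameters()`).
#' @param trainable_only count only tensors with `requires_grad` (default).
#' @return integer total number of parameter elements.
#' @export
count_parameters <- function(model, trainable_only = TRUE) {
  ps <- parameters(model)
  if (trainable_only) ps <- Filter(function(p) p$requires, ps)
  sum(vapply(ps, function(p) length(p$v), numeric(1)))
}

#' Switch a layer tree between training and evaluation mode
#' @param layer a layer.
#' @param training logical.
#' @export
set_train <- function(layer, training = TRUE) {
  layer$training <- training
  for (ch in layer$children) set_train(ch, training)
  invisible(layer)
}

#' @export
print.nn_layer <- function(x, ...) {
  cat("<", class(x)[1], ": ", format(count_parameters(x), big.mark = ","),
      " trainable parameters>\n", sep = "")
  invisible(x)
}

# ------------------------------------------------------------------- init --

init_kaiming <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

param <- function(x) dt_tensor(x, requires_grad = TRUE)

# ----------------------------------------------------------------- linear --

#' Fully connected layer
#' @param in_features,out_features layer widths.
#' @param bias include a bias vector?
#' @return a layer; its forward maps `(n, in)` matrices to `(n, out)`.
#' @export
nn_linear <- function(in_features, out_features, bias = TRUE) {
  W <- param(matrix(init_kaiming(in_features, in_features * out_features),
                    in_features, out_features))
  l <- new_layer("nn_linear", in_features = in_features,
                 out_features = out_features,
                 params = c(list(weight = W),
                            if (bias) list(bias = param(array(0, out_features)))))
  l
}

#' @export
forward.nn_linear <- function(layer, x, ...) {
  x <- as_dt(x)
  out <- dt_matmul(x, layer$params$weight)
  if (!is.null(layer$params$bias)) {
    b <- layer$params$bias
    out <- dt_add(out, dt_reshape(b, c(1L, layer$out_features)))
  }
  out
}

# ------------------------------------------------------------------ conv --

# Precompute the im2col gather index matrix: (H'W', kh*kw) linear indices into
# a padded (Hp, Wp) grid; tap order matches the col-major layout of a
# (kh, kw, ...) kernel array.
conv_index <- function(Hp, Wp, kh, kw, stride, dil) {
  oh <- (Hp - (kh - 1L) * dil - 1L) %/% stride + 1L
  ow <- (Wp - (kw - 1L) * dil - 1L) %/% stride + 1L
  orow <- (seq_len(oh) - 1L) * stride + 1L
  ocol <- (seq_len(ow) - 1L) * stride + 1L
  base_r <- rep(orow, times = ow)
  base_c <- rep(ocol, each = oh)
  taps <- as.matrix(expand.grid(u = seq_len(kh), v = seq_len(kw)))
  idx <- matrix(0L, oh * ow, kh * kw)
  for (j in seq_len(nrow(taps))) {
    rr <- base_r + (taps[j, 1] - 1L) * dil
    cc <- base_c + (taps[j, 2] - 1L) * dil
    idx[, j] <- rr + (cc - 1L) * Hp
  }
  list(idx = idx, oh = oh, ow = ow)
}

# Shared conv padding rule: odd kernels get symmetric "same" padding; even
# kernels pad the remainder on the bottom/right only.
same_pad <- function(k, dil) {
  tot <- (k - 1L) * dil
  c(tot %/% 2L, tot - tot %/% 2L)
}

#' 2-D convolution layer
#'
#' Dense or depthwise convolution over `(H, W, C, N)` feature maps with
#' configurable stride, dilation and padding.  `padding = "same"` preserves the
#' spatial size at stride 1 (even kernels pad on the bottom/right).
#'
#' @param in_channels,out_channels channel widths. For `depthwise = TRUE`,
#'   `out_channels` must equal `in_channels`.
#' @param kernel_size integer (square kernels).
#' @param stride,dilation integers.
#' @param padding `"same"`, `"valid"`, or integer `c(top, bottom, left, right)`.
#' @param bias include per-output-channel bias?
#' @param depthwise one filter per channel (groups = channels)?
#' @return a layer.
#' @export
nn_conv2d <- function(in_channels, out_channels, kernel_size, stride = 1L,
                      dilation = 1L, padding = "same", bias = TRUE,
                      depthwise = FALSE) {
  k <- as.integer(kernel_size)
  if (depthwise) {
    if (out_channels != in_channels)
      stop("depthwise convolution requires out_channels == in_channels")
    W <- param(array(init_kaiming(k * k, k * k * in_channels), dim = c(k, k, in_channels)))
  } else {
    W <- param(array(init_kaiming(k * k * in_channels, k * k * in_channels * out_channels),
                     dim = c(k, k, in_channels, out_channels)))
  }
  new_layer("nn_conv2d",
            in_channels = as.integer(in_channels),
            out_channels = as.integer(out_channels),
            k = k, stride = as.integer(stride), dilation = as.integer(dilation),
            padding = padding, depthwise = depthwise,
            params = c(list(weight = W),
                       if (bias) list(bias = param(array(0, out_channels)))))
}

resolve_pad <- function(padding, k, dil) {
  if (identical(padding, "same")) {
    p <- same_pad(k, dil)
    c(p[1], p[2], p[1], p[2])
  } else if (identical(padding, "valid")) {
    c(0L, 0L, 0L, 0L)
  } else as.integer(padding)
}

#' @export
forward.nn_conv2d <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  if (d[3] != layer$in_channels)
    stop("nn_conv2d: input has ", d[3], " channels, expected ", layer$in_channels)
  pad <- resolve_pad(layer$padding, layer$k, layer$dilation)
  xp <- dt_pad_hw(x, pad)
  dt_conv2d_core(xp, layer$params$weight, layer$params$bias,
                 layer$stride, layer$dilation, layer$depthwise)
}

# Fused convolution op on a pre-padded input tensor.
dt_conv2d_core <- function(xp, W, b, stride, dil, depthwise) {
  dv <- dim(xp$v)
  Hp <- dv[1]; Wp <- dv[2]; C <- dv[3]; N <- dv[4]
  kd <- dim(W$v)
  kh <- kd[1]; kw <- kd[2]
  ci <- conv_index(Hp, Wp, kh, kw, stride, dil)
  idx <- ci$idx; oh <- ci$oh; ow <- ci$ow
  L <- oh * ow; K <- kh * kw
  xpf <- xp$v
  dim(xpf) <- c(Hp * Wp, C, N)
  col <- xpf[as.vector(idx), , , drop = FALSE]      # (L*K, C, N)
  dim(col) <- c(L, K, C, N)
  # slice helpers that never drop dims unintentionally
  col_jn <- function(j, n) {                        # (L, C)
    m <- col[, j, , n, drop = FALSE]; dim(m) <- c(L, C); m
  }
  col_n <- function(n) {                            # (L, K*C)
    m <- col[, , , n, drop = FALSE]; dim(m) <- c(L, K * C); m
  }
  Wv <- W$v
  if (depthwise) {
    Cout <- C
    val <- array(0, dim = c(L, C, N))
    Wm <- matrix(Wv, K, C)
    for (n in seq_len(N)) {
      acc <- matrix(0, L, C)
      for (j in seq_len(K))
        acc <- acc + col_jn(j, n) * matrix(Wm[j, ], nrow = L, ncol = C, byrow = TRUE)
      val[, , n] <- acc
    }
  } else {
    Cout <- kd[4]
    Wm <- matrix(Wv, K * C, Cout)
    val <- array(0, dim = c(L, Cout, N))
    for (n in seq_len(N)) val[, , n] <- col_n(n) %*% Wm
  }
  if (!is.null(b)) val <- val + array(rep(b$v, each = L), dim = c(L, Cout, N))
  dim(val) <- c(oh, ow, Cout, N)
  inputs <- c(list(xp, W), if (!is.null(b)) list(b))
  dt_op(val, inputs, function(g) {
    dim(g) <- c(L, Cout, N)
    g_n <- function(n) { m <- g[, , n, drop = FALSE]; dim(m) <- c(L, Cout); m }
    gxpf <- array(0, dim = c(Hp * Wp, C, N))
    dcol <- array(0, dim = c(L, K, C, N))
    if (depthwise) {
      gWm <- matrix(0, K, C)
      for (n in seq_len(N)) {
        gn <- g_n(n)
        for (j in seq_len(K)) {
          gWm[j, ] <- gWm[j, ] + colSums(col_jn(j, n) * gn)
          dcol[, j, , n] <- gn * matrix(Wm[j, ], nrow = L, ncol = C, byrow = TRUE)
        }
      }
      gW <- array(gWm, dim = dim(Wv))
    } else {
      gWm <- matrix(0, K * C, Cout)
      for (n in seq_len(N)) {
        gn <- g_n(n)
        gWm <- gWm + crossprod(col_n(n), gn)
        dM <- gn %*% t(Wm)
        dim(dM) <- c(L, K, C)
        dcol[, , , n] <- dM
      }
      gW <- array(gWm, dim = dim(Wv))
    }
    for (j in seq_len(K)) {
      ij <- idx[, j]
      dc <- dcol[, j, , , drop = FALSE]
      dim(dc) <- c(L, C, N)
      gxpf[ij, , ] <- array(gxpf[ij, , , drop = FALSE], dim = c(L, C, N)) + dc
    }
    gb <- if (!is.null(b)) apply(g, 2, sum) else NULL
    dim(gxpf) <- c(Hp, Wp, C, N)
    c(list(gxpf, gW), if (!is.null(b)) list(gb))
  })
}

# ---------------------------------------------------------------- norms --

#' Batch normalization over `(H, W, N)` per channel
#' @param channels channel count.
#' @param momentum running-statistics momentum.
#' @param eps numerical floor for the variance.
#' @return a layer.
#' @export
nn_batchnorm2d <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("nn_batchnorm2d", channels = channels, momentum = momentum, eps = eps,
            running_mean = array(0, channels), running_var = array(1, channels),
            params = list(gamma = param(array(1, channels)),
                          beta = param(array(0, channels))))
}

#' @export
forward.nn_batchnorm2d <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  C <- d[3]
  eps <- layer$eps
  gamma <- layer$params$gamma
  beta <- layer$params$beta
  if (!layer$training) {
    m <- layer$running_mean
    v <- layer$running_var
    mt <- dt_tensor(array(m, dim = c(1L, 1L, C, 1L)))
    ist <- dt_tensor(array(1 / sqrt(v + eps), dim = c(1L, 1L, C, 1L)))
    xhat <- dt_mul(dt_sub(x, mt), ist)
    g <- dt_reshape(gamma, c(1L, 1L, C, 1L))
    b <- dt_reshape(beta, c(1L, 1L, C, 1L))
    return(dt_add(dt_mul(xhat, g), b))
  }
  # training: batch statistics, exact gradients through them
  m <- apply(x$v, 3, mean)
  v <- apply(x$v, 3, function(ch) mean((ch - mean(ch))^2))
  layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * m
  layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
  n <- prod(d[c(1, 2, 4)])
  ivs <- 1 / sqrt(v + eps)
  xhat_v <- sweep(sweep(x$v, 3, m), 3, ivs, `*`)
  dt_op(sweep(sweep(xhat_v, 3, gamma$v, `*`), 3, beta$v, `+`),
        list(x, gamma, beta),
        function(g) {
          ggamma <- apply(g * xhat_v, 3, sum)
          gbeta <- apply(g, 3, sum)
          gxhat <- sweep(g, 3, gamma$v, `*`)
          s1 <- apply(gxhat, 3, sum)
          s2 <- apply(gxhat * xhat_v, 3, sum)
          gx <- sweep(gxhat, 3, ivs, `*`) -
            sweep(array(1, dim = d), 3, s1 * ivs / n, `*`) -
            sweep(xhat_v, 3, s2 * ivs / n, `*`)
          list(gx, ggamma, gbeta)
        })
}

#' Layer normalization over a chosen axis
#' @param normalized_dim size of the normalized axis.
#' @param axis which axis to normalize (default: last-but-one channel axis 3
#'   is *not* assumed; pass explicitly).
#' @param eps numerical floor.
#' @return a layer.
#' @export
nn_layernorm <- function(normalized_dim, axis, eps = 1e-5) {
  new_layer("nn_layernorm", dim = normalized_dim, axis = axis, eps = eps,
            params = list(gamma = param(array(1, normalized_dim)),
                          beta = param(array(0, normalized_dim))))
}

#' @export
forward.nn_layernorm <- function(layer, x, ...) {
  x <- as_dt(x)
  dt_layernorm_core(x, layer$params$gamma, layer$params$beta, layer$axis, layer$eps)
}

dt_layernorm_core <- function(x, gamma, beta, axis, eps) {
  d <- dim(x$v)
  C <- d[axis]
  td <- d; td[axis] <- 1L
  m <- reduce_to(x$v, td) / C
  xc <- x$v - expand_to(m, d)
  v <- reduce_to(xc^2, td) / C
  ivs <- 1 / sqrt(v + eps)
  xhat <- xc * expand_to(ivs, d)
  shp <- rep(1L, length(d)); shp[axis] <- C
  gv <- array(gamma$v, dim = shp)
  bv <- array(beta$v, dim = shp)
  val <- xhat * expand_to(gv, d) + expand_to(bv, d)
  dt_op(val, list(x, gamma, beta), function(g) {
    ggamma <- reduce_to(g * xhat, shp)
    gbeta <- reduce_to(g, shp)
    gxhat <- g * expand_to(gv, d)
    s1 <- reduce_to(gxhat, td) / C
    s2 <- reduce_to(gxhat * xhat, td) / C
    gx <- (gxhat - expand_to(s1, d) - xhat * expand_to(s2, d)) * expand_to(ivs, d)
    list(gx, array(ggamma, dim = dim(gamma$v)), array(gbeta, dim = dim(beta$v)))
  })
}

#' Per-channel spatial standardization (group norm with one channel per group)
#'
#' Normalizes each channel of each sample over its spatial extent, with affine
#' parameters per channel. This is the `GN` operator inside the spatial branch
#' of shuffle attention.
#'
#' @param channels channel count.
#' @param eps numerical floor.
#' @return a layer.
#' @export
nn_groupnorm_pc <- function(channels, eps = 1e-5) {
  new_layer("nn_groupnorm_pc", channels = channels, eps = eps,
            params = list(gamma = param(array(1, channels)),
                          beta = param(array(0, channels))))
}

#' @export
forward.nn_groupnorm_pc <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  eps <- layer$eps
  n <- d[1] * d[2]
  td <- c(1L, 1L, d[3], d[4])
  m <- reduce_to(x$v, td) / n
  xc <- x$v - expand_to(m, d)
  v <- reduce_to(xc^2, td) / n
  ivs <- 1 / sqrt(v + eps)
  xhat <- xc * expand_to(ivs, d)
  gamma <- layer$params$gamma
  beta <- layer$params$beta
  shp <- c(1L, 1L, d[3], 1L)
  gv <- array(gamma$v, dim = shp)
  bv <- array(beta$v, dim = shp)
  val <- xhat * expand_to(gv, d) + expand_to(bv, d)
  dt_op(val, list(x, gamma, beta), function(g) {
    ggamma <- reduce_to(g * xhat, shp)
    gbeta <- reduce_to(g, shp)
    gxhat <- g * expand_to(gv, d)
    s1 <- reduce_to(gxhat, td) / n
    s2 <- reduce_to(gxhat * xhat, td) / n
    gx <- (gxhat - expand_to(s1, d) - xhat * expand_to(s2, d)) * expand_to(ivs, d)
    list(gx, array(ggamma, dim = dim(gamma$v)), array(gbeta, dim = dim(beta$v)))
  })
}

# -------------------------------------------------------------- optimizer --

#' SGD with momentum and decoupled weight decay
#'
#' @param params named list of `dt_tensor` parameters (see [parameters()]).
#' @param lr learning rate.
#' @param momentum classical momentum coefficient.
#' @param weight_decay L2 coefficient added to the gradient.
#' @return an optimizer object with `$step()`, `$zero_grad()`, `$set_lr()`.
#' @export
optim_sgd <- function(params, lr = 1e-4, momentum = 0.9, weight_decay = 0) {
  vel <- lapply(params, function(p) array(0, dim = dim(p$v)))
  e <- new.env(parent = emptyenv())
  e$lr <- lr
  e$step <- function() {
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (is.null(p$grad)) next
      g <- p$grad + weight_decay * p$v
      vel[[i]] <<- momentum * vel[[i]] + g
      p$v <- p$v - e$lr * vel[[i]]
    }
    invisible(NULL)
  }
  e$zero_grad <- function() {
    for (p in params) p$grad <- NULL
    invisible(NULL)
  }
  e$set_lr <- function(lr) e$lr <- lr
  class(e) <- "dfunet_optimizer"
  e
}
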