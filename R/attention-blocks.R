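# Attention operators of the GDA block (global context block, dilated
# convolution with learnable spacings, coordinate attention) and the shuffle
# attention fusion operator.

# ------------------------------------------------------ global context block --

#' Global context block (GCB)
#'
#' Softmax attention pooling over all spatial positions (one logit per
#' position from a 1x1 convolution), followed by a bottleneck transform
#' `W_v2 ReLU(LN(W_v1 z))` whose output is broadcast-added back to the input.
#'
#' @param channels input channel count.
#' @param reduction bottleneck reduction ratio (hidden width
#'   `ceiling(channels / reduction)`).
#' @return a layer.
#' @export
gcb_block <- function(channels, reduction = 8L) {
  hidden <- max(1L, as.integer(ceiling(channels / reduction)))
  new_layer("gcb_block", channels = as.integer(channels), hidden = hidden,
            children = list(
              wk = nn_conv2d(channels, 1L, 1L),
              wv1 = nn_conv2d(channels, hidden, 1L),
              ln = nn_layernorm(hidden, axis = 3L),
              wv2 = nn_conv2d(hidden, channels, 1L)))
}

#' Global attention pooling weights
#'
#' Returns the per-position softmax weights `alpha_j` of a [gcb_block()]:
#' non-negative and summing to one over the spatial positions of each batch
#' item.
#'
#' @param x feature map `(H, W, C, N)`.
#' @param layer a `gcb_block`.
#' @return `dt_tensor` of dims `(H*W, 1, N)`.
#' @export
gcb_attention_weights <- function(x, layer) {
  x <- as_dt(x)
  d <- dim(x$v)
  logits <- forward(layer$children$wk, x)             # (H, W, 1, N)
  lf <- dt_reshape(logits, c(d[1] * d[2], 1L, d[4]))
  dt_softmax(lf, 1L)
}

#' @export
forward.gcb_block <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  alpha <- gcb_attention_weights(x, layer)            # (HW, 1, N)
  xr <- dt_reshape(x, c(d[1] * d[2], d[3], d[4]))
  z <- dt_sum_axes(dt_mul(xr, alpha), 1L)             # (1, C, N)
  zmap <- dt_reshape(z, c(1L, 1L, d[3], d[4]))
  t1 <- forward(layer$children$wv1, zmap)
  t2 <- dt_relu(forward(layer$children$ln, t1))
  delta <- forward(layer$children$wv2, t2)            # (1, 1, C, N)
  dt_add(x, delta)
}

# ------------------------------------- dilated conv with learnable spacings --

# Build an (L, L, Cin, Cout) kernel by bilinearly spreading each kernel
# element's weights at its continuous 2-D position.  Differentiable in the
# weights and the positions.
dt_dcls_kernel <- function(W, P, extent) {
  Wv <- W$v; Pv <- P$v
  nel <- dim(Wv)[1]; Cin <- dim(Wv)[2]; Cout <- dim(Wv)[3]
  L <- as.integer(extent)
  py <- pmin(pmax(Pv[1, ], 0), L - 1)
  px <- pmin(pmax(Pv[2, ], 0), L - 1)
  y0 <- pmin(floor(py), L - 2); x0 <- pmin(floor(px), L - 2)
  fy <- py - y0; fx <- px - x0
  K <- array(0, dim = c(L, L, Cin, Cout))
  corners <- list(c(0, 0, NA), c(0, 1, NA), c(1, 0, NA), c(1, 1, NA))
  wq <- function(q, e) switch(q,
    (1 - fy[e]) * (1 - fx[e]), (1 - fy[e]) * fx[e],
    fy[e] * (1 - fx[e]), fy[e] * fx[e])
  for (e in seq_len(nel)) {
    We <- Wv[e, , , drop = FALSE]
    dim(We) <- c(Cin, Cout)
    for (q in 1:4) {
      dy <- corners[[q]][1]; dx <- corners[[q]][2]
      K[y0[e] + 1 + dy, x0[e] + 1 + dx, , ] <-
        K[y0[e] + 1 + dy, x0[e] + 1 + dx, , ] + wq(q, e) * We
    }
  }
  dt_op(K, list(W, P), function(g) {
    gW <- array(0, dim = dim(Wv))
    gP <- array(0, dim = dim(Pv))
    inside_y <- Pv[1, ] > 0 & Pv[1, ] < L - 1
    inside_x <- Pv[2, ] > 0 & Pv[2, ] < L - 1
    for (e in seq_len(nel)) {
      We <- Wv[e, , , drop = FALSE]
      dim(We) <- c(Cin, Cout)
      gy <- 0; gx <- 0
      for (q in 1:4) {
        dy <- corners[[q]][1]; dx <- corners[[q]][2]
        gK <- g[y0[e] + 1 + dy, x0[e] + 1 + dx, , ]
        dim(gK) <- c(Cin, Cout)
        gW[e, , ] <- array(gW[e, , ], dim = c(Cin, Cout)) + wq(q, e) * gK
        sgn_y <- if (dy == 0) -1 else 1
        sgn_x <- if (dx == 0) -1 else 1
        wy <- if (dx == 0) 1 - fx[e] else fx[e]
        wx <- if (dy == 0) 1 - fy[e] else fy[e]
        s <- sum(gK * We)
        gy <- gy + sgn_y * wy * s
        gx <- gx + sgn_x * wx * s
      }
      gP[1, e] <- if (inside_y[e]) gy else 0
      gP[2, e] <- if (inside_x[e]) gx else 0
    }
    list(gW, gP)
  })
}

#' Dilated convolution with learnable spacings (DCLS)
#'
#' A convolution whose kernel elements sit at continuous, trainable 2-D
#' positions within an `extent x extent` support; the effective kernel is the
#' bilinear spread of each element's weights, so the operator is
#' differentiable in the positions as well as the weights.  Same-padding.
#'
#' @param channels input = output channel count (dense channel mixing:
#'   one weight per in/out channel pair per element).
#' @param n_elements number of kernel elements.
#' @param extent maximum spatial extent `L` (positions live in `[0, L-1]^2`).
#' @return a layer.
#' @export
dcls_block <- function(channels, n_elements = 5L, extent = 7L) {
  c <- as.integer(channels)
  nel <- as.integer(n_elements)
  if (nel < 1) stop("dcls_block: n_elements must be >= 1")
  W <- param(array(init_kaiming(nel * c, nel * c * c), dim = c(nel, c, c)))
  P <- param(rbind(stats::runif(nel, 0, extent - 1),
                   stats::runif(nel, 0, extent - 1)))
  new_layer("dcls_block", channels = c, n_elements = nel,
            extent = as.integer(extent),
            params = list(weight = W, positions = P,
                          bias = param(array(0, c))))
}

#' @export
forward.dcls_block <- function(layer, x, ...) {
  x <- as_dt(x)
  if (dim(x$v)[3] != layer$channels) stop("dcls_block: channel mismatch")
  L <- layer$extent
  K <- dt_dcls_kernel(layer$params$weight, layer$params$positions, L)
  p <- same_pad(L, 1L)
  xp <- dt_pad_hw(x, c(p[1], p[2], p[1], p[2]))
  dt_conv2d_core(xp, K, layer$params$bias, 1L, 1L, depthwise = FALSE)
}

# ------------------------------------------------------ coordinate attention --

#' Coordinate attention (CA)
#'
#' Pools the input along each spatial direction, transforms the concatenated
#' profiles through a shared 1x1 bottleneck (BN + hard-swish), splits them
#' back, and produces per-direction sigmoid gates:
#' `y_c(i,j) = x_c(i,j) * g_h_c(i) * g_w_c(j)`.
#'
#' @param channels input channel count.
#' @param reduction bottleneck reduction ratio.
#' @return a layer.
#' @export
coord_attention <- function(channels, reduction = 8L) {
  hidden <- max(1L, as.integer(ceiling(channels / reduction)))
  new_layer("coord_attention", channels = as.integer(channels), hidden = hidden,
            children = list(
              f1 = nn_conv2d(channels, hidden, 1L),
              bn = nn_batchnorm2d(hidden),
              fh = nn_conv2d(hidden, channels, 1L),
              fw = nn_conv2d(hidden, channels, 1L)))
}

#' @export
forward.coord_attention <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  H <- d[1]; W <- d[2]
  zh <- dt_mean_axes(x, 2L)                       # (H, 1, C, N)
  zw <- dt_aperm(dt_mean_axes(x, 1L), c(2, 1, 3, 4))  # (W, 1, C, N)
  f <- forward(layer$children$f1, dt_concat(list(zh, zw), 1L))
  f <- dt_hardswish(forward(layer$children$bn, f))
  fh <- dt_take(f, seq_len(H), 1L)
  fw <- dt_aperm(dt_take(f, H + seq_len(W), 1L), c(2, 1, 3, 4))
  gh <- dt_sigmoid(forward(layer$children$fh, fh))    # (H, 1, C, N)
  gw <- dt_sigmoid(forward(layer$children$fw, fw))    # (1, W, C, N)
  dt_mul(dt_mul(x, gh), gw)
}

# --------------------------------------------------------- shuffle attention --

#' Shuffle attention (SA)
#'
#' Splits the channels into `groups` groups; each group is halved into a
#' channel-attention branch (gated by an affine transform of the per-channel
#' spatial mean) and a spatial-attention branch (gated by an affine transform
#' of the per-channel group-normalized map).  Halves and groups are re-joined
#' and a final channel shuffle mixes the sub-features.  The four affine
#' vectors and the group-norm pair are shared across groups (each of length
#' `channels / (2 * groups)`), so the block owns `3 * channels / groups`
#' parameters.
#'
#' @param channels input channel count (divisible by `2 * groups`).
#' @param groups number of groups `G`.
#' @return a layer.
#' @export
sa_block <- function(channels, groups = 3L) {
  C <- as.integer(channels); G <- as.integer(groups)
  if (C %% (2L * G) != 0) {
    valid <- Filter(function(g) C %% (2L * g) == 0, seq_len(C %/% 2L))
    stop("sa_block: channels (", C, ") must be divisible by 2*groups; ",
         "valid group counts: ", paste(valid, collapse = ", "))
  }
  half <- C %/% (2L * G)
  new_layer("sa_block", channels = C, groups = G, half = half,
            params = list(cw = param(array(1, half)),
                          cb = param(array(0, half)),
                          sw = param(array(1, half)),
                          sb = param(array(0, half))),
            children = list(gn = nn_groupnorm_pc(half)))
}

#' @export
forward.sa_block <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  C <- layer$channels; G <- layer$groups; half <- layer$half
  if (d[3] != C) stop("sa_block: channel mismatch")
  shp <- c(1L, 1L, half, 1L)
  cw <- dt_reshape(layer$params$cw, shp)
  cb <- dt_reshape(layer$params$cb, shp)
  sw <- dt_reshape(layer$params$sw, shp)
  sb <- dt_reshape(layer$params$sb, shp)
  outs <- vector("list", G)
  for (g in seq_len(G)) {
    base <- (g - 1L) * 2L * half
    x1 <- dt_take(x, base + seq_len(half), 3L)
    x2 <- dt_take(x, base + half + seq_len(half), 3L)
    s <- dt_mean_axes(x1, c(1L, 2L))                       # (1,1,half,N)
    gate_c <- dt_sigmoid(dt_add(dt_mul(cw, s), cb))
    x1p <- dt_mul(x1, gate_c)
    gnx <- forward(layer$children$gn, x2)
    gate_s <- dt_sigmoid(dt_add(dt_mul(sw, gnx), sb))
    x2p <- dt_mul(x2, gate_s)
    outs[[g]] <- dt_concat(list(x1p, x2p), 3L)
  }
  out <- if (G == 1) outs[[1]] else dt_concat(outs, 3L)
  channel_shuffle(out, 2L)
}

# ---------------------------------------------------------------- GDA block --

#' Global dilated attention (GDA) block
#'
#' Composition `CA(DCLS(GCB(x)))`: global context modeling, receptive-field
#' expansion with learnable kernel spacings, and coordinate attention.
#' Shape-preserving.
#'
#' @param channels stage channel width.
#' @param gcb_reduction,ca_reduction bottleneck ratios of the GCB and CA.
#' @param dcls_elements,dcls_extent DCLS kernel configuration.
#' @return a layer.
#' @export
gda_block <- function(channels, gcb_reduction = 8L, ca_reduction = 8L,
                      dcls_elements = 5L, dcls_extent = 7L) {
  new_layer("gda_block", channels = as.integer(channels),
            children = list(
              gcb = gcb_block(channels, gcb_reduction),
              dcls = dcls_block(channels, dcls_elements, dcls_extent),
              ca = coord_attention(channels, ca_reduction)))
}

#' @export
forward.gda_block <- function(layer, x, ...) {
  forward(layer$children$ca,
          forward(layer$children$dcls,
                  forward(layer$children$gcb, x)))
}
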