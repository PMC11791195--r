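# Building blocks of the EMADN track: ghost module, channel shuffle, MixConv,
# dilated depth-wise separable convolution (DDSC), deformable convolution, and
# the LMDS block that composes them.

#' LMDS block configuration
#'
#' Describes one lightweight multi-scale deformable shuffle (LMDS) stage.
#' The block runs a ghost module, splits into a shuffle+MixConv branch and a
#' DDSC branch at `branch_channels`, merges the branches by element-wise
#' (Hadamard) product, and down-samples with a deformable convolution.
#'
#' @param in_channels,out_channels stage widths.
#' @param branch_channels working width of the two parallel branches
#'   (the ghost module's output width); must be even.
#' @param ghost_ratio intrinsic-to-total split of the ghost module
#'   (`ratio = 2` means half the output channels are "cheap" ghost maps).
#' @param shuffle_groups channel-shuffle groups in the MixConv branch; must
#'   divide `branch_channels`.
#' @param mixconv_kernel_sizes odd kernel sizes of the MixConv groups.
#' @param ddsc_kernel_size,ddsc_dilation DDSC depth-wise kernel size and
#'   dilation (defaults 2 and 2: receptive field 3).
#' @param deform_kernel_size,deform_stride deformable convolution kernel and
#'   stride (the stride performs the block's down-sampling).
#' @return a list of class `lmds_config`.
#' @export
lmds_config <- function(in_channels, out_channels,
                        branch_channels = out_channels,
                        ghost_ratio = 2L,
                        shuffle_groups = 2L,
                        mixconv_kernel_sizes = c(3L, 5L, 7L),
                        ddsc_kernel_size = 2L,
                        ddsc_dilation = 2L,
                        deform_kernel_size = 3L,
                        deform_stride = 2L) {
  if (length(mixconv_kernel_sizes) == 0)
    stop("lmds_config: mixconv_kernel_sizes must be non-empty")
  if (any(mixconv_kernel_sizes %% 2 == 0))
    stop("lmds_config: MixConv kernel sizes must be odd (same-padding)")
  if (branch_channels %% shuffle_groups != 0)
    stop("lmds_config: branch_channels (", branch_channels,
         ") not divisible by shuffle_groups (", shuffle_groups, ")")
  if (branch_channels %% ghost_ratio != 0)
    stop("lmds_config: branch_channels not divisible by ghost_ratio")
  if (deform_stride < 1) stop("lmds_config: deform_stride must be >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 branch_channels = as.integer(branch_channels),
                 ghost_ratio = as.integer(ghost_ratio),
                 shuffle_groups = as.integer(shuffle_groups),
                 mixconv_kernel_sizes = as.integer(mixconv_kernel_sizes),
                 ddsc_kernel_size = as.integer(ddsc_kernel_size),
                 ddsc_dilation = as.integer(ddsc_dilation),
                 deform_kernel_size = as.integer(deform_kernel_size),
                 deform_stride = as.integer(deform_stride)),
            class = "lmds_config")
}

# ------------------------------------------------------------ ghost module --

#' Ghost module
#'
#' Produces `out_channels` feature maps as the concatenation of
#' `out_channels / ratio` intrinsic maps (a dense convolution) and
#' `out_channels - out_channels / ratio` ghost maps obtained from the
#' intrinsic maps by a cheap depth-wise convolution.  With `ratio = 1` the
#' module degenerates to the intrinsic convolution alone.  Followed by batch
#' normalization and ReLU.
#'
#' @param in_channels,out_channels widths.
#' @param ratio intrinsic-to-total ratio (>= 1).
#' @param kernel_size intrinsic convolution kernel (default 3).
#' @param cheap_kernel_size depth-wise ghost kernel (default 3).
#' @return a layer.
#' @export
ghost_module <- function(in_channels, out_channels, ratio = 2L,
                         kernel_size = 3L, cheap_kernel_size = 3L) {
  intrinsic_ch <- out_channels %/% ratio
  if (intrinsic_ch * ratio != out_channels)
    stop("ghost_module: out_channels must be divisible by ratio")
  ghost_ch <- out_channels - intrinsic_ch
  children <- list(intrinsic = nn_conv2d(in_channels, intrinsic_ch, kernel_size))
  if (ghost_ch > 0) {
    if (ghost_ch != intrinsic_ch)
      stop("ghost_module: only ratio-2 style splits (ghost == intrinsic) or ratio 1 supported")
    children$cheap <- nn_conv2d(intrinsic_ch, intrinsic_ch, cheap_kernel_size,
                                depthwise = TRUE)
  }
  children$bn <- nn_batchnorm2d(out_channels)
  new_layer("ghost_module", in_channels = as.integer(in_channels),
            out_channels = as.integer(out_channels), ratio = as.integer(ratio),
            children = children)
}

#' @export
forward.ghost_module <- function(layer, x, ...) {
  x <- as_dt(x)
  if (dim(x$v)[3] != layer$in_channels)
    stop("ghost_module: input has ", dim(x$v)[3], " channels, expected ",
         layer$in_channels)
  intr <- forward(layer$children$intrinsic, x)
  out <- if (!is.null(layer$children$cheap)) {
    dt_concat(list(intr, forward(layer$children$cheap, intr)), 3)
  } else intr
  dt_relu(forward(layer$children$bn, out))
}

# --------------------------------------------------------- channel shuffle --

#' Channel shuffle permutation
#'
#' `shuffle_index(channels, groups)` returns 1-based source indices: output
#' channel `p` (0-based) takes input channel
#' `(p mod groups) * (channels/groups) + floor(p/groups)` — the reshape to
#' `(groups, channels/groups)`, transpose, flatten reading. For 6 channels in
#' 2 groups the output order is `0, 3, 1, 4, 2, 5`.
#'
#' @param channels channel count (divisible by `groups`).
#' @param groups shuffle group count.
#' @return integer vector of 1-based source indices.
#' @export
shuffle_index <- function(channels, groups) {
  channels <- as.integer(channels); groups <- as.integer(groups)
  if (channels %% groups != 0L)
    stop("channel_shuffle: ", channels, " channels not divisible by ",
         groups, " groups")
  p <- seq_len(channels) - 1L
  (p %% groups) * (channels %/% groups) + p %/% groups + 1L
}

#' Channel shuffle
#'
#' Pure permutation of the channel axis: channels are regrouped so that each
#' output group mixes one channel from every input group; spatial content is
#' untouched.
#'
#' @param x feature map (`dt_tensor` or array, dims `(H, W, C, N)`).
#' @param groups group count dividing the channel count.
#' @return shuffled `dt_tensor`.
#' @export
channel_shuffle <- function(x, groups) {
  x <- as_dt(x)
  dt_take(x, shuffle_index(dim(x$v)[3], groups), 3)
}

# ------------------------------------------------------------------ mixconv --

#' Mixed depth-wise convolution (MixConv)
#'
#' Splits the channels into `length(kernel_sizes)` contiguous groups and
#' depth-wise convolves each group with its own kernel size (same padding).
#' When the channel count does not divide evenly, leading groups receive the
#' remainder (one extra channel each).
#'
#' @param channels channel count.
#' @param kernel_sizes odd kernel sizes, one per group.
#' @return a layer.
#' @export
mixconv <- function(channels, kernel_sizes = c(3L, 5L, 7L)) {
  if (length(kernel_sizes) == 0) stop("mixconv: kernel_sizes must be non-empty")
  if (any(kernel_sizes %% 2 == 0))
    stop("mixconv: even kernel sizes are not allowed (same-padding undefined)")
  channels <- as.integer(channels)
  ng <- length(kernel_sizes)
  base <- channels %/% ng
  rem <- channels - base * ng
  sizes <- base + as.integer(seq_len(ng) <= rem)
  if (any(sizes == 0)) stop("mixconv: more kernel groups than channels")
  children <- list()
  for (i in seq_len(ng))
    children[[paste0("g", i)]] <- nn_conv2d(sizes[i], sizes[i], kernel_sizes[i],
                                            depthwise = TRUE)
  new_layer("mixconv", channels = as.integer(channels), sizes = sizes,
            kernel_sizes = as.integer(kernel_sizes), children = children)
}

#' @export
forward.mixconv <- function(layer, x, ...) {
  x <- as_dt(x)
  if (dim(x$v)[3] != layer$channels)
    stop("mixconv: channel mismatch")
  offs <- cumsum(c(0L, layer$sizes))
  outs <- lapply(seq_along(layer$sizes), function(i) {
    xi <- dt_take(x, (offs[i] + 1L):offs[i + 1L], 3)
    forward(layer$children[[paste0("g", i)]], xi)
  })
  if (length(outs) == 1) outs[[1]] else dt_concat(outs, 3)
}

# --------------------------------------------------------------------- ddsc --

#' Dilated depth-wise separable convolution (DDSC)
#'
#' A depth-wise convolution with dilation (enlarging the receptive field to
#' `(k - 1) * dilation + 1`) followed by a 1x1 point-wise mix.  Same-padding:
#' the even default kernel pads only on the bottom/right so the spatial size
#' is preserved.
#'
#' @param channels input = output channel count.
#' @param kernel_size depth-wise kernel (default 2).
#' @param dilation dilation factor (default 2).
#' @return a layer.
#' @export
ddsc <- function(channels, kernel_size = 2L, dilation = 2L) {
  new_layer("ddsc", channels = as.integer(channels),
            children = list(
              depthwise = nn_conv2d(channels, channels, kernel_size,
                                    dilation = dilation, depthwise = TRUE),
              pointwise = nn_conv2d(channels, channels, 1L)))
}

#' @export
forward.ddsc <- function(layer, x, ...) {
  forward(layer$children$pointwise, forward(layer$children$depthwise, x))
}

# -------------------------------------------------------- deformable conv --

# Fused deformable-convolution op: samples the padded input at offset tap
# positions via bilinear interpolation, then convolves.  `off` has 2*k^2
# channels on the output grid: channels 1..k^2 are row (dy) offsets per tap,
# k^2+1..2k^2 are column (dx) offsets (taps in column-major (u, v) order).
dt_deform_core <- function(xp, off, W, b, stride) {
  dv <- dim(xp$v)
  Hp <- dv[1]; Wp <- dv[2]; C <- dv[3]; N <- dv[4]
  kd <- dim(W$v)
  kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  K <- kh * kw
  od <- dim(off$v)
  if (od[3] != 2L * K)
    stop("deformable conv: offset map has ", od[3], " channels, expected ", 2L * K)
  oh <- od[1]; ow <- od[2]
  L <- oh * ow
  xpf <- xp$v
  dim(xpf) <- c(Hp * Wp, C, N)
  offv <- off$v
  dim(offv) <- c(L, 2L * K, N)
  taps <- as.matrix(expand.grid(u = seq_len(kh), v = seq_len(kw)))
  base_r <- rep((seq_len(oh) - 1L) * stride + 1L, times = ow)
  base_c <- rep((seq_len(ow) - 1L) * stride + 1L, each = oh)

  col <- array(0, dim = c(L, K, C, N))
  # cached sampling geometry for the backward pass
  geom <- vector("list", N)
  for (n in seq_len(N)) {
    gj <- vector("list", K)
    for (j in seq_len(K)) {
      ry <- base_r + (taps[j, 1] - 1L) + offv[, j, n]
      rx <- base_c + (taps[j, 2] - 1L) + offv[, K + j, n]
      y0 <- floor(ry); x0 <- floor(rx)
      fy <- ry - y0; fx <- rx - x0
      corners <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
      wts <- list((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
      samp <- matrix(0, L, C)
      cinfo <- vector("list", 4)
      for (q in 1:4) {
        yy <- y0 + corners[[q]][1]
        xx <- x0 + corners[[q]][2]
        valid <- yy >= 1 & yy <= Hp & xx >= 1 & xx <= Wp
        lin <- ifelse(valid, yy + (xx - 1) * Hp, 1L)
        V <- xpf[lin, , n, drop = FALSE]
        dim(V) <- c(L, C)
        V[!valid, ] <- 0
        samp <- samp + wts[[q]] * V
        cinfo[[q]] <- list(lin = lin, valid = valid, w = wts[[q]], V = V)
      }
      col[, j, , n] <- samp
      gj[[j]] <- list(fy = fy, fx = fx, cinfo = cinfo)
    }
    geom[[n]] <- gj
  }
  Wm <- matrix(W$v, K * C, Cout)
  val <- array(0, dim = c(L, Cout, N))
  for (n in seq_len(N)) {
    M <- col[, , , n, drop = FALSE]
    dim(M) <- c(L, K * C)
    val[, , n] <- M %*% Wm
  }
  if (!is.null(b)) val <- val + array(rep(b$v, each = L), dim = c(L, Cout, N))
  dim(val) <- c(oh, ow, Cout, N)
  inputs <- c(list(xp, off, W), if (!is.null(b)) list(b))
  dt_op(val, inputs, function(g) {
    dim(g) <- c(L, Cout, N)
    gWm <- matrix(0, K * C, Cout)
    gxpf <- array(0, dim = c(Hp * Wp, C, N))
    goff <- array(0, dim = c(L, 2L * K, N))
    for (n in seq_len(N)) {
      gn <- g[, , n, drop = FALSE]
      dim(gn) <- c(L, Cout)
      M <- col[, , , n, drop = FALSE]
      dim(M) <- c(L, K * C)
      gWm <- gWm + crossprod(M, gn)
      dM <- gn %*% t(Wm)
      dim(dM) <- c(L, K, C)
      for (j in seq_len(K)) {
        dcj <- dM[, j, , drop = FALSE]
        dim(dcj) <- c(L, C)
        gj <- geom[[n]][[j]]
        fy <- gj$fy; fx <- gj$fx
        dsdy <- matrix(0, L, C); dsdx <- matrix(0, L, C)
        sgn_y <- c(-1, -1, 1, 1)
        wy <- list(1 - fx, fx, 1 - fx, fx)       # |d w_q / d ry|
        sgn_x <- c(-1, 1, -1, 1)
        wx <- list(1 - fy, 1 - fy, fy, fy)       # |d w_q / d rx|
        for (q in 1:4) {
          ci <- gj$cinfo[[q]]
          contrib <- ci$w * dcj
          contrib[!ci$valid, ] <- 0
          agg <- rowsum(contrib, group = ci$lin)
          rows <- as.integer(rownames(agg))
          keep <- rows >= 1
          gxpf[rows[keep], , n] <-
            array(gxpf[rows[keep], , n, drop = FALSE], dim = c(sum(keep), C)) +
            agg[keep, , drop = FALSE]
          dsdy <- dsdy + sgn_y[q] * wy[[q]] * ci$V
          dsdx <- dsdx + sgn_x[q] * wx[[q]] * ci$V
        }
        goff[, j, n] <- rowSums(dcj * dsdy)
        goff[, K + j, n] <- rowSums(dcj * dsdx)
      }
    }
    gb <- if (!is.null(b)) apply(g, 2, sum) else NULL
    dim(gxpf) <- c(Hp, Wp, C, N)
    dim(goff) <- od
    c(list(gxpf, goff, array(gWm, dim = kd)), if (!is.null(b)) list(gb))
  })
}

#' Deformable convolution with explicit offsets
#'
#' Samples the input at `grid position + learned offset` via bilinear
#' interpolation and convolves.  With all offsets zero this equals a standard
#' convolution with the same weights.
#'
#' @param x input feature map `(H, W, C, N)`.
#' @param offsets offset map on the *output* grid with `2 * k^2` channels:
#'   the first `k^2` are row offsets per kernel tap, the rest column offsets.
#' @param weight `(k, k, C, C_out)` tensor.
#' @param bias optional `(C_out)` tensor.
#' @param stride spatial stride (down-sampling factor).
#' @return `dt_tensor` of dims `(H/stride, W/stride, C_out, N)`.
#' @export
deform_conv2d <- function(x, offsets, weight, bias = NULL, stride = 1L) {
  x <- as_dt(x); offsets <- as_dt(offsets)
  weight <- as_dt(weight)
  if (!is.null(bias)) bias <- as_dt(bias)
  k <- dim(weight$v)[1]
  p <- same_pad(k, 1L)
  xp <- dt_pad_hw(x, c(p[1], p[2], p[1], p[2]))
  dt_deform_core(xp, offsets, weight, bias, stride)
}

#' Deformable convolution layer
#'
#' The offsets are predicted by a dedicated 3x3 convolution over the input,
#' zero-initialized so that training starts as a regular convolution.
#' Followed by batch normalization and ReLU.
#'
#' @param in_channels,out_channels widths.
#' @param kernel_size deformable kernel (default 3).
#' @param stride down-sampling stride.
#' @return a layer.
#' @export
nn_deform_conv2d <- function(in_channels, out_channels, kernel_size = 3L,
                             stride = 1L) {
  k <- as.integer(kernel_size)
  off <- nn_conv2d(in_channels, 2L * k * k, 3L, stride = stride)
  off$params$weight$v[] <- 0
  off$params$bias$v[] <- 0
  W <- param(array(init_kaiming(k * k * in_channels,
                                k * k * in_channels * out_channels),
                   dim = c(k, k, in_channels, out_channels)))
  new_layer("nn_deform_conv2d",
            in_channels = as.integer(in_channels),
            out_channels = as.integer(out_channels),
            k = k, stride = as.integer(stride),
            params = list(weight = W, bias = param(array(0, out_channels))),
            children = list(offset = off, bn = nn_batchnorm2d(out_channels)))
}

#' @export
forward.nn_deform_conv2d <- function(layer, x, ...) {
  x <- as_dt(x)
  offs <- forward(layer$children$offset, x)
  out <- deform_conv2d(x, offs, layer$params$weight, layer$params$bias,
                       layer$stride)
  dt_relu(forward(layer$children$bn, out))
}

# --------------------------------------------------------------- LMDS block --

#' LMDS block
#'
#' Lightweight multi-scale deformable shuffle block:
#' ghost module -> two parallel branches (channel shuffle + MixConv; DDSC)
#' -> element-wise (Hadamard) product merge -> strided deformable convolution.
#'
#' @param cfg an [lmds_config()].
#' @return a layer.
#' @export
lmds_block <- function(cfg) {
  stopifnot(inherits(cfg, "lmds_config"))
  new_layer("lmds_block", cfg = cfg,
            children = list(
              ghost = ghost_module(cfg$in_channels, cfg$branch_channels,
                                   ratio = cfg$ghost_ratio),
              mix = mixconv(cfg$branch_channels, cfg$mixconv_kernel_sizes),
              ddsc = ddsc(cfg$branch_channels, cfg$ddsc_kernel_size,
                          cfg$ddsc_dilation),
              deform = nn_deform_conv2d(cfg$branch_channels, cfg$out_channels,
                                        cfg$deform_kernel_size,
                                        cfg$deform_stride)))
}

#' @export
forward.lmds_block <- function(layer, x, ...) {
  x <- as_dt(x)
  cfg <- layer$cfg
  if (dim(x$v)[3] != cfg$in_channels)
    stop("lmds_block: input has ", dim(x$v)[3], " channels, expected ",
         cfg$in_channels)
  g <- forward(layer$children$ghost, x)
  a <- forward(layer$children$mix, channel_shuffle(g, cfg$shuffle_groups))
  b <- forward(layer$children$ddsc, g)
  if (!identical(dim(a$v), dim(b$v)))
    stop("lmds_block: branch shapes diverged at the Hadamard merge")
  merged <- dt_mul(a, b)
  forward(layer$children$deform, merged)
}
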