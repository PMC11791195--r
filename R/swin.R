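# Hierarchical shifted-window transformer track: patch partition/embedding,
# W-MSA / SW-MSA block pairs, patch merging, and the windowed-attention
# complexity calculator.

#' Swin track configuration
#'
#' @param img_size input image side (pixels; square inputs).
#' @param patch_size patch side in pixels (default 4).
#' @param embed_dim stage-one embedding width (doubles at each merge).
#' @param depths number of transformer blocks per stage (W-MSA/SW-MSA
#'   alternating; even entries give whole block pairs).
#' @param heads attention heads per stage.
#' @param window window side `M` in tokens.
#' @param mlp_ratio MLP expansion ratio.
#' @param qkv_bias bias on the qkv projection?
#' @param rpb include a relative position bias table (one `(2M-1)^2` table per
#'   block, shared across heads)?
#' @param patch_norm layer norm after patch embedding?
#' @param final_norm layer norm after the last stage?
#' @param merge_bias bias on the patch-merging reduction?
#' @param merge_norm layer norm inside patch merging?
#' @return a list of class `swin_config`.
#' @export
swin_config <- function(img_size = 224L, patch_size = 4L, embed_dim = 96L,
                        depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                        window = 7L, mlp_ratio = 4L, qkv_bias = TRUE,
                        rpb = TRUE, patch_norm = TRUE, final_norm = TRUE,
                        merge_bias = TRUE, merge_norm = FALSE) {
  if (length(depths) != length(heads))
    stop("swin_config: depths and heads must have the same length")
  structure(list(img_size = as.integer(img_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depths = as.integer(depths), heads = as.integer(heads),
                 window = as.integer(window), mlp_ratio = as.integer(mlp_ratio),
                 qkv_bias = qkv_bias, rpb = rpb, patch_norm = patch_norm,
                 final_norm = final_norm, merge_bias = merge_bias,
                 merge_norm = merge_norm),
            class = "swin_config")
}

# Apply a linear layer along the channel axis (axis 3) of an (H, W, C, N) map.
linear_channels <- function(x, layer) {
  d <- dim(x$v)
  xm <- dt_reshape(dt_aperm(x, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3]))
  y <- forward(layer, xm)
  cout <- layer$out_features
  dt_aperm(dt_reshape(y, c(d[1], d[2], d[4], cout)), c(1, 2, 4, 3))
}

# --------------------------------------------------------------- patch embed --

#' Patch partition + linear embedding
#'
#' Splits the image into non-overlapping `patch x patch` patches and linearly
#' embeds each patch's raw RGB values (a strided convolution), optionally
#' followed by layer normalization.
#'
#' @param in_channels image channels (3).
#' @param embed_dim token embedding width.
#' @param patch_size patch side.
#' @param patch_norm apply layer norm after embedding?
#' @return a layer mapping `(H, W, 3, N)` to `(H/p, W/p, embed_dim, N)`.
#' @export
patch_embed <- function(in_channels, embed_dim, patch_size = 4L,
                        patch_norm = TRUE) {
  children <- list(proj = nn_conv2d(in_channels, embed_dim, patch_size,
                                    stride = patch_size, padding = "valid"))
  if (patch_norm) children$norm <- nn_layernorm(embed_dim, axis = 3L)
  new_layer("patch_embed", patch_size = as.integer(patch_size),
            children = children)
}

#' @export
forward.patch_embed <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  p <- layer$patch_size
  if (d[1] %% p != 0 || d[2] %% p != 0)
    stop("patch_embed: image size ", d[1], "x", d[2],
         " is not divisible by the patch size ", p)
  tg <- forward(layer$children$proj, x)
  if (!is.null(layer$children$norm)) tg <- forward(layer$children$norm, tg)
  tg
}

# --------------------------------------------------------- window attention --

# Partition (Ht, Wt, C, N) into windows -> (M^2, nW, C, N); inverse with
# window_reverse.  Token t within a window is (row-major within columns):
# t = m_row + (m_col - 1) * M.
window_partition <- function(x, M) {
  d <- dim(x$v)
  nh <- d[1] %/% M; nw <- d[2] %/% M
  x <- dt_reshape(x, c(M, nh, M, nw, d[3], d[4]))
  x <- dt_aperm(x, c(1, 3, 2, 4, 5, 6))
  dt_reshape(x, c(M * M, nh * nw, d[3], d[4]))
}

window_reverse <- function(x, M, Ht, Wt) {
  d <- dim(x$v)
  nh <- Ht %/% M; nw <- Wt %/% M
  x <- dt_reshape(x, c(M, M, nh, nw, d[3], d[4]))
  x <- dt_aperm(x, c(1, 3, 2, 4, 5, 6))
  dt_reshape(x, c(Ht, Wt, d[3], d[4]))
}

# Relative-position index (T x T) into a (2M-1)^2 bias table.
rpb_index <- function(M) {
  pos <- expand.grid(r = seq_len(M), c = seq_len(M))
  T <- M * M
  idx <- matrix(0L, T, T)
  for (i in seq_len(T)) for (j in seq_len(T)) {
    dy <- pos$r[i] - pos$r[j] + M - 1L
    dx <- pos$c[i] - pos$c[j] + M - 1L
    idx[i, j] <- dy + dx * (2L * M - 1L) + 1L
  }
  idx
}

# Additive attention mask (T, T, nW) for the shifted configuration: -1e9
# where two tokens of a window originate from different image regions.
shift_mask <- function(Ht, Wt, M, shift) {
  ids <- matrix(0, Ht, Wt)
  hs <- list(seq_len(Ht - M), seq(Ht - M + 1, Ht - shift), seq(Ht - shift + 1, Ht))
  ws <- list(seq_len(Wt - M), seq(Wt - M + 1, Wt - shift), seq(Wt - shift + 1, Wt))
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    if (length(hs[[a]]) && length(ws[[b]])) ids[hs[[a]], ws[[b]]] <- k
    k <- k + 1
  }
  idt <- dt_tensor(array(ids, dim = c(Ht, Wt, 1, 1)))
  wid <- dt_value(window_partition(idt, M))           # (T, nW, 1, 1)
  T <- M * M; nW <- dim(wid)[2]
  mask <- array(0, dim = c(T, T, nW))
  for (w in seq_len(nW)) {
    v <- wid[, w, 1, 1]
    mask[, , w] <- ifelse(outer(v, v, `!=`), -1e9, 0)
  }
  mask
}

#' Window-based multi-head self-attention layer
#'
#' Multi-head self-attention restricted to `M x M` token windows; in shifted
#' mode the grid is cyclically shifted by `floor(M/2)` before windowing and
#' un-shifted afterwards, with an additive mask preventing attention across
#' original window boundaries.  If the window is larger than the grid it
#' degenerates to full-grid attention (window clipped to the grid).
#'
#' @param dim token embedding width.
#' @param heads number of attention heads (`dim` divisible by `heads`).
#' @param window window side `M`.
#' @param shifted use the shifted-window variant?
#' @param qkv_bias bias on the qkv projection?
#' @param rpb learnable relative position bias (shared across heads)?
#' @return a layer on `(Ht, Wt, C, N)` token grids.
#' @export
nn_wmsa <- function(dim, heads, window, shifted = FALSE, qkv_bias = TRUE,
                    rpb = TRUE) {
  if (dim %% heads != 0) stop("nn_wmsa: dim must be divisible by heads")
  params <- list()
  if (rpb) params$rpb_table <- param(array(0, (2L * window - 1L)^2))
  new_layer("nn_wmsa", dim = as.integer(dim), heads = as.integer(heads),
            window = as.integer(window), shifted = shifted, use_rpb = rpb,
            params = params,
            children = list(qkv = nn_linear(dim, 3L * dim, bias = qkv_bias),
                            proj = nn_linear(dim, dim)),
            last_attention = NULL)
}

#' @export
forward.nn_wmsa <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  Ht <- d[1]; Wt <- d[2]; C <- d[3]; N <- d[4]
  M <- min(layer$window, Ht, Wt)
  if (Ht %% M != 0 || Wt %% M != 0)
    stop("nn_wmsa: token grid ", Ht, "x", Wt, " not divisible by window ", M)
  h <- layer$heads
  dh <- C %/% h
  shift <- if (layer$shifted && (Ht > M || Wt > M)) M %/% 2L else 0L
  if (shift > 0) x <- dt_roll_hw(x, c(-shift, -shift))
  xw <- window_partition(x, M)                        # (T, nW, C, N)
  T <- M * M; nW <- (Ht %/% M) * (Wt %/% M)
  xt <- dt_reshape(dt_aperm(xw, c(1, 2, 4, 3)), c(T * nW * N, C))
  qkv <- forward(layer$children$qkv, xt)              # (T*nW*N, 3C)
  qkv <- dt_reshape(qkv, c(T, nW, N, 3L * C))
  split_head <- function(cols) {
    q <- dt_take(qkv, cols, 4L)                       # (T, nW, N, C)
    q <- dt_reshape(q, c(T, nW, N, dh, h))
    q <- dt_aperm(q, c(1, 4, 5, 2, 3))                # (T, dh, h, nW, N)
    dt_reshape(q, c(T, dh, h * nW * N))
  }
  q <- split_head(seq_len(C))
  k <- split_head(C + seq_len(C))
  v <- split_head(2L * C + seq_len(C))
  s <- dt_scale(dt_bmm(q, k, transpose_b = TRUE), 1 / sqrt(dh))  # (T,T,B)
  if (layer$use_rpb) {
    bias <- dt_take(layer$params$rpb_table, as.vector(rpb_index(M)), 1L)
    s <- dt_add(s, dt_reshape(bias, c(T, T, 1L)))
  }
  if (shift > 0) {
    mask <- shift_mask(Ht, Wt, M, shift)              # (T, T, nW)
    s5 <- dt_reshape(s, c(T, T, h, nW, N))
    s5 <- dt_add(s5, dt_tensor(array(mask, dim = c(T, T, 1L, nW, 1L))))
    s <- dt_reshape(s5, c(T, T, h * nW * N))
  }
  attn <- dt_softmax(s, 2L)
  layer$last_attention <- dt_value(attn)
  out <- dt_bmm(attn, v)                              # (T, dh, B)
  out <- dt_reshape(out, c(T, dh, h, nW, N))
  out <- dt_aperm(out, c(1, 4, 5, 2, 3))              # (T, nW, N, dh, h)
  out <- dt_reshape(out, c(T * nW * N, C))
  out <- forward(layer$children$proj, out)
  out <- dt_reshape(out, c(T, nW, N, C))
  out <- dt_aperm(out, c(1, 2, 4, 3))                 # (T, nW, C, N)
  y <- window_reverse(out, M, Ht, Wt)
  if (shift > 0) y <- dt_roll_hw(y, c(shift, shift))
  y
}

# ------------------------------------------------------------- swin blocks --

#' One transformer block (LN -> (S)W-MSA -> residual, LN -> MLP -> residual)
#'
#' @param dim,heads,window,shifted,qkv_bias,rpb see [nn_wmsa()].
#' @param mlp_ratio hidden expansion of the two-layer GELU MLP.
#' @return a layer.
#' @export
nn_swin_block <- function(dim, heads, window, shifted = FALSE, mlp_ratio = 4L,
                          qkv_bias = TRUE, rpb = TRUE) {
  new_layer("nn_swin_block", dim = as.integer(dim),
            children = list(
              ln1 = nn_layernorm(dim, axis = 3L),
              attn = nn_wmsa(dim, heads, window, shifted, qkv_bias, rpb),
              ln2 = nn_layernorm(dim, axis = 3L),
              fc1 = nn_linear(dim, dim * mlp_ratio),
              fc2 = nn_linear(dim * mlp_ratio, dim)))
}

#' @export
forward.nn_swin_block <- function(layer, x, ...) {
  x <- as_dt(x)
  a <- forward(layer$children$attn, forward(layer$children$ln1, x))
  x <- dt_add(x, a)
  m <- linear_channels(forward(layer$children$ln2, x), layer$children$fc1)
  m <- linear_channels(dt_gelu(m), layer$children$fc2)
  dt_add(x, m)
}

#' W-MSA / SW-MSA block pair
#'
#' Two consecutive transformer blocks sharing a stage configuration, the
#' first with regular and the second with shifted windows — the canonical
#' residual structure
#' `z_hat = WMSA(LN(z)) + z; z = MLP(LN(z_hat)) + z_hat` followed by the same
#' with SW-MSA.
#'
#' @inheritParams nn_swin_block
#' @return a layer.
#' @export
swin_block_pair <- function(dim, heads, window, mlp_ratio = 4L,
                            qkv_bias = TRUE, rpb = TRUE) {
  new_layer("swin_block_pair",
            children = list(
              b1 = nn_swin_block(dim, heads, window, FALSE, mlp_ratio,
                                 qkv_bias, rpb),
              b2 = nn_swin_block(dim, heads, window, TRUE, mlp_ratio,
                                 qkv_bias, rpb)))
}

#' @export
forward.swin_block_pair <- function(layer, x, ...) {
  forward(layer$children$b2, forward(layer$children$b1, x))
}

# ------------------------------------------------------------ patch merging --

#' Patch merging
#'
#' Concatenates each 2x2 neighborhood of tokens (4C channels) and linearly
#' reduces it to 2C, quartering the token count and halving each spatial
#' dimension.
#'
#' @param dim input embedding width `C`.
#' @param bias bias on the reduction?
#' @param norm layer norm on the concatenated 4C features?
#' @return a layer.
#' @export
patch_merging <- function(dim, bias = TRUE, norm = FALSE) {
  children <- list(reduction = nn_linear(4L * dim, 2L * dim, bias = bias))
  if (norm) children$norm <- nn_layernorm(4L * dim, axis = 3L)
  new_layer("patch_merging", dim = as.integer(dim), children = children)
}

#' @export
forward.patch_merging <- function(layer, x, ...) {
  x <- as_dt(x)
  d <- dim(x$v)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    stop("patch_merging: token grid ", d[1], "x", d[2], " must be even")
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  x00 <- dt_take(dt_take(x, ro, 1L), co, 2L)
  x10 <- dt_take(dt_take(x, re, 1L), co, 2L)
  x01 <- dt_take(dt_take(x, ro, 1L), ce, 2L)
  x11 <- dt_take(dt_take(x, re, 1L), ce, 2L)
  cat4 <- dt_concat(list(x00, x10, x01, x11), 3L)
  if (!is.null(layer$children$norm)) cat4 <- forward(layer$children$norm, cat4)
  linear_channels(cat4, layer$children$reduction)
}

# --------------------------------------------------------------- full track --

#' Swin transformer track
#'
#' Four hierarchical stages of W-MSA/SW-MSA blocks with patch merging between
#' stages.  Under the reference configuration a `224 x 224 x 3` image yields a
#' `7 x 7 x 768` feature map (resolutions H/4, H/8, H/16, H/32; width doubling
#' per stage).
#'
#' @param cfg a [swin_config()].
#' @return a layer.
#' @export
swin_track <- function(cfg) {
  stopifnot(inherits(cfg, "swin_config"))
  ns <- length(cfg$depths)
  children <- list(embed = patch_embed(3L, cfg$embed_dim, cfg$patch_size,
                                       cfg$patch_norm))
  dim_i <- cfg$embed_dim
  for (s in seq_len(ns)) {
    for (b in seq_len(cfg$depths[s])) {
      children[[sprintf("s%d_b%d", s, b)]] <-
        nn_swin_block(dim_i, cfg$heads[s], cfg$window, shifted = (b %% 2 == 0),
                      mlp_ratio = cfg$mlp_ratio, qkv_bias = cfg$qkv_bias,
                      rpb = cfg$rpb)
    }
    if (s < ns) {
      children[[sprintf("merge%d", s)]] <- patch_merging(dim_i, cfg$merge_bias,
                                                         cfg$merge_norm)
      dim_i <- dim_i * 2L
    }
  }
  if (cfg$final_norm) children$norm <- nn_layernorm(dim_i, axis = 3L)
  new_layer("swin_track", cfg = cfg, out_channels = dim_i, children = children)
}

#' @export
forward.swin_track <- function(layer, x, ...) {
  x <- as_dt(x)
  cfg <- layer$cfg
  d <- dim(x$v)
  ns <- length(cfg$depths)
  for (ax in 1:2) {
    g <- d[ax]
    if (g %% cfg$patch_size != 0)
      stop("swin_track: input size ", d[1], "x", d[2],
           " is not divisible by the patch size ", cfg$patch_size)
    g <- g %/% cfg$patch_size
    for (s in seq_len(ns)) {
      M <- min(cfg$window, g)
      if (g %% M != 0)
        stop("swin_track: stage ", s, " token grid ", g,
             " is not divisible by the window size ", M,
             "; use an input size of the form patch*window*2^(stages-1)*k")
      if (s < ns) {
        if (g %% 2L != 0)
          stop("swin_track: stage ", s, " token grid ", g,
               " is odd and cannot be patch-merged")
        g <- g %/% 2L
      }
    }
  }
  tg <- forward(layer$children$embed, x)
  ns <- length(cfg$depths)
  for (s in seq_len(ns)) {
    for (b in seq_len(cfg$depths[s]))
      tg <- forward(layer$children[[sprintf("s%d_b%d", s, b)]], tg)
    if (s < ns) tg <- forward(layer$children[[sprintf("merge%d", s)]], tg)
  }
  if (!is.null(layer$children$norm)) tg <- forward(layer$children$norm, tg)
  tg
}

# --------------------------------------------------------------- complexity --

#' Windowed-attention computational complexity
#'
#' Returns `4*h*w*C^2 + 2*M^2*h*w*C`, the floating-point cost of window-based
#' multi-head self-attention over an `h x w` token grid of width `C` with
#' `M x M` windows.
#'
#' @param h,w token grid dimensions.
#' @param C channel (embedding) width.
#' @param M window side.
#' @return the complexity as a (double-precision) count.
#' @export
wmsa_complexity <- function(h, w, C, M) {
  vals <- c(h = h, w = w, C = C, M = M)
  if (any(vals <= 0) || any(vals != floor(vals)))
    stop("wmsa_complexity: h, w, C, M must be positive integers")
  4 * h * w * C^2 + 2 * M^2 * h * w * C
}
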