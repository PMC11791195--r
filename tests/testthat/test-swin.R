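# Shifted-window transformer track: embedding, window attention and masking,
# residual block structure, patch merging, and the complexity calculator.

test_that("patch embedding: grid arithmetic and constant-image tokens", {
  set.seed(401)
  pe <- patch_embed(3, 16, 4)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  tg <- dt_value(forward(pe, x))
  expect_identical(dim(tg), c(8L, 8L, 16L, 2L))
  # 224 / 4 = 56 tokens per side under the reference patch size
  expect_identical(224L %/% 4L, 56L)
  # constant image: all tokens identical
  pe2 <- patch_embed(3, 8, 4, patch_norm = FALSE)
  tc <- dt_value(forward(pe2, array(0.7, c(8, 8, 3, 1))))
  expect_lt(max(abs(sweep(matrix(tc, 4, 8), 2, tc[1, 1, , 1]))), 1e-12)
  expect_error(forward(pe, array(0, c(30, 30, 3, 1))), "divisible")
  # embedding weights receive gradient
  xg <- dt_tensor(x, requires_grad = FALSE)
  o <- forward(pe, xg)
  dt_backward(dt_sum(dt_mul(o, o)))
  expect_false(is.null(dt_grad(pe$children$proj$params$weight)))
})

test_that("window attention rows sum to one; shifted masking blocks crossings", {
  set.seed(402)
  tg <- dt_tensor(array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2)))
  wm <- nn_wmsa(16, 4, 4, shifted = FALSE)
  o <- forward(wm, tg)
  expect_identical(dim(dt_value(o)), dim(dt_value(tg)))
  expect_lt(max(abs(apply(wm$last_attention, c(1, 3), sum) - 1)), 1e-6)
  # shifted: cross-region attention mass below 1e-8
  wms <- nn_wmsa(16, 4, 4, shifted = TRUE)
  invisible(forward(wms, tg))
  at <- wms$last_attention
  msk <- dfunet:::shift_mask(8, 8, 4, 2)
  dim(at) <- c(16, 16, 4, 4, 2)          # (T, T, heads, windows, batch)
  worst <- 0
  for (w in 1:4) {
    blocked <- msk[, , w] < 0
    if (!any(blocked)) next
    for (h in 1:4) for (n in 1:2)
      worst <- max(worst, max(at[, , h, w, n][blocked]))
  }
  expect_lt(worst, 1e-8)
})

test_that("single-window grids make shifted and unshifted attention coincide", {
  set.seed(403)
  tg <- dt_tensor(array(rnorm(4 * 4 * 16), c(4, 4, 16, 1)))
  a <- nn_wmsa(16, 4, 4, shifted = FALSE)
  b <- nn_wmsa(16, 4, 4, shifted = TRUE)
  copy_layer_params(a, b)
  expect_equal(dt_value(forward(a, tg)), dt_value(forward(b, tg)),
               tolerance = 1e-12)
})

test_that("block pair has the exact residual structure", {
  set.seed(404)
  tg <- dt_tensor(array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2)))
  bp <- swin_block_pair(16, 4, 4)
  # zero attention/MLP output projections: the pair is the identity map
  for (b in c("b1", "b2")) {
    blk <- bp$children[[b]]
    blk$children$attn$children$proj$params$weight$v[] <- 0
    blk$children$attn$children$proj$params$bias$v[] <- 0
    blk$children$fc2$params$weight$v[] <- 0
    blk$children$fc2$params$bias$v[] <- 0
  }
  expect_equal(dt_value(forward(bp, tg)), dt_value(tg), tolerance = 1e-12)
  # shape preservation with active parameters
  bp2 <- swin_block_pair(16, 4, 4)
  expect_identical(dim(dt_value(forward(bp2, tg))), dim(dt_value(tg)))
})

test_that("single-token grid reduces the block equations to LN/MLP algebra", {
  set.seed(405)
  blk <- nn_swin_block(2, 1, 1, shifted = FALSE, mlp_ratio = 2, rpb = FALSE)
  z <- array(c(0.4, -1.2), c(1, 1, 2, 1))
  got <- dt_value(forward(blk, z))
  # hand evaluation: attention of one token with itself returns v; then the
  # two residual equations
  ln <- function(v, g, b) ((v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)) * g + b
  p <- function(l) dt_value(l$params$weight)
  bias <- function(l) dt_value(l$params$bias)
  z0 <- as.numeric(z)
  h <- ln(z0, dt_value(blk$children$ln1$params$gamma), dt_value(blk$children$ln1$params$beta))
  qkv <- as.numeric(h %*% p(blk$children$attn$children$qkv)) +
    bias(blk$children$attn$children$qkv)
  v <- qkv[5:6]                       # softmax over a single key is 1
  attn_out <- as.numeric(v %*% p(blk$children$attn$children$proj)) +
    bias(blk$children$attn$children$proj)
  z1 <- z0 + attn_out
  h2 <- ln(z1, dt_value(blk$children$ln2$params$gamma), dt_value(blk$children$ln2$params$beta))
  gelu <- function(u) u * pnorm(u)
  m <- gelu(as.numeric(h2 %*% p(blk$children$fc1)) + bias(blk$children$fc1))
  z2 <- z1 + as.numeric(m %*% p(blk$children$fc2)) + bias(blk$children$fc2)
  expect_equal(as.numeric(got), as.numeric(z2), tolerance = 1e-10)
})

test_that("patch merging quarters tokens and doubles the width", {
  set.seed(406)
  tg <- dt_tensor(array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2)))
  pm <- patch_merging(16)
  o <- dt_value(forward(pm, tg))
  expect_identical(dim(o), c(4L, 4L, 32L, 2L))
  # 56x56x96 -> 28x28x192 at the reference scale (token count / 4)
  expect_identical((56L * 56L) %/% 4L, 28L * 28L)
  # constant 2x2 neighborhoods: output is a linear map of one repeated vector
  tc <- array(0, c(4, 4, 4, 1))
  vrep <- rnorm(4)
  for (c in 1:4) tc[, , c, 1] <- vrep[c]
  pm2 <- patch_merging(4)
  W <- dt_value(pm2$children$reduction$params$weight)
  b <- dt_value(pm2$children$reduction$params$bias)
  expect_equal(as.numeric(dt_value(forward(pm2, tc))[1, 1, , 1]),
               as.numeric(rep(vrep, 4) %*% W) + as.numeric(b),
               tolerance = 1e-12)
  expect_error(forward(pm, dt_tensor(array(0, c(5, 4, 16, 1)))), "even")
})

test_that("full track bookkeeping: stage resolutions and output width", {
  set.seed(407)
  cfgt <- swin_config(img_size = 32, patch_size = 4, embed_dim = 8,
                      depths = c(2, 2, 2, 2), heads = c(2, 2, 4, 4), window = 2)
  trk <- swin_track(cfgt)
  x <- array(runif(32 * 32 * 3 * 2, -1, 1), c(32, 32, 3, 2))
  o <- dt_value(forward(trk, x))
  expect_identical(dim(o), c(1L, 1L, 64L, 2L))   # H/32, width 8*2^3
  expect_true(all(is.finite(o)))
  # indivisible input: rejected with a clear error
  expect_error(forward(trk, array(0, c(24, 24, 3, 1))), "window|merged")
  # with all residual projections zeroed the track stays finite/correct
  trk0 <- swin_track(cfgt)
  for (nm in names(trk0$children)) {
    ch <- trk0$children[[nm]]
    if (inherits(ch, "nn_swin_block")) {
      ch$children$attn$children$proj$params$weight$v[] <- 0
      ch$children$attn$children$proj$params$bias$v[] <- 0
      ch$children$fc2$params$weight$v[] <- 0
      ch$children$fc2$params$bias$v[] <- 0
    }
  }
  o0 <- dt_value(forward(trk0, x))
  expect_identical(dim(o0), c(1L, 1L, 64L, 2L))
  expect_true(all(is.finite(o0)))
})

test_that("reference track parameter count matches the published track size", {
  n <- count_parameters(build_variant("swin"))
  expect_equal(n, 27512560)
})

test_that("complexity calculator: closed form and shape-based oracle", {
  expect_equal(wmsa_complexity(1, 1, 1, 1), 6)
  # doubling C more than doubles the cost (quadratic term dominates)
  expect_gt(wmsa_complexity(8, 8, 64, 4), 2 * wmsa_complexity(8, 8, 32, 4))
  # shape-based FLOP oracle: per window, qkv/proj projections cost
  # 4*M^2*C^2 mults and the two attention matrix products 2*M^4*C; summed
  # over (h*w)/M^2 windows this is 4*h*w*C^2 + 2*M^2*h*w*C
  flops_oracle <- function(h, w, C, M) {
    n_win <- (h * w) / M^2
    per_win <- 4 * M^2 * C^2 + 2 * M^4 * C
    n_win * per_win
  }
  for (case in list(c(56, 56, 96, 7), c(8, 8, 32, 4), c(14, 14, 192, 7)))
    expect_equal(wmsa_complexity(case[1], case[2], case[3], case[4]),
                 flops_oracle(case[1], case[2], case[3], case[4]))
  expect_error(wmsa_complexity(0, 1, 1, 1), "positive")
})
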