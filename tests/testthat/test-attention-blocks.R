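# GDA components (GCB, DCLS, CA) and shuffle attention, each checked against
# literal loop-based evaluations of their defining equations.

test_that("GCB attention weights are a softmax over positions", {
  set.seed(301)
  gcb <- gcb_block(4, reduction = 2)
  # hand-set logits via the 1x1 conv on a 1x2 grid
  x <- array(0, c(1, 2, 4, 1))
  gcb$children$wk$params$weight$v[] <- 0
  gcb$children$wk$params$bias$v[] <- 0
  a <- dt_value(gcb_attention_weights(x, gcb))
  expect_equal(as.numeric(a), c(0.5, 0.5))
  # logits (ln 2, 0) -> weights (2/3, 1/3)
  gcb$children$wk$params$weight$v[1, 1, 1, 1] <- log(2)
  x[1, 1, 1, 1] <- 1
  a <- dt_value(gcb_attention_weights(x, gcb))
  expect_equal(as.numeric(a), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # random input: matches an exhaustive position-by-position softmax
  gcb2 <- gcb_block(4, reduction = 2)
  xr <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  a2 <- dt_value(gcb_attention_weights(xr, gcb2))
  wk <- dt_value(gcb2$children$wk$params$weight)
  wkb <- dt_value(gcb2$children$wk$params$bias)
  for (n in 1:2) {
    lo <- numeric(9)
    for (j in 1:3) for (i in 1:3)
      lo[i + (j - 1) * 3] <- sum(wk[1, 1, , 1] * xr[i, j, , n]) + wkb[1]
    expect_equal(as.numeric(a2[, 1, n]), exp(lo) / sum(exp(lo)),
                 tolerance = 1e-12)
  }
  # weights sum to one on randomized inputs
  for (rep in 1:5) {
    xr <- array(rnorm(4 * 5 * 4 * 3), c(4, 5, 4, 3))
    s <- apply(dt_value(gcb_attention_weights(xr, gcb2)), 3, sum)
    expect_lt(max(abs(s - 1)), 1e-6)
  }
})

test_that("GCB forward matches a loop evaluation of the bottleneck transform", {
  set.seed(302)
  gcb <- gcb_block(4, reduction = 2)
  x <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  got <- dt_value(forward(gcb, x))
  wk <- dt_value(gcb$children$wk$params$weight); wkb <- dt_value(gcb$children$wk$params$bias)
  wv1 <- dt_value(gcb$children$wv1$params$weight); wv1b <- dt_value(gcb$children$wv1$params$bias)
  lng <- dt_value(gcb$children$ln$params$gamma); lnb <- dt_value(gcb$children$ln$params$beta)
  wv2 <- dt_value(gcb$children$wv2$params$weight); wv2b <- dt_value(gcb$children$wv2$params$bias)
  ref <- x
  for (n in 1:2) {
    logit <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      logit[i, j] <- sum(wk[1, 1, , 1] * x[i, j, , n]) + wkb[1]
    al <- exp(logit); al <- al / sum(al)
    z <- numeric(4)
    for (i in 1:3) for (j in 1:3) z <- z + al[i, j] * x[i, j, , n]
    t1 <- as.vector(t(matrix(wv1[1, 1, , ], 4, 2)) %*% z) + wv1b
    mu <- mean(t1); v <- mean((t1 - mu)^2)
    t2 <- pmax(0, ((t1 - mu) / sqrt(v + 1e-5)) * lng + lnb)
    dl <- as.vector(t(matrix(wv2[1, 1, , ], 2, 4)) %*% t2) + wv2b
    for (i in 1:3) for (j in 1:3) ref[i, j, , n] <- x[i, j, , n] + dl
  }
  expect_equal(got, ref, tolerance = 1e-10)
  # constant input: the context vector is the constant (convexity)
  xc <- array(0, c(4, 4, 4, 1))
  for (c in 1:4) xc[, , c, ] <- c
  a <- dt_value(gcb_attention_weights(xc, gcb))
  z <- sapply(1:4, function(c) sum(a[, 1, 1] * xc[1, 1, c, 1]))
  expect_equal(z, 1:4, tolerance = 1e-12)
  # W_v2 = 0: output equals input exactly
  gcb$children$wv2$params$weight$v[] <- 0
  gcb$children$wv2$params$bias$v[] <- 0
  expect_identical(dt_value(forward(gcb, x)), x)
})

test_that("DCLS equals a standard convolution on frozen grid positions", {
  set.seed(303)
  dc <- dcls_block(3, n_elements = 9, extent = 3)
  P <- as.matrix(expand.grid(0:2, 0:2))
  dc$params$positions$v <- t(P)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  got <- dt_value(forward(dc, x))
  cv <- nn_conv2d(3, 3, 3)
  Wd <- array(0, c(3, 3, 3, 3))
  for (e in 1:9) Wd[P[e, 1] + 1, P[e, 2] + 1, , ] <- dt_value(dc$params$weight)[e, , ]
  cv$params$weight$v <- Wd
  cv$params$bias$v <- array(dt_value(dc$params$bias), 3)
  expect_equal(got, dt_value(forward(cv, x)), tolerance = 1e-5)
  # frozen positions on a dilation-2 grid reproduce a dilated convolution
  dc5 <- dcls_block(2, n_elements = 9, extent = 5)
  P5 <- as.matrix(expand.grid(c(0, 2, 4), c(0, 2, 4)))
  dc5$params$positions$v <- t(P5)
  cv5 <- nn_conv2d(2, 2, 3, dilation = 2)
  W5 <- array(0, c(3, 3, 2, 2))
  for (e in 1:9) W5[P5[e, 1] / 2 + 1, P5[e, 2] / 2 + 1, , ] <-
    dt_value(dc5$params$weight)[e, , ]
  cv5$params$weight$v <- W5
  cv5$params$bias$v <- array(dt_value(dc5$params$bias), 2)
  x5 <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  expect_equal(dt_value(forward(dc5, x5)), dt_value(forward(cv5, x5)),
               tolerance = 1e-5)
})

test_that("DCLS: identity element and trainable positions", {
  # a single center element with an identity channel map is the identity
  dc <- dcls_block(3, n_elements = 1, extent = 7)
  dc$params$positions$v <- matrix(c(3, 3), 2, 1)
  dc$params$weight$v[1, , ] <- diag(3)
  dc$params$bias$v[] <- 0
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3, 1))
  expect_equal(dt_value(forward(dc, x)), x, tolerance = 1e-12)
  # position gradients are non-zero for a non-constant input and match
  # finite differences
  set.seed(304)
  dc2 <- dcls_block(3, n_elements = 4, extent = 5)
  xg <- dt_tensor(array(rnorm(5 * 5 * 3), c(5, 5, 3, 1)), requires_grad = TRUE)
  fn <- function() { o <- forward(dc2, xg); dt_sum(dt_mul(o, o)) }
  expect_true(isTRUE(fd_gradient_check(fn, c(list(xg), dc2$params))))
  dt_tape_reset()
  dt_backward(fn())
  expect_gt(max(abs(dt_grad(dc2$params$positions))), 0)
})

test_that("coordinate attention matches a loop evaluation and is a contraction", {
  set.seed(305)
  ca <- coord_attention(8, reduction = 2)
  set_train(ca, FALSE)
  x <- array(rnorm(4 * 5 * 8 * 1), c(4, 5, 8, 1))
  got <- dt_value(forward(ca, x))
  f1 <- dt_value(ca$children$f1$params$weight); f1b <- dt_value(ca$children$f1$params$bias)
  fhW <- dt_value(ca$children$fh$params$weight); fhb <- dt_value(ca$children$fh$params$bias)
  fwW <- dt_value(ca$children$fw$params$weight); fwb <- dt_value(ca$children$fw$params$bias)
  hsw <- function(v) v * pmin(pmax(v + 3, 0), 6) / 6
  sig <- function(v) 1 / (1 + exp(-v))
  zh <- apply(x[, , , 1], c(1, 3), mean)      # directional pooled profiles
  zw <- apply(x[, , , 1], c(2, 3), mean)
  f <- sweep(rbind(zh, zw) %*% matrix(f1[1, 1, , ], 8, 4), 2, f1b, "+")
  f <- sweep(sweep(f, 2, ca$children$bn$running_mean), 2,
             sqrt(ca$children$bn$running_var + 1e-5), "/")
  f <- hsw(f)
  gh <- sig(sweep(f[1:4, , drop = FALSE] %*% matrix(fhW[1, 1, , ], 4, 8), 2, fhb, "+"))
  gw <- sig(sweep(f[5:9, , drop = FALSE] %*% matrix(fwW[1, 1, , ], 4, 8), 2, fwb, "+"))
  ref <- x
  for (i in 1:4) for (j in 1:5) for (c in 1:8)
    ref[i, j, c, 1] <- x[i, j, c, 1] * gh[i, c] * gw[j, c]
  expect_equal(got, ref, tolerance = 1e-10)
  # |out| <= |in| element-wise (product of sigmoid gates)
  expect_true(all(abs(got) <= abs(x)))
  # constant input: pooled profiles are the constant
  xc <- array(2.5, c(3, 4, 8, 1))
  expect_equal(unname(apply(xc[, , , 1], c(1, 3), mean)),
               matrix(2.5, 3, 8))
})

test_that("shuffle attention matches a loop evaluation of its two gates", {
  set.seed(306)
  sa <- sa_block(12, groups = 2)
  sa$params$cw$v[] <- rnorm(3); sa$params$cb$v[] <- rnorm(3)
  sa$params$sw$v[] <- rnorm(3); sa$params$sb$v[] <- rnorm(3)
  x <- array(rnorm(5 * 5 * 12 * 2), c(5, 5, 12, 2))
  got <- dt_value(forward(sa, x))
  sig <- function(v) 1 / (1 + exp(-v))
  gng <- dt_value(sa$children$gn$params$gamma)
  gnb <- dt_value(sa$children$gn$params$beta)
  pre <- array(0, dim(x))
  for (n in 1:2) for (g in 1:2) {
    base <- (g - 1) * 6
    for (c in 1:3) {
      x1 <- x[, , base + c, n]
      s <- mean(x1)
      pre[, , base + c, n] <-
        x1 * sig(dt_value(sa$params$cw)[c] * s + dt_value(sa$params$cb)[c])
      x2 <- x[, , base + 3 + c, n]
      m <- mean(x2); v <- mean((x2 - m)^2)
      gn <- ((x2 - m) / sqrt(v + 1e-5)) * gng[c] + gnb[c]
      pre[, , base + 3 + c, n] <-
        x2 * sig(dt_value(sa$params$sw)[c] * gn + dt_value(sa$params$sb)[c])
    }
  }
  ref <- pre[, , shuffle_index(12, 2), , drop = FALSE]
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("shuffle attention: saturated gates give a pure channel permutation", {
  sa <- sa_block(12, groups = 2)
  sa$params$cw$v[] <- 0; sa$params$sw$v[] <- 0
  sa$params$cb$v[] <- 40; sa$params$sb$v[] <- 40     # sigmoid ~ 1
  x <- array(rnorm(4 * 4 * 12), c(4, 4, 12, 1))
  got <- dt_value(forward(sa, x))
  expect_equal(got, x[, , shuffle_index(12, 2), , drop = FALSE],
               tolerance = 1e-12)
})

test_that("shuffle attention owns 3C/G parameters; 918 at the fused width", {
  expect_equal(count_parameters(sa_block(12, 2)), 3 * 12 / 2)
  expect_equal(count_parameters(sa_block(24, 3)), 3 * 24 / 3)
  expect_equal(count_parameters(sa_block(918, 3)), 918)
  expect_error(sa_block(10, 4), "valid group counts")
})

test_that("GDA block composes shape-preservingly and trains end to end", {
  set.seed(307)
  for (C in c(6, 12)) {
    gda <- gda_block(C, 2, 2, 4, 5)
    x <- array(runif(7 * 7 * C * 2, -1, 1), c(7, 7, C, 2))
    o <- dt_value(forward(gda, x))
    expect_identical(dim(o), dim(x))
    expect_true(all(is.finite(o)))
  }
  gda <- gda_block(6, 2, 2, 4, 5)
  xg <- dt_tensor(array(rnorm(7 * 7 * 6 * 2), c(7, 7, 6, 2)), requires_grad = TRUE)
  dt_backward(dt_sum(dt_mul(forward(gda, xg), forward(gda, xg))))
  ps <- parameters(gda)
  expect_true(all(!vapply(ps, function(p) is.null(dt_grad(p)), logical(1))))
})

test_that("GDA with identity-configured sub-blocks is the identity", {
  gda <- gda_block(3, 2, 2, 1, 7)
  gda$children$gcb$children$wv2$params$weight$v[] <- 0
  gda$children$gcb$children$wv2$params$bias$v[] <- 0
  gda$children$dcls$params$positions$v <- matrix(c(3, 3), 2, 1)
  gda$children$dcls$params$weight$v[1, , ] <- diag(3)
  gda$children$dcls$params$bias$v[] <- 0
  gda$children$ca$children$fh$params$weight$v[] <- 0
  gda$children$ca$children$fw$params$weight$v[] <- 0
  gda$children$ca$children$fh$params$bias$v[] <- 40   # saturated gates
  gda$children$ca$children$fw$params$bias$v[] <- 40
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3, 1))
  expect_equal(dt_value(forward(gda, x)), x, tolerance = 1e-9)
})

test_that("attention operators preserve batch independence", {
  set.seed(308)
  x <- array(rnorm(5 * 5 * 12 * 3), c(5, 5, 12, 3))
  perm <- c(3, 1, 2)
  for (build in list(function() gcb_block(12, 4),
                     function() coord_attention(12, 4),
                     function() sa_block(12, 2))) {
    l <- build()
    set_train(l, FALSE)
    o1 <- dt_value(forward(l, x))
    o2 <- dt_value(forward(l, x[, , , perm, drop = FALSE]))
    expect_equal(o2, o1[, , , perm, drop = FALSE], tolerance = 1e-12)
  }
})
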