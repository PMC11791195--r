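# Compact tape-based reverse-mode automatic differentiation on dense R arrays.
#
# A tensor is an environment holding a numeric array (`v`), an accumulated
# gradient (`grad`), and a `requires` flag.  Every differentiable operation
# pushes a node onto a global tape; `dt_backward()` walks the tape in reverse
# and accumulates gradients into every tensor that requires them (including
# intermediates, which Grad-CAM relies on).

.dt <- new.env(parent = emptyenv())
.dt$tape <- list()
.dt$n <- 0L
.dt$enabled <- TRUE

#' Create a tensor
#'
#' Wraps a numeric array (or vector/matrix) as an autograd tensor.
#'
#' @param x numeric array.
#' @param requires_grad should gradients be accumulated for this tensor?
#' @return an object of class `dt_tensor`.
#' @export
dt_tensor <- function(x, requires_grad = FALSE) {
  if (is.null(dim(x))) x <- array(as.numeric(x), dim = length(x))
  e <- new.env(parent = emptyenv())
  e$v <- x
  e$grad <- NULL
  e$requires <- isTRUE(requires_grad)
  class(e) <- "dt_tensor"
  e
}

#' @export
print.dt_tensor <- function(x, ...) {
  cat("<dt_tensor dim=[", paste(dim(x$v), collapse = ","),
      "] requires_grad=", x$requires, ">\n", sep = "")
  invisible(x)
}

is_dt <- function(x) inherits(x, "dt_tensor")

as_dt <- function(x) if (is_dt(x)) x else dt_tensor(x)

#' Extract the value of a tensor
#' @param x a `dt_tensor` (plain arrays pass through).
#' @return the underlying numeric array.
#' @export
dt_value <- function(x) if (is_dt(x)) x$v else x

#' Extract the accumulated gradient of a tensor
#' @param x a `dt_tensor`.
#' @return gradient array, or `NULL` if none has been accumulated.
#' @export
dt_grad <- function(x) x$grad

#' Zero the gradient of one tensor
#' @param x a `dt_tensor`.
#' @export
dt_zero_grad <- function(x) {
  x$grad <- NULL
  invisible(x)
}

#' Evaluate an expression without recording gradients
#'
#' Used for evaluation-mode forward passes; no tape nodes are created inside.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
dt_no_grad <- function(expr) {
  old <- .dt$enabled
  .dt$enabled <- FALSE
  on.exit(.dt$enabled <- old)
  force(expr)
}

dt_tape_reset <- function() {
  .dt$tape <- list()
  .dt$n <- 0L
  invisible(NULL)
}

# Register a differentiable op.  `backward` receives the output gradient and
# must return a list of gradients aligned with `inputs` (NULL allowed for
# inputs that do not require grad).
dt_op <- function(value, inputs, backward) {
  req <- .dt$enabled && any(vapply(inputs, function(t) t$requires, logical(1)))
  out <- dt_tensor(value, requires_grad = req)
  if (req) {
    .dt$n <- .dt$n + 1L
    .dt$tape[[.dt$n]] <- list(inputs = inputs, output = out, backward = backward)
  }
  out
}

#' Run backpropagation from a scalar tensor
#'
#' Accumulates gradients into every tensor on the tape that requires them,
#' then clears the tape.
#'
#' @param loss a scalar `dt_tensor`.
#' @param grad optional seed gradient (defaults to 1).
#' @export
dt_backward <- function(loss, grad = NULL) {
  if (!is_dt(loss)) stop("dt_backward() needs a dt_tensor")
  if (is.null(grad)) grad <- array(1, dim = dim(loss$v))
  acc_grad(loss, grad)
  if (.dt$n > 0L) {
    for (i in seq(.dt$n, 1L)) {
      node <- .dt$tape[[i]]
      g <- node$output$grad
      if (is.null(g)) next
      gs <- node$backward(g)
      for (j in seq_along(node$inputs)) {
        inp <- node$inputs[[j]]
        if (inp$requires && !is.null(gs[[j]])) acc_grad(inp, gs[[j]])
      }
    }
  }
  dt_tape_reset()
  invisible(NULL)
}

acc_grad <- function(t, g) {
  if (!identical(dim(t$v), dim(g))) dim(g) <- dim(t$v)
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(NULL)
}

# ---------------------------------------------------------------- helpers --

# Sum an array over the axes where `target_dim` is 1, keeping dims.
reduce_to <- function(g, target_dim) {
  d <- dim(g)
  for (ax in seq_along(d)) {
    if (target_dim[ax] == 1L && d[ax] > 1L) {
      perm <- c(ax, seq_along(d)[-ax])
      m <- colSums(matrix(aperm(g, perm), nrow = d[ax]))
      g <- aperm(array(m, dim = c(1L, d[perm[-1]])), order(perm))
      d[ax] <- 1L
    }
  }
  g
}

# Materialize a broadcast of `g` (dims with 1s) to full dims `d`.
expand_to <- function(g, d) {
  gd <- dim(g)
  if (identical(gd, d)) return(g)
  idx <- lapply(seq_along(d), function(ax) if (gd[ax] == 1L) rep(1L, d[ax]) else seq_len(d[ax]))
  do.call(`[`, c(list(g), idx, list(drop = FALSE)))
}

check_bcast <- function(da, db) {
  if (length(da) != length(db) || any(da != db & da != 1L & db != 1L))
    stop("shapes are not broadcastable: [", paste(da, collapse = ","),
         "] vs [", paste(db, collapse = ","), "]")
}

# ------------------------------------------------------------ element ops --

#' @rdname dt_ops
#' @name dt_ops
#' @title Differentiable array operations
#' @description Element-wise, broadcasting, reduction, and shape operations on
#'   [dt_tensor] objects. Broadcasting follows the usual rule: axes of size one
#'   are expanded to match.
#' @param a,b,x tensors (plain arrays are promoted).
#' @return a `dt_tensor`.
NULL

#' @rdname dt_ops
#' @export
dt_add <- function(a, b) {
  a <- as_dt(a); b <- as_dt(b)
  da <- dim(a$v); db <- dim(b$v)
  check_bcast(da, db)
  val <- expand_to(a$v, pmax(da, db)) + expand_to(b$v, pmax(da, db))
  dt_op(val, list(a, b), function(g) list(reduce_to(g, da), reduce_to(g, db)))
}

#' @rdname dt_ops
#' @export
dt_sub <- function(a, b) {
  a <- as_dt(a); b <- as_dt(b)
  da <- dim(a$v); db <- dim(b$v)
  check_bcast(da, db)
  val <- expand_to(a$v, pmax(da, db)) - expand_to(b$v, pmax(da, db))
  dt_op(val, list(a, b), function(g) list(reduce_to(g, da), reduce_to(-g, db)))
}

#' @rdname dt_ops
#' @export
dt_mul <- function(a, b) {
  a <- as_dt(a); b <- as_dt(b)
  da <- dim(a$v); db <- dim(b$v)
  check_bcast(da, db)
  d <- pmax(da, db)
  av <- expand_to(a$v, d); bv <- expand_to(b$v, d)
  dt_op(av * bv, list(a, b),
        function(g) list(reduce_to(g * bv, da), reduce_to(g * av, db)))
}

#' @rdname dt_ops
#' @param s a plain numeric scalar.
#' @export
dt_scale <- function(a, s) {
  a <- as_dt(a)
  dt_op(a$v * s, list(a), function(g) list(g * s))
}

#' @rdname dt_ops
#' @export
dt_relu <- function(x) {
  x <- as_dt(x)
  m <- x$v > 0
  dt_op(x$v * m, list(x), function(g) list(g * m))
}

#' @rdname dt_ops
#' @export
dt_gelu <- function(x) {
  x <- as_dt(x)
  v <- x$v
  Phi <- stats::pnorm(v)
  dt_op(v * Phi, list(x), function(g) list(g * (Phi + v * stats::dnorm(v))))
}

#' @rdname dt_ops
#' @export
dt_sigmoid <- function(x) {
  x <- as_dt(x)
  s <- 1 / (1 + exp(-x$v))
  dt_op(s, list(x), function(g) list(g * s * (1 - s)))
}

#' @rdname dt_ops
#' @description `dt_hardswish()` is the smooth gating nonlinearity
#'   x * relu6(x + 3) / 6 used inside coordinate attention.
#' @export
dt_hardswish <- function(x) {
  x <- as_dt(x)
  v <- x$v
  r6 <- pmin(pmax(v + 3, 0), 6)
  dt_op(v * r6 / 6, list(x), function(g) {
    dr <- (v > -3 & v < 3) * 1
    list(g * (r6 / 6 + v * dr / 6))
  })
}

# --------------------------------------------------------------- shape ops --

#' @rdname dt_ops
#' @param d integer vector of target dimensions.
#' @export
dt_reshape <- function(x, d) {
  x <- as_dt(x)
  d <- as.integer(d)
  if (prod(d) != length(x$v)) stop("dt_reshape: element count mismatch")
  old <- dim(x$v)
  v <- x$v
  dim(v) <- d
  dt_op(v, list(x), function(g) { dim(g) <- old; list(g) })
}

#' @rdname dt_ops
#' @param perm permutation of axes.
#' @export
dt_aperm <- function(x, perm) {
  x <- as_dt(x)
  dt_op(aperm(x$v, perm), list(x), function(g) list(aperm(g, order(perm))))
}

#' @rdname dt_ops
#' @param tensors list of tensors to concatenate.
#' @param axis axis along which to concatenate.
#' @export
dt_concat <- function(tensors, axis) {
  tensors <- lapply(tensors, as_dt)
  dims <- lapply(tensors, function(t) dim(t$v))
  nd <- length(dims[[1]])
  sizes <- vapply(dims, function(d) d[axis], numeric(1))
  outd <- dims[[1]]
  outd[axis] <- sum(sizes)
  perm <- c(axis, seq_len(nd)[-axis])
  mats <- lapply(tensors, function(t) matrix(aperm(t$v, perm), nrow = dim(t$v)[axis]))
  val <- aperm(array(do.call(rbind, mats), dim = c(outd[axis], outd[-axis])), order(perm))
  offs <- cumsum(c(0, sizes))
  dt_op(val, tensors, function(g) {
    gp <- matrix(aperm(g, perm), nrow = outd[axis])
    lapply(seq_along(tensors), function(i) {
      gi <- gp[(offs[i] + 1):offs[i + 1], , drop = FALSE]
      aperm(array(gi, dim = c(sizes[i], outd[-axis])), order(perm))
    })
  })
}

#' @rdname dt_ops
#' @param idx integer index vector to take along `axis`.
#' @param axis axis indexed by `idx`.
#' @export
dt_take <- function(x, idx, axis) {
  x <- as_dt(x)
  d <- dim(x$v)
  args <- lapply(d, function(n) substitute())
  args[[axis]] <- idx
  val <- do.call(`[`, c(list(x$v), args, list(drop = FALSE)))
  dt_op(val, list(x), function(g) {
    gx <- array(0, dim = d)
    perm <- c(axis, seq_along(d)[-axis])
    gm <- matrix(aperm(g, perm), nrow = length(idx))
    acc <- rowsum(gm, group = idx)
    rows <- as.integer(rownames(acc))
    gxp <- matrix(aperm(gx, perm), nrow = d[axis])
    gxp[rows, ] <- gxp[rows, , drop = FALSE] + acc
    list(aperm(array(gxp, dim = c(d[axis], d[-axis])), order(perm)))
  })
}

#' @rdname dt_ops
#' @param pad integer `c(top, bottom, left, right)` zero padding of the first
#'   two (spatial) axes of an `(H, W, C, N)` array.
#' @export
dt_pad_hw <- function(x, pad) {
  x <- as_dt(x)
  d <- dim(x$v)
  if (all(pad == 0L)) return(dt_op(x$v, list(x), function(g) list(g)))
  Hp <- d[1] + pad[1] + pad[2]
  Wp <- d[2] + pad[3] + pad[4]
  val <- array(0, dim = c(Hp, Wp, d[3], d[4]))
  val[pad[1] + seq_len(d[1]), pad[3] + seq_len(d[2]), , ] <- x$v
  dt_op(val, list(x), function(g)
    list(g[pad[1] + seq_len(d[1]), pad[3] + seq_len(d[2]), , , drop = FALSE]))
}

#' @rdname dt_ops
#' @param shift integer `c(rows, cols)` cyclic shift of the spatial axes.
#' @export
dt_roll_hw <- function(x, shift) {
  x <- as_dt(x)
  d <- dim(x$v)
  ri <- ((seq_len(d[1]) - 1 - shift[1]) %% d[1]) + 1
  ci <- ((seq_len(d[2]) - 1 - shift[2]) %% d[2]) + 1
  val <- x$v[ri, ci, , , drop = FALSE]
  dt_op(val, list(x), function(g) {
    rb <- ((seq_len(d[1]) - 1 + shift[1]) %% d[1]) + 1
    cb <- ((seq_len(d[2]) - 1 + shift[2]) %% d[2]) + 1
    list(g[rb, cb, , , drop = FALSE])
  })
}

# ---------------------------------------------------------- matrix / sums --

#' @rdname dt_ops
#' @export
dt_matmul <- function(a, b) {
  a <- as_dt(a); b <- as_dt(b)
  av <- a$v; bv <- b$v
  dt_op(av %*% bv, list(a, b),
        function(g) list(g %*% t(bv), t(av) %*% g))
}

#' @rdname dt_ops
#' @description `dt_bmm()` multiplies stacks of matrices: `a` is `(m, k, B)`
#'   and `b` is `(k, n, B)` (or `(n, k, B)` with `transpose_b`).
#' @param transpose_b transpose each slice of `b` before multiplying.
#' @export
dt_bmm <- function(a, b, transpose_b = FALSE) {
  a <- as_dt(a); b <- as_dt(b)
  av <- a$v; bv <- b$v
  da <- dim(av); db <- dim(bv)
  B <- da[3]
  if (db[3] != B) stop("dt_bmm: batch mismatch")
  slice <- function(x, d, i) { m <- x[, , i, drop = FALSE]; dim(m) <- d[1:2]; m }
  n <- if (transpose_b) db[1] else db[2]
  val <- array(0, dim = c(da[1], n, B))
  for (i in seq_len(B)) {
    bi <- if (transpose_b) t(slice(bv, db, i)) else slice(bv, db, i)
    val[, , i] <- slice(av, da, i) %*% bi
  }
  dt_op(val, list(a, b), function(g) {
    dg <- dim(g)
    ga <- array(0, dim = da); gb <- array(0, dim = db)
    for (i in seq_len(B)) {
      gi <- slice(g, dg, i)
      bi <- if (transpose_b) t(slice(bv, db, i)) else slice(bv, db, i)
      ga[, , i] <- gi %*% t(bi)
      gbi <- crossprod(slice(av, da, i), gi)
      gb[, , i] <- if (transpose_b) t(gbi) else gbi
    }
    list(ga, gb)
  })
}

#' @rdname dt_ops
#' @param axes axes to sum/average over (kept as size-one dims).
#' @export
dt_mean_axes <- function(x, axes) {
  x <- as_dt(x)
  d <- dim(x$v)
  td <- d
  td[axes] <- 1L
  n <- prod(d[axes])
  val <- reduce_to(x$v, td) / n
  dt_op(val, list(x), function(g) list(expand_to(g / n, d)))
}

#' @rdname dt_ops
#' @export
dt_sum_axes <- function(x, axes) {
  x <- as_dt(x)
  d <- dim(x$v)
  td <- d
  td[axes] <- 1L
  val <- reduce_to(x$v, td)
  dt_op(val, list(x), function(g) list(expand_to(g, d)))
}

#' @rdname dt_ops
#' @export
dt_sum <- function(x) {
  x <- as_dt(x)
  d <- dim(x$v)
  dt_op(array(sum(x$v), dim = c(1L)), list(x),
        function(g) list(array(as.numeric(g), dim = d)))
}

#' @rdname dt_ops
#' @description `dt_softmax()` normalizes along `axis` with the max-subtraction
#'   trick for stability.
#' @export
dt_softmax <- function(x, axis) {
  x <- as_dt(x)
  d <- dim(x$v)
  td <- d; td[axis] <- 1L
  mx <- reduce_max(x$v, axis)
  e <- exp(x$v - expand_to(mx, d))
  s <- reduce_to(e, td)
  p <- e / expand_to(s, d)
  dt_op(p, list(x), function(g) {
    dot <- reduce_to(g * p, td)
    list(p * (g - expand_to(dot, d)))
  })
}

reduce_max <- function(v, axis) {
  d <- dim(v)
  perm <- c(axis, seq_along(d)[-axis])
  m <- apply(matrix(aperm(v, perm), nrow = d[axis]), 2, max)
  td <- d; td[axis] <- 1L
  aperm(array(m, dim = c(1L, d[-axis])), order(perm))
}

#' @rdname dt_ops
#' @param p dropout probability in `[0, 1)`.
#' @param training if `FALSE` the op is the identity.
#' @export
dt_dropout <- function(x, p, training = TRUE) {
  x <- as_dt(x)
  if (!training || p <= 0) return(dt_op(x$v, list(x), function(g) list(g)))
  keep <- (array(stats::runif(length(x$v)), dim = dim(x$v)) >= p) / (1 - p)
  dt_op(x$v * keep, list(x), function(g) list(g * keep))
}

#' Mean cross-entropy loss from logits
#'
#' @param logits `(K, N)` tensor of unnormalized class scores.
#' @param labels integer vector of length `N` with values in `1..K`.
#' @return scalar `dt_tensor`.
#' @export
dt_cross_entropy <- function(logits, labels) {
  logits <- as_dt(logits)
  v <- logits$v
  K <- dim(v)[1]; N <- dim(v)[2]
  mx <- matrix(apply(v, 2, max), nrow = 1)
  e <- exp(v - mx[rep(1, K), , drop = FALSE])
  p <- e / matrix(colSums(e), nrow = K, ncol = N, byrow = TRUE)
  ll <- -mean(log(p[cbind(labels, seq_len(N))] + 1e-300))
  dt_op(array(ll, dim = 1L), list(logits), function(g) {
    gi <- p
    gi[cbind(labels, seq_len(N))] <- gi[cbind(labels, seq_len(N))] - 1
    list(gi * as.numeric(g) / N)
  })
}
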