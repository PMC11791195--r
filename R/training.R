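# Training loop (SGD with momentum or Adam, step-decay scheduler,
# cross-entropy), model checkpointing, and the grid-search harness.

#' Training configuration
#'
#' Defaults follow the tuned settings of the study: learning rate 1e-4,
#' weight decay 1e-3, SGD with momentum 0.9, step-LR with step size 1 and
#' gamma 0.99, dropout handled by the model config.
#'
#' @param lr learning rate.
#' @param weight_decay L2 coefficient.
#' @param optimizer `"sgd"` (momentum 0.9) or `"adam"`.
#' @param momentum SGD momentum.
#' @param step_size scheduler period in epochs.
#' @param gamma multiplicative LR decay applied every `step_size` epochs.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed RNG seed for shuffling and dropout.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-3, optimizer = "sgd",
                         momentum = 0.9, step_size = 1L, gamma = 0.99,
                         epochs = 10L, batch_size = 32L, seed = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, gamma > 0, gamma <= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 optimizer = match.arg(optimizer, c("sgd", "adam")),
                 momentum = momentum, step_size = as.integer(step_size),
                 gamma = gamma, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Scheduled learning rate after a number of completed epochs
#' @param cfg a [train_config()].
#' @param epoch number of completed epochs.
#' @return the decayed learning rate `lr * gamma^(floor(epoch / step_size))`.
#' @export
scheduled_lr <- function(cfg, epoch) {
  cfg$lr * cfg$gamma^(epoch %/% cfg$step_size)
}

#' Adam optimizer
#' @param params named list of `dt_tensor`s.
#' @param lr,beta1,beta2,eps,weight_decay usual Adam hyper-parameters.
#' @return an optimizer object.
#' @export
optim_adam <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  m <- lapply(params, function(p) array(0, dim = dim(p$v)))
  v <- lapply(params, function(p) array(0, dim = dim(p$v)))
  e <- new.env(parent = emptyenv())
  e$lr <- lr
  t <- 0L
  e$step <- function() {
    t <<- t + 1L
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (is.null(p$grad)) next
      g <- p$grad + weight_decay * p$v
      m[[i]] <<- beta1 * m[[i]] + (1 - beta1) * g
      v[[i]] <<- beta2 * v[[i]] + (1 - beta2) * g^2
      mh <- m[[i]] / (1 - beta1^t)
      vh <- v[[i]] / (1 - beta2^t)
      p$v <- p$v - e$lr * mh / (sqrt(vh) + eps)
    }
    invisible(NULL)
  }
  e$zero_grad <- function() { for (p in params) p$grad <- NULL; invisible(NULL) }
  e$set_lr <- function(lr) e$lr <- lr
  class(e) <- "dfunet_optimizer"
  e
}

#' Snapshot / restore model weights
#' @param model a layer.
#' @return named list of parameter value arrays.
#' @export
model_state <- function(model) lapply(parameters(model), function(p) p$v)

#' @rdname model_state
#' @param state a state list from [model_state()].
#' @export
load_state <- function(model, state) {
  ps <- parameters(model)
  stopifnot(identical(names(ps), names(state)))
  for (nm in names(ps)) ps[[nm]]$v <- state[[nm]]
  invisible(model)
}

batch_slices <- function(n, bs) {
  split(seq_len(n), ceiling(seq_len(n) / bs))
}

eval_split <- function(model, x, y, bs) {
  n <- length(y)
  loss <- 0; correct <- 0
  for (ix in batch_slices(n, bs)) {
    xb <- x[, , , ix, drop = FALSE]
    lg <- dt_no_grad(forward(model, xb))
    loss <- loss + as.numeric(dt_value(dt_cross_entropy(lg, y[ix]))) * length(ix)
    correct <- correct + sum(apply(dt_value(lg), 2, which.max) == y[ix])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train a model
#'
#' Minibatch training with per-epoch train/validation history, step-decay
#' learning-rate scheduling, and best-validation checkpointing (the
#' final-epoch weights are also returned).  Aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param model a model layer (modified in place).
#' @param data list with `$train` and optionally `$val`, each `list(x, y)`
#'   where `x` is `(H, W, 3, N)` and `y` integer labels.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress?
#' @return list with `history` (data.frame), `best_state`, `final_state`,
#'   `best_epoch`.
#' @export
train_model <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(data$train$y) == 0) stop("train_model: empty training data")
  set.seed(cfg$seed)
  ps <- parameters(model)
  opt <- if (cfg$optimizer == "sgd")
    optim_sgd(ps, lr = cfg$lr, momentum = cfg$momentum,
              weight_decay = cfg$weight_decay)
  else optim_adam(ps, lr = cfg$lr, weight_decay = cfg$weight_decay)
  hist <- list()
  best <- list(metric = -Inf, state = model_state(model), epoch = 0L)
  n <- length(data$train$y)
  for (ep in seq_len(cfg$epochs)) {
    opt$set_lr(scheduled_lr(cfg, ep - 1L))
    set_train(model, TRUE)
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (ix in batch_slices(n, cfg$batch_size)) {
      sel <- ord[ix]
      xb <- data$train$x[, , , sel, drop = FALSE]
      opt$zero_grad()
      dt_tape_reset()
      lg <- forward(model, xb)
      loss <- dt_cross_entropy(lg, data$train$y[sel])
      lv <- as.numeric(dt_value(loss))
      if (!is.finite(lv))
        stop("train_model: non-finite loss at epoch ", ep,
             " (learning rate too high or degenerate inputs)")
      dt_backward(loss)
      opt$step()
      ep_loss <- ep_loss + lv * length(sel)
      ep_correct <- ep_correct + sum(apply(dt_value(lg), 2, which.max) ==
                                     data$train$y[sel])
    }
    set_train(model, FALSE)
    row <- data.frame(epoch = ep, lr = opt$lr, train_loss = ep_loss / n,
                      train_acc = ep_correct / n, val_loss = NA_real_,
                      val_acc = NA_real_)
    if (!is.null(data$val) && length(data$val$y)) {
      vm <- eval_split(model, data$val$x, data$val$y, cfg$batch_size)
      row$val_loss <- vm["loss"]; row$val_acc <- vm["acc"]
      if (vm["acc"] > best$metric) {
        best <- list(metric = vm["acc"], state = model_state(model), epoch = ep)
      }
    }
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f  val acc %s",
                      ep, opt$lr, row$train_loss, row$train_acc,
                      ifelse(is.na(row$val_acc), "-",
                             sprintf("%.3f", row$val_acc))))
  }
  list(history = do.call(rbind, hist),
       best_state = best$state, best_epoch = best$epoch,
       final_state = model_state(model))
}

#' Save / load a model checkpoint
#'
#' A checkpoint holds the parameter state plus a digest of the model
#' configuration so mismatched loads fail loudly.
#'
#' @param model a model with a `cfg` field.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(state = model_state(model),
               config = model$cfg,
               n_params = count_parameters(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(ck$n_params, count_parameters(model)))
    stop("load_checkpoint: parameter count mismatch (checkpoint ",
         ck$n_params, ", model ", count_parameters(model), ")")
  load_state(model, ck$state)
  invisible(model)
}

#' Exhaustive grid search over training hyper-parameters
#'
#' Evaluates every configuration in the cartesian product of the supplied
#' value vectors by validation macro F1 (ties broken by the first row in grid
#' order) and returns the full results table.
#'
#' @param space named list of value vectors (subset of the [train_config()]
#'   fields, e.g. `list(lr = c(1e-3, 1e-4), dropout = c(0.4, 0.6))`;
#'   `dropout` is routed to the model builder).
#' @param data split data as in [train_model()] (needs `$val`).
#' @param build_model function(dropout) returning a fresh model.
#' @param epochs training epochs per grid point.
#' @param base a [train_config()] supplying unsearched fields.
#' @return list with `best` (the winning config row), `results` (data.frame
#'   with one row per configuration and its validation metrics).
#' @export
grid_search <- function(space, data, build_model, epochs = 5L,
                        base = train_config()) {
  if (!length(space) || any(!vapply(space, length, integer(1))))
    stop("grid_search: empty grid")
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- grid
  res$val_macro_f1 <- NA_real_
  res$val_acc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    for (nm in setdiff(names(grid), "dropout")) cfg[[nm]] <- grid[[nm]][i]
    cfg$epochs <- as.integer(epochs)
    model <- if ("dropout" %in% names(grid)) build_model(grid$dropout[i])
             else build_model()
    ok <- tryCatch({
      fit <- train_model(model, data, cfg)
      load_state(model, fit$best_state)
      set_train(model, FALSE)
      m <- evaluate(model, data$val)
      res$val_macro_f1[i] <- m$macro$f1
      res$val_acc[i] <- m$accuracy
      TRUE
    }, error = function(e) {
      warning("grid point ", i, " failed: ", conditionMessage(e))
      FALSE
    })
  }
  best_i <- which.max(res$val_macro_f1)   # first maximum: deterministic
  list(best = res[best_i, , drop = FALSE], results = res)
}
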