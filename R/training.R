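# Training: per-channel standardization, SGD with momentum and weight
# decay, step learning-rate decay, and validation-based checkpointing.

#' Fit per-channel standardization statistics
#'
#' Pools every pixel of every training tile and computes the per-channel
#' mean and standard deviation of the population; applying the resulting
#' transform to the pool gives per-channel mean 0 and sd 1. Standard
#' deviations are floored at 1e-8 so constant channels stay well-defined.
#'
#' @param tiles non-empty list of (H, W, 3) RGB arrays (0-255 scale).
#' @return object of class `vesselfcn_standardizer` with `mean` and `sd`
#'   numeric triples.
#' @export
fit_standardizer <- function(tiles) {
  if (length(tiles) == 0L) stop("`tiles` must be a non-empty list")
  tiles <- lapply(tiles, as_feature_map)
  nch <- dim(tiles[[1L]])[3L]
  n <- 0
  s1 <- numeric(nch)
  s2 <- numeric(nch)
  for (t in tiles) {
    d <- dim(t)
    n <- n + d[1L] * d[2L]
    for (c in seq_len(nch)) {
      s1[c] <- s1[c] + sum(t[, , c])
      s2[c] <- s2[c] + sum(t[, , c]^2)
    }
  }
  mu <- s1 / n
  v <- pmax(s2 / n - mu^2, 0)
  structure(list(mean = mu, sd = pmax(sqrt(v), 1e-8)),
            class = "vesselfcn_standardizer")
}

#' Apply standardization statistics to a tile
#'
#' @param tile (H, W, C) array.
#' @param stats a `vesselfcn_standardizer`.
#' @return standardized numeric array of the same shape.
#' @export
standardize <- function(tile, stats) {
  x <- as_feature_map(tile)
  for (c in seq_len(dim(x)[3L])) {
    x[, , c] <- (x[, , c] - stats$mean[c]) / stats$sd[c]
  }
  x
}

#' Training hyper-parameter configuration
#'
#' Defaults follow the original recipe: SGD with momentum 0.99, weight
#' decay 0.0005, mini-batches of 5 tiles, and a learning rate initialized
#' at 0.01 and decreased by a factor of 10 every 1000 iterations.
#'
#' @param base_lr initial learning rate.
#' @param lr_step_iters iterations between learning-rate drops.
#' @param lr_gamma multiplicative decay per step, in (0, 1).
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 regularization coefficient.
#' @param batch_size tiles per mini-batch.
#' @param max_iters maximum number of iterations.
#' @param val_every iterations between validation evaluations.
#' @param patience validation evaluations without improvement before
#'   early stopping.
#' @param seed integer seed driving mini-batch shuffling.
#' @return a `vesselfcn_training_config` list.
#' @export
training_config <- function(base_lr = 0.01, lr_step_iters = 1000L,
                            lr_gamma = 0.1, momentum = 0.99,
                            weight_decay = 0.0005, batch_size = 5L,
                            max_iters = 10000L, val_every = 100L,
                            patience = 5L, seed = 1L) {
  cfg <- list(base_lr = base_lr, lr_step_iters = as.integer(lr_step_iters),
              lr_gamma = lr_gamma, momentum = momentum,
              weight_decay = weight_decay, batch_size = as.integer(batch_size),
              max_iters = as.integer(max_iters),
              val_every = as.integer(val_every),
              patience = as.integer(patience), seed = as.integer(seed))
  stopifnot(cfg$base_lr > 0, cfg$lr_step_iters > 0,
            cfg$lr_gamma > 0, cfg$lr_gamma < 1,
            cfg$momentum >= 0, cfg$momentum < 1, cfg$weight_decay >= 0,
            cfg$batch_size >= 1L, cfg$max_iters >= 0L,
            cfg$val_every >= 1L, cfg$patience >= 1L)
  structure(cfg, class = "vesselfcn_training_config")
}

#' Learning rate at a given iteration
#'
#' Step decay: `base_lr * lr_gamma ^ floor(iteration / lr_step_iters)`.
#' With the defaults this is 0.01 at iteration 0, 0.001 at 1000 and
#' 0.0001 at 2500.
#'
#' @param iteration non-negative integer (0-based).
#' @param config a [training_config()].
#' @return positive learning rate.
#' @export
lr_at <- function(iteration, config) {
  stopifnot(all(iteration >= 0))
  config$base_lr * config$lr_gamma^floor(iteration / config$lr_step_iters)
}

#' One SGD step with momentum and weight decay
#'
#' For each parameter: `buf <- momentum * buf + (grad + weight_decay * w)`
#' then `w <- w - lr * buf`. Biases and upsampling kernels are treated like
#' any other parameter.
#'
#' @param parameters named list of numeric arrays.
#' @param gradients named list matching `parameters`.
#' @param momentum_buffers named list matching `parameters` (zeros on the
#'   first call), or `NULL` to initialize.
#' @param lr learning rate for this step.
#' @param config a [training_config()] supplying momentum and weight decay.
#' @return list with updated `parameters` and `momentum_buffers`.
#' @export
sgd_step <- function(parameters, gradients, momentum_buffers, lr, config) {
  if (is.null(momentum_buffers)) {
    momentum_buffers <- lapply(parameters, function(p) array(0, dim(p) %||% length(p)))
  }
  for (nm in names(parameters)) {
    g <- gradients[[nm]]
    if (is.null(g)) next
    if (!all(is.finite(g))) stop("non-finite gradient for parameter ", nm)
    buf <- config$momentum * momentum_buffers[[nm]] +
      (g + config$weight_decay * parameters[[nm]])
    momentum_buffers[[nm]] <- buf
    parameters[[nm]] <- parameters[[nm]] - lr * buf
  }
  list(parameters = parameters, momentum_buffers = momentum_buffers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean loss over a sample list (inference only, no parameter updates).
evaluate_loss <- function(net, samples) {
  mean(vapply(samples, function(s) {
    softmax_loss_grad(net_forward(net, s$image)$out, s$mask,
                      want_grad = FALSE)$loss
  }, numeric(1)))
}

#' Standardize a sample list with fitted statistics
#'
#' Convenience for preparing training/validation sets: replaces each
#' sample's image with its standardized version. Statistics must come from
#' the training set only.
#'
#' @param samples list of samples, each a list with `image` and `mask`.
#' @param stats a `vesselfcn_standardizer`.
#' @return list of samples with standardized images.
#' @export
prepare_samples <- function(samples, stats) {
  lapply(samples, function(s) {
    s$image <- standardize(s$image, stats)
    s
  })
}

#' Train a network with SGD
#'
#' Mini-batches are drawn by seeded epoch shuffling; the loss is the
#' per-pixel softmax cross-entropy averaged over pixels and batch. The
#' validation loss is evaluated every `val_every` iterations without
#' updating parameters; the returned network carries the parameters from
#' the iteration with the lowest validation loss, and training stops early
#' when `patience` consecutive evaluations bring no improvement.
#'
#' @param model a `vesselfcn_network`.
#' @param train_set,val_set disjoint lists of samples (`image` already
#'   standardized with training-set statistics, `mask` integer labels).
#' @param config a [training_config()].
#' @param verbose print a progress line at each validation evaluation.
#' @return list with `network` (best-validation checkpoint) and `log`, a
#'   tibble with columns `iteration`, `train_loss`, `val_loss` (NA between
#'   evaluations) plus attributes `best_iteration` and `seed`.
#' @export
train <- function(model, train_set, val_set, config = training_config(),
                  verbose = FALSE) {
  stopifnot(length(train_set) >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  params <- net_parameters(model)
  bufs <- NULL
  best <- list(params = params, val = Inf, iter = 0L)
  n <- length(train_set)
  perm <- sample.int(n)
  cursor <- 1L
  its <- integer(0)
  tr_loss <- numeric(0)
  va_loss <- numeric(0)
  bad_evals <- 0L

  iter <- 0L
  while (iter < config$max_iters) {
    iter <- iter + 1L
    # next batch from the shuffled cycle; reshuffle at epoch boundaries
    idx <- integer(0)
    while (length(idx) < config$batch_size) {
      take <- min(config$batch_size - length(idx), n - cursor + 1L)
      idx <- c(idx, perm[cursor:(cursor + take - 1L)])
      cursor <- cursor + take
      if (cursor > n) {
        perm <- sample.int(n)
        cursor <- 1L
      }
    }

    gsum <- NULL
    loss <- 0
    for (i in idx) {
      s <- train_set[[i]]
      fwd <- net_forward(model, s$image, keep = TRUE)
      lg <- softmax_loss_grad(fwd$out, s$mask)
      loss <- loss + lg$loss
      g <- net_backward(model, fwd, lg$grad)
      gsum <- if (is.null(gsum)) g else {
        for (nm in names(g)) gsum[[nm]] <- gsum[[nm]] + g[[nm]]
        gsum
      }
    }
    nb <- length(idx)
    loss <- loss / nb
    if (!is.finite(loss)) {
      stop("non-finite training loss at iteration ", iter,
           "; lower the learning rate")
    }
    for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] / nb

    upd <- sgd_step(params, gsum, bufs, lr_at(iter - 1L, config), config)
    params <- upd$parameters
    bufs <- upd$momentum_buffers
    model <- net_set_parameters(model, params)

    its <- c(its, iter)
    tr_loss <- c(tr_loss, loss)
    vl <- NA_real_
    if (iter %% config$val_every == 0L || iter == config$max_iters) {
      vl <- evaluate_loss(model, val_set)
      if (verbose) {
        message(sprintf("iter %d  lr %.2g  train %.4f  val %.4f",
                        iter, lr_at(iter - 1L, config), loss, vl))
      }
      if (vl < best$val) {
        best <- list(params = params, val = vl, iter = iter)
        bad_evals <- 0L
      } else {
        bad_evals <- bad_evals + 1L
        if (bad_evals >= config$patience) {
          va_loss <- c(va_loss, vl)
          break
        }
      }
    }
    va_loss <- c(va_loss, vl)
  }

  log <- tibble::tibble(iteration = its, train_loss = tr_loss,
                        val_loss = va_loss)
  attr(log, "best_iteration") <- best$iter
  attr(log, "seed") <- config$seed
  list(network = net_set_parameters(model, best$params), log = log)
}

#' Choose the stopping iteration from a validation trace
#'
#' Returns the evaluated iteration with the minimum validation loss
#' (earliest on ties).
#'
#' @param iterations integer vector of evaluated iterations.
#' @param val_losses numeric vector of matching validation losses.
#' @return the chosen stopping iteration.
#' @export
stopping_iteration <- function(iterations, val_losses) {
  stopifnot(length(iterations) == length(val_losses), length(iterations) >= 1L)
  iterations[which.min(val_losses)]
}

#' Save a trained model as a checkpoint with a JSON manifest
#'
#' Writes the parameters and normalization statistics to `<path>.rds` and a
#' human-readable manifest (architecture spec, width multiplier, class
#' names, normalization stats) to `<path>.json`.
#'
#' @param model a `vesselfcn_network`.
#' @param stats a `vesselfcn_standardizer`.
#' @param path file stem (without extension).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, stats, path) {
  saveRDS(list(spec = model$spec, parameters = net_parameters(model),
               stats = stats), paste0(path, ".rds"))
  manifest <- list(
    arch = model$spec$arch,
    n_classes = model$spec$n_classes,
    width_multiplier = model$spec$width_multiplier,
    class_names = c("background", "microvessel"),
    normalization = list(mean = stats$mean, sd = stats$sd)
  )
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path file stem used at save time.
#' @return list with `network` and `stats`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(paste0(path, ".rds"))
  builder <- if (ck$spec$arch == "proposed") build_proposed_fcn else build_fcn8s_baseline
  net <- builder(ck$spec$n_classes, ck$spec$width_multiplier, ck$spec$seed)
  net <- net_set_parameters(net, ck$parameters)
  list(network = net, stats = ck$stats)
}
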