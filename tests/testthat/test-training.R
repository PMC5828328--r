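test_that("standardizer pools per-channel statistics and floors the sd", {
  t1 <- array(10, c(4, 4, 3))
  t2 <- array(20, c(4, 4, 3))
  st <- fit_standardizer(list(t1, t2))
  expect_equal(st$mean, rep(15, 3))
  # channel-wise standardization of a mixed tile
  t3 <- array(0, c(2, 2, 3))
  z <- standardize(t3, st)
  expect_equal(dim(z), dim(t3))
  expect_true(all(is.finite(z)))
  # constant data: sd floored, never a division by zero
  st0 <- fit_standardizer(list(array(5, c(3, 3, 3))))
  expect_true(all(is.finite(standardize(array(5, c(3, 3, 3)), st0))))
  # exact z-scores for a hand case
  tile <- array(c(rep(0, 4), rep(2, 4)), c(2, 2, 2, 1))[, , , 1]
  dim(tile) <- c(2, 2, 2)
  stz <- fit_standardizer(list(tile))
  zz <- standardize(tile, stz)
  expect_equal(mean(zz[, , 1]), 0)
})

test_that("training_config exposes the published optimizer defaults", {
  cfg <- training_config()
  expect_equal(cfg$base_lr, 0.01)
  expect_equal(cfg$lr_step_iters, 1000L)
  expect_equal(cfg$lr_gamma, 0.1)
  expect_equal(cfg$momentum, 0.99)
  expect_equal(cfg$weight_decay, 5e-4)
  expect_equal(cfg$batch_size, 5L)
  expect_error(training_config(base_lr = -1))
  expect_error(training_config(momentum = 1.5))
})

test_that("learning-rate schedule steps down by gamma every step interval", {
  cfg <- training_config()
  expect_equal(lr_at(0, cfg), 0.01)
  expect_equal(lr_at(999, cfg), 0.01)
  expect_equal(lr_at(1000, cfg), 0.001)
  expect_equal(lr_at(2500, cfg), 0.0001)
  expect_equal(lr_at(3000, cfg), 1e-5)
  # vectorized
  expect_equal(lr_at(c(0, 1000, 2000), cfg), c(1e-2, 1e-3, 1e-4))
})

test_that("sgd_step reproduces hand-computed momentum updates", {
  cfg <- training_config(momentum = 0.9, weight_decay = 0)
  p <- list(w = array(1, c(1, 1, 1, 1)))
  g <- list(w = array(0.5, c(1, 1, 1, 1)))
  # step 1: buf = 0.5, w = 1 - 0.1 * 0.5 = 0.95
  s1 <- sgd_step(p, g, NULL, lr = 0.1, cfg)
  expect_equal(as.numeric(s1$parameters$w), 0.95, tolerance = 1e-12)
  expect_equal(as.numeric(s1$momentum_buffers$w), 0.5, tolerance = 1e-12)
  # step 2 with zero grad: buf = 0.9 * 0.5 = 0.45, w = 0.95 - 0.045 = 0.905
  s2 <- sgd_step(s1$parameters, list(w = array(0, c(1, 1, 1, 1))),
                 s1$momentum_buffers, lr = 0.1, cfg)
  expect_equal(as.numeric(s2$parameters$w), 0.905, tolerance = 1e-12)
  # with weight decay 0.01: buf = 0.5 + 0.01 * 1 = 0.51, w = 1 - 0.051
  cfg_wd <- training_config(momentum = 0.9, weight_decay = 0.01)
  s3 <- sgd_step(p, g, NULL, lr = 0.1, cfg_wd)
  expect_equal(as.numeric(s3$parameters$w), 1 - 0.1 * 0.51,
               tolerance = 1e-12)
  # non-finite gradients are an error, never silently applied
  expect_error(sgd_step(p, list(w = array(NaN, c(1, 1, 1, 1))), NULL,
                        0.1, cfg), "non-finite")
})

test_that("stopping_iteration picks the minimum validation loss", {
  expect_equal(stopping_iteration(c(100, 200, 300), c(0.5, 0.3, 0.4)), 200)
  # earliest on ties
  expect_equal(stopping_iteration(c(100, 200), c(0.3, 0.3)), 100)
  expect_error(stopping_iteration(c(100), c(0.1, 0.2)))
})

make_toy_sets <- function(n_train = 6, n_val = 2, seed = 10) {
  cfg <- desk_synthetic_config(tile_height_px = 32, tile_width_px = 32,
                               vessel_count = 1,
                               vessel_radius_px_range = c(4L, 6L))
  raw <- generate_dataset(cfg, n_train + n_val, seed = seed)
  stats <- fit_standardizer(lapply(raw, `[[`, "image"))
  list(train = prepare_samples(raw[seq_len(n_train)], stats),
       val = prepare_samples(raw[n_train + seq_len(n_val)], stats),
       stats = stats)
}

test_that("train runs, logs every iteration and returns the best network", {
  sets <- make_toy_sets()
  net <- build_proposed_fcn(2L, width_multiplier = 1 / 16, seed = 1)
  cfg <- training_config(max_iters = 6L, val_every = 3L, batch_size = 2L,
                         seed = 7L)
  fit <- train(net, sets$train, sets$val, cfg)
  expect_s3_class(fit$log, "tbl_df")
  expect_equal(nrow(fit$log), 6L)
  expect_equal(fit$log$iteration, 1:6)
  expect_true(all(is.finite(fit$log$train_loss)))
  # validation evaluated exactly at multiples of val_every (and the end)
  expect_equal(which(!is.na(fit$log$val_loss)), c(3L, 6L))
  expect_true(attr(fit$log, "best_iteration") %in% c(3L, 6L))
  expect_s3_class(fit$network, "vesselfcn_network")
  # zero-iteration budget yields an empty log and the initial network
  fit0 <- train(net, sets$train, sets$val,
                training_config(max_iters = 0L))
  expect_equal(nrow(fit0$log), 0L)
})

test_that("training is reproducible for a fixed seed", {
  sets <- make_toy_sets()
  cfg <- training_config(max_iters = 4L, val_every = 2L, batch_size = 2L,
                         seed = 11L)
  net <- build_proposed_fcn(2L, width_multiplier = 1 / 16, seed = 2)
  f1 <- train(net, sets$train, sets$val, cfg)
  f2 <- train(net, sets$train, sets$val, cfg)
  expect_identical(f1$log$train_loss, f2$log$train_loss)
  expect_identical(net_parameters(f1$network), net_parameters(f2$network))
  # a different data order (seed) changes the trace
  f3 <- train(net, sets$train, sets$val,
              training_config(max_iters = 4L, val_every = 2L,
                              batch_size = 2L, seed = 12L))
  expect_false(identical(f1$log$train_loss, f3$log$train_loss))
})

test_that("checkpoints round-trip the network and standardizer", {
  sets <- make_toy_sets(n_train = 2, n_val = 1)
  net <- build_proposed_fcn(2L, width_multiplier = 1 / 16, seed = 3)
  path <- file.path(withr_tempdir <- tempfile("ckpt"), "model")
  dir.create(withr_tempdir)
  save_checkpoint(net, sets$stats, path)
  expect_true(file.exists(paste0(path, ".rds")))
  expect_true(file.exists(paste0(path, ".json")))
  ck <- load_checkpoint(path)
  expect_identical(net_parameters(ck$network), net_parameters(net))
  expect_equal(ck$stats$mean, sets$stats$mean)
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(manifest$arch, "proposed")
  expect_equal(manifest$n_classes, 2L)
  expect_equal(unlist(manifest$normalization$mean), sets$stats$mean)
  unlink(withr_tempdir, recursive = TRUE)
})
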