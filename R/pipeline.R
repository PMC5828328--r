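# End-to-end orchestration: synth -> train -> predict -> evaluate ->
# features, with seeded reproducibility and on-disk artifacts per stage.

#' Pipeline configuration
#'
#' Bundles the sub-configurations of every stage plus the split sizes and
#' a single global seed from which all stage seeds are derived.
#'
#' @param synthetic a [synthetic_config()].
#' @param training a [training_config()].
#' @param match an [object_match_config()].
#' @param neighborhood a [neighborhood_config()].
#' @param n_train,n_val,n_test split sizes (tiles).
#' @param arches architectures to train and compare; any subset of
#'   `c("proposed", "fcn8s")`.
#' @param width_multiplier network width scaling shared by all
#'   architectures.
#' @param images_per_patient test tiles grouped per synthetic patient for
#'   the feature table.
#' @param seed global seed.
#' @return a `vesselfcn_pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            training = training_config(),
                            match = object_match_config(),
                            neighborhood = neighborhood_config(),
                            n_train = 300L, n_val = 50L, n_test = 35L,
                            arches = c("proposed", "fcn8s"),
                            width_multiplier = 1,
                            images_per_patient = 3L,
                            seed = 1L) {
  arches <- match.arg(arches, c("proposed", "fcn8s"), several.ok = TRUE)
  stopifnot(n_train >= 1L, n_val >= 1L, n_test >= 1L,
            images_per_patient >= 1L)
  structure(list(synthetic = synthetic, training = training, match = match,
                 neighborhood = neighborhood,
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), arches = arches,
                 width_multiplier = width_multiplier,
                 images_per_patient = as.integer(images_per_patient),
                 seed = as.integer(seed)),
            class = "vesselfcn_pipeline_config")
}

#' Reduced desk-scale pipeline preset
#'
#' 64 x 64 synthetic tiles, 1/8-width networks, 200 training / 40
#' validation tiles and a capped iteration budget: a full two-architecture
#' comparison that runs on one CPU in minutes.
#'
#' @param n_train,n_val,n_test split sizes.
#' @param max_iters training iteration cap.
#' @param seed global seed.
#' @param ... further overrides passed to [pipeline_config()].
#' @return a `vesselfcn_pipeline_config`.
#' @export
desk_pipeline_config <- function(n_train = 200L, n_val = 40L, n_test = 20L,
                                 max_iters = 400L, seed = 1L, ...) {
  pipeline_config(
    synthetic = desk_synthetic_config(),
    training = training_config(max_iters = max_iters, val_every = 50L,
                               patience = 5L, seed = seed),
    n_train = n_train, n_val = n_val, n_test = n_test,
    width_multiplier = 1 / 8, seed = seed, ...
  )
}

#' Derive a per-stage seed from the global pipeline seed
#'
#' Distinct offsets give distinct, deterministic seeds, so the synthesis
#' splits, weight initialization and mini-batch shuffling draw from
#' independent streams.
#'
#' @param seed global integer seed.
#' @param offset integer stage offset.
#' @return derived integer seed.
#' @export
stage_seed <- function(seed, offset) {
  (seed + 7919L * offset) %% (.Machine$integer.max - 1L)
}

#' Run the full segmentation pipeline on synthetic data
#'
#' Executes, in order: tile synthesis (train/validation/test splits with
#' disjoint derived seeds), per-architecture training with
#' validation-based stopping, prediction on the held-out tiles,
#' pixel-level (pooled confusion) and object-level evaluation, and
#' per-image feature extraction from the predicted masks. Artifacts
#' (predicted masks, training logs, feature table, JSON summary) are
#' written under `out_dir`; reruns with the same config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); `NULL` skips all disk
#'   artifacts.
#' @param verbose print a line per stage transition.
#' @return the summary list, invisibly also written as
#'   `summary.json`: per-architecture `pA`, `mA`, `mIU`, `fp`, `fn`, `tp`,
#'   stopping iteration, loss trace ends, plus seeds and the config echo.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "vesselfcn_pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # --- stage 1: synthesize splits -----------------------------------
  say("[synth] %d train / %d val / %d test tiles (seed %d)",
      config$n_train, config$n_val, config$n_test, config$seed)
  train_raw <- generate_dataset(config$synthetic, config$n_train,
                                seed = stage_seed(config$seed, 1L))
  val_raw <- generate_dataset(config$synthetic, config$n_val,
                              seed = stage_seed(config$seed, 2L))
  test_raw <- generate_dataset(config$synthetic, config$n_test,
                               seed = stage_seed(config$seed, 3L))

  stats <- fit_standardizer(lapply(train_raw, `[[`, "image"))
  train_set <- prepare_samples(train_raw, stats)
  val_set <- prepare_samples(val_raw, stats)

  results <- list()
  for (arch in config$arches) {
    say("[train] %s (width %.3g)", arch, config$width_multiplier)
    builder <- if (arch == "proposed") build_proposed_fcn else build_fcn8s_baseline
    net <- builder(n_classes = 2L, width_multiplier = config$width_multiplier,
                   seed = stage_seed(config$seed, 4L))
    fit <- train(net, train_set, val_set, config$training, verbose = verbose)

    say("[predict] %s on %d test tiles", arch, config$n_test)
    preds <- lapply(test_raw, function(s) {
      predict(fit$network, s$image, stats)
    })

    say("[evaluate] %s", arch)
    cm <- matrix(0, 2, 2)
    fp <- fn <- tp <- 0L
    for (i in seq_along(test_raw)) {
      cm <- cm + confusion_matrix(preds[[i]], test_raw[[i]]$mask)$counts
      oc <- count_fp_fn(preds[[i]], test_raw[[i]]$mask, config$match)
      fp <- fp + oc$fp
      fn <- fn + oc$fn
      tp <- tp + oc$tp
    }
    pm <- pixel_metrics(cm)

    results[[arch]] <- list(
      pA = pm$pA, mA = pm$mA, mIU = pm$mIU,
      fp = fp, fn = fn, tp = tp,
      stopping_iteration = attr(fit$log, "best_iteration"),
      initial_train_loss = if (nrow(fit$log)) fit$log$train_loss[1L] else NA,
      final_train_loss = if (nrow(fit$log)) fit$log$train_loss[nrow(fit$log)] else NA,
      # 10-iteration moving averages of the loss trace ends
      initial_smoothed_loss = if (nrow(fit$log)) {
        mean(head(fit$log$train_loss, 10L))
      } else NA,
      final_smoothed_loss = if (nrow(fit$log)) {
        mean(utils::tail(fit$log$train_loss, 10L))
      } else NA
    )

    if (!is.null(out_dir)) {
      adir <- file.path(out_dir, arch)
      dir.create(adir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(preds)) {
        write_mask(preds[[i]], file.path(adir, sprintf("pred_%03d.png", i)))
      }
      write.csv(fit$log, file.path(adir, "training_log.csv"),
                row.names = FALSE)
    }
    if (arch == config$arches[1L]) {
      primary_preds <- preds
    }
  }

  # --- features from the primary architecture's predictions ---------
  say("[features] %d test tiles", config$n_test)
  nh <- modifyList(config$neighborhood,
                   list(pixel_size_um = config$synthetic$pixel_size_um))
  feats <- do.call(rbind, lapply(seq_along(test_raw), function(i) {
    vessel_feature_record(
      primary_preds[[i]], test_raw[[i]]$cells,
      image_id = sprintf("img%03d", i),
      patient_id = sprintf("pt%03d",
                           (i - 1L) %/% config$images_per_patient + 1L),
      config = nh
    )
  }))
  feats <- aggregate_per_patient(feats)

  summary <- list(
    seed = config$seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    config = list(
      tile = c(config$synthetic$tile_height_px,
               config$synthetic$tile_width_px),
      width_multiplier = config$width_multiplier,
      n_train = config$n_train, n_val = config$n_val,
      n_test = config$n_test,
      max_iters = config$training$max_iters
    ),
    architectures = results
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
    js <- summary
    js$elapsed_s <- NULL  # keep the summary file bit-reproducible
    jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary$features <- feats
  invisible(summary)
}
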