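# Network graphs: a declarative layer list executed forward and backward.
# Each layer is a list(name, op, inputs, ...) entry; `order` is a valid
# topological order (builders emit layers already ordered).

new_network <- function(spec, layers) {
  structure(list(spec = spec, layers = layers, order = names(layers)),
            class = "vesselfcn_network")
}

conv_layer <- function(name, input, kh, kw, c_in, c_out, pad,
                       init = c("xavier", "zero")) {
  init <- match.arg(init)
  W <- if (init == "xavier") {
    xavier_draw(c(kh, kw, c_in, c_out))
  } else {
    array(0, c(kh, kw, c_in, c_out))
  }
  list(name = name, op = "conv", inputs = input,
       W = W, b = numeric(c_out), pad = as.integer(pad))
}

deconv_layer <- function(name, input, factor, n_ch) {
  k <- bilinear_kernel(factor, n_ch)
  list(name = name, op = "deconv", inputs = input, W = k,
       factor = as.integer(factor),
       stride = as.integer(factor),
       pad = as.integer((dim(k)[1L] - factor) %/% 2L))
}

pool_layer <- function(name, input, k) {
  list(name = name, op = "pool", inputs = input,
       k = as.integer(k), stride = as.integer(k))
}

relu_layer <- function(name, input) {
  list(name = name, op = "relu", inputs = input)
}

# crop `inputs[1]` (top-left) to the spatial dims of `inputs[2]`;
# gradient flows to inputs[1] only.
crop_layer <- function(name, input, ref) {
  list(name = name, op = "crop", inputs = c(input, ref))
}

add_layer <- function(name, a, b) {
  list(name = name, op = "add", inputs = c(a, b))
}

#' Run a network forward pass
#'
#' @param net a `vesselfcn_network`.
#' @param x (H, W, C) input array matching the network's input channels.
#' @param keep keep every intermediate output plus the pooling argmax
#'   caches (required for [net_backward()]).
#' @return list with `out` (the final score map) and, when
#'   `keep = TRUE`, `outs` and `caches`.
#' @export
net_forward <- function(net, x, keep = FALSE) {
  outs <- vector("list", length(net$order))
  names(outs) <- net$order
  caches <- list()
  for (nm in net$order) {
    ly <- net$layers[[nm]]
    outs[[nm]] <- switch(ly$op,
      input = as_feature_map(x),
      conv = {
        w <- ly$W
        kd <- dim(w)
        cf_conv2d_fwd(outs[[ly$inputs]], as.numeric(w), kd[1L], kd[2L],
                      kd[4L], ly$b, ly$pad)
      },
      relu = pmax(outs[[ly$inputs]], 0),
      pool = {
        if (ly$k == 1L && ly$stride == 1L) {
          outs[[ly$inputs]]
        } else {
          r <- cf_maxpool_fwd(outs[[ly$inputs]], ly$k, ly$stride)
          if (keep) caches[[nm]] <- r$idx
          r$y
        }
      },
      deconv = {
        kd <- dim(ly$W)
        cf_deconv_fwd(outs[[ly$inputs]], as.numeric(ly$W), kd[1L], kd[2L],
                      kd[4L], ly$stride, ly$pad)
      },
      crop = {
        src <- outs[[ly$inputs[1L]]]
        ref <- outs[[ly$inputs[2L]]]
        dr <- dim(ref)
        src[seq_len(dr[1L]), seq_len(dr[2L]), , drop = FALSE]
      },
      add = outs[[ly$inputs[1L]]] + outs[[ly$inputs[2L]]],
      stop("unknown layer op: ", ly$op)
    )
  }
  list(out = outs[[net$order[length(net$order)]]],
       outs = if (keep) outs else NULL,
       caches = if (keep) caches else NULL)
}

#' Run a network backward pass
#'
#' @param net a `vesselfcn_network`.
#' @param fwd result of [net_forward()] with `keep = TRUE`.
#' @param gout gradient of the loss with respect to the final score map.
#' @return named list of parameter gradients (`"<layer>.W"`,
#'   `"<layer>.b"`).
#' @export
net_backward <- function(net, fwd, gout) {
  outs <- fwd$outs
  gmap <- list()
  gmap[[net$order[length(net$order)]]] <- gout
  grads <- list()
  for (nm in rev(net$order)) {
    g <- gmap[[nm]]
    if (is.null(g)) next
    ly <- net$layers[[nm]]
    push <- function(target, gr) {
      gmap[[target]] <<- if (is.null(gmap[[target]])) gr else gmap[[target]] + gr
    }
    switch(ly$op,
      input = NULL,
      conv = {
        kd <- dim(ly$W)
        r <- cf_conv2d_bwd(outs[[ly$inputs]], as.numeric(ly$W), kd[1L],
                           kd[2L], kd[4L], g, ly$pad)
        grads[[paste0(nm, ".W")]] <- array(r$gw, kd)
        grads[[paste0(nm, ".b")]] <- as.numeric(r$gb)
        push(ly$inputs, r$gx)
      },
      relu = push(ly$inputs, g * (outs[[ly$inputs]] > 0)),
      pool = {
        if (ly$k == 1L && ly$stride == 1L) {
          push(ly$inputs, g)
        } else {
          d <- dim(outs[[ly$inputs]])
          push(ly$inputs, cf_maxpool_bwd(g, fwd$caches[[nm]], d[1L], d[2L]))
        }
      },
      deconv = {
        kd <- dim(ly$W)
        r <- cf_deconv_bwd(outs[[ly$inputs]], as.numeric(ly$W), kd[1L],
                           kd[2L], kd[4L], ly$stride, ly$pad, g)
        grads[[paste0(nm, ".W")]] <- array(r$gw, kd)
        push(ly$inputs, r$gx)
      },
      crop = {
        src <- outs[[ly$inputs[1L]]]
        gfull <- array(0, dim(src))
        gfull[seq_len(dim(g)[1L]), seq_len(dim(g)[2L]), ] <- g
        push(ly$inputs[1L], gfull)
      },
      add = {
        push(ly$inputs[1L], g)
        push(ly$inputs[2L], g)
      }
    )
    gmap[[nm]] <- NULL  # free
  }
  grads
}

#' Trainable parameters of a network
#'
#' @param net a `vesselfcn_network`.
#' @return named list of parameter arrays (`"<layer>.W"`, `"<layer>.b"`).
#' @export
net_parameters <- function(net) {
  out <- list()
  for (nm in net$order) {
    ly <- net$layers[[nm]]
    if (!is.null(ly$W)) out[[paste0(nm, ".W")]] <- ly$W
    if (!is.null(ly$b)) out[[paste0(nm, ".b")]] <- ly$b
  }
  out
}

#' Replace the trainable parameters of a network
#'
#' @param net a `vesselfcn_network`.
#' @param params named list in the layout of [net_parameters()].
#' @return the network with the parameters installed.
#' @export
net_set_parameters <- function(net, params) {
  for (pn in names(params)) {
    parts <- strsplit(pn, ".", fixed = TRUE)[[1L]]
    nm <- paste(parts[-length(parts)], collapse = ".")
    slot <- parts[length(parts)]
    net$layers[[nm]][[slot]] <- params[[pn]]
  }
  net
}

#' Number of spatial-reduction pooling stages in a network
#'
#' Counts pooling layers whose window actually reduces the spatial extent
#' (k > 1); a 1x1/stride-1 pooling is the identity and is not counted.
#'
#' @param net a `vesselfcn_network`.
#' @return integer count.
#' @export
n_spatial_reductions <- function(net) {
  sum(vapply(net$layers, function(ly) {
    identical(ly$op, "pool") && ly$k > 1L
  }, logical(1)))
}

#' Final upsampling factor of a network
#'
#' The factor of the last deconvolution (learned upsampling) layer in the
#' graph: 2 for the proposed all-stage-fusion variant, 8 for FCN-8s.
#'
#' @param net a `vesselfcn_network`.
#' @return integer factor.
#' @export
final_upsample_factor <- function(net) {
  fac <- NA_integer_
  for (ly in net$layers) if (identical(ly$op, "deconv")) fac <- ly$factor
  fac
}

vgg_channels <- function(width_multiplier) {
  pmax(1L, as.integer(round(c(64, 128, 256, 512, 512) * width_multiplier)))
}

# Shared VGG-style encoder: 5 stages of 3x3 same-padded conv + ReLU blocks,
# each closed by a pooling layer (k per stage). Returns layers + per-stage
# pool names.
encoder_layers <- function(channels, pool_k) {
  nconv <- c(2L, 2L, 3L, 3L, 3L)
  layers <- list()
  layers[["input"]] <- list(name = "input", op = "input", inputs = character())
  prev <- "input"
  c_in <- 3L
  pools <- character(5L)
  for (s in 1:5) {
    for (i in seq_len(nconv[s])) {
      cn <- sprintf("conv%d_%d", s, i)
      layers[[cn]] <- conv_layer(cn, prev, 3L, 3L, c_in, channels[s], pad = 1L)
      rn <- sprintf("relu%d_%d", s, i)
      layers[[rn]] <- relu_layer(rn, cn)
      prev <- rn
      c_in <- channels[s]
    }
    pn <- sprintf("pool%d", s)
    layers[[pn]] <- pool_layer(pn, prev, pool_k[s])
    prev <- pn
    pools[s] <- pn
  }
  list(layers = layers, pools = pools)
}

#' Build the proposed all-stage-fusion FCN
#'
#' A VGG-16-style encoder in which only the first four pooling layers
#' reduce the spatial extent (the fifth pools over a 1x1 region, i.e. does
#' nothing), without the two large fully-connected-equivalent convolutions.
#' A 1x1 score convolution taps the output of every pooling stage; the
#' deepest score map is fused (summed) with the stage-4 map at the same
#' resolution, then repeatedly 2x-upsampled and fused with each shallower
#' stage's score map, so the final learned upsampling is only 2x.
#'
#' @param n_classes number of output classes (>= 2; default 2,
#'   vessel vs background).
#' @param width_multiplier scales the VGG block widths 64/128/256/512/512
#'   (in (0, 1]); 1/8 is the reduced desk preset.
#' @param seed integer seed for the Xavier initialization.
#' @return a `vesselfcn_network` whose forward pass maps an (H, W, 3) tile
#'   to an (H, W, n_classes) score map for any H, W >= 32.
#' @export
build_proposed_fcn <- function(n_classes = 2L, width_multiplier = 1,
                               seed = 1L) {
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  if (width_multiplier <= 0 || width_multiplier > 1) {
    stop("`width_multiplier` must be in (0, 1]")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ch <- vgg_channels(width_multiplier)
  enc <- encoder_layers(ch, pool_k = c(2L, 2L, 2L, 2L, 1L))
  layers <- enc$layers
  for (s in 1:5) {
    sn <- sprintf("score%d", s)
    layers[[sn]] <- conv_layer(sn, enc$pools[s], 1L, 1L, ch[s], n_classes,
                               pad = 0L)
  }
  # pool5 is a 1x1 no-op so score5 and score4 share a resolution
  layers[["fuse4"]] <- add_layer("fuse4", "score5", "score4")
  prev <- "fuse4"
  for (s in 3:1) {
    up <- sprintf("up%d", s)
    layers[[up]] <- deconv_layer(up, prev, 2L, n_classes)
    cr <- sprintf("crop%d", s)
    layers[[cr]] <- crop_layer(cr, up, sprintf("score%d", s))
    fu <- sprintf("fuse%d", s)
    layers[[fu]] <- add_layer(fu, cr, sprintf("score%d", s))
    prev <- fu
  }
  layers[["up_final"]] <- deconv_layer("up_final", prev, 2L, n_classes)
  layers[["out"]] <- crop_layer("out", "up_final", "input")
  spec <- list(arch = "proposed", n_classes = as.integer(n_classes),
               width_multiplier = width_multiplier, channels = ch,
               final_upsample_factor = 2L, seed = as.integer(seed))
  new_network(spec, layers)
}

#' Build the FCN-8s comparison baseline
#'
#' The standard FCN-8s topology at a configurable width: five
#' spatial-reduction poolings, 7x7/1x1 fully-connected-equivalent
#' convolutions, fusion of the pool4 and pool3 score maps with the deepest
#' scores, and a final learned 8x upsampling.
#'
#' @inheritParams build_proposed_fcn
#' @return a `vesselfcn_network`; same forward contract as the proposed
#'   variant.
#' @export
build_fcn8s_baseline <- function(n_classes = 2L, width_multiplier = 1,
                                 seed = 1L) {
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  if (width_multiplier <= 0 || width_multiplier > 1) {
    stop("`width_multiplier` must be in (0, 1]")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ch <- vgg_channels(width_multiplier)
  fc_ch <- max(1L, as.integer(round(4096 * width_multiplier)))
  enc <- encoder_layers(ch, pool_k = c(2L, 2L, 2L, 2L, 2L))
  layers <- enc$layers
  layers[["fc6"]] <- conv_layer("fc6", "pool5", 7L, 7L, ch[5], fc_ch, pad = 3L)
  layers[["relu6"]] <- relu_layer("relu6", "fc6")
  layers[["fc7"]] <- conv_layer("fc7", "relu6", 1L, 1L, fc_ch, fc_ch, pad = 0L)
  layers[["relu7"]] <- relu_layer("relu7", "fc7")
  layers[["score_fr"]] <- conv_layer("score_fr", "relu7", 1L, 1L, fc_ch,
                                     n_classes, pad = 0L)
  layers[["score_pool4"]] <- conv_layer("score_pool4", "pool4", 1L, 1L,
                                        ch[4], n_classes, pad = 0L)
  layers[["score_pool3"]] <- conv_layer("score_pool3", "pool3", 1L, 1L,
                                        ch[3], n_classes, pad = 0L)
  layers[["upscore2"]] <- deconv_layer("upscore2", "score_fr", 2L, n_classes)
  layers[["crop4"]] <- crop_layer("crop4", "upscore2", "score_pool4")
  layers[["fuse_pool4"]] <- add_layer("fuse_pool4", "crop4", "score_pool4")
  layers[["upscore_pool4"]] <- deconv_layer("upscore_pool4", "fuse_pool4",
                                            2L, n_classes)
  layers[["crop3"]] <- crop_layer("crop3", "upscore_pool4", "score_pool3")
  layers[["fuse_pool3"]] <- add_layer("fuse_pool3", "crop3", "score_pool3")
  layers[["upscore8"]] <- deconv_layer("upscore8", "fuse_pool3", 8L, n_classes)
  layers[["out"]] <- crop_layer("out", "upscore8", "input")
  spec <- list(arch = "fcn8s", n_classes = as.integer(n_classes),
               width_multiplier = width_multiplier, channels = ch,
               fc_channels = fc_ch, final_upsample_factor = 8L,
               seed = as.integer(seed))
  new_network(spec, layers)
}

#' @export
print.vesselfcn_network <- function(x, ...) {
  np <- sum(vapply(net_parameters(x), length, numeric(1)))
  cat(sprintf(
    "<vesselfcn_network> arch=%s classes=%d width=%.3g layers=%d parameters=%d\n",
    x$spec$arch, x$spec$n_classes, x$spec$width_multiplier,
    length(x$layers), np))
  invisible(x)
}

#' Predict a binary vessel mask for a tile
#'
#' Standardizes the tile with the stored training-set statistics, runs the
#' forward pass and takes the per-pixel argmax over class scores. Score
#' ties are broken toward the lower class index (background).
#'
#' @param object a trained `vesselfcn_network`.
#' @param tile (H, W, 3) RGB array, 0-255 integer or numeric, H, W >= 32.
#' @param stats `NormalizationStats` from [fit_standardizer()].
#' @param ... unused.
#' @return integer (H, W) matrix with 1 = microvessel foreground.
#' @export
predict.vesselfcn_network <- function(object, tile, stats, ...) {
  tile <- as_feature_map(tile)
  if (nrow(tile) < 32L || ncol(tile) < 32L) {
    stop("tile must be at least 32 x 32 pixels")
  }
  x <- standardize(tile, stats)
  scores <- net_forward(object, x)$out
  score_argmax(scores)
}

# Per-pixel argmax with ties toward the lower class index.
score_argmax <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, d[1L] * d[2L], d[3L])
  lab <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1L], d[2L])
}
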