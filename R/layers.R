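# Layer primitives: the building blocks the network graphs are assembled
# from, each also exported on its own so its numerics can be inspected.

drop_channel <- function(y) array(y, dim(y)[1:2])

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  storage.mode(x) <- "double"
  x
}

#' 2-D convolution of a single-channel feature map
#'
#' True mathematical convolution: the kernel is reflected, so
#' `output[x, y] = sum_a sum_b input(x - a, y - b) * kernel(a, b)`.
#' This is the textbook operation the convolutional layers are built on;
#' the network layers themselves use the machine-learning cross-correlation
#' convention (no reflection), which differs only by a kernel flip.
#'
#' @param input numeric matrix (single-channel feature map).
#' @param kernel numeric matrix, the filter.
#' @param mode `"valid"` evaluates only fully overlapping positions;
#'   `"same_zero_pad"` zero-pads so the output matches the input size
#'   (odd-sized kernels only).
#' @return numeric matrix with the convolved values.
#' @examples
#' convolve2d(matrix(1:9, 3), matrix(c(1, 0, 0, 1), 2), mode = "valid")
#' @export
convolve2d <- function(input, kernel, mode = c("valid", "same_zero_pad")) {
  mode <- match.arg(mode)
  if (!is.matrix(input) || length(input) == 0L) {
    stop("`input` must be a non-empty numeric matrix")
  }
  if (!is.matrix(kernel) || length(kernel) == 0L) {
    stop("`kernel` must be a non-empty numeric matrix")
  }
  kh <- nrow(kernel)
  kw <- ncol(kernel)
  if (mode == "valid" && (kh > nrow(input) || kw > ncol(input))) {
    stop("kernel larger than input in valid mode")
  }
  if (mode == "same_zero_pad" && (kh %% 2L == 0L || kw %% 2L == 0L)) {
    stop("same_zero_pad mode requires odd kernel dimensions")
  }
  if (mode == "same_zero_pad") {
    # pad each dimension by its own half-width, then run in valid mode
    ph <- (kh - 1L) %/% 2L
    pw <- (kw - 1L) %/% 2L
    padded <- matrix(0, nrow(input) + 2L * ph, ncol(input) + 2L * pw)
    padded[ph + seq_len(nrow(input)), pw + seq_len(ncol(input))] <- input
    input <- padded
  }
  # convolution = cross-correlation with the kernel rotated 180 degrees
  flipped <- kernel[kh:1, kw:1, drop = FALSE]
  out <- cf_conv2d_fwd(as_feature_map(input),
                       as.numeric(flipped), kh, kw, 1L,
                       0, 0L)
  drop_channel(out)
}

#' Max pooling over k-by-k regions
#'
#' Each output cell is the maximum of its `k` x `k` window. `k = 1` with
#' stride 1 is the identity. Partial windows at the lower/right border are
#' pooled over their in-bounds pixels (ceil-mode), so no input pixel is
#' dropped when the extent is not a multiple of the stride.
#'
#' @param input numeric matrix or (H, W, C) array.
#' @param k window size (positive integer).
#' @param stride step between windows; defaults to `k`.
#' @return pooled array with the same number of channels.
#' @export
max_pool <- function(input, k, stride = k) {
  stopifnot(k >= 1L, stride >= 1L)
  x <- as_feature_map(input)
  if (stride > nrow(x) || stride > ncol(x)) {
    stop("stride exceeds the input extent")
  }
  y <- cf_maxpool_fwd(x, as.integer(k), as.integer(stride))$y
  if (is.matrix(input)) drop_channel(y) else y
}

#' Rectified linear activation
#'
#' Thresholds activations at zero: `max(0, x)` elementwise. Idempotent.
#'
#' @param input numeric vector, matrix or array.
#' @return object of the same shape with negative entries replaced by 0.
#' @export
relu <- function(input) {
  pmax(input, 0)
}

#' Learned upsampling (transposed convolution)
#'
#' "Deconvolution" in the FCN sense: up-pooling followed by convolution,
#' with a learnable kernel. With kernel size `2 * factor`, stride `factor`
#' and padding `factor / 2` the spatial extent is multiplied exactly by
#' `factor`.
#'
#' @param input numeric matrix or (H, W, C) array.
#' @param kernel 4-D array `(kh, kw, c_in, c_out)`; for `factor = 1` a 1x1
#'   identity kernel leaves the input unchanged. See [bilinear_kernel()] for
#'   the standard initialization.
#' @param factor integer upsampling factor (>= 1).
#' @return array with spatial dims multiplied by `factor`.
#' @export
deconvolve <- function(input, kernel, factor) {
  if (factor < 1L) stop("`factor` must be >= 1")
  x <- as_feature_map(input)
  if (!is.array(kernel) || length(dim(kernel)) != 4L) {
    stop("`kernel` must be a 4-D (kh, kw, c_in, c_out) array")
  }
  kd <- dim(kernel)
  if (kd[3L] != dim(x)[3L]) stop("kernel input channels do not match input")
  if (factor == 1L) {
    stride <- 1L
    pad <- (kd[1L] - 1L) %/% 2L
  } else {
    stride <- as.integer(factor)
    pad <- as.integer((kd[1L] - stride) %/% 2L)
  }
  y <- cf_deconv_fwd(x, as.numeric(kernel), kd[1L], kd[2L], kd[4L],
                     stride, pad)
  if (is.matrix(input) && kd[4L] == 1L) drop_channel(y) else y
}

#' Bilinear interpolation kernel for learned upsampling
#'
#' The standard FCN initialization for deconvolution layers: a separable
#' triangle filter of size `2 * factor` that performs bilinear
#' interpolation, replicated per channel with no cross-channel mixing.
#'
#' @param factor integer upsampling factor.
#' @param n_channels number of channels (kernel is `n_channels` ->
#'   `n_channels`, diagonal).
#' @return 4-D array `(2*factor, 2*factor, n_channels, n_channels)`.
#' @export
bilinear_kernel <- function(factor, n_channels) {
  stopifnot(factor >= 1L, n_channels >= 1L)
  size <- 2L * factor - factor %% 2L
  f <- ceiling(size / 2)
  center <- if (size %% 2L == 1L) (size - 1) / 2 else f - 0.5
  w1 <- 1 - abs(seq_len(size) - 1 - center) / f
  k2 <- outer(w1, w1)
  out <- array(0, c(size, size, n_channels, n_channels))
  for (c in seq_len(n_channels)) out[, , c, c] <- k2
  out
}

#' Per-pixel softmax cross-entropy loss
#'
#' The training criterion: per-pixel softmax over class scores followed by
#' the mean negative log-probability of the true class (multinomial
#' logistic loss), averaged over all pixels.
#'
#' @param scores (H, W, n_classes) array of real-valued class scores.
#' @param labels integer matrix (H, W) with entries in `0:(n_classes - 1)`.
#' @return non-negative scalar loss.
#' @export
softmax_with_loss <- function(scores, labels) {
  softmax_loss_grad(scores, labels, want_grad = FALSE)$loss
}

# Shared softmax/NLL evaluation; grad is d(loss)/d(scores) for the
# pixel-mean reduction.
softmax_loss_grad <- function(scores, labels, want_grad = TRUE) {
  scores <- as_feature_map(scores)
  d <- dim(scores)
  if (!all(dim(labels) == d[1:2])) {
    stop("scores and labels must share spatial dimensions")
  }
  ncl <- d[3L]
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= ncl)) {
    stop("labels must lie in 0:(n_classes - 1)")
  }
  n <- d[1L] * d[2L]
  m <- matrix(scores, n, ncl)
  mx <- m[cbind(seq_len(n), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  s <- rowSums(e)
  p_true <- e[cbind(seq_len(n), lab + 1L)] / s
  loss <- -mean(log(p_true))
  if (!want_grad) return(list(loss = loss))
  p <- e / s
  p[cbind(seq_len(n), lab + 1L)] <- p[cbind(seq_len(n), lab + 1L)] - 1
  list(loss = loss, grad = array(p / n, d))
}

#' Xavier (Glorot) uniform weight initialization
#'
#' Draws weights uniformly on `[-sqrt(3 / fan_in), +sqrt(3 / fan_in)]`,
#' where for a `(kh, kw, c_in, c_out)` kernel `fan_in = kh * kw * c_in`,
#' giving each draw variance `1 / fan_in`.
#'
#' @param shape integer vector of kernel dimensions; for convolution
#'   kernels use `(kh, kw, c_in, c_out)`.
#' @param seed integer seed making the draw deterministic.
#' @return array of the requested shape.
#' @export
xavier_init <- function(shape, seed) {
  stopifnot(all(shape >= 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  xavier_draw(shape)
}

# Draw from the current RNG stream (used by the builders, which seed once).
xavier_draw <- function(shape) {
  fan_in <- if (length(shape) >= 3L) prod(shape[-length(shape)]) else shape[1L]
  c0 <- sqrt(3 / fan_in)
  array(runif(prod(shape), -c0, c0), shape)
}
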