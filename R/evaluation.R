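# Segmentation evaluation: pixel-level metrics from a class confusion
# matrix, and object-level FP/FN counting of matched vessel components.

#' Pixel confusion matrix between prediction and ground truth
#'
#' Entry (i, j) counts the pixels of true class i predicted as class j
#' (classes 0-based in the masks, 1-based in the matrix rows/columns).
#'
#' @param pred,truth integer label matrices of equal dimensions with
#'   entries in `0:(n_cl - 1)`.
#' @param n_cl number of classes (default 2).
#' @return a `vesselfcn_confusion` object: `counts` (n_cl x n_cl integer
#'   matrix) and `n_cl`.
#' @export
confusion_matrix <- function(pred, truth, n_cl = 2L) {
  if (!all(dim(pred) == dim(truth))) {
    stop("pred and truth must share dimensions")
  }
  p <- as.integer(pred)
  t <- as.integer(truth)
  if (any(p < 0L | p >= n_cl) || any(t < 0L | t >= n_cl)) {
    stop("labels must lie in 0:(n_cl - 1)")
  }
  counts <- matrix(tabulate(t * n_cl + p + 1L, nbins = n_cl * n_cl),
                   n_cl, n_cl, byrow = TRUE)
  structure(list(counts = counts, n_cl = as.integer(n_cl)),
            class = "vesselfcn_confusion")
}

#' Coerce a plain count matrix to a confusion object
#'
#' @param cm a `vesselfcn_confusion` (returned unchanged) or a square
#'   count matrix with rows indexed by true class.
#' @param n_cl unused; the class count is taken from the matrix.
#' @return a `vesselfcn_confusion`.
#' @export
as_confusion <- function(cm, n_cl = NULL) {
  if (inherits(cm, "vesselfcn_confusion")) return(cm)
  if (is.matrix(cm)) {
    return(structure(list(counts = cm, n_cl = nrow(cm)),
                     class = "vesselfcn_confusion"))
  }
  stop("`cm` must be a confusion matrix")
}

#' Pixel accuracy, mean accuracy and mean IoU
#'
#' From confusion counts `n_ij` (true class i predicted j) with
#' `t_i = sum_j n_ij`:
#' * `pA  = sum_i n_ii / sum_i t_i`
#' * `mA  = (1 / n_cl) sum_i n_ii / t_i`
#' * `mIU = (1 / n_cl) sum_i n_ii / (t_i + sum_j n_ji - n_ii)`
#'
#' Degenerate classes are excluded from the averages instead of
#' contributing 0/0: a class absent from the truth is dropped from `mA`,
#' and a class absent from both truth and prediction is dropped from
#' `mIU`. A perfect prediction with all classes present scores exactly 1
#' on all three.
#'
#' @param cm a `vesselfcn_confusion` or plain square count matrix.
#' @return tibble with one row: `pA`, `mA`, `mIU`.
#' @export
pixel_metrics <- function(cm) {
  cm <- as_confusion(cm)
  counts <- cm$counts
  if (sum(counts) == 0) stop("confusion matrix is empty")
  t_i <- rowSums(counts)
  p_i <- colSums(counts)
  d <- diag(counts)
  pa <- sum(d) / sum(t_i)
  ma_classes <- t_i > 0
  ma <- mean(d[ma_classes] / t_i[ma_classes])
  iu_classes <- (t_i + p_i) > 0
  iu_den <- t_i + p_i - d
  miu <- mean(d[iu_classes] / iu_den[iu_classes])
  tibble::tibble(pA = pa, mA = ma, mIU = miu)
}

#' Object-matching configuration
#'
#' Controls how predicted and true vessel objects are extracted and
#' matched: connected components (8-connectivity by default, vessels being
#' blob-like) smaller than `min_component_px` are discarded, and a
#' predicted component counts as a detection when its best one-to-one IoU
#' with a truth component reaches `iou_threshold`.
#'
#' @param min_component_px minimum component size in pixels (default 30).
#' @param iou_threshold IoU required for a match, in (0, 1] (default 0.25).
#' @param connectivity 4 or 8 (default 8).
#' @return a `vesselfcn_match_config` list.
#' @export
object_match_config <- function(min_component_px = 30L, iou_threshold = 0.25,
                                connectivity = 8L) {
  stopifnot(min_component_px >= 0L, iou_threshold > 0, iou_threshold <= 1,
            connectivity %in% c(4L, 8L))
  structure(list(min_component_px = as.integer(min_component_px),
                 iou_threshold = iou_threshold,
                 connectivity = as.integer(connectivity)),
            class = "vesselfcn_match_config")
}

#' Extract vessel components from a binary mask
#'
#' Labels connected foreground components at the configured connectivity
#' and drops components below the minimum size.
#'
#' @param mask binary integer matrix (values 0/1).
#' @param config an [object_match_config()].
#' @return list of components, each a list with `id`, `size` and `pixels`
#'   (n x 2 matrix of 0-based row/col coordinates); the label matrix is
#'   attached as attribute `"labels"`.
#' @export
extract_components <- function(mask, config = object_match_config()) {
  check_binary_mask(mask)
  m <- mask
  storage.mode(m) <- "integer"
  lab <- cf_label_components(m, config$connectivity)
  n <- max(lab)
  comps <- list()
  for (id in seq_len(n)) {
    w <- which(lab == id)
    if (length(w) < config$min_component_px) next
    comps[[length(comps) + 1L]] <- list(
      id = id, size = length(w),
      pixels = cbind(row = (w - 1L) %% nrow(m),
                     col = (w - 1L) %/% nrow(m))
    )
  }
  attr(comps, "labels") <- lab
  comps
}

check_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary with values 0/1")
  invisible(mask)
}

#' Object-level false positives and false negatives
#'
#' Extracts components from both masks, computes all pairwise IoUs, and
#' matches predicted to true components greedily in descending IoU under a
#' one-to-one constraint. Pairs with IoU at or above the threshold are
#' true positives; unmatched predicted components are false positives
#' ("predicted microvessels that were not actually microvessels") and
#' unmatched truth components are false negatives ("microvessels that were
#' not successfully detected").
#'
#' @param pred,truth binary masks of equal dimensions.
#' @param config an [object_match_config()].
#' @return list with `tp`, `fp`, `fn` and `matches`, a tibble of matched
#'   pairs (`pred_id`, `truth_id`, `iou`).
#' @export
count_fp_fn <- function(pred, truth, config = object_match_config()) {
  if (!all(dim(pred) == dim(truth))) {
    stop("pred and truth must share dimensions")
  }
  pc <- extract_components(pred, config)
  tc <- extract_components(truth, config)
  np <- length(pc)
  nt <- length(tc)
  pairs <- NULL
  if (np > 0L && nt > 0L) {
    key <- function(px) px[, 1L] + nrow(pred) * px[, 2L]
    tkeys <- lapply(tc, function(c) key(c$pixels))
    for (i in seq_len(np)) {
      pk <- key(pc[[i]]$pixels)
      for (j in seq_len(nt)) {
        inter <- length(intersect(pk, tkeys[[j]]))
        if (inter == 0L) next
        iou <- inter / (length(pk) + length(tkeys[[j]]) - inter)
        pairs <- rbind(pairs, c(i, j, iou))
      }
    }
  }
  matches <- tibble::tibble(pred_id = integer(), truth_id = integer(),
                            iou = numeric())
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs[, 3L], pairs[, 1L], pairs[, 2L]), ,
                   drop = FALSE]
    used_p <- logical(np)
    used_t <- logical(nt)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]
      j <- pairs[r, 2L]
      if (used_p[i] || used_t[j]) next
      if (pairs[r, 3L] < config$iou_threshold) next
      used_p[i] <- TRUE
      used_t[j] <- TRUE
      matches <- rbind(matches,
                       tibble::tibble(pred_id = as.integer(i),
                                      truth_id = as.integer(j),
                                      iou = pairs[r, 3L]))
    }
  }
  tp <- nrow(matches)
  list(tp = tp, fp = np - tp, fn = nt - tp, matches = matches)
}
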