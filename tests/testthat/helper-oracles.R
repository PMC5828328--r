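# Independent brute-force oracles. These re-derive each quantity with
# plain loops, deliberately sharing no code with the package internals.

# true convolution (kernel reflected), valid positions only
oracle_convolve_valid <- function(input, kernel) {
  kh <- nrow(kernel)
  kw <- ncol(kernel)
  out <- matrix(0, nrow(input) - kh + 1, ncol(input) - kw + 1)
  for (x in seq_len(nrow(out))) {
    for (y in seq_len(ncol(out))) {
      acc <- 0
      for (a in 0:(kh - 1)) {
        for (b in 0:(kw - 1)) {
          acc <- acc + input[x + kh - 1 - a, y + kw - 1 - b] *
            kernel[a + 1, b + 1]
        }
      }
      out[x, y] <- acc
    }
  }
  out
}

# pixel metrics straight from a pair of masks, explicit counting loops
oracle_pixel_metrics <- function(pred, truth, n_cl = 2) {
  n <- matrix(0, n_cl, n_cl)
  for (q in seq_along(pred)) {
    n[truth[q] + 1, pred[q] + 1] <- n[truth[q] + 1, pred[q] + 1] + 1
  }
  diag_sum <- 0
  total <- 0
  acc_terms <- c()
  iu_terms <- c()
  for (i in seq_len(n_cl)) {
    t_i <- sum(n[i, ])
    p_i <- sum(n[, i])
    diag_sum <- diag_sum + n[i, i]
    total <- total + t_i
    if (t_i > 0) acc_terms <- c(acc_terms, n[i, i] / t_i)
    if (t_i + p_i > 0) iu_terms <- c(iu_terms, n[i, i] / (t_i + p_i - n[i, i]))
  }
  list(pA = diag_sum / total, mA = mean(acc_terms), mIU = mean(iu_terms))
}

# BFS connected-component labeling (4- or 8-connectivity)
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (mask[i, j] == 0 || lab[i, j] != 0) next
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (d in seq_len(nrow(nb))) {
          ni <- p[1] + nb[d, 1]
          nj <- p[2] + nb[d, 2]
          if (ni < 1 || ni > H || nj < 1 || nj > W) next
          if (mask[ni, nj] != 0 && lab[ni, nj] == 0) {
            lab[ni, nj] <- nxt
            queue <- c(queue, list(c(ni, nj)))
          }
        }
      }
    }
  }
  lab
}

# exhaustive one-to-one matching: maximize the number of pairs with
# IoU >= threshold over every injective prediction -> truth assignment
oracle_match_counts <- function(pred, truth, min_px = 30, thr = 0.25,
                                connectivity = 8) {
  comp_sets <- function(mask) {
    lab <- oracle_label(mask, connectivity)
    sets <- list()
    for (id in seq_len(max(lab))) {
      w <- which(lab == id)
      if (length(w) >= min_px) sets[[length(sets) + 1]] <- w
    }
    sets
  }
  ps <- comp_sets(pred)
  ts <- comp_sets(truth)
  np <- length(ps)
  nt <- length(ts)
  iou <- matrix(0, max(np, 1), max(nt, 1))
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      inter <- length(intersect(ps[[i]], ts[[j]]))
      iou[i, j] <- inter / (length(ps[[i]]) + length(ts[[j]]) - inter)
    }
  }
  best_tp <- 0
  if (np > 0 && nt > 0) {
    # enumerate assignments of each prediction to a truth id or 0 (none)
    grid <- expand.grid(rep(list(0:nt), np))
    for (r in seq_len(nrow(grid))) {
      asg <- as.integer(grid[r, ])
      used <- asg[asg > 0]
      if (anyDuplicated(used)) next
      tp <- sum(vapply(seq_len(np), function(i) {
        asg[i] > 0 && iou[i, asg[i]] >= thr
      }, logical(1)))
      if (tp > best_tp) best_tp <- tp
    }
  }
  list(tp = best_tp, fp = np - best_tp, fn = nt - best_tp)
}

# direct transposed-convolution loops (for the upsampling layer)
oracle_deconv <- function(x, w4, stride, pad) {
  kh <- dim(w4)[1]
  kw <- dim(w4)[2]
  ci <- dim(w4)[3]
  co <- dim(w4)[4]
  h <- dim(x)[1]
  wd <- dim(x)[2]
  Ho <- (h - 1) * stride - 2 * pad + kh
  Wo <- (wd - 1) * stride - 2 * pad + kw
  y <- array(0, c(Ho, Wo, co))
  for (oc in 1:co) for (ic in 1:ci) for (i in 1:h) for (j in 1:wd) {
    for (a in 1:kh) for (b in 1:kw) {
      oi <- (i - 1) * stride - pad + a
      oj <- (j - 1) * stride - pad + b
      if (oi >= 1 && oi <= Ho && oj >= 1 && oj <= Wo) {
        y[oi, oj, oc] <- y[oi, oj, oc] + x[i, j, ic] * w4[a, b, ic, oc]
      }
    }
  }
  y
}

# distance from a point to the nearest foreground pixel, full double loop
oracle_min_dist <- function(mask, row0, col0) {
  best <- Inf
  for (j in seq_len(ncol(mask))) {
    for (i in seq_len(nrow(mask))) {
      if (mask[i, j] != 0) {
        d <- sqrt((row0 - (i - 1))^2 + (col0 - (j - 1))^2)
        if (d < best) best <- d
      }
    }
  }
  best
}

# small random binary mask helper
random_mask <- function(h, w, p = 0.4) {
  matrix(as.integer(runif(h * w) < p), h, w)
}
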