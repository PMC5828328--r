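# Synthetic H&E-like tile generator: seeded tiles with ground-truth vessel
# masks, cell centroids, and red-blood-cell confounders, emulating 20X
# lung-adenocarcinoma tiles at 0.5 um/pixel. Microvessels appear as a
# bright lumen ringed by elongated endothelial nuclei; the mask covers
# lumen plus wall. RBC clusters mimic vessel colour cues but are never
# foreground.

# H&E-ish colour anchors (RGB, 0-255)
.col_eosin <- c(230, 180, 200)
.col_wall <- c(215, 160, 185)
.col_lumen <- c(245, 240, 245)
.col_nucleus <- c(80, 60, 140)
.col_rbc <- c(200, 60, 60)

#' Configuration of the synthetic tile generator
#'
#' Defaults emulate the source imagery: 384 x 384 tiles at 20X
#' magnification (0.5 um/pixel) with a handful of microvessels, scattered
#' nuclei and red-blood-cell clusters as confounders.
#'
#' @param tile_height_px,tile_width_px tile dimensions (>= 32).
#' @param pixel_size_um physical pixel size in micrometres.
#' @param vessel_count number of non-overlapping vessels to place.
#' @param vessel_radius_px_range `(min, max)` lumen radius in pixels.
#' @param nuclei_density_per_1000px2 scattered nuclei per 1000 square
#'   pixels.
#' @param rbc_cluster_count number of red-blood-cell clusters.
#' @param tumor_cell_fraction probability that a scattered cell is a tumor
#'   cell, in `[0, 1]`.
#' @param noise_sd standard deviation of the additive Gaussian texture
#'   noise (8-bit scale).
#' @param seed integer seed; the same config reproduces a byte-identical
#'   tile.
#' @return a `vesselfcn_synthetic_config` list.
#' @export
synthetic_config <- function(tile_height_px = 384L, tile_width_px = 384L,
                             pixel_size_um = 0.5, vessel_count = 5L,
                             vessel_radius_px_range = c(8L, 20L),
                             nuclei_density_per_1000px2 = 1.5,
                             rbc_cluster_count = 3L,
                             tumor_cell_fraction = 0.5,
                             noise_sd = 8, seed = 1L) {
  cfg <- list(tile_height_px = as.integer(tile_height_px),
              tile_width_px = as.integer(tile_width_px),
              pixel_size_um = pixel_size_um,
              vessel_count = as.integer(vessel_count),
              vessel_radius_px_range = as.integer(vessel_radius_px_range),
              nuclei_density_per_1000px2 = nuclei_density_per_1000px2,
              rbc_cluster_count = as.integer(rbc_cluster_count),
              tumor_cell_fraction = tumor_cell_fraction,
              noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(cfg$tile_height_px >= 32L, cfg$tile_width_px >= 32L,
            cfg$pixel_size_um > 0, cfg$vessel_count >= 0L,
            length(cfg$vessel_radius_px_range) == 2L,
            cfg$vessel_radius_px_range[1L] >= 1L,
            cfg$vessel_radius_px_range[2L] >= cfg$vessel_radius_px_range[1L],
            cfg$nuclei_density_per_1000px2 >= 0,
            cfg$rbc_cluster_count >= 0L,
            cfg$tumor_cell_fraction >= 0, cfg$tumor_cell_fraction <= 1,
            cfg$noise_sd >= 0)
  structure(cfg, class = "vesselfcn_synthetic_config")
}

#' Reduced preset for desk-scale experiments
#'
#' 64 x 64 tiles with two smaller vessels; paired with the 1/8-width
#' networks this keeps a full train/predict/evaluate cycle tractable on a
#' single CPU while preserving the appearance model.
#'
#' @param ... overrides passed to [synthetic_config()]; any field may be
#'   overridden, including the preset ones.
#' @return a `vesselfcn_synthetic_config`.
#' @export
desk_synthetic_config <- function(...) {
  args <- modifyList(list(tile_height_px = 64L, tile_width_px = 64L,
                          vessel_count = 2L,
                          vessel_radius_px_range = c(4L, 8L),
                          rbc_cluster_count = 1L),
                     list(...))
  do.call(synthetic_config, args)
}

# bbox-local rasterization of an (optionally deformed) rotated ellipse:
# returns NULL or list(rows, cols, sel) with `sel` a local logical matrix
ellipse_patch <- function(H, W, cy, cx, a, b, angle,
                          amp = 0, lobes = 0L, phase = 0,
                          grow = 0, ring_inner = NULL) {
  s <- ceiling(max(a, b) * (1 + abs(amp)) + grow + 1)
  i0 <- max(1L, floor(cy - s))
  i1 <- min(H, ceiling(cy + s))
  j0 <- max(1L, floor(cx - s))
  j1 <- min(W, ceiling(cx + s))
  if (i0 > i1 || j0 > j1) return(NULL)
  ii <- i0:i1
  jj <- j0:j1
  u <- outer(ii - 1 - cy, rep(1, length(jj)))
  v <- outer(rep(1, length(ii)), jj - 1 - cx)
  ur <- cos(angle) * u + sin(angle) * v
  vr <- (-sin(angle) * u + cos(angle) * v) * (a / b)
  rho <- sqrt(ur^2 + vr^2)
  base <- a * (1 + amp * sin(lobes * atan2(vr, ur) + phase))
  sel <- rho <= base + grow
  if (!is.null(ring_inner)) sel <- sel & rho > base + ring_inner
  list(rows = ii, cols = jj, sel = sel)
}

# paint `color` (+ jitter) over a patch, optionally keeping off `exclude`
paint_patch <- function(img, patch, color, jitter = 0, exclude = NULL) {
  if (is.null(patch) || !any(patch$sel)) return(img)
  sel <- patch$sel
  if (!is.null(exclude)) sel <- sel & !exclude[patch$rows, patch$cols]
  for (ch in 1:3) {
    sl <- img[patch$rows, patch$cols, ch]
    sl[sel] <- color[ch] + jitter[min(ch, length(jitter))]
    img[patch$rows, patch$cols, ch] <- sl
  }
  img
}

# OR a patch into a full-size logical matrix
apply_patch <- function(target, patch, exclude = NULL) {
  if (is.null(patch)) return(target)
  sel <- patch$sel
  if (!is.null(exclude)) sel <- sel & !exclude[patch$rows, patch$cols]
  target[patch$rows, patch$cols] <- target[patch$rows, patch$cols] | sel
  target
}

patch_overlaps <- function(patch, full) {
  if (is.null(patch)) return(FALSE)
  any(patch$sel & full[patch$rows, patch$cols])
}

#' Generate one synthetic H&E tile with ground truth
#'
#' Renders the eosin background, places `vessel_count` non-overlapping
#' deformed-ellipse vessels (bright lumen plus a wall ring carrying
#' elongated dark nuclei; the mask is lumen union wall), scatters nuclei
#' recorded as cell centroids with tumor / non-tumor classes, adds
#' red-blood-cell clusters that are never mask foreground, and finishes
#' with Gaussian texture noise. Deterministic for a fixed config.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_sample`: `image` (H, W, 3 integer, 0-255), `mask`
#'   (H, W integer, 1 = vessel), `cells` (tibble `row_px`, `col_px`,
#'   `cell_class`; 0-based coordinates), `config_echo`, and `aux` with the
#'   diagnostic `rbc_mask`.
#' @export
generate_sample <- function(config) {
  stopifnot(inherits(config, "vesselfcn_synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  H <- config$tile_height_px
  W <- config$tile_width_px
  rim_w <- 3
  gap <- 2
  img <- array(0, c(H, W, 3))
  tile_jitter <- rnorm(3, 0, 3)
  for (ch in 1:3) img[, , ch] <- .col_eosin[ch] + tile_jitter[ch]

  mask <- matrix(FALSE, H, W)
  keepout <- matrix(FALSE, H, W)  # vessel extent + separation gap
  rmax <- config$vessel_radius_px_range[2L]
  margin <- rmax * 1.2 + rim_w + gap + 1
  vessels <- list()

  for (v in seq_len(config$vessel_count)) {
    placed <- FALSE
    for (try in seq_len(100L)) {
      if (margin >= H - 1 - margin || margin >= W - 1 - margin) break
      r <- runif(1, config$vessel_radius_px_range[1L], rmax)
      cy <- runif(1, margin, H - 1 - margin)
      cx <- runif(1, margin, W - 1 - margin)
      angle <- runif(1, 0, pi)
      ecc <- runif(1, 0.6, 0.95)
      amp <- runif(1, 0.08, 0.18)
      lobes <- sample(3:6, 1)
      phase <- runif(1, 0, 2 * pi)
      geo <- list(cy = cy, cx = cx, a = r, b = r * ecc, angle = angle,
                  amp = amp, lobes = lobes, phase = phase)
      dil <- ellipse_patch(H, W, cy, cx, r, r * ecc, angle, amp, lobes,
                           phase, grow = rim_w + gap)
      if (patch_overlaps(dil, mask)) next
      lumen <- ellipse_patch(H, W, cy, cx, r, r * ecc, angle, amp, lobes,
                             phase, grow = 0)
      wall <- ellipse_patch(H, W, cy, cx, r, r * ecc, angle, amp, lobes,
                            phase, grow = rim_w, ring_inner = 0)
      mask <- apply_patch(apply_patch(mask, lumen), wall)
      keepout <- apply_patch(keepout, dil)
      vessels[[length(vessels) + 1L]] <- c(geo, list(lumen = lumen,
                                                     wall = wall))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place ", config$vessel_count,
           " non-overlapping vessels on a ", H, " x ", W,
           " tile after 100 retries; enlarge the tile or reduce ",
           "vessel_count / radii")
    }
  }

  # vessel rendering: wall shade, bright lumen, tangential rim nuclei
  for (ve in vessels) {
    img <- paint_patch(img, ve$wall, .col_wall, rnorm(3, 0, 2))
    img <- paint_patch(img, ve$lumen, .col_lumen, rnorm(3, 0, 2))
    n_rim <- sample(3:6, 1)
    th <- sort(runif(n_rim, 0, 2 * pi))
    for (t in th) {
      rr <- ve$a * (1 + ve$amp * sin(ve$lobes * t + ve$phase)) + rim_w / 2
      ur0 <- rr * cos(t)
      vr0 <- rr * sin(t) * (ve$b / ve$a)
      ny <- ve$cy + cos(ve$angle) * ur0 - sin(ve$angle) * vr0
      nx <- ve$cx + sin(ve$angle) * ur0 + cos(ve$angle) * vr0
      # elongated nucleus, roughly tangent to the wall
      radial <- atan2(nx - ve$cx, ny - ve$cy)
      nuc <- ellipse_patch(H, W, ny, nx, 3, 1.2, radial + pi / 2)
      img <- paint_patch(img, nuc, .col_nucleus, rnorm(3, 0, 4))
    }
  }

  # scattered nuclei = cell centroids (kept off the vessels)
  n_cells <- round(config$nuclei_density_per_1000px2 * H * W / 1000)
  cell_rows <- numeric(0)
  cell_cols <- numeric(0)
  for (k in seq_len(n_cells)) {
    for (try in seq_len(20L)) {
      py <- runif(1, 2, H - 3)
      px <- runif(1, 2, W - 3)
      if (keepout[round(py) + 1L, round(px) + 1L]) next
      a <- runif(1, 2, 3.5)
      nuc <- ellipse_patch(H, W, py, px, a, a * runif(1, 0.6, 1),
                           runif(1, 0, pi))
      img <- paint_patch(img, nuc, .col_nucleus, rnorm(3, 0, 4),
                         exclude = mask)
      cell_rows <- c(cell_rows, py)
      cell_cols <- c(cell_cols, px)
      break
    }
  }
  classes <- if (length(cell_rows) > 0) {
    ifelse(runif(length(cell_rows)) < config$tumor_cell_fraction,
           "tumor", "non_tumor")
  } else {
    character(0)
  }

  # RBC clusters: vessel-like colour cues that are never mask foreground
  rbc <- matrix(FALSE, H, W)
  for (k in seq_len(config$rbc_cluster_count)) {
    for (try in seq_len(50L)) {
      cr <- runif(1, min(5, H / 8), min(10, H / 6))
      py <- runif(1, cr + 1, H - cr - 2)
      px <- runif(1, cr + 1, W - cr - 2)
      if (keepout[round(py) + 1L, round(px) + 1L]) next
      n_blob <- sample(8:18, 1)
      for (bl in seq_len(n_blob)) {
        by <- py + rnorm(1, 0, cr / 2)
        bx <- px + rnorm(1, 0, cr / 2)
        br <- runif(1, 1.5, 3)
        blob <- ellipse_patch(H, W, by, bx, br, br * runif(1, 0.7, 1),
                              runif(1, 0, pi))
        rbc <- apply_patch(rbc, blob, exclude = mask)
        img <- paint_patch(img, blob, .col_rbc, rnorm(3, 0, 5),
                           exclude = mask)
      }
      break
    }
  }

  img <- img + array(rnorm(H * W * 3, 0, config$noise_sd), c(H, W, 3))
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  maski <- matrix(as.integer(mask), H, W)

  structure(list(
    image = img,
    mask = maski,
    cells = tibble::tibble(row_px = cell_rows, col_px = cell_cols,
                           cell_class = classes),
    config_echo = config,
    aux = list(rbc_mask = matrix(as.integer(rbc), H, W))
  ), class = "synthetic_sample")
}

#' Generate a dataset of synthetic tiles
#'
#' Derives one seed per tile deterministically from the master seed and
#' calls [generate_sample()] for each, so tiles are mutually distinct and
#' the whole dataset is reproducible.
#'
#' @param config a [synthetic_config()] shared by all tiles (its own seed
#'   is ignored).
#' @param n_tiles number of tiles (>= 1).
#' @param seed master seed.
#' @return list of `synthetic_sample` objects.
#' @export
generate_dataset <- function(config, n_tiles, seed = config$seed) {
  stopifnot(n_tiles >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tile_seeds <- sample.int(.Machine$integer.max - 1L, n_tiles)
  lapply(tile_seeds, function(s) {
    generate_sample(modifyList(config, list(seed = s)))
  })
}

#' Display a synthetic tile and its vessel mask
#'
#' @param x a `synthetic_sample`.
#' @param what `"image"`, `"mask"`, or `"both"` (side by side).
#' @param ... unused.
#' @export
plot.synthetic_sample <- function(x, what = c("both", "image", "mask"), ...) {
  what <- match.arg(what)
  show_img <- function(a, main) {
    r <- grDevices::as.raster(a / 255)
    graphics::plot(c(0, ncol(a)), c(0, nrow(a)), type = "n", asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = main)
    graphics::rasterImage(r, 0, 0, ncol(a), nrow(a))
  }
  if (what == "both") {
    op <- graphics::par(mfrow = c(1, 2), mar = c(0.5, 0.5, 2, 0.5))
    on.exit(graphics::par(op))
  }
  if (what %in% c("both", "image")) show_img(x$image, "synthetic H&E tile")
  if (what %in% c("both", "mask")) {
    show_img(array(x$mask * 255L, c(dim(x$mask), 3)), "vessel mask")
  }
  invisible(x)
}
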