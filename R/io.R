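# Disk formats: 8-bit RGB PNG tiles, single-channel 0/255 PNG masks,
# cell CSVs (`row_px,col_px,cell_class`), JSON config sidecars.

#' Write a synthetic sample to disk
#'
#' Emits `<stem>.png` (RGB tile), `<stem>_mask.png` (0/255), and, when the
#' sample carries them, `<stem>_cells.csv` and `<stem>_config.json`.
#'
#' @param sample a `synthetic_sample` (or any list with `image`, `mask`).
#' @param dir output directory (created if missing).
#' @param stem file stem.
#' @return invisible character vector of the files written.
#' @export
write_sample <- function(sample, dir, stem) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, paste0(stem, ".png"))
  write_tile(sample$image, f)
  files <- c(files, f)
  f <- file.path(dir, paste0(stem, "_mask.png"))
  write_mask(sample$mask, f)
  files <- c(files, f)
  if (!is.null(sample$cells)) {
    f <- file.path(dir, paste0(stem, "_cells.csv"))
    write.csv(sample$cells, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(sample$config_echo)) {
    f <- file.path(dir, paste0(stem, "_config.json"))
    jsonlite::write_json(unclass(sample$config_echo), f,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write an RGB tile as 8-bit PNG
#' @param image (H, W, 3) array on the 0-255 scale.
#' @param path output file.
#' @export
write_tile <- function(image, path) {
  png::writePNG(as_feature_map(image) / 255, path)
  invisible(path)
}

#' Read an RGB tile from PNG
#' @param path PNG file.
#' @return (H, W, 3) integer array on the 0-255 scale.
#' @export
read_tile <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]  # drop alpha if present
  a <- round(a * 255)
  storage.mode(a) <- "integer"
  a
}

#' Write a binary mask as a single-channel PNG (0/255)
#' @param mask integer matrix with values 0/1.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  check_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Read a binary mask PNG into in-memory 0/1 labels
#' @param path PNG file (any nonzero intensity is foreground).
#' @return integer matrix with values 0/1.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- matrix(as.integer(a > 0.5), nrow(a), ncol(a))
  m
}

#' Read a cell-annotation CSV
#' @param path CSV with header `row_px,col_px,cell_class`.
#' @return tibble with those columns.
#' @export
read_cells <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("row_px", "col_px", "cell_class") %in% names(df)))
  tibble::as_tibble(df)
}
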