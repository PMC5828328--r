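# Microvessel-density features per image: total vessel area and the
# fraction of tumor cells in the neighborhood of any vessel.

#' Neighborhood configuration for "cells around the microvessel"
#'
#' A cell counts as "around" a vessel when its centroid lies within
#' `radius_um` (converted to pixels via `pixel_size_um`) of any vessel
#' foreground pixel. The radius is a package choice exposed here so
#' reports can state it; 50 um is a plausible perivascular neighborhood at
#' 20X magnification.
#'
#' @param radius_um neighborhood radius in micrometres (default 50).
#' @param pixel_size_um physical pixel size in micrometres (default 0.5,
#'   i.e. 20X magnification).
#' @return a `vesselfcn_neighborhood_config` list.
#' @export
neighborhood_config <- function(radius_um = 50, pixel_size_um = 0.5) {
  stopifnot(radius_um > 0, pixel_size_um > 0)
  structure(list(radius_um = radius_um, pixel_size_um = pixel_size_um),
            class = "vesselfcn_neighborhood_config")
}

#' Total microvessel area of a mask
#'
#' Physical area of the vessel foreground: `foreground pixel count *
#' pixel_size_um^2`, plus the dimensionless foreground fraction.
#'
#' @param mask binary integer matrix, 1 = vessel foreground.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return list with `area_um2` and `area_fraction`.
#' @export
total_vessel_area <- function(mask, pixel_size_um = 0.5) {
  check_binary_mask(mask)
  stopifnot(pixel_size_um > 0)
  fg <- sum(mask == 1L)
  list(area_um2 = fg * pixel_size_um^2,
       area_fraction = fg / length(mask))
}

#' Fraction of tumor cells near the microvessels
#'
#' Among cells whose centroid lies within the configured radius of any
#' vessel foreground pixel, returns the number of tumor cells divided by
#' the total number of cells. When no cell falls in the neighborhood the
#' fraction is undefined and returned as `NA` (never imputed as 0).
#'
#' @param mask binary vessel mask.
#' @param cells data frame with columns `row_px`, `col_px` (0-based pixel
#'   coordinates) and `cell_class` (`"tumor"` or `"non_tumor"`).
#' @param config a [neighborhood_config()].
#' @return list with `fraction` (NA when undefined), `n_cells_near_vessels`,
#'   `n_tumor_near_vessels` and `undefined` flag.
#' @export
tumor_cell_fraction_near_vessels <- function(mask, cells,
                                             config = neighborhood_config()) {
  check_binary_mask(mask)
  if (config$radius_um <= 0) stop("radius must be positive")
  if (nrow(cells) == 0L) {
    return(list(fraction = NA_real_, n_cells_near_vessels = 0L,
                n_tumor_near_vessels = 0L, undefined = TRUE))
  }
  stopifnot(all(c("row_px", "col_px", "cell_class") %in% names(cells)))
  if (any(cells$row_px < 0 | cells$row_px > nrow(mask) - 1 |
          cells$col_px < 0 | cells$col_px > ncol(mask) - 1)) {
    stop("cell coordinates outside the tile bounds")
  }
  m <- mask
  storage.mode(m) <- "integer"
  radius_px <- config$radius_um / config$pixel_size_um
  d <- cf_min_dist_to_mask(m, as.numeric(cells$row_px),
                           as.numeric(cells$col_px))
  near <- is.finite(d) & d <= radius_px
  n_near <- sum(near)
  n_tumor <- sum(near & cells$cell_class == "tumor")
  if (n_near == 0L) {
    return(list(fraction = NA_real_, n_cells_near_vessels = 0L,
                n_tumor_near_vessels = 0L, undefined = TRUE))
  }
  list(fraction = n_tumor / n_near,
       n_cells_near_vessels = as.integer(n_near),
       n_tumor_near_vessels = as.integer(n_tumor),
       undefined = FALSE)
}

#' Per-image microvessel feature record
#'
#' Combines [total_vessel_area()] and
#' [tumor_cell_fraction_near_vessels()] into one feature row for an image.
#'
#' @param mask binary vessel mask.
#' @param cells cell centroid table (see
#'   [tumor_cell_fraction_near_vessels()]).
#' @param image_id,patient_id identifiers carried into the record.
#' @param config a [neighborhood_config()] (also supplies the pixel size).
#' @return one-row tibble with columns `patient_id`, `image_id`,
#'   `vessel_area_um2`, `vessel_area_fraction`,
#'   `tumor_cell_fraction_near_vessels`, `n_cells_near_vessels`.
#' @export
vessel_feature_record <- function(mask, cells, image_id, patient_id,
                                  config = neighborhood_config()) {
  area <- total_vessel_area(mask, config$pixel_size_um)
  frac <- tumor_cell_fraction_near_vessels(mask, cells, config)
  tibble::tibble(
    patient_id = as.character(patient_id),
    image_id = as.character(image_id),
    vessel_area_um2 = area$area_um2,
    vessel_area_fraction = area$area_fraction,
    tumor_cell_fraction_near_vessels = frac$fraction,
    n_cells_near_vessels = frac$n_cells_near_vessels
  )
}

#' Group per-image feature records per patient
#'
#' Validates and orders the long-format feature table keyed by
#' `(patient_id, image_id)`. Every image row is preserved — features are
#' never averaged away, so downstream survival models can treat multiple
#' images from one patient as correlated observations.
#'
#' @param records tibble of rows from [vessel_feature_record()].
#' @return the validated table ordered by patient then image.
#' @export
aggregate_per_patient <- function(records) {
  stopifnot(all(c("patient_id", "image_id") %in% names(records)))
  if (any(is.na(records$patient_id))) stop("every record needs a patient_id")
  key <- paste(records$patient_id, records$image_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, image_id) keys in feature records")
  }
  records[order(records$patient_id, records$image_id), , drop = FALSE]
}
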