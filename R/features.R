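#' Per-image intensity normalization
#'
#' Affine min-max rescale of one channel to `[0, 255]`:
#' `(x - min) / (max - min) * 255`. A constant image maps to all zeros.
#' Intensity and texture features are always computed on this normalized
#' scale so that their discretization (bin width 25) is comparable across
#' fields and acquisition depths.
#'
#' @param image an [image_grid()].
#' @return A normalized [image_grid()] with the same channel tag.
#' @export
normalize_image <- function(image) {
  stopifnot(is_image_grid(image))
  px <- image$pixels
  rng <- range(px)
  px <- if (rng[2L] > rng[1L]) (px - rng[1L]) / (rng[2L] - rng[1L]) * 255
        else matrix(0, nrow(px), ncol(px))
  image_grid(px, image$channel)
}

#' Extract the full per-cell feature table
#'
#' For every cell of `instances`: the 14 shape features from its mask; 18
#' intensity and 42 texture features on the normalized brightfield within
#' the mask (all in-mask pixels used); and, when a fluorescent channel is
#' supplied, vesicles are detected on the original fluorescent image
#' ([detect_vesicles()]), erased ([erase_vesicles()]), the erased image is
#' normalized, and the same 60 intensity/texture features are computed
#' within the *brightfield-derived* mask with zero-valued pixels excluded
#' (the fluorescent background is exactly zero, and erased vesicle pixels
#' become zero, so neither contributes). The vesicle count per cell is
#' appended as `ca2+_number_of_vesicles`.
#'
#' Per-cell feature failures (e.g. a cell with no nonzero fluorescent pixel)
#' are recorded as `NA` and never abort the table. Cells touching the image
#' border are kept by default; partial visibility shows up in the features
#' themselves.
#'
#' @param brightfield brightfield [image_grid()].
#' @param fluorescent optional fluorescent [image_grid()].
#' @param instances [instance_set()] from segmentation.
#' @param vparams [vesicle_params()] for the fluorescent channel.
#' @param drop_border drop cells whose mask touches the image border.
#' @return A `data.frame` of class `feature_table` with columns `cell_id`,
#'   `image_id`, then exactly [feature_catalog()] (135 with fluorescent,
#'   74 without), plus attributes `vesicles` (the `vesicle_set`, if any) and
#'   `n_excluded` (zero-pixel exclusion count per cell).
#' @export
extract_features <- function(brightfield, fluorescent = NULL, instances,
                             vparams = vesicle_params(),
                             drop_border = FALSE) {
  stopifnot(is_image_grid(brightfield))
  has_fl <- !is.null(fluorescent)
  if (n_instances(instances))
    stopifnot_same_dims(brightfield$pixels, instances$masks[[1L]],
                        "brightfield and masks")
  if (has_fl)
    stopifnot_same_dims(brightfield$pixels, fluorescent$pixels,
                        "brightfield and fluorescent")
  if (drop_border && n_instances(instances)) {
    keep <- !vapply(instances$masks, touches_border, TRUE)
    instances <- instance_set(instances$image_id, instances$masks[keep],
                              scores = instances$scores[keep],
                              cell_ids = instances$cell_ids[keep])
  }
  catalog <- feature_catalog(fluorescent = has_fl)
  nc_ <- length(catalog)
  ncell <- n_instances(instances)

  bf_norm <- normalize_image(brightfield)
  vesicles <- NULL
  if (has_fl) {
    vesicles <- detect_vesicles(fluorescent, instances, vparams)
    fl_norm <- normalize_image(erase_vesicles(fluorescent, vesicles))
  }

  rows <- matrix(NA_real_, ncell, nc_, dimnames = list(NULL, catalog))
  n_excluded <- integer(ncell)
  for (k in seq_len(ncell)) {
    mask <- instances$masks[[k]]
    rows[k, ] <- fill_catalog_row(catalog, mask, bf_norm,
                                  if (has_fl) fl_norm else NULL)
    if (has_fl) {
      fl_int <- tryCatch(
        intensity_features(fl_norm, mask, exclude_zero = TRUE),
        error = function(e) NULL)
      if (!is.null(fl_int))
        n_excluded[k] <- attr(fl_int, "n_excluded")
      rows[k, "ca2+_number_of_vesicles"] <-
        vesicles$counts[[instances$cell_ids[k]]]
    }
  }
  out <- data.frame(cell_id = instances$cell_ids,
                    image_id = rep(instances$image_id, ncell),
                    stringsAsFactors = FALSE)
  feats <- as.data.frame(rows, check.names = FALSE)
  if (ncell == 0L)
    feats <- as.data.frame(matrix(numeric(0), 0L, nc_,
                                  dimnames = list(NULL, catalog)),
                           check.names = FALSE)
  out <- cbind(out, feats)
  class(out) <- c("feature_table", "data.frame")
  attr(out, "vesicles") <- vesicles
  attr(out, "n_excluded") <- n_excluded
  out
}

fill_catalog_row <- function(catalog, mask, bf_norm, fl_norm) {
  row <- setNames(rep(NA_real_, length(catalog)), catalog)
  sf <- tryCatch(shape_features(mask), error = function(e) NULL)
  if (!is.null(sf)) row[names(sf)] <- sf
  bi <- tryCatch(intensity_features(bf_norm, mask, exclude_zero = FALSE),
                 error = function(e) NULL)
  if (!is.null(bi)) row[paste0(names(bi), "_bf")] <- bi
  bt <- tryCatch(texture_features(bf_norm, mask), error = function(e) NULL)
  if (!is.null(bt)) row[paste0(names(bt), "_bf")] <- bt
  if (!is.null(fl_norm)) {
    fi <- tryCatch(intensity_features(fl_norm, mask, exclude_zero = TRUE),
                   error = function(e) NULL)
    if (!is.null(fi)) row[paste0(names(fi), "_fl")] <- fi
    ft <- tryCatch(texture_features(fl_norm, mask, exclude_zero = TRUE),
                   error = function(e) NULL)
    if (!is.null(ft)) row[paste0(names(ft), "_fl")] <- ft
  }
  row
}

touches_border <- function(mask) {
  any(mask[1L, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1L]) || any(mask[, ncol(mask)])
}

#' Write / read a feature table as CSV
#'
#' Columns are `cell_id`, `image_id`, then the catalog order; missing
#' values are written as empty fields.
#'
#' @param features a `feature_table`.
#' @param path CSV path.
#' @return `save_feature_table`: `path` invisibly; `load_feature_table`:
#'   the table.
#' @export
save_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname save_feature_table
#' @export
load_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$cell_id <- as.character(df$cell_id)
  df$image_id <- as.character(df$image_id)
  class(df) <- c("feature_table", "data.frame")
  df
}
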