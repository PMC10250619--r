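#' Load a microscopy image as an intensity grid
#'
#' Reads an 8/16-bit grayscale or RGB TIFF or PNG file. RGB input is collapsed
#' to grayscale with fixed ITU-R BT.709 luma weights
#' `(0.2125, 0.7154, 0.0721)` so that downstream texture features are
#' reproducible bit-for-bit; an alpha channel, if present, is ignored.
#' Integer sample values are returned on their native scale (a 16-bit pixel of
#' value 300 reads as 300).
#'
#' @param path path to a TIFF or PNG file.
#' @param channel channel tag, `"brightfield"` or `"fluorescent"`.
#' @return An [image_grid()].
#' @export
load_image <- function(path, channel = c("brightfield", "fluorescent")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop(sprintf("cannot read image '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    z <- png::readPNG(path, info = TRUE)
    depth <- attr(z, "info")$bit.depth
    if (is.null(depth)) depth <- 8
    round(z * (2^depth - 1))
  } else {
    stop(sprintf("cannot read image '%s': unsupported format '%s'", path, ext))
  }
  if (is.list(arr)) arr <- arr[[1L]]
  arr <- grid_from_array(arr, path)
  image_grid(arr, channel)
}

# collapse h x w [x channels] arrays to grayscale
grid_from_array <- function(arr, path = "<array>") {
  plane <- function(a, k) {
    m <- a[, , k, drop = FALSE]
    dim(m) <- dim(a)[1:2]
    m
  }
  if (length(dim(arr)) == 2L) {
    mat <- arr
  } else if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch %in% c(1L, 2L)) {              # gray (+alpha): drop alpha
      mat <- plane(arr, 1L)
    } else if (nch %in% c(3L, 4L)) {       # RGB(A): luma collapse
      w <- luma_weights()
      mat <- w[1L] * plane(arr, 1L) + w[2L] * plane(arr, 2L) +
        w[3L] * plane(arr, 3L)
    } else {
      stop(sprintf("image '%s' has %d channels; expected gray or RGB", path, nch))
    }
  } else {
    stop(sprintf("image '%s' has more than 2 spatial dimensions", path))
  }
  storage.mode(mat) <- "double"
  attributes(mat) <- list(dim = dim(mat))
  mat
}

#' BT.709 luma weights used for RGB collapse
#' @return Named numeric vector of length 3.
#' @export
luma_weights <- function() c(r = 0.2125, g = 0.7154, b = 0.0721)

#' Save an intensity grid to disk
#'
#' TIFF output is 16-bit (values are rounded and clipped to `[0, 65535]`);
#' PNG output is 8-bit (clipped to `[0, 255]`). Integer-valued grids within
#' the target bit depth round-trip exactly through [load_image()].
#'
#' @param grid an [image_grid()] or numeric matrix.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(grid, path) {
  mat <- if (is_image_grid(grid)) grid$pixels else grid
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- pmin(pmax(round(mat), 0), 65535)
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    v <- pmin(pmax(round(mat), 0), 255)
    png::writePNG(v / 255, path)
  } else {
    stop(sprintf("unsupported output format '%s'", ext))
  }
  invisible(path)
}

#' Write an instance set to disk as a label map
#'
#' Non-overlapping instance sets are stored as a single 16-bit TIFF label map
#' (0 = background, `k` = instance `k`, in detection order).
#'
#' @param instances an [instance_set()].
#' @param path output `.tif` path.
#' @param dims image dimensions, needed when the set is empty.
#' @return `path`, invisibly.
#' @export
save_labelmap <- function(instances, path, dims = NULL) {
  save_image(instances_to_labelmap(instances, dims = dims), path)
}

#' Read a label-map mask file into an instance set
#'
#' @param path 16-bit TIFF/PNG label map (0 = background).
#' @param image_id field identifier; defaults to the file stem.
#' @return An [instance_set()].
#' @export
load_labelmap <- function(path, image_id = NULL) {
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  g <- load_image(path, "brightfield")
  labelmap_to_instances(round(g$pixels), image_id)
}

#' Read / write point tables
#'
#' Points are exchanged as CSV with columns `image_id,row,col` (plus
#' `cell_id` when owners are known). Coordinates are 1-based pixel indices.
#'
#' @param path CSV path.
#' @param image_id optional filter: keep only this field's points.
#' @return `load_points`: a [point_set()] (owners taken from a `cell_id`
#'   column when present). `save_points`: `path`, invisibly.
#' @export
load_points <- function(path, image_id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col") %in% names(df)))
    stop("points CSV must have 'row' and 'col' columns")
  if (!is.null(image_id) && "image_id" %in% names(df))
    df <- df[df$image_id == image_id, , drop = FALSE]
  owners <- if ("cell_id" %in% names(df)) df$cell_id else NULL
  point_set(cbind(df$row, df$col), owner_ids = owners)
}

#' @param points a [point_set()].
#' @rdname load_points
#' @export
save_points <- function(points, path, image_id = "") {
  df <- data.frame(image_id = image_id,
                   row = points$points[, 1L], col = points$points[, 2L])
  if (!is.null(points$owner_ids)) df$cell_id <- points$owner_ids
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
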