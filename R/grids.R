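#' Single-channel intensity image
#'
#' An `image_grid` is the basic container for one channel of one microscopy
#' field of view: a numeric matrix of non-negative, finite intensities plus a
#' channel tag. Coordinates throughout the package are `(row, col)` and
#' 1-based; row 1 is the top image row.
#'
#' @param pixels numeric matrix of intensities (finite, `>= 0`).
#' @param channel one of `"brightfield"` or `"fluorescent"`.
#' @return An object of class `image_grid` with elements `pixels`, `height`,
#'   `width` and `channel`.
#' @examples
#' g <- image_grid(matrix(0, 8, 8), "brightfield")
#' dim(g$pixels)
#' @export
image_grid <- function(pixels, channel = c("brightfield", "fluorescent")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1x1")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (any(pixels < 0))
    stop("image intensities must be non-negative")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         channel = channel),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d, channel = %s, range [%g, %g]\n",
              x$height, x$width, x$channel, min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_image_grid <- function(x) inherits(x, "image_grid")

stopifnot_same_dims <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

#' Point collection with optional owners
#'
#' Holds `(row, col)` coordinates, e.g. vesicle centers or cell centroids,
#' with an optional owning cell id per point.
#'
#' @param points two-column numeric matrix (or data.frame) of `(row, col)`
#'   coordinates; a 0-row matrix is a valid empty set.
#' @param owner_ids optional character vector of the same length.
#' @return An object of class `point_set` with a `points` matrix (columns
#'   `row`, `col`) and `owner_ids`.
#' @export
point_set <- function(points = matrix(numeric(0), 0, 2), owner_ids = NULL) {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), 0, 2)
  if (ncol(points) != 2) stop("`points` must have two columns (row, col)")
  storage.mode(points) <- "double"
  colnames(points) <- c("row", "col")
  if (!is.null(owner_ids)) {
    owner_ids <- as.character(owner_ids)
    if (length(owner_ids) != nrow(points))
      stop("`owner_ids` must have one entry per point")
  }
  structure(list(points = points, owner_ids = owner_ids), class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points\n", nrow(x$points)))
  invisible(x)
}

n_points <- function(ps) nrow(ps$points)
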