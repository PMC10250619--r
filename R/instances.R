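#' Per-field collection of cell instance masks
#'
#' Stores the binary segmentation masks of the cells detected in one field of
#' view, together with per-mask confidence scores and globally unique cell
#' ids. Masks are dense logical matrices of the source image dimensions and
#' may overlap; no single label map is imposed.
#'
#' Cell ids follow the convention `"{image_id}_{k}"` with `k` the 1-based
#' detection order, which keeps ids unique across images as long as image ids
#' are unique.
#'
#' @param image_id field identifier (character scalar).
#' @param masks list of logical matrices, all with identical dimensions; each
#'   must contain at least one foreground pixel.
#' @param scores numeric confidence per mask, in `[0, 1]`.
#' @param cell_ids optional explicit ids; defaults to `"{image_id}_{k}"`.
#' @return An object of class `instance_set`.
#' @examples
#' m <- matrix(FALSE, 6, 6); m[2:4, 2:4] <- TRUE
#' instance_set("f1", list(m), scores = 1)
#' @export
instance_set <- function(image_id, masks, scores = rep(1, length(masks)),
                         cell_ids = NULL) {
  image_id <- as.character(image_id)
  if (length(image_id) != 1L) stop("`image_id` must be a single id")
  if (!is.list(masks)) stop("`masks` must be a list of logical matrices")
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) stop("each mask must be a matrix")
    m <- m != 0
    if (!any(m)) stop("each mask must contain at least one foreground pixel")
    m
  })
  if (length(masks) > 1L) {
    d1 <- dim(masks[[1L]])
    for (m in masks) stopifnot_same_dims(masks[[1L]], m, "masks")
  }
  scores <- as.numeric(scores)
  if (length(scores) != length(masks)) stop("one score per mask required")
  if (length(scores) && (any(scores < 0) || any(scores > 1)))
    stop("scores must lie in [0, 1]")
  if (is.null(cell_ids)) {
    cell_ids <- if (length(masks)) paste(image_id, seq_along(masks), sep = "_")
                else character(0)
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != length(masks)) stop("one cell id per mask required")
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique within a field")
  structure(
    list(image_id = image_id, masks = masks, scores = scores,
         cell_ids = cell_ids),
    class = "instance_set"
  )
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("<instance_set> image '%s': %d instances\n",
              x$image_id, length(x$masks)))
  invisible(x)
}

n_instances <- function(x) length(x$masks)

#' Centroids of an instance set
#'
#' @param instances an [instance_set()].
#' @return A [point_set()] of mask centroids (mean foreground coordinates),
#'   with `owner_ids` set to the cell ids.
#' @export
instance_centroids <- function(instances) {
  if (!n_instances(instances)) return(point_set())
  pts <- t(vapply(instances$masks, function(m) {
    w <- which(m, arr.ind = TRUE)
    c(mean(w[, 1L]), mean(w[, 2L]))
  }, numeric(2)))
  point_set(pts, owner_ids = instances$cell_ids)
}

#' Convert an instance set to a label map
#'
#' Produces an integer matrix with 0 background and value `k` for instance
#' `k`. Only valid when masks do not overlap.
#'
#' @param instances an [instance_set()].
#' @param dims image dimensions, required when the set is empty.
#' @return Integer label matrix.
#' @export
instances_to_labelmap <- function(instances, dims = NULL) {
  if (!n_instances(instances)) {
    if (is.null(dims)) stop("`dims` required for an empty instance set")
    return(matrix(0L, dims[1L], dims[2L]))
  }
  lab <- matrix(0L, nrow(instances$masks[[1L]]), ncol(instances$masks[[1L]]))
  for (k in seq_along(instances$masks)) {
    m <- instances$masks[[k]]
    if (any(lab[m] != 0L))
      stop("masks overlap; a label map cannot represent this instance set")
    lab[m] <- k
  }
  lab
}

#' Convert a label map to an instance set
#'
#' @param labelmap integer matrix, 0 = background, `k` = instance `k`.
#' @param image_id field identifier used to build cell ids.
#' @param scores optional per-instance scores (default all 1).
#' @return An [instance_set()]; labels are taken in increasing order.
#' @export
labelmap_to_instances <- function(labelmap, image_id, scores = NULL) {
  labs <- sort(unique(labelmap[labelmap > 0]))
  masks <- lapply(labs, function(l) labelmap == l)
  if (is.null(scores)) scores <- rep(1, length(masks))
  instance_set(image_id, masks, scores = scores)
}
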