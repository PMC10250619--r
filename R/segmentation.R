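#' Segmentation backends
#'
#' Cell detection runs behind a backend contract: a backend is any object
#' carrying a `name`, a `trainable` flag and a predict method mapping an
#' [image_grid()] to an [instance_set()] whose masks lie within image bounds
#' and whose scores lie in `[0, 1]`. Two constructors are provided:
#'
#' * `classical_backend()` — the always-available classical pipeline: Otsu
#'   threshold on the Gaussian-smoothed inverse brightfield, hole filling,
#'   distance-transform watershed to split touching cells, and removal of
#'   regions below `min_area` pixels. Scores are 1 for every instance.
#' * `function_backend()` — wraps an arbitrary user-supplied predict function
#'   (e.g. an external deep detection model exposed from another runtime),
#'   so trained models can be plugged in without changing the pipeline.
#'
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param min_area minimum instance area in pixels; smaller regions are
#'   discarded as debris.
#' @param tolerance watershed minima-merging tolerance (intensity units of
#'   the distance map).
#' @return A `segmentation_backend` object.
#' @export
classical_backend <- function(sigma = 2, min_area = 50, tolerance = 1) {
  structure(
    list(name = "classical", trainable = FALSE, sigma = sigma,
         min_area = min_area, tolerance = tolerance),
    class = c("classical_backend", "segmentation_backend")
  )
}

#' @param name backend name used in error messages and logs.
#' @param fn function `(image_grid) -> instance_set`.
#' @rdname classical_backend
#' @export
function_backend <- function(name, fn) {
  stopifnot(is.function(fn))
  structure(list(name = name, trainable = FALSE, fn = fn),
            class = c("function_backend", "segmentation_backend"))
}

#' Backend predict contract
#' @param backend a `segmentation_backend`.
#' @param image an [image_grid()].
#' @return An [instance_set()].
#' @export
predict_instances <- function(backend, image) UseMethod("predict_instances")

#' @export
predict_instances.function_backend <- function(backend, image) {
  backend$fn(image)
}

#' @export
predict_instances.classical_backend <- function(backend, image) {
  px <- image$pixels
  rng <- range(px)
  if (rng[2L] <= rng[1L])                       # constant field: nothing to find
    return(instance_set(image_id_of(image), list(), scores = numeric(0)))
  # cells are dark on a bright background: work on the inverted image in [0,1]
  inv <- (rng[2L] - px) / (rng[2L] - rng[1L])
  sm <- EBImage::gblur(inv, sigma = backend$sigma)
  sm <- pmin(pmax(sm, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  fg <- sm > thr
  if (!any(fg) || all(fg))
    return(instance_set(image_id_of(image), list(), scores = numeric(0)))
  fg <- EBImage::fillHull(EBImage::Image(fg)) > 0
  dm <- EBImage::distmap(fg)
  lab <- EBImage::watershed(dm, tolerance = backend$tolerance)
  lab <- as.matrix(EBImage::imageData(lab))
  keep <- which(tabulate(as.integer(lab[lab > 0])) >= backend$min_area)
  masks <- lapply(keep, function(l) lab == l)
  instance_set(image_id_of(image), masks, scores = rep(1, length(masks)))
}

image_id_of <- function(image) {
  id <- attr(image, "image_id")
  if (is.null(id)) "image" else id
}

#' Attach a field identifier to an image
#'
#' The identifier seeds the `"{image_id}_{k}"` cell-id convention.
#' @param image an [image_grid()].
#' @param image_id character scalar.
#' @return The image with the id recorded.
#' @export
set_image_id <- function(image, image_id) {
  attr(image, "image_id") <- as.character(image_id)
  image
}

#' Detect and segment cells in a brightfield field
#'
#' Runs the backend and filters instances by confidence. Cell ids are
#' reassigned as `"{image_id}_{k}"` in detection order after filtering.
#'
#' @param image brightfield [image_grid()] (tag the field with
#'   [set_image_id()] first for stable cell ids).
#' @param backend a `segmentation_backend`; default [classical_backend()].
#' @param min_score minimum confidence kept, in `[0, 1]`.
#' @return An [instance_set()].
#' @export
segment <- function(image, backend = classical_backend(), min_score = 0.5) {
  stopifnot(is_image_grid(image))
  if (image$channel != "brightfield")
    stop("segmentation expects the brightfield channel")
  inst <- tryCatch(predict_instances(backend, image), error = function(e)
    stop(sprintf("segmentation backend '%s' failed: %s",
                 backend$name, conditionMessage(e))))
  keep <- which(inst$scores >= min_score)
  instance_set(inst$image_id, inst$masks[keep], scores = inst$scores[keep])
}
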