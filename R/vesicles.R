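#' Vesicle detection parameters
#'
#' Constants of the Ca2+ vesicle detection algorithm. Vesicles appear in the
#' fluorescent (Fluo-4) channel as small high-intensity spots inside cells;
#' they are found as local maxima of the median-filtered image that pass a
#' ball/annulus intensity-contrast test on the original image.
#'
#' @param m median filter side in pixels (odd, `>= 1`); suppresses
#'   single-pixel noise spikes. Default 3.
#' @param d local-maximum neighborhood radius in pixels (L1 ball); a
#'   candidate must be the maximum of its radius-`d` ball, which guarantees
#'   at most one detection per vesicle. Default 10.
#' @param v vesicle radius in pixels: the detected vesicle region is the
#'   L1 ball of radius `v` around the maximum. Default 4.
#' @param c context radius in pixels defining the surrounding annulus
#'   (`c > v`). Default 8.
#' @param t minimum contrast, in intensity units, between the mean inside
#'   the vesicle ball and the mean over the annulus. Default 1.
#' @return An object of class `vesicle_params`.
#' @export
vesicle_params <- function(m = 3, d = 10, v = 4, c = 8, t = 1) {
  m <- as.integer(m); d <- as.integer(d); v <- as.integer(v); c <- as.integer(c)
  if (m < 1L || m %% 2L == 0L) stop("`m` must be odd and >= 1")
  if (v < 1L) stop("`v` must be >= 1")
  if (c <= v) stop("`c` must exceed `v`")
  if (d < 1L) stop("`d` must be >= 1")
  if (t < 0) stop("`t` must be >= 0")
  structure(list(m = m, d = d, v = v, c = c, t = t), class = "vesicle_params")
}

#' @export
print.vesicle_params <- function(x, ...) {
  cat(sprintf("<vesicle_params> m=%d d=%d v=%d c=%d t=%g\n",
              x$m, x$d, x$v, x$c, x$t))
  invisible(x)
}

#' Pixels of a strict L1 ball
#'
#' The ball of radius `r` around `center` with respect to the L1 (taxicab)
#' distance contains the pixels `p` with `||p - center||_1 < r` (strict),
#' clipped to image bounds. An interior ball has `2 r^2 - 2 r + 1` pixels.
#'
#' @param center `(row, col)` integer center.
#' @param radius `r >= 1`.
#' @param dims image dimensions `c(rows, cols)`.
#' @return Two-column integer matrix of `(row, col)` pixel coordinates.
#' @export
l1_ball <- function(center, radius, dims) {
  stopifnot(radius >= 1)
  r0 <- as.integer(round(center[1L])); c0 <- as.integer(round(center[2L]))
  off <- seq.int(-(radius - 1L), radius - 1L)
  grid <- expand.grid(dr = off, dc = off)
  grid <- grid[abs(grid$dr) + abs(grid$dc) < radius, , drop = FALSE]
  rr <- r0 + grid$dr; cc <- c0 + grid$dc
  keep <- rr >= 1L & rr <= dims[1L] & cc >= 1L & cc <= dims[2L]
  cbind(row = as.integer(rr[keep]), col = as.integer(cc[keep]))
}

#' Median filter with reflect padding
#' @param image an [image_grid()] or numeric matrix.
#' @param m odd window side.
#' @return Matrix of the same dimensions.
#' @export
median_filter <- function(image, m = 3) {
  mat <- if (is_image_grid(image)) image$pixels else image
  .median_filter_cpp(mat, as.integer(m))
}

#' Local intensity maxima for vesicle candidates
#'
#' Applies an `m x m` median filter (reflect padding), then marks pixels
#' whose filtered value equals the maximum over their L1 ball of radius `d`
#' and strictly exceeds the filtered image minimum (so constant images yield
#' no candidates). Each connected plateau of marked pixels collapses to its
#' rounded centroid.
#'
#' @param image fluorescent [image_grid()].
#' @param params [vesicle_params()].
#' @return A [point_set()] of candidate centers.
#' @export
local_maxima <- function(image, params = vesicle_params()) {
  stopifnot(is_image_grid(image))
  med <- median_filter(image$pixels, params$m)
  mx <- .l1_max_filter_cpp(med, params$d)
  marked <- (med == mx) & (med > min(med))
  if (!any(marked)) return(point_set())
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(marked)))
  centers <- do.call(rbind, lapply(seq_len(max(lab)), function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    round(c(mean(w[, 1L]), mean(w[, 2L])))
  }))
  point_set(centers)
}

#' Ball/annulus contrast test for a vesicle candidate
#'
#' A candidate center passes when the mean intensity over its L1 ball of
#' radius `v`, minus the threshold `t`, strictly exceeds the mean intensity
#' over the annulus (ball of radius `c` minus ball of radius `v`). Means are
#' computed on the original, unfiltered image.
#'
#' @param image fluorescent [image_grid()].
#' @param center `(row, col)` candidate center (in bounds).
#' @param params [vesicle_params()].
#' @return List with `is_vesicle` (logical) and `inner_mean`.
#' @export
vesicle_test <- function(image, center, params = vesicle_params()) {
  dims <- dim(image$pixels)
  inner <- l1_ball(center, params$v, dims)
  outer_ <- l1_ball(center, params$c, dims)
  key <- function(px) px[, 1L] + dims[1L] * px[, 2L]
  ann <- outer_[!(key(outer_) %in% key(inner)), , drop = FALSE]
  inner_mean <- mean(image$pixels[inner])
  if (nrow(ann) == 0L) {
    warning("annulus empty after clipping to image bounds; candidate rejected")
    return(list(is_vesicle = FALSE, inner_mean = inner_mean))
  }
  ann_mean <- mean(image$pixels[ann])
  list(is_vesicle = (inner_mean - params$t) > ann_mean,
       inner_mean = inner_mean)
}

#' Detect Ca2+ vesicles in the fluorescent channel
#'
#' Candidates are the [local_maxima()] of the whole fluorescent image; those
#' passing [vesicle_test()] are kept and each is assigned to the cell whose
#' segmentation mask (transferred from the brightfield channel) contains its
#' center. Centers falling outside every mask are reported as unassigned.
#'
#' @param fluor fluorescent [image_grid()].
#' @param instances [instance_set()] with masks matching `fluor` dimensions.
#' @param params [vesicle_params()].
#' @return An object of class `vesicle_set`: `centers` (data.frame
#'   `cell_id`, `row`, `col`, `inner_mean`; `cell_id` is `NA` for unassigned
#'   centers), `counts` (named integer vector per cell id, zeros included)
#'   and `params`.
#' @export
detect_vesicles <- function(fluor, instances, params = vesicle_params()) {
  if (n_instances(instances))
    stopifnot_same_dims(fluor$pixels, instances$masks[[1L]],
                        "fluorescent image and masks")
  cand <- local_maxima(fluor, params)
  rows <- list()
  if (n_points(cand)) {
    for (i in seq_len(n_points(cand))) {
      ctr <- cand$points[i, ]
      res <- vesicle_test(fluor, ctr, params)
      if (!res$is_vesicle) next
      owner <- NA_character_
      for (k in seq_len(n_instances(instances))) {
        if (instances$masks[[k]][ctr[1L], ctr[2L]]) {
          owner <- instances$cell_ids[k]
          break
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = owner, row = ctr[1L], col = ctr[2L],
        inner_mean = res$inner_mean, stringsAsFactors = FALSE)
    }
  }
  centers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), row = numeric(0), col = numeric(0),
               inner_mean = numeric(0))
  counts <- setNames(rep(0L, n_instances(instances)), instances$cell_ids)
  assigned <- centers$cell_id[!is.na(centers$cell_id)]
  if (length(assigned)) {
    tab <- table(assigned)
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(centers = centers, counts = counts, params = params),
            class = "vesicle_set")
}

#' @export
print.vesicle_set <- function(x, ...) {
  cat(sprintf("<vesicle_set> %d vesicles (%d unassigned) across %d cells\n",
              nrow(x$centers), sum(is.na(x$centers$cell_id)), length(x$counts)))
  invisible(x)
}

#' Erase detected vesicles from an image
#'
#' Sets the intensity to zero over each vesicle's L1 ball of radius `v`, so
#' that vesicle pixels — like zero background — no longer contribute to
#' fluorescent intensity and texture features. Idempotent.
#'
#' @param image fluorescent [image_grid()].
#' @param vesicles a `vesicle_set` from [detect_vesicles()].
#' @param params [vesicle_params()]; defaults to those stored in `vesicles`.
#' @return A new [image_grid()] with vesicle balls zeroed.
#' @export
erase_vesicles <- function(image, vesicles, params = NULL) {
  if (is.null(params)) params <- vesicles$params
  px <- image$pixels
  df <- vesicles$centers
  if (!is.null(df) && nrow(df)) {
    for (i in seq_len(nrow(df))) {
      ball <- l1_ball(c(df$row[i], df$col[i]), params$v, dim(px))
      px[ball] <- 0
    }
  }
  image_grid(px, image$channel)
}

#' Precision and recall of point detections
#'
#' Matches predicted points to annotated points by minimum-cost one-to-one
#' assignment ([match_centroids()]) and counts a prediction as correct when
#' its matched annotation lies within `tolerance` pixels (Euclidean).
#'
#' @param pred,truth [point_set()] objects.
#' @param tolerance match radius in pixels (default 5).
#' @return List with `precision`, `recall`, `matched`, `n_pred`, `n_truth`.
#'   An empty prediction set has precision 1 by convention.
#' @export
score_detection <- function(pred, truth, tolerance = 5) {
  stopifnot(tolerance > 0)
  m <- match_centroids(pred, truth)
  matched <- sum(m$pairs$distance <= tolerance)
  np <- n_points(pred); nt <- n_points(truth)
  list(precision = if (np == 0L) 1 else matched / np,
       recall = if (nt == 0L) 1 else matched / nt,
       matched = matched, n_pred = np, n_truth = nt)
}
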