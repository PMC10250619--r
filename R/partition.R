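#' Cross-validation partition of labeled cells
#'
#' Builds the k-fold assignment used by the AutoML objective. Two modes:
#'
#' * `"random_stratified"` — cells are assigned to folds per class in
#'   shuffled round-robin order, so fold sizes differ by at most 1 and every
#'   class is spread as evenly as possible.
#' * `"image_grouped_stratified"` — whole images are assigned to folds so
#'   that cells from a single image never appear in both a training and a
#'   validation set; images (largest first) go greedily to the fold whose
#'   per-class counts they balance best.
#'
#' @param labeled data.frame with at least `cell_id`, `image_id`, `label`.
#' @param mode `"random_stratified"` or `"image_grouped_stratified"`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return An object of class `cv_partition`: `fold` (integer per row of
#'   `labeled`), `k`, `mode`, `seed`.
#' @export
make_partition <- function(labeled,
                           mode = c("random_stratified",
                                    "image_grouped_stratified"),
                           k = 5L, seed = 0L) {
  mode <- match.arg(mode)
  n <- nrow(labeled)
  if (n < k) stop(sprintf("need at least k = %d labeled cells, have %d", k, n))
  classes <- table(labeled$label)
  if (any(classes < k))
    warning(sprintf("class(es) %s have fewer than k = %d members; stratification is best-effort",
                    paste(names(classes)[classes < k], collapse = ", "), k))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(n)
  if (mode == "random_stratified") {
    # one continuous round-robin over folds, walked class by class: per-class
    # counts and total fold sizes both differ by at most 1
    ptr <- sample.int(k, 1L) - 1L
    perm <- sample.int(k)                   # random fold relabeling
    for (cl in sample(names(classes))) {
      idx <- sample(which(labeled$label == cl))
      fold[idx] <- perm[(ptr + seq_along(idx) - 1L) %% k + 1L]
      ptr <- ptr + length(idx)
    }
  } else {
    imgs <- unique(labeled$image_id)
    if (length(imgs) < k)
      stop(sprintf("grouped mode needs >= k = %d distinct images, have %d",
                   k, length(imgs)))
    per_img <- lapply(imgs, function(im) table(factor(
      labeled$label[labeled$image_id == im], levels = names(classes))))
    sizes <- vapply(per_img, sum, 0)
    ord <- sample(seq_along(imgs))          # random tie order
    ord <- ord[order(-sizes[ord])]          # largest images first
    fold_counts <- matrix(0, k, length(classes),
                          dimnames = list(NULL, names(classes)))
    img_fold <- integer(length(imgs))
    for (i in ord) {
      # assign to the fold minimizing the spread of per-class counts
      score <- vapply(seq_len(k), function(f) {
        trial <- fold_counts
        trial[f, ] <- trial[f, ] + as.numeric(per_img[[i]])
        sum(apply(trial, 2L, function(col) max(col) - min(col))) +
          (max(rowSums(trial)) - min(rowSums(trial)))
      }, 0)
      f <- which.min(score)
      fold_counts[f, ] <- fold_counts[f, ] + as.numeric(per_img[[i]])
      img_fold[i] <- f
    }
    fold <- img_fold[match(labeled$image_id, imgs)]
  }
  structure(list(fold = fold, k = as.integer(k), mode = mode,
                 seed = as.integer(seed)),
            class = "cv_partition")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cv_partition <- function(x, ...) {
  cat(sprintf("<cv_partition> %d folds, mode = %s (sizes: %s)\n",
              x$k, x$mode, paste(tabulate(x$fold, x$k), collapse = ", ")))
  invisible(x)
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recalls over the classes present in
#' `truth`; robust to class imbalance and therefore the cross-validation
#' objective of the AutoML search.
#'
#' @param truth,pred label vectors of equal positive length.
#' @return Value in `[0, 1]`.
#' @examples
#' balanced_accuracy(c("A", "A", "B", "B"), c("A", "B", "B", "B"))  # 0.75
#' @export
balanced_accuracy <- function(truth, pred) {
  if (length(truth) != length(pred) || !length(truth))
    stop("`truth` and `pred` must have the same positive length")
  truth <- as.character(truth); pred <- as.character(pred)
  recalls <- vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, 0)
  mean(recalls)
}

#' Inverse-frequency class weights
#'
#' `weight(c)` proportional to `1 / frequency(c)`, normalized so the mean
#' weight over classes is 1. Applied as per-sample weights during fitting to
#' counter class imbalance.
#'
#' @param labels label vector.
#' @return Named numeric vector, one weight per class.
#' @examples
#' class_weights(c("A", "A", "A", "B"))  # B three times A's weight
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (!length(tab)) stop("at least one class required")
  w <- 1 / (as.numeric(tab) / sum(tab))
  w <- w / mean(w)
  setNames(w, names(tab))
}
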