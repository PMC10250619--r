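#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of identical dimensions.
#' @return IoU in `[0, 1]` (0 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  stopifnot_same_dims(a, b, "masks")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' Average precision of instance segmentations
#'
#' COCO-style evaluation of predicted instance masks against ground truth at
#' a fixed mask-IoU threshold. Detections are ranked by confidence across
#' all images (ties broken by larger mask area, then id order) and matched
#' greedily one-to-one: each detection claims the unmatched ground-truth
#' mask of highest IoU in its image, provided IoU meets the threshold. AP is
#' the area under the resulting precision-recall step curve with all-points
#' interpolation (precision envelope).
#'
#' @param pred,truth parallel lists of [instance_set()] objects over the same
#'   image ids.
#' @param iou_threshold mask IoU required for a match, in `(0, 1]`.
#' @return List of class `ap_result`: `iou_threshold`, `ap`, `n_truth`,
#'   `n_pred`, and `per_image` (data.frame of matched/unmatched counts).
#' @export
mask_ap <- function(pred, truth, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must cover the same images")
  pid <- vapply(pred, `[[`, "", "image_id")
  tid <- vapply(truth, `[[`, "", "image_id")
  if (!setequal(pid, tid) || anyDuplicated(pid) || anyDuplicated(tid))
    stop("`pred` and `truth` must carry identical, unique image ids")
  truth <- truth[match(pid, tid)]

  det <- do.call(rbind, lapply(seq_along(pred), function(i) {
    p <- pred[[i]]
    if (!n_instances(p)) return(NULL)
    data.frame(img = i, k = seq_len(n_instances(p)), score = p$scores,
               area = vapply(p$masks, sum, 0))
  }))
  n_truth <- sum(vapply(truth, n_instances, 0L))
  n_pred <- if (is.null(det)) 0L else nrow(det)
  per_image <- data.frame(image_id = pid,
                          n_truth = vapply(truth, n_instances, 0L),
                          matched = 0L, false_positive = 0L)
  if (n_pred == 0L || n_truth == 0L) {
    return(structure(list(iou_threshold = iou_threshold,
                          ap = 0, n_truth = n_truth, n_pred = n_pred,
                          per_image = per_image), class = "ap_result"))
  }
  ord <- order(-det$score, -det$area, det$img, det$k)
  det <- det[ord, , drop = FALSE]
  truth_used <- lapply(truth, function(t) rep(FALSE, n_instances(t)))
  tp <- logical(n_pred)
  for (r in seq_len(n_pred)) {
    i <- det$img[r]
    m <- pred[[i]]$masks[[det$k[r]]]
    best_iou <- 0; best_j <- 0L
    for (j in seq_len(n_instances(truth[[i]]))) {
      if (truth_used[[i]][j]) next
      iou <- mask_iou(m, truth[[i]]$masks[[j]])
      if (iou > best_iou) { best_iou <- iou; best_j <- j }
    }
    if (best_j > 0L && best_iou >= iou_threshold) {
      tp[r] <- TRUE
      truth_used[[i]][best_j] <- TRUE
      per_image$matched[i] <- per_image$matched[i] + 1L
    } else {
      per_image$false_positive[i] <- per_image$false_positive[i] + 1L
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_len(n_pred)
  recall <- cum_tp / n_truth
  structure(list(iou_threshold = iou_threshold,
                 ap = ap_from_pr(precision, recall),
                 n_truth = n_truth, n_pred = n_pred, per_image = per_image),
            class = "ap_result")
}

# area under the PR step curve with the interpolated-precision envelope
ap_from_pr <- function(precision, recall) {
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> AP = %.4f at IoU >= %.2f (%d truth, %d predictions)\n",
              x$ap, x$iou_threshold, x$n_truth, x$n_pred))
  invisible(x)
}
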