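#' Sample cells for expert annotation
#'
#' Uniformly samples `n` cells without replacement across all images of a
#' feature table and returns an empty label table (columns `cell_id`,
#' `label`) for the expert to fill in. When `crops_dir` and the source
#' images are given, one single-cell crop per sampled cell is written as
#' PNG (mask bounding box plus an 8-pixel margin, filename `{cell_id}.png`)
#' so labels can be assigned by eye.
#'
#' @param features a `feature_table` from [extract_features()].
#' @param n number of cells to sample (`<=` number of rows).
#' @param seed integer seed making the sample reproducible.
#' @param crops_dir optional output directory for single-cell crops.
#' @param images named list of brightfield [image_grid()] per image id
#'   (required for crops).
#' @param instances named list of [instance_set()] per image id (required
#'   for crops).
#' @param margin crop margin in pixels around the mask bounding box.
#' @param per_image balance the sample across images (round-robin) instead
#'   of plain uniform sampling, to cover cells from many fields.
#' @return A `data.frame` with columns `cell_id` and `label` (all labels
#'   empty strings).
#' @export
sample_for_annotation <- function(features, n, seed = 0L, crops_dir = NULL,
                                  images = NULL, instances = NULL,
                                  margin = 8L, per_image = FALSE) {
  total <- nrow(features)
  if (n > total)
    stop(sprintf("requested %d cells for annotation but only %d available",
                 n, total))
  set.seed(seed)
  if (per_image) {
    split_idx <- split(seq_len(total), features$image_id)
    split_idx <- lapply(split_idx, sample)
    picked <- integer(0)
    round <- 1L
    while (length(picked) < n) {
      for (s in split_idx) {
        if (length(picked) >= n) break
        if (length(s) >= round) picked <- c(picked, s[round])
      }
      round <- round + 1L
    }
    idx <- sort(picked[seq_len(n)])
  } else {
    idx <- sort(sample.int(total, n))
  }
  labels <- data.frame(cell_id = features$cell_id[idx], label = "",
                       stringsAsFactors = FALSE)
  if (!is.null(crops_dir)) {
    if (is.null(images) || is.null(instances))
      stop("`images` and `instances` are required to write crops")
    dir.create(crops_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in idx) {
      cid <- features$cell_id[i]; iid <- features$image_id[i]
      inst <- instances[[iid]]
      k <- match(cid, inst$cell_ids)
      if (is.na(k)) next
      crop <- crop_cell(images[[iid]], inst$masks[[k]], margin)
      save_image(crop, file.path(crops_dir, paste0(cid, ".png")))
    }
  }
  labels
}

crop_cell <- function(image, mask, margin) {
  w <- which(mask, arr.ind = TRUE)
  r <- range(w[, 1L]); c <- range(w[, 2L])
  rows <- max(1L, r[1L] - margin):min(nrow(mask), r[2L] + margin)
  cols <- max(1L, c[1L] - margin):min(ncol(mask), c[2L] + margin)
  px <- image$pixels[rows, cols, drop = FALSE]
  rng <- range(px)
  if (rng[2L] > rng[1L]) px <- (px - rng[1L]) / (rng[2L] - rng[1L]) * 255
  px
}

#' Merge expert labels onto a feature table
#'
#' Splits the table into the labeled partition (non-empty label; the
#' training set for supervised classification) and the unlabeled partition.
#' Label-table ids that do not occur in the feature table are reported but
#' do not abort the merge.
#'
#' @param features a `feature_table`.
#' @param labels data.frame with columns `cell_id`, `label` (empty string or
#'   `NA` = unlabeled). Duplicate ids are an error.
#' @return List with `labeled` (feature rows + `label` column), `unlabeled`
#'   and `rejected_ids`.
#' @export
merge_labels <- function(features, labels) {
  if (!all(c("cell_id", "label") %in% names(labels)))
    stop("label table must have 'cell_id' and 'label' columns")
  if (anyDuplicated(labels$cell_id))
    stop("duplicate cell ids in label table")
  labels$label[is.na(labels$label)] <- ""
  rejected <- setdiff(labels$cell_id, features$cell_id)
  lab <- labels[labels$cell_id %in% features$cell_id, , drop = FALSE]
  lab <- lab[lab$label != "", , drop = FALSE]
  idx <- match(lab$cell_id, features$cell_id)
  labeled <- features[idx, , drop = FALSE]
  labeled$label <- lab$label
  unlabeled <- features[setdiff(seq_len(nrow(features)), idx), , drop = FALSE]
  rownames(labeled) <- rownames(unlabeled) <- NULL
  list(labeled = labeled, unlabeled = unlabeled, rejected_ids = rejected)
}
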