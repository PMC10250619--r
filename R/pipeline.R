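#' Run one pipeline step from a configuration
#'
#' Terminal-style entry point mirroring the four analysis steps (segment,
#' extract, annotate, classify) plus the synthetic generator and the two
#' evaluation utilities. Each step reads/writes the standard on-disk layout
#' (`images/<id>_bf.tif`, `images/<id>_fl.tif`, `masks/<id>.tif`, CSV
#' tables) and writes its resolved configuration to
#' `<out>/run_config.txt` for provenance.
#'
#' @param step one of `"synth"`, `"segment"`, `"extract"`, `"annotate"`,
#'   `"classify"`, `"eval-seg"`, `"eval-vesicles"`.
#' @param config named list of options; see the per-step defaults in
#'   [default_config()]. Unknown keys are an error.
#' @return Step-dependent result, invisibly (e.g. the feature table for
#'   `"extract"`).
#' @export
run_step <- function(step, config = list()) {
  steps <- c("synth", "segment", "extract", "annotate", "classify",
             "eval-seg", "eval-vesicles")
  if (!step %in% steps)
    stop(sprintf("unknown step '%s'; expected one of: %s", step,
                 paste(steps, collapse = ", ")))
  cfg <- resolve_config(step, config)
  fn <- switch(step,
    synth = run_synth, segment = run_segment, extract = run_extract,
    annotate = run_annotate, classify = run_classify,
    `eval-seg` = run_eval_seg, `eval-vesicles` = run_eval_vesicles)
  fn(cfg)
}

#' Default configuration per step
#' @param step step name as in [run_step()].
#' @return Named list of defaults.
#' @export
default_config <- function(step) {
  common <- list(out = ".", seed = 0L)
  extra <- switch(step,
    synth = list(fields = 5L),
    segment = list(input = ".", backend = "classical", min_score = 0.5),
    extract = list(input = ".", masks = "masks", fluor = TRUE,
                   m = 3L, d = 10L, v = 4L, c = 8L, t = 1),
    annotate = list(features = "features.csv", n = 50L, crops = "",
                    input = ".", masks = "masks"),
    classify = list(features = "features.csv", labels = "labels.csv",
                    mode = "random", k = 5L, trials = 25L),
    `eval-seg` = list(pred = "pred_masks", truth = "masks", iou = 0.5),
    `eval-vesicles` = list(pred = "pred_vesicles.csv",
                           truth = "vesicles.csv", tol = 5),
    list())
  c(common, extra)
}

resolve_config <- function(step, config) {
  cfg <- default_config(step)
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s) for step '%s': %s", step,
                 paste(unknown, collapse = ", ")))
  cfg[names(config)] <- config
  for (key in c("seed", "fields", "n", "k", "trials", "m", "d", "v", "c"))
    if (!is.null(cfg[[key]])) cfg[[key]] <- as.integer(cfg[[key]])
  for (key in c("min_score", "t", "iou", "tol"))
    if (!is.null(cfg[[key]])) cfg[[key]] <- as.numeric(cfg[[key]])
  if (!is.null(cfg$fluor)) cfg$fluor <- as.logical(cfg$fluor)
  cfg
}

#' Parse a plain key=value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' @param path file path.
#' @return Named list of character values (coerced per step later).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop(sprintf("malformed config line: '%s'", lines[bad][1L]))
  vals <- lapply(kv, function(p) trimws(paste(p[-1L], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  vals
}

write_run_log <- function(cfg, out, extra = character()) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  lines <- c(sprintf("# resolved configuration, %s", format(Sys.time())),
             vapply(names(cfg), function(k)
               sprintf("%s = %s", k, paste(format(cfg[[k]]), collapse = ",")),
               ""),
             extra)
  writeLines(lines, file.path(out, "run_config.txt"))
}

field_ids <- function(images_dir) {
  bf <- list.files(images_dir, pattern = "_bf\\.(tif|tiff|png)$")
  sort(sub("_bf\\.(tif|tiff|png)$", "", bf))
}

find_channel <- function(images_dir, id, suffix) {
  for (ext in c("tif", "tiff", "png")) {
    p <- file.path(images_dir, sprintf("%s_%s.%s", id, suffix, ext))
    if (file.exists(p)) return(p)
  }
  NA_character_
}

run_synth <- function(cfg) {
  manifest <- render_benchmark(cfg$fields, synthetic_spec(), dir = cfg$out,
                               seed = cfg$seed)
  write_run_log(cfg, cfg$out, sprintf("# cells = %d", nrow(manifest)))
  invisible(manifest)
}

run_segment <- function(cfg) {
  backend <- switch(cfg$backend,
    classical = classical_backend(),
    stop(sprintf("unknown backend '%s'", cfg$backend)))
  ids <- field_ids(file.path(cfg$input, "images"))
  if (!length(ids)) stop(sprintf("no *_bf images under '%s'", cfg$input))
  dir.create(file.path(cfg$out, "pred_masks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(cfg$out, "overlays"), recursive = TRUE,
             showWarnings = FALSE)
  cells <- list()
  for (id in ids) {
    img <- set_image_id(
      load_image(find_channel(file.path(cfg$input, "images"), id, "bf"),
                 "brightfield"), id)
    inst <- segment(img, backend, min_score = cfg$min_score)
    save_labelmap(inst, file.path(cfg$out, "pred_masks", paste0(id, ".tif")),
                  dims = dim(img$pixels))
    ov <- overlay(img, inst)
    png::writePNG(ov, file.path(cfg$out, "overlays", paste0(id, ".png")))
    ctr <- instance_centroids(inst)
    cells[[id]] <- if (n_instances(inst)) data.frame(
      cell_id = inst$cell_ids, image_id = id,
      centroid_row = ctr$points[, 1L], centroid_col = ctr$points[, 2L],
      score = inst$scores, stringsAsFactors = FALSE) else NULL
  }
  cells <- do.call(rbind, cells)
  write.csv(cells, file.path(cfg$out, "cells.csv"), row.names = FALSE)
  write_run_log(cfg, cfg$out,
                sprintf("# cells = %d over %d images",
                        if (is.null(cells)) 0L else nrow(cells), length(ids)))
  invisible(cells)
}

run_extract <- function(cfg) {
  ids <- field_ids(file.path(cfg$input, "images"))
  if (!length(ids)) stop(sprintf("no *_bf images under '%s'", cfg$input))
  vp <- vesicle_params(m = cfg$m, d = cfg$d, v = cfg$v, c = cfg$c, t = cfg$t)
  tabs <- list()
  for (id in ids) {
    bf <- set_image_id(
      load_image(find_channel(file.path(cfg$input, "images"), id, "bf"),
                 "brightfield"), id)
    flp <- find_channel(file.path(cfg$input, "images"), id, "fl")
    fl <- if (isTRUE(cfg$fluor) && !is.na(flp))
      load_image(flp, "fluorescent") else NULL
    inst <- load_labelmap(file.path(cfg$input, cfg$masks, paste0(id, ".tif")),
                          image_id = id)
    tabs[[id]] <- extract_features(bf, fl, inst, vparams = vp)
  }
  features <- do.call(rbind, tabs)
  rownames(features) <- NULL
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  save_feature_table(features, file.path(cfg$out, "features.csv"))
  write_run_log(cfg, cfg$out,
                sprintf("# cells = %d, feature columns = %d",
                        nrow(features), ncol(features) - 2L))
  invisible(features)
}

run_annotate <- function(cfg) {
  features <- load_feature_table(cfg$features)
  crops_dir <- if (nzchar(cfg$crops)) cfg$crops else NULL
  images <- instances <- NULL
  if (!is.null(crops_dir)) {
    ids <- unique(features$image_id)
    images <- setNames(lapply(ids, function(id) set_image_id(
      load_image(find_channel(file.path(cfg$input, "images"), id, "bf"),
                 "brightfield"), id)), ids)
    instances <- setNames(lapply(ids, function(id) load_labelmap(
      file.path(cfg$input, cfg$masks, paste0(id, ".tif")), image_id = id)),
      ids)
  }
  labels <- sample_for_annotation(features, n = cfg$n, seed = cfg$seed,
                                  crops_dir = crops_dir, images = images,
                                  instances = instances)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(labels, file.path(cfg$out, "labels.csv"), row.names = FALSE)
  write_run_log(cfg, cfg$out, sprintf("# sampled = %d of %d cells",
                                      nrow(labels), nrow(features)))
  invisible(labels)
}

run_classify <- function(cfg) {
  features <- load_feature_table(cfg$features)
  labels <- read.csv(cfg$labels, stringsAsFactors = FALSE)
  labels$cell_id <- as.character(labels$cell_id)
  m <- merge_labels(features, labels[, c("cell_id", "label")])
  mode <- switch(cfg$mode, random = "random_stratified",
                 grouped = "image_grouped_stratified",
                 stop(sprintf("unknown CV mode '%s'", cfg$mode)))
  part <- make_partition(m$labeled, mode = mode, k = cfg$k, seed = cfg$seed)
  res <- automl(m$labeled, part, trials_per_family = cfg$trials,
                seed = cfg$seed)
  out_tab <- predict_unlabeled(res$bundle, features,
                               labels[, c("cell_id", "label")])
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(out_tab[, c("cell_id", "image_id", "predicted_label",
                        "label_source")],
            file.path(cfg$out, "predictions.csv"), row.names = FALSE)
  oof <- res$bundle$oof_predictions
  confusion <- table(truth = m$labeled$label, predicted = oof)
  report <- list(
    best_family = res$bundle$family,
    best_params = res$bundle$params,
    cv_balanced_accuracy = res$bundle$cv_balanced_accuracy,
    fold_scores = res$bundle$fold_scores,
    n_trials = nrow(res$history),
    history = res$history[, c("trial", "family", "params", "mean_score")],
    importances = as.list(res$bundle$importances),
    confusion_out_of_fold = as.data.frame(confusion))
  jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(cfg, cfg$out,
                sprintf("# trials = %d, best = %s (%.4f)",
                        nrow(res$history), res$bundle$family,
                        res$bundle$cv_balanced_accuracy))
  invisible(res)
}

run_eval_seg <- function(cfg) {
  load_dir <- function(d) {
    files <- sort(list.files(d, pattern = "\\.(tif|tiff|png)$",
                             full.names = TRUE))
    lapply(files, load_labelmap)
  }
  pred <- load_dir(cfg$pred); truth <- load_dir(cfg$truth)
  res <- mask_ap(pred, truth, iou_threshold = cfg$iou)
  message(sprintf("AP@%.2f = %.4f (%d truth, %d predictions)",
                  res$iou_threshold, res$ap, res$n_truth, res$n_pred))
  invisible(res)
}

run_eval_vesicles <- function(cfg) {
  pred_df <- read.csv(cfg$pred, stringsAsFactors = FALSE)
  truth_df <- read.csv(cfg$truth, stringsAsFactors = FALSE)
  ids <- union(unique(pred_df$image_id), unique(truth_df$image_id))
  tot_m <- 0L; tot_p <- 0L; tot_t <- 0L
  for (id in ids) {
    p <- point_set(as.matrix(pred_df[pred_df$image_id == id,
                                     c("row", "col"), drop = FALSE]))
    t <- point_set(as.matrix(truth_df[truth_df$image_id == id,
                                      c("row", "col"), drop = FALSE]))
    s <- score_detection(p, t, tolerance = cfg$tol)
    tot_m <- tot_m + s$matched; tot_p <- tot_p + s$n_pred
    tot_t <- tot_t + s$n_truth
  }
  res <- list(precision = if (tot_p) tot_m / tot_p else 1,
              recall = if (tot_t) tot_m / tot_t else 1,
              matched = tot_m, n_pred = tot_p, n_truth = tot_t)
  message(sprintf("precision = %.4f, recall = %.4f (%d/%d matched of %d truth)",
                  res$precision, res$recall, tot_m, tot_p, tot_t))
  invisible(res)
}
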