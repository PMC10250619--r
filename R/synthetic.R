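#' Synthetic field specification
#'
#' Parameters of the synthetic microscopy generator used to exercise every
#' pipeline stage without external data. A field holds non-overlapping cells
#' of four phenotypes on a bright background (brightfield) plus a
#' correlated fluorescent channel with exact-zero background, per-cell
#' baseline signal and planted high-intensity vesicle spots.
#'
#' Phenotypes: discocytes are discs with a central pallor; echinocytes have
#' a sinusoidally perturbed radius (spicules, hence lower solidity);
#' stomatocytes are discs with an off-center dark slit; sickles are
#' high-eccentricity crescents (difference of two offset discs).
#'
#' The exact-zero fluorescent background is deliberate: it exercises the
#' zero-intensity exclusion rule of the fluorescent feature path. Vesicle
#' spots are planted with peak amplitude well above the noise level and
#' pairwise center distances of at least `2 * c` (the context diameter), the
#' regime the detector is specified to resolve.
#'
#' @param dims field dimensions in pixels.
#' @param cells_per_class named counts for classes discocyte, echinocyte,
#'   stomatocyte, sickle.
#' @param radius_range cell radius range in pixels.
#' @param spike_count,spike_amplitude echinocyte boundary perturbation:
#'   number of spicules and relative amplitude.
#' @param sickle_offset crescent cut-out offset as a fraction of the radius.
#' @param vesicle_rate Poisson mean of planted vesicles per cell.
#' @param vesicle_peak spot peak amplitude above the cell baseline.
#' @param vesicle_sigma Gaussian spot standard deviation in pixels.
#' @param vesicle_min_dist minimum pairwise spot distance in pixels
#'   (default `2 * 8`, twice the context radius).
#' @param noise_sd brightfield Gaussian noise standard deviation.
#' @param fl_noise_sd fluorescent-channel noise standard deviation (high-SNR
#'   fluorescence: small relative to the in-cell baseline).
#' @param bf_background,bf_cell brightfield background and cell shade.
#' @param fl_baseline in-cell fluorescent baseline at the cell interior.
#' @param fl_ramp_drop,fl_ramp_depth in-cell fluorescent profile: intensity
#'   falls off linearly from the flat interior plateau to
#'   `fl_baseline - fl_ramp_drop` at the membrane over the outermost
#'   `fl_ramp_depth` pixels, emulating the smooth signal decay of real cells
#'   toward their boundary. The resulting slope keeps the cell's own
#'   ball/annulus contrast below the detector's minimum contrast `t` while
#'   ensuring every near-membrane pixel has brighter inward neighbours (so
#'   only planted spots produce acceptable local maxima).
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dims = c(768L, 1024L),
                           cells_per_class = c(discocyte = 12L,
                                               echinocyte = 6L,
                                               stomatocyte = 6L,
                                               sickle = 6L),
                           radius_range = c(32, 42),
                           spike_count = 7L, spike_amplitude = 0.16,
                           sickle_offset = 0.65,
                           vesicle_rate = 1,
                           vesicle_peak = 120, vesicle_sigma = 1.8,
                           vesicle_min_dist = 16,
                           noise_sd = 5, fl_noise_sd = 0.5,
                           bf_background = 200, bf_cell = 120,
                           fl_baseline = 60, fl_ramp_drop = 3.2,
                           fl_ramp_depth = 16,
                           seed = 0L) {
  stopifnot(all(cells_per_class >= 0), length(dims) == 2L,
            radius_range[1L] <= radius_range[2L])
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Render one synthetic field with full ground truth
#'
#' @param spec a [synthetic_spec()].
#' @param image_id field identifier (drives cell ids).
#' @return List with `brightfield` and `fluorescent` [image_grid()]s,
#'   `instances` (truth [instance_set()]), `vesicles` (truth [point_set()]
#'   with owner cell ids) and `labels` (data.frame `cell_id`, `label`).
#'   Fully deterministic given `spec$seed`.
#' @export
render_field <- function(spec, image_id = "field_001") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  dims <- as.integer(spec$dims)
  classes <- rep(names(spec$cells_per_class), spec$cells_per_class)
  classes <- sample(classes)
  n <- length(classes)
  rmax <- spec$radius_range[2L] * (1 + spec$spike_amplitude)

  centers <- place_centers(n, dims, min_dist = 2 * rmax + 4,
                           margin = rmax + 4)
  if (nrow(centers) < n)
    stop("could not place the requested cells without overlap; request fewer cells or a larger field")

  bf <- matrix(spec$bf_background, dims[1L], dims[2L])
  fl <- matrix(0, dims[1L], dims[2L])
  masks <- vector("list", n)
  radii <- runif(n, spec$radius_range[1L], spec$radius_range[2L])
  for (k in seq_len(n)) {
    cell <- render_cell(classes[k], centers[k, ], radii[k], spec, dims)
    masks[[k]] <- cell$mask
    bf[cell$mask] <- cell$bf[cell$mask]
    # linear ramp in boundary distance into a flat interior plateau
    dmk <- as.matrix(EBImage::distmap(cell$mask))
    prof <- spec$fl_baseline -
      spec$fl_ramp_drop * (1 - pmin(dmk, spec$fl_ramp_depth) / spec$fl_ramp_depth)
    fl[cell$mask] <- prof[cell$mask]
  }
  instances <- instance_set(image_id, masks)

  # plant vesicles: centers inside cells, inner ball fully in-mask, pairwise
  # spacing >= vesicle_min_dist across the whole field
  ves_rows <- list()
  placed <- matrix(numeric(0), 0L, 2L)
  for (k in seq_len(n)) {
    count <- rpois(1L, spec$vesicle_rate)
    if (count == 0L) next
    dm <- as.matrix(EBImage::distmap(masks[[k]]))
    eligible <- which(dm > 5, arr.ind = TRUE)
    if (!nrow(eligible)) next
    got <- 0L; tries <- 0L
    while (got < count && tries < 200L) {
      tries <- tries + 1L
      p <- eligible[sample.int(nrow(eligible), 1L), ]
      if (nrow(placed)) {
        dmin <- min(sqrt((placed[, 1L] - p[1L])^2 + (placed[, 2L] - p[2L])^2))
        if (dmin < spec$vesicle_min_dist) next
      }
      placed <- rbind(placed, p)
      ves_rows[[length(ves_rows) + 1L]] <-
        data.frame(cell_id = instances$cell_ids[k], row = p[1L], col = p[2L])
      got <- got + 1L
    }
  }
  ves <- if (length(ves_rows)) do.call(rbind, ves_rows) else
    data.frame(cell_id = character(0), row = numeric(0), col = numeric(0))

  # stamp Gaussian spots, then noise; masking keeps the background exactly 0
  for (i in seq_len(nrow(ves))) {
    fl <- stamp_spot(fl, c(ves$row[i], ves$col[i]), spec$vesicle_peak,
                     spec$vesicle_sigma)
  }
  any_mask <- Reduce(`|`, masks, matrix(FALSE, dims[1L], dims[2L]))
  bf <- pmax(bf + matrix(rnorm(prod(dims), 0, spec$noise_sd), dims[1L]), 0)
  fl_noise <- matrix(rnorm(prod(dims), 0, spec$fl_noise_sd), dims[1L])
  fl <- pmax(fl + fl_noise, 1) * any_mask

  list(brightfield = set_image_id(image_grid(bf, "brightfield"), image_id),
       fluorescent = set_image_id(image_grid(fl, "fluorescent"), image_id),
       instances = instances,
       vesicles = point_set(as.matrix(ves[, c("row", "col")]),
                            owner_ids = ves$cell_id),
       labels = data.frame(cell_id = instances$cell_ids,
                           label = classes, stringsAsFactors = FALSE))
}

place_centers <- function(n, dims, min_dist, margin, max_tries = 40000L) {
  centers <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  while (nrow(centers) < n && tries < max_tries) {
    tries <- tries + 1L
    p <- c(runif(1L, margin, dims[1L] - margin),
           runif(1L, margin, dims[2L] - margin))
    if (nrow(centers)) {
      d <- sqrt((centers[, 1L] - p[1L])^2 + (centers[, 2L] - p[2L])^2)
      if (min(d) < min_dist) next
    }
    centers <- rbind(centers, p)
  }
  centers
}

# boundary-in-polar-coordinates mask plus per-class brightfield shading
render_cell <- function(class, center, radius, spec, dims) {
  half <- ceiling(radius * 1.6) + 2L
  rows <- max(1L, round(center[1L]) - half):min(dims[1L], round(center[1L]) + half)
  cols <- max(1L, round(center[2L]) - half):min(dims[2L], round(center[2L]) + half)
  dr <- outer(rows - center[1L], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2L])
  rr <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  phase <- runif(1L, 0, 2 * pi)
  local_mask <- switch(class,
    discocyte = rr <= radius,
    echinocyte = rr <= radius *
      (1 + spec$spike_amplitude * sin(spec$spike_count * theta + phase)),
    stomatocyte = rr <= radius,
    sickle = {
      # curved capsule: pixels within w of a circular arc -> an elongated,
      # round-ended crescent (high eccentricity, no razor-thin horns)
      w <- 0.30 * radius
      arc_r <- 1.6 * radius
      arc_ctr <- center + arc_r * c(cos(phase), sin(phase))
      span <- 0.85 * radius / arc_r           # half-angle: arc length ~1.7 R
      ang <- phase + pi + seq(-span, span, length.out = 41L)
      ar <- arc_ctr[1L] + arc_r * cos(ang)
      ac <- arc_ctr[2L] + arc_r * sin(ang)
      d2min <- matrix(Inf, length(rows), length(cols))
      for (s in seq_along(ang)) {
        d2 <- outer((rows - ar[s])^2, rep(1, length(cols))) +
          outer(rep(1, length(rows)), (cols - ac[s])^2)
        d2min <- pmin(d2min, d2)
      }
      d2min <= w^2
    },
    stop("unknown class"))
  shade <- matrix(spec$bf_cell, length(rows), length(cols))
  if (class %in% c("discocyte", "stomatocyte"))
    shade[rr <= 0.45 * radius] <- spec$bf_cell + 50   # central pallor
  if (class == "stomatocyte") {
    # off-center dark slit: a narrow band through the cell
    slit <- abs(dr * cos(phase) + dc * sin(phase) - 0.3 * radius) <
      0.12 * radius
    shade[slit & rr <= 0.8 * radius] <- spec$bf_cell - 35
  }
  mask <- matrix(FALSE, dims[1L], dims[2L])
  mask[rows, cols] <- local_mask
  bf <- matrix(spec$bf_background, dims[1L], dims[2L])
  bf[rows, cols] <- shade
  list(mask = mask, bf = bf)
}

stamp_spot <- function(img, center, peak, sigma) {
  half <- ceiling(3 * sigma)
  rows <- max(1L, center[1L] - half):min(nrow(img), center[1L] + half)
  cols <- max(1L, center[2L] - half):min(ncol(img), center[2L] + half)
  d2 <- outer((rows - center[1L])^2, rep(1, length(cols))) +
    outer(rep(1, length(rows)), (cols - center[2L])^2)
  img[rows, cols] <- img[rows, cols] + peak * exp(-d2 / (2 * sigma^2))
  img
}

#' Render a multi-field benchmark to disk
#'
#' Writes `n_fields` synthetic fields in the pipeline's input layout:
#' `images/<id>_bf.tif` and `<id>_fl.tif` (16-bit), `masks/<id>.tif`
#' (16-bit truth label maps), `vesicles.csv` (truth vesicle centers,
#' columns `image_id,cell_id,row,col`), `labels.csv` (truth class labels)
#' and `manifest.csv` (one row per cell).
#'
#' @param n_fields number of fields.
#' @param spec a [synthetic_spec()]; its seed is re-derived per field from
#'   `seed`.
#' @param dir output directory (created).
#' @param seed integer master seed.
#' @return The manifest data.frame, invisibly; the per-field ground truth is
#'   also returned in the `fields` attribute when `keep_fields = TRUE`.
#' @param keep_fields also return the in-memory field objects.
#' @export
render_benchmark <- function(n_fields, spec = synthetic_spec(), dir = NULL,
                             seed = 0L, keep_fields = FALSE) {
  write_out <- !is.null(dir)
  if (write_out) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- list(); ves_all <- list(); lab_all <- list(); fields <- list()
  for (i in seq_len(n_fields)) {
    id <- sprintf("field_%03d", i)
    fspec <- spec
    fspec$seed <- as.integer(seed) + 101L * i
    fld <- render_field(fspec, image_id = id)
    ctr <- instance_centroids(fld$instances)
    manifest[[i]] <- data.frame(
      image_id = id, cell_id = fld$instances$cell_ids,
      label = fld$labels$label,
      centroid_row = ctr$points[, 1L], centroid_col = ctr$points[, 2L],
      n_vesicles = as.integer(table(factor(fld$vesicles$owner_ids,
                                           levels = fld$instances$cell_ids))),
      stringsAsFactors = FALSE)
    ves_all[[i]] <- data.frame(
      image_id = id,
      cell_id = if (n_points(fld$vesicles)) fld$vesicles$owner_ids else character(0),
      row = fld$vesicles$points[, 1L], col = fld$vesicles$points[, 2L],
      stringsAsFactors = FALSE)
    lab_all[[i]] <- cbind(image_id = id, fld$labels)
    if (write_out) {
      save_image(fld$brightfield, file.path(dir, "images", paste0(id, "_bf.tif")))
      save_image(fld$fluorescent, file.path(dir, "images", paste0(id, "_fl.tif")))
      save_labelmap(fld$instances, file.path(dir, "masks", paste0(id, ".tif")))
    }
    if (keep_fields) fields[[id]] <- fld
  }
  manifest <- do.call(rbind, manifest)
  if (write_out) {
    write.csv(do.call(rbind, ves_all), file.path(dir, "vesicles.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, lab_all), file.path(dir, "labels.csv"),
              row.names = FALSE)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  if (keep_fields) attr(manifest, "fields") <- fields
  invisible(manifest)
}
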