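#' Render segmentation and vesicle detections over an image
#'
#' Produces an RGB array (values in `[0, 1]`) of the input image with
#' instance mask outlines recolored and, optionally, a square box of side
#' `2 v + 1` drawn around every detected vesicle center, mirroring the usual
#' review overlay of segmentation results on brightfield and detected
#' vesicles on fluorescent channels. All pixels not on an outline or box
#' retain their (display-normalized) intensity.
#'
#' @param image an [image_grid()].
#' @param instances an [instance_set()] with masks matching `image`.
#' @param vesicles optional `vesicle_set` from [detect_vesicles()].
#' @param v half-side of the vesicle boxes (defaults to the vesicle radius
#'   stored in `vesicles`, else 4).
#' @param outline_color,box_color RGB triplets in `[0, 1]`.
#' @return `height x width x 3` numeric array.
#' @export
overlay <- function(image, instances, vesicles = NULL, v = NULL,
                    outline_color = c(1, 0.2, 0.2), box_color = c(1, 1, 1)) {
  if (n_instances(instances))
    stopifnot_same_dims(image$pixels, instances$masks[[1L]],
                        "image and instance masks")
  base <- image$pixels
  rng <- range(base)
  base <- if (rng[2L] > rng[1L]) (base - rng[1L]) / (rng[2L] - rng[1L])
          else matrix(0, nrow(base), ncol(base))
  rgb <- array(base, dim = c(dim(base), 3L))
  for (m in instances$masks) {
    edge <- mask_outline(m)
    for (ch in 1:3) {
      plane <- rgb[, , ch]; plane[edge] <- outline_color[ch]
      rgb[, , ch] <- plane
    }
  }
  if (!is.null(vesicles)) {
    if (is.null(v)) v <- if (!is.null(vesicles$params)) vesicles$params$v else 4
    for (ctr in vesicle_centers_list(vesicles)) {
      box <- box_outline_pixels(ctr, v, dim(base))
      for (ch in 1:3) {
        plane <- rgb[, , ch]; plane[box] <- box_color[ch]
        rgb[, , ch] <- plane
      }
    }
  }
  rgb
}

# boundary = foreground pixels with a 4-neighbour in background (or on border)
mask_outline <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !core
}

# linear indices of the hollow square of side 2v+1 centered at ctr, clipped
box_outline_pixels <- function(ctr, v, dims) {
  r <- round(ctr[1L]); c <- round(ctr[2L])
  rows <- (r - v):(r + v); cols <- (c - v):(c + v)
  on_edge <- outer(rows %in% c(r - v, r + v), rep(TRUE, length(cols))) |
    outer(rep(TRUE, length(rows)), cols %in% c(c - v, c + v))
  rr <- outer(rows, rep(1L, length(cols)))
  cc <- outer(rep(1L, length(rows)), cols)
  keep <- on_edge & rr >= 1 & rr <= dims[1L] & cc >= 1 & cc <= dims[2L]
  cbind(rr[keep], cc[keep])
}

vesicle_centers_list <- function(vesicles) {
  df <- vesicles$centers
  if (is.null(df) || !nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) c(df$row[i], df$col[i]))
}
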