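#' Shape features of a binary cell mask
#'
#' Computes the 14 two-dimensional shape descriptors of the catalog from a
#' segmentation mask at native pixel resolution. Definitions:
#'
#' * `pixel_surface` — foreground pixel count A.
#' * `perimeter` — weighted boundary-pixel count P: border pixels (foreground
#'   with a 4-neighbour in background) are convolved with a neighbour-coding
#'   kernel and weighted 1, `sqrt(2)` or `(1 + sqrt(2))/2` according to the
#'   local boundary direction.
#' * `major_axis_length`, `minor_axis_length` — `4 * sqrt(eigenvalue)` of the
#'   pixel-coordinate covariance matrix (moment-equivalent ellipse axes).
#' * `maximum_diameter` — largest pairwise distance between mask pixels.
#' * `perimeter_surface_ratio` — `P / A`.
#' * `sphericity` — `2 * sqrt(pi * A) / P` (1 for a perfect disc).
#' * `elongation` — `sqrt(lambda_minor / lambda_major)` (1 = isotropic).
#' * `convex_area` — lattice points in the closed convex hull of the mask
#'   pixels, counted exactly via Pick's theorem.
#' * `bounding_box_area`, `extent` — axis-aligned bounding-box area and
#'   `A / bounding_box_area`.
#' * `eccentricity` — `sqrt(1 - lambda_minor / lambda_major)` of the
#'   moment-equivalent ellipse (0 = circle).
#' * `equivalent_diameter` — diameter of the disc of area A.
#' * `solidity` — `A / convex_area`.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return Named numeric vector of length 14 (names per
#'   [feature_catalog()]); a single-pixel mask yields degenerate axis
#'   lengths of 0.
#' @export
shape_features <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) stop("shape features require a non-empty mask")
  w <- which(mask, arr.ind = TRUE)
  area <- nrow(w)

  per <- mask_perimeter(mask)

  # moment-equivalent ellipse from the (population) coordinate covariance
  ctr <- colMeans(w)
  dr <- w[, 1L] - ctr[1L]; dc <- w[, 2L] - ctr[2L]
  cov <- matrix(c(mean(dr * dr), mean(dr * dc), mean(dr * dc), mean(dc * dc)), 2L)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1L]); minor <- 4 * sqrt(ev[2L])
  ecc <- if (ev[1L] > 0) sqrt(1 - ev[2L] / ev[1L]) else 0
  elong <- if (ev[1L] > 0) sqrt(ev[2L] / ev[1L]) else 1

  hull_idx <- chull(w[, 2L], w[, 1L])
  hull <- w[hull_idx, , drop = FALSE]
  maxdiam <- if (nrow(hull) == 1L) 0 else {
    d2 <- outer(hull[, 1L], hull[, 1L], "-")^2 +
      outer(hull[, 2L], hull[, 2L], "-")^2
    sqrt(max(d2))
  }
  conv_area <- convex_lattice_area(hull)
  conv_area <- max(conv_area, area)     # guard against rounding on thin masks

  bbox_area <- (diff(range(w[, 1L])) + 1) * (diff(range(w[, 2L])) + 1)

  c(shape_pixel_surface = area,
    shape_perimeter = per,
    shape_major_axis_length = major,
    shape_minor_axis_length = minor,
    shape_maximum_diameter = maxdiam,
    shape_perimeter_surface_ratio = per / area,
    shape_sphericity = if (per > 0) 2 * sqrt(pi * area) / per else NA_real_,
    shape_elongation = elong,
    shape_convex_area = conv_area,
    shape_bounding_box_area = bbox_area,
    shape_extent = area / bbox_area,
    shape_eccentricity = ecc,
    shape_equivalent_diameter = sqrt(4 * area / pi),
    shape_solidity = area / conv_area)
}

# weighted border-pixel perimeter: border pixels are coded by how many of
# their orthogonal (weight 2) and diagonal (weight 10) neighbours are also
# border pixels; each code maps to a length contribution.
mask_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  border <- mask & !interior
  bp <- matrix(0, nr + 2L, nc + 2L)
  bp[2:(nr + 1L), 2:(nc + 1L)] <- border
  core <- function(sr, sc) bp[(2:(nr + 1L)) + sr, (2:(nc + 1L)) + sc]
  orth <- core(-1L, 0L) + core(1L, 0L) + core(0L, -1L) + core(0L, 1L)
  diag_ <- core(-1L, -1L) + core(-1L, 1L) + core(1L, -1L) + core(1L, 1L)
  code <- 10 * diag_ + 2 * orth + 1
  weights <- numeric(50)
  weights[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
  weights[c(21, 33) + 1L] <- sqrt(2)
  weights[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
  sum(weights[code[border] + 1L])
}

# lattice points inside or on the convex hull polygon, by Pick's theorem:
# points = A + B/2 + 1 with A the shoelace area, B boundary lattice points.
convex_lattice_area <- function(hull) {
  n <- nrow(hull)
  if (n == 1L) return(1)
  if (n == 2L) {
    d <- abs(hull[2L, ] - hull[1L, ])
    return(gcd2(d[1L], d[2L]) + 1)
  }
  r <- hull[, 1L]; c <- hull[, 2L]
  nxt <- c(2:n, 1L)
  a2 <- abs(sum(r * c[nxt] - r[nxt] * c))
  b <- sum(mapply(function(i, j) gcd2(abs(r[i] - r[j]), abs(c[i] - c[j])),
                  seq_len(n), nxt))
  a2 / 2 + b / 2 + 1
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}
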