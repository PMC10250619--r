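#' Texture features of a masked region
#'
#' Computes the 42 gray-level-matrix texture statistics of the catalog from
#' one channel of one cell: 15 from the gray level co-occurrence matrix
#' (GLCM), 7 from the gray level dependence matrix (GLDM), 9 from the gray
#' level size zone matrix (GLSZM) and 11 from the gray level run length
#' matrix (GLRLM). Intensities are first discretized with a fixed bin width
#' (default 25 on the normalized `[0, 255]` scale, at most 11 levels,
#' [discretize_intensities()]). GLCM and GLRLM are accumulated at distance 1
#' over the standard four 2-D directions (0, 45, 90, 135 degrees) and the
#' per-direction feature values are averaged; GLDM uses the 8-neighbourhood
#' with dependence tolerance 0; GLSZM zones are 8-connected regions of equal
#' level.
#'
#' When only a single gray level is present, difference-type features take
#' their analytic limits (e.g. contrast 0, joint energy 1) and
#' correlation-type features (`glcm_correlation`, `glcm_imc1`, `glcm_imc2`,
#' `glcm_mcc`) are `NA`.
#'
#' @param image an [image_grid()] or numeric matrix on the normalized scale.
#' @param mask logical matrix, same dimensions; pixels outside the mask (and,
#'   for the fluorescent channel, zero-valued pixels already excluded
#'   upstream) do not contribute.
#' @param bin_width discretization bin width.
#' @param exclude_zero drop zero-valued pixels from the region first.
#' @return Named numeric vector of length 42.
#' @export
texture_features <- function(image, mask, bin_width = 25,
                             exclude_zero = FALSE) {
  px <- if (is_image_grid(image)) image$pixels else image
  stopifnot_same_dims(px, mask, "image and mask")
  region <- mask != 0
  if (exclude_zero) region <- region & (px != 0)
  if (sum(region) < 2L)
    stop("texture features require >= 2 in-region pixels")
  lev <- discretize_intensities(px, bin_width)
  lev[!region] <- NA_integer_
  # crop to the region bounding box for speed
  w <- which(region, arr.ind = TRUE)
  lev <- lev[min(w[, 1L]):max(w[, 1L]), min(w[, 2L]):max(w[, 2L]), drop = FALSE]
  c(glcm_features(lev), gldm_features(lev), glszm_features(lev),
    glrlm_features(lev))
}

texture_directions <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

# ---- GLCM -----------------------------------------------------------------

# symmetric co-occurrence counts of `lev` (NA = outside region) for one offset
glcm_matrix <- function(lev, offset, nlev) {
  nr <- nrow(lev); nc <- ncol(lev)
  dr <- offset[1L]; dc <- offset[2L]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  m <- matrix(0, nlev, nlev)
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = seq_len(nlev)),
                 factor(b[ok], levels = seq_len(nlev)))
    m <- unclass(tab) + t(unclass(tab))   # symmetric
  }
  m
}

glcm_features <- function(lev) {
  nlev <- max(lev, na.rm = TRUE)
  vals <- vapply(texture_directions(), function(off) {
    m <- glcm_matrix(lev, off, nlev)
    glcm_stats(m)
  }, numeric(15L))
  out <- rowMeans(vals)
  setNames(out, glcm_feature_names())
}

glcm_stats <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(rep(NA_real_, 15L))
  p <- counts / tot
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(n) * px); muy <- sum(seq_len(n) * py)
  sx2 <- sum((seq_len(n) - mux)^2 * px); sy2 <- sum((seq_len(n) - muy)^2 * py)
  # difference distribution p_{|i-j|}(k), k = 0..n-1
  k <- abs(row(p) - col(p))
  pd <- vapply(0:(n - 1L), function(kk) sum(p[k == kk]), 0)
  da <- sum((0:(n - 1L)) * pd)
  nz <- pd > 0
  contrast <- sum((i - j)^2 * p)
  autoc <- sum(i * j * p)
  correlation <- if (sx2 > 0 && sy2 > 0)
    (sum(i * j * p) - mux * muy) / sqrt(sx2 * sy2) else NA_real_
  diff_entropy <- -sum(pd[nz] * log2(pd[nz]))
  diff_variance <- sum(((0:(n - 1L)) - da)^2 * pd)
  id <- sum(pd / (1 + 0:(n - 1L)))
  idm <- sum(pd / (1 + (0:(n - 1L))^2))
  inv_var <- if (n > 1L) sum(pd[-1L] / (1:(n - 1L))^2) else 0
  joint_energy <- sum(p^2)
  pz <- p > 0
  hxy <- -sum(p[pz] * log2(p[pz]))
  pxy <- outer(px, py)
  ok1 <- pz & pxy > 0
  hxy1 <- -sum(p[ok1] * log2(pxy[ok1]))
  ok2 <- pxy > 0
  hxy2 <- -sum(pxy[ok2] * log2(pxy[ok2]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else NA_real_
  if (max(hx, hy) == 0) imc2 <- NA_real_
  mcc <- glcm_mcc(p, px, py)
  c(contrast, correlation, autoc, da, diff_entropy, diff_variance, id, idm,
    imc1, imc2, inv_var, mux, joint_energy, hxy, mcc)
}

# sqrt of the second largest eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k) /
# (px(i) py(k)); NA when fewer than two gray levels occur
glcm_mcc <- function(p, px, py) {
  keep <- px > 0
  if (sum(keep) < 2L || sum(py > 0) < 2L) return(NA_real_)
  pk <- p[keep, py > 0, drop = FALSE]
  pxk <- px[keep]; pyk <- py[py > 0]
  q <- sweep(pk, 1L, pxk, "/") %*% t(sweep(pk, 2L, pyk, "/"))
  ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
  val <- ev[2L]
  if (is.na(val)) return(NA_real_)
  sqrt(max(val, 0))
}

# ---- GLDM -----------------------------------------------------------------

gldm_features <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  pad <- matrix(NA_integer_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lev
  core <- function(sr, sc) pad[(2:(nr + 1L)) + sr, (2:(nc + 1L)) + sc]
  dep <- matrix(0L, nr, nc)
  for (off in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                   c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    nb <- core(off[1L], off[2L])
    dep <- dep + (!is.na(nb) & !is.na(lev) & nb == lev)
  }
  ok <- !is.na(lev)
  i <- lev[ok]                 # gray level per pixel
  j <- dep[ok] + 1L            # dependence size (neighbours + 1)
  nz <- length(i)
  p <- as.data.frame(table(i = i, j = j), stringsAsFactors = FALSE)
  p <- p[p$Freq > 0, ]
  gi <- as.numeric(p$i); gj <- as.numeric(p$j); f <- p$Freq
  pr <- f / nz
  mu_i <- sum(pr * gi); mu_j <- sum(pr * gj)
  out <- c(
    gldm_dependence_entropy = -sum(pr * log2(pr)),
    gldm_dependence_non_uniformity =
      sum(tapply(f, gj, sum)^2) / nz,
    gldm_dependence_variance = sum(pr * (gj - mu_j)^2),
    gldm_gray_level_non_uniformity = sum(tapply(f, gi, sum)^2) / nz,
    gldm_gray_level_variance = sum(pr * (gi - mu_i)^2),
    gldm_low_gray_level_emphasis = sum(f / gi^2) / nz,
    gldm_high_gray_level_emphasis = sum(f * gi^2) / nz)
  setNames(out, gldm_feature_names())
}

# ---- GLSZM ----------------------------------------------------------------

# zones: 8-connected components of equal gray level, found by flood fill
glszm_zones_ff <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  visited <- matrix(FALSE, nr, nc)
  zones <- list()
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (idx in which(!is.na(lev))) {
    if (visited[idx]) next
    g <- lev[idx]
    stack <- idx
    visited[idx] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (o in seq_len(8L)) {
        rr <- r + offs[o, 1L]; cc <- c + offs[o, 2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        ii <- (cc - 1L) * nr + rr
        if (!visited[ii] && !is.na(lev[ii]) && lev[ii] == g) {
          visited[ii] <- TRUE
          stack <- c(stack, ii)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  do.call(rbind, zones)
}

glszm_features <- function(lev) {
  z <- glszm_zones_ff(lev)
  gi <- z[, 1L]; s <- z[, 2L]
  nz <- nrow(z)
  out <- c(
    sum(gi^2) / nz,
    sum(s^2) / nz,
    sum(gi^2 * s^2) / nz,
    sum(s^2 / gi^2) / nz,
    sum(1 / gi^2) / nz,
    sum(tapply(rep(1, nz), s, sum)^2) / nz,
    sum(1 / s^2) / nz,
    sum(gi^2 / s^2) / nz,
    sum(1 / (gi^2 * s^2)) / nz)
  setNames(out, glszm_feature_names())
}

# ---- GLRLM ----------------------------------------------------------------

# run-length counts (gray level, run length) along one direction
glrlm_runs <- function(lev, dir) {
  nr <- nrow(lev); nc <- ncol(lev)
  lines <- switch(paste(dir, collapse = ","),
    "0,1" = lapply(seq_len(nr), function(r) lev[r, ]),
    "-1,0" = lapply(seq_len(nc), function(c) lev[, c]),
    "-1,1" = lapply(seq(-(nr - 1L), nc - 1L), function(k) {
      r <- seq_len(nr); c <- r + k
      ok <- c >= 1L & c <= nc
      lev[cbind(rev(r[ok]), rev(c[ok]))]
    }),
    "-1,-1" = lapply(seq_len(nr + nc - 1L), function(k) {
      r <- seq_len(nr); c <- k - r + 1L
      ok <- c >= 1L & c <= nc
      lev[cbind(r[ok], c[ok])]
    }),
    stop("unknown direction"))
  runs <- list()
  for (ln in lines) {
    if (!length(ln)) next
    rl <- rle(ifelse(is.na(ln), -1L, ln))
    keep <- rl$values != -1L
    if (any(keep))
      runs[[length(runs) + 1L]] <- cbind(rl$values[keep], rl$lengths[keep])
  }
  do.call(rbind, runs)
}

glrlm_features <- function(lev) {
  np <- sum(!is.na(lev))
  vals <- vapply(texture_directions(), function(dir) {
    rn <- glrlm_runs(lev, dir)
    gi <- rn[, 1L]; r <- rn[, 2L]
    nr_ <- nrow(rn)
    pr <- rep(1 / nr_, nr_)
    mu_r <- sum(pr * r)
    p_tab <- table(gi, r) / nr_
    pnz <- p_tab[p_tab > 0]
    c(sum(r^2) / nr_,
      sum(gi^2 * r^2) / nr_,
      sum(r^2 / gi^2) / nr_,
      sum(1 / gi^2) / nr_,
      -sum(pnz * log2(pnz)),
      sum(tapply(rep(1, nr_), r, sum)^2) / nr_,
      nr_ / np,
      sum(pr * (r - mu_r)^2),
      sum(1 / r^2) / nr_,
      sum(gi^2 / r^2) / nr_,
      sum(1 / (gi^2 * r^2)) / nr_)
  }, numeric(11L))
  setNames(rowMeans(vals), glrlm_feature_names())
}
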