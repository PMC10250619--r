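# shared fixtures and independent oracles; everything is generated in code

# ---- simple mask builders -------------------------------------------------

disc_mask <- function(radius, dims = rep(2L * radius + 11L, 2L),
                      center = (dims + 1) / 2) {
  rr <- outer((seq_len(dims[1L]) - center[1L])^2, rep(1, dims[2L]))
  cc <- outer(rep(1, dims[1L]), (seq_len(dims[2L]) - center[2L])^2)
  rr + cc <= radius^2
}

square_mask <- function(side, dims = c(side + 10L, side + 10L), at = c(6L, 6L)) {
  m <- matrix(FALSE, dims[1L], dims[2L])
  m[at[1L]:(at[1L] + side - 1L), at[2L]:(at[2L] + side - 1L)] <- TRUE
  m
}

ellipse_mask <- function(a, b, dims = c(2L * a + 11L, 2L * a + 11L)) {
  ctr <- (dims + 1) / 2
  rr <- outer((seq_len(dims[1L]) - ctr[1L])^2 / a^2, rep(1, dims[2L]))
  cc <- outer(rep(1, dims[1L]), (seq_len(dims[2L]) - ctr[2L])^2 / b^2)
  rr + cc <= 1
}

# ---- independent oracles --------------------------------------------------

# exhaustive minimum-cost assignment of size min(n, m)
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) {
    res <- brute_force_assignment(t(cost))
    return(list(cost = res$cost))
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    cols <- p[seq_len(n)]
    tot <- sum(cost[cbind(seq_len(n), cols)])
    if (tot < best) best <- tot
  }
  list(cost = best)
}

# independent average-precision computation: explicit per-rank PR points and
# direct envelope integration, with its own greedy matcher
brute_force_ap <- function(pred, truth, iou_threshold) {
  recs <- list()
  for (i in seq_along(pred)) {
    p <- pred[[i]]
    for (k in seq_along(p$masks))
      recs[[length(recs) + 1L]] <- list(img = i, k = k, score = p$scores[k],
                                        area = sum(p$masks[[k]]))
  }
  npos <- sum(vapply(truth, function(t) length(t$masks), 0L))
  if (!length(recs) || npos == 0L) return(0)
  ord <- order(-vapply(recs, `[[`, 0, "score"),
               -vapply(recs, `[[`, 0, "area"),
               vapply(recs, `[[`, 0, "img"),
               vapply(recs, `[[`, 0, "k"))
  recs <- recs[ord]
  used <- lapply(truth, function(t) rep(FALSE, length(t$masks)))
  tp <- logical(length(recs))
  for (r in seq_along(recs)) {
    i <- recs[[r]]$img
    m <- pred[[i]]$masks[[recs[[r]]$k]]
    ious <- vapply(seq_along(truth[[i]]$masks), function(j) {
      if (used[[i]][j]) return(-1)
      inter <- sum(m & truth[[i]]$masks[[j]])
      uni <- sum(m | truth[[i]]$masks[[j]])
      if (uni == 0) 0 else inter / uni
    }, 0)
    if (length(ious) && max(ious) >= iou_threshold) {
      j <- which.max(ious)
      used[[i]][j] <- TRUE
      tp[r] <- TRUE
    }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / npos
  # integrate the envelope over every rank position
  ap <- 0; r_prev <- 0
  for (r in seq_along(tp)) {
    p_env <- max(prec[r:length(prec)])
    ap <- ap + (rec[r] - r_prev) * p_env
    r_prev <- rec[r]
  }
  ap
}

# ---- memoized expensive fixtures ------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# one default-sized synthetic field with vesicles
fx_field <- function(seed = 3L) {
  fixture(paste0("field", seed), function()
    render_field(synthetic_spec(seed = seed), sprintf("fx%d", seed)))
}

# small field (few cells) for cheap vesicle/segmentation tests
fx_small_field <- function(seed = 11L, vesicle_rate = 1) {
  fixture(sprintf("small%d_%g", seed, vesicle_rate), function() {
    spec <- synthetic_spec(
      dims = c(320L, 320L),
      cells_per_class = c(discocyte = 2L, echinocyte = 1L,
                          stomatocyte = 0L, sickle = 0L),
      vesicle_rate = vesicle_rate, seed = seed)
    render_field(spec, sprintf("small%d", seed))
  })
}

# 150-cell labeled feature table over 5 fields (shared by classify and
# acceptance tests)
fx_table150 <- function() {
  fixture("table150", function() {
    tabs <- list(); labs <- list()
    for (i in 1:5) {
      f <- render_field(synthetic_spec(seed = 100L + i), sprintf("f%03d", i))
      tabs[[i]] <- extract_features(f$brightfield, f$fluorescent, f$instances)
      labs[[i]] <- f$labels
    }
    features <- do.call(rbind, tabs)
    rownames(features) <- NULL
    list(features = features, labels = do.call(rbind, labs))
  })
}

# memoized automl run on planted-threshold data (shared by classify tests
# and the acceptance suite)
fx_planted_run <- function() {
  fixture("planted_run", function() {
    df <- fx_planted(n = 200L, seed = 1L)
    train <- df[1:120, ]; test <- df[121:200, ]
    part <- make_partition(train, "random_stratified", k = 5, seed = 0)
    res <- automl(train, part, trials_per_family = 6L, seed = 0)
    list(train = train, test = test, res = res)
  })
}

# planted-threshold tabular data: one informative feature among noise
fx_planted <- function(n = 200L, p_noise = 20L, seed = 0L) {
  set.seed(seed)
  y <- rep(c("pos", "neg"), length.out = n)
  x <- matrix(rnorm(n * (p_noise + 1L)), n, p_noise + 1L)
  x[, 1L] <- ifelse(y == "pos", 1, -1) + rnorm(n, 0, 0.25)
  colnames(x) <- c("planted", paste0("noise_", seq_len(p_noise)))
  df <- data.frame(cell_id = paste0("c", seq_len(n)),
                   image_id = paste0("img", rep(1:10, length.out = n)),
                   label = y, stringsAsFactors = FALSE)
  cbind(df, as.data.frame(x))
}
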