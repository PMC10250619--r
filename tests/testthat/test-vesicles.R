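test_that("strict L1 balls have 2r^2 - 2r + 1 interior pixels and clip", {
  dims <- c(50L, 50L)
  expect_equal(nrow(l1_ball(c(25, 25), 1, dims)), 1L)      # just the center
  expect_equal(nrow(l1_ball(c(25, 25), 4, dims)), 25L)     # 2*16 - 8 + 1
  expect_equal(nrow(l1_ball(c(25, 25), 8, dims)), 113L)
  # corner center keeps only the in-bounds quadrant
  corner <- l1_ball(c(1, 1), 4, dims)
  expect_true(all(corner >= 1))
  expect_lt(nrow(corner), 25L)
  # direct definition check
  ball <- l1_ball(c(25, 30), 4, dims)
  expect_true(all(abs(ball[, 1] - 25) + abs(ball[, 2] - 30) < 4))
})

test_that("median filter removes single-pixel spikes; plateaus collapse", {
  px <- matrix(0, 40, 40)
  px[20, 20] <- 500                       # one-pixel spike
  img <- image_grid(px, "fluorescent")
  expect_equal(nrow(local_maxima(img)$points), 0L)

  # constant image: no strict excess over the minimum, no candidates
  expect_equal(nrow(local_maxima(image_grid(matrix(7, 30, 30),
                                            "fluorescent"))$points), 0L)
})

test_that("two separated bright blocks give exactly their two centers", {
  px <- matrix(0, 60, 60)
  px[14:16, 14:16] <- 100
  px[44:46, 44:46] <- 100                 # centers 30 * sqrt(2) > d apart
  img <- image_grid(px, "fluorescent")
  pts <- local_maxima(img)$points
  expect_equal(nrow(pts), 2L)
  expect_true(any(pts[, 1] == 15 & pts[, 2] == 15))
  expect_true(any(pts[, 1] == 45 & pts[, 2] == 45))
})

test_that("ball/annulus contrast test follows the t-threshold arithmetic", {
  dims <- c(40L, 40L)
  px <- matrix(0, dims[1L], dims[2L])
  ball <- l1_ball(c(20, 20), 4, dims)
  px[ball] <- 100
  img <- image_grid(px, "fluorescent")
  expect_true(vesicle_test(img, c(20, 20))$is_vesicle)    # 99 > 0

  expect_false(vesicle_test(image_grid(matrix(50, 40, 40), "fluorescent"),
                            c(20, 20))$is_vesicle)        # constant fails

  # inner mean 10, annulus mean 9.5, t = 1: 9 > 9.5 is false
  px2 <- matrix(0, dims[1L], dims[2L])
  px2[l1_ball(c(20, 20), 8, dims)] <- 9.5
  px2[ball] <- 10
  expect_false(vesicle_test(image_grid(px2, "fluorescent"),
                            c(20, 20))$is_vesicle)
})

test_that("detection assigns planted spots to owning cells", {
  f <- fx_small_field()
  vs <- detect_vesicles(f$fluorescent, f$instances)
  truth_counts <- table(factor(f$vesicles$owner_ids,
                               levels = f$instances$cell_ids))
  expect_equal(as.integer(vs$counts), as.integer(truth_counts))
  # every assigned center lies inside its cell's mask
  for (i in seq_len(nrow(vs$centers))) {
    cid <- vs$centers$cell_id[i]
    if (is.na(cid)) next
    k <- match(cid, f$instances$cell_ids)
    expect_true(f$instances$masks[[k]][vs$centers$row[i], vs$centers$col[i]])
  }
})

test_that("constant fluorescence gives zero counts everywhere", {
  f <- fx_small_field()
  flat <- image_grid(matrix(30, nrow(f$fluorescent$pixels),
                            ncol(f$fluorescent$pixels)), "fluorescent")
  vs <- detect_vesicles(flat, f$instances)
  expect_true(all(vs$counts == 0L))
})

test_that("a spot outside all masks is kept as unassigned", {
  dims <- c(120L, 160L)
  px <- matrix(0, dims[1L], dims[2L])
  px[l1_ball(c(30, 120), 3, dims)] <- 150   # bright spot in background
  mask <- disc_mask(20, dims = dims, center = c(70, 50))
  px[mask] <- 40
  inst <- instance_set("f", list(mask))
  vs <- detect_vesicles(image_grid(px, "fluorescent"), inst)
  expect_equal(as.integer(vs$counts), 0L)
  expect_equal(sum(is.na(vs$centers$cell_id)), 1L)
})

test_that("erasure zeroes exactly the L1 ball and is idempotent", {
  f <- fx_small_field()
  vs <- detect_vesicles(f$fluorescent, f$instances)
  erased <- erase_vesicles(f$fluorescent, vs)
  v <- vs$params$v
  ball_px <- unique(do.call(rbind, lapply(seq_len(nrow(vs$centers)),
    function(i) l1_ball(c(vs$centers$row[i], vs$centers$col[i]), v,
                        dim(f$fluorescent$pixels)))))
  expect_true(all(erased$pixels[ball_px] == 0))
  changed <- which(erased$pixels != f$fluorescent$pixels)
  expect_true(all(changed %in% (ball_px[, 1] + (ball_px[, 2] - 1) *
                                  nrow(erased$pixels))))
  twice <- erase_vesicles(erased, vs)
  expect_identical(twice$pixels, erased$pixels)
})

test_that("erase-then-detect on a vesicle-free image is the identity", {
  f <- fx_small_field(seed = 13L, vesicle_rate = 0)
  expect_equal(nrow(f$vesicles$points), 0L)
  vs <- detect_vesicles(f$fluorescent, f$instances)
  expect_equal(nrow(vs$centers), 0L)
  out <- erase_vesicles(f$fluorescent, vs)
  expect_identical(out$pixels, f$fluorescent$pixels)
})

test_that("detection is translation-equivariant away from borders", {
  f <- fx_small_field()
  dr <- 6L; dc <- 9L
  # embed shifted content in a larger canvas so nothing is clipped
  embed <- function(m, fill = 0) {
    out <- matrix(fill, nrow(m) + dr, ncol(m) + dc)
    out[(1 + dr):(nrow(m) + dr), (1 + dc):(ncol(m) + dc)] <- m
    out
  }
  fl2 <- image_grid(embed(f$fluorescent$pixels), "fluorescent")
  inst2 <- instance_set(f$instances$image_id,
                        lapply(f$instances$masks, embed, fill = FALSE))
  a <- detect_vesicles(f$fluorescent, f$instances)$centers
  b <- detect_vesicles(fl2, inst2)$centers
  expect_equal(nrow(b), nrow(a))
  ord_a <- order(a$row, a$col); ord_b <- order(b$row, b$col)
  expect_equal(b$row[ord_b], a$row[ord_a] + dr)
  expect_equal(b$col[ord_b], a$col[ord_a] + dc)
})

test_that("intensity scaling with fixed t never shrinks the detected set", {
  f <- fx_small_field()
  base <- detect_vesicles(f$fluorescent, f$instances)$centers
  scaled <- detect_vesicles(image_grid(f$fluorescent$pixels * 3,
                                       "fluorescent"), f$instances)$centers
  key <- function(df) paste(df$row, df$col)
  expect_true(all(key(base) %in% key(scaled)))
})

test_that("point-detection scoring applies the 5-pixel criterion", {
  p <- point_set(rbind(c(10, 10), c(40, 40)))
  s <- score_detection(p, p)
  expect_equal(s$precision, 1); expect_equal(s$recall, 1)

  far <- score_detection(point_set(rbind(c(10, 10))),
                         point_set(rbind(c(10, 16))))   # distance 6
  expect_equal(far$precision, 0); expect_equal(far$recall, 0)

  two <- score_detection(point_set(rbind(c(10, 10), c(30, 30))),
                         point_set(rbind(c(12, 10))))   # one within 5 px
  expect_equal(two$precision, 0.5); expect_equal(two$recall, 1)

  none <- score_detection(point_set(), point_set(rbind(c(1, 1))))
  expect_equal(none$precision, 1); expect_equal(none$recall, 0)
})

test_that("vesicle parameter bounds are enforced", {
  expect_error(vesicle_params(m = 2), "odd")
  expect_error(vesicle_params(c = 4, v = 4), "exceed")
  expect_error(vesicle_params(t = -1), ">= 0")
})
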