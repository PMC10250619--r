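test_that("rendering is bit-identical under a fixed seed", {
  a <- fx_small_field()
  b <- render_field(synthetic_spec(
    dims = c(320L, 320L),
    cells_per_class = c(discocyte = 2L, echinocyte = 1L,
                        stomatocyte = 0L, sickle = 0L),
    vesicle_rate = 1, seed = 11L), "small11")
  expect_identical(a$brightfield$pixels, b$brightfield$pixels)
  expect_identical(a$fluorescent$pixels, b$fluorescent$pixels)
  expect_identical(a$vesicles$points, b$vesicles$points)
  # distinct seeds give distinct layouts
  c_ <- fx_small_field(seed = 13L, vesicle_rate = 0)
  expect_false(identical(a$brightfield$pixels, c_$brightfield$pixels))
})

test_that("requested class counts come back as labeled truth masks", {
  f <- fx_field()
  expect_equal(length(f$instances$masks), 30L)
  counts <- table(factor(f$labels$label,
                         levels = c("discocyte", "echinocyte",
                                    "stomatocyte", "sickle")))
  expect_equal(as.integer(counts), c(12L, 6L, 6L, 6L))
  expect_equal(f$labels$cell_id, f$instances$cell_ids)
})

test_that("truth masks never overlap and vesicles sit inside their cells", {
  f <- fx_field()
  overlap <- Reduce(`+`, lapply(f$instances$masks, function(m) m * 1L))
  expect_lte(max(overlap), 1L)
  for (i in seq_len(nrow(f$vesicles$points))) {
    k <- match(f$vesicles$owner_ids[i], f$instances$cell_ids)
    expect_true(f$instances$masks[[k]][f$vesicles$points[i, 1],
                                       f$vesicles$points[i, 2]])
  }
  # planted spots are pairwise separated by at least 2c = 16 px
  if (nrow(f$vesicles$points) > 1) {
    d <- dist(f$vesicles$points)
    expect_gte(min(d), 16)
  }
})

test_that("fluorescent background is exactly zero outside cells", {
  f <- fx_field()
  any_mask <- Reduce(`|`, f$instances$masks)
  expect_true(all(f$fluorescent$pixels[!any_mask] == 0))
  expect_true(all(f$fluorescent$pixels[any_mask] > 0))
})

test_that("class-conditional shape structure holds in the generator", {
  f <- fx_field()
  sf <- t(vapply(f$instances$masks, shape_features, numeric(14)))
  cls <- f$labels$label
  ecc <- sf[, "shape_eccentricity"]
  sol <- sf[, "shape_solidity"]
  expect_gt(mean(ecc[cls == "sickle"]), mean(ecc[cls == "discocyte"]))
  expect_lt(mean(sol[cls == "echinocyte"]), mean(sol[cls == "discocyte"]))
})

test_that("benchmark rendering writes the full input layout", {
  dir <- file.path(tempdir(), "bench-test")
  spec <- synthetic_spec(dims = c(320L, 320L),
                         cells_per_class = c(discocyte = 2L, echinocyte = 1L,
                                             stomatocyte = 0L, sickle = 0L))
  manifest <- render_benchmark(2L, spec, dir = dir, seed = 4L)
  expect_equal(nrow(manifest), 6L)          # 3 cells x 2 fields
  expect_true(file.exists(file.path(dir, "images", "field_001_bf.tif")))
  expect_true(file.exists(file.path(dir, "images", "field_002_fl.tif")))
  expect_true(file.exists(file.path(dir, "masks", "field_001.tif")))
  expect_true(file.exists(file.path(dir, "vesicles.csv")))
  expect_true(file.exists(file.path(dir, "labels.csv")))
  # label maps round trip to the rendered masks
  back <- load_labelmap(file.path(dir, "masks", "field_001.tif"), "field_001")
  expect_equal(length(back$masks), 3L)
  unlink(dir, recursive = TRUE)
})
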