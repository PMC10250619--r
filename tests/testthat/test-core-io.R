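test_that("image grids validate their invariants", {
  expect_error(image_grid(matrix(-1, 2, 2)), "non-negative")
  expect_error(image_grid(matrix(NaN, 2, 2)), "finite")
  g <- image_grid(matrix(0:5, 2, 3), "fluorescent")
  expect_equal(g$height, 2L)
  expect_equal(g$width, 3L)
  expect_equal(g$channel, "fluorescent")
})

test_that("TIFF round trip preserves 16-bit integer grids exactly", {
  x <- matrix(c(0, 300, 65535, 12, 77, 1024), 2, 3)
  path <- tempfile(fileext = ".tif")
  save_image(image_grid(x), path)
  back <- load_image(path, "brightfield")
  expect_identical(back$pixels, x)
})

test_that("PNG round trip preserves 8-bit grids and scales to native range", {
  x <- matrix(c(0, 17, 255, 128), 2, 2)
  path <- tempfile(fileext = ".png")
  save_image(image_grid(x), path)
  back <- load_image(path, "brightfield")
  expect_equal(back$pixels, x)
})

test_that("RGB collapses with BT.709 luma weights; gray input is unchanged", {
  # equal channels give the channel value; pure red gives 0.2125 * 255
  arr <- array(0, c(1, 2, 3))
  arr[1, 1, ] <- c(100, 100, 100)
  arr[1, 2, ] <- c(255, 0, 0)
  g <- rbcprofiler:::grid_from_array(arr)
  expect_equal(g[1, 1], 100)
  expect_equal(g[1, 2], 0.2125 * 255, tolerance = 1e-12)
  # idempotence on already-gray input
  expect_identical(rbcprofiler:::grid_from_array(g), g)
})

test_that("unreadable files and excess dimensions raise clear errors", {
  expect_error(load_image("no/such/file.tif"), "no such file")
  arr4 <- array(0, c(2, 2, 2, 2))
  expect_error(rbcprofiler:::grid_from_array(arr4), "spatial dimensions")
})

test_that("instance sets enforce mask and id invariants", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  expect_error(instance_set("i", list(matrix(FALSE, 4, 4))), "foreground")
  expect_error(instance_set("i", list(m), scores = 2), "\\[0, 1\\]")
  inst <- instance_set("img7", list(m, m))
  expect_equal(inst$cell_ids, c("img7_1", "img7_2"))
  expect_error(instance_set("i", list(m, m), cell_ids = c("a", "a")),
               "unique")
})

test_that("label maps round trip through disk for non-overlapping sets", {
  m1 <- matrix(FALSE, 8, 8); m1[2:3, 2:3] <- TRUE
  m2 <- matrix(FALSE, 8, 8); m2[6:7, 5:8] <- TRUE
  inst <- instance_set("f", list(m1, m2))
  path <- tempfile(fileext = ".tif")
  save_labelmap(inst, path)
  back <- load_labelmap(path, image_id = "f")
  expect_equal(length(back$masks), 2L)
  expect_identical(back$masks[[1]], m1)
  expect_identical(back$masks[[2]], m2)
  # overlapping masks cannot be written as a label map
  expect_error(instances_to_labelmap(instance_set("f", list(m1, m1))),
               "overlap")
})

test_that("overlay recolors outlines and draws vesicle boxes of side 2v+1", {
  px <- matrix(50, 20, 20)
  img <- image_grid(px)
  empty <- instance_set("f", list(), scores = numeric(0))
  ov <- overlay(img, empty)
  expect_equal(dim(ov), c(20L, 20L, 3L))
  expect_true(all(ov[, , 1] == ov[, , 2]))   # pure grayscale, no marks

  m <- disc_mask(5, dims = c(20L, 20L), center = c(10, 10))
  ov2 <- overlay(img, instance_set("f", list(m)))
  expect_gt(sum(ov2[, , 1] != ov2[, , 2]), 0)  # outline recolored

  box <- rbcprofiler:::box_outline_pixels(c(10, 10), 4, c(20L, 20L))
  # hollow square of side 9 has 4 * 9 - 4 = 32 pixels
  expect_equal(nrow(box), 32L)
})
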