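test_that("normalization rescales to [0, 255] with the degenerate-case rule", {
  g <- image_grid(matrix(c(10, 20, 30, 10), 2, 2))
  n <- normalize_image(g)
  expect_equal(sort(unique(as.numeric(n$pixels))), c(0, 127.5, 255))
  flat <- normalize_image(image_grid(matrix(42, 3, 3)))
  expect_true(all(flat$pixels == 0))
  already <- image_grid(matrix(seq(0, 255, length.out = 16), 4, 4))
  expect_equal(normalize_image(already)$pixels, already$pixels)
})

test_that("the catalog has 135 names with fluorescence and 74 without", {
  expect_length(feature_catalog(TRUE), 135L)
  expect_length(feature_catalog(FALSE), 74L)
  expect_equal(sum(startsWith(feature_catalog(TRUE), "shape_")), 14L)
  expect_equal(sum(grepl("^intensity_.*_bf$", feature_catalog(TRUE))), 18L)
  expect_equal(sum(grepl("^(glcm|gldm|glszm|glrlm)_.*_fl$",
                         feature_catalog(TRUE))), 42L)
  expect_true("ca2+_number_of_vesicles" %in% feature_catalog(TRUE))
  expect_false("ca2+_number_of_vesicles" %in% feature_catalog(FALSE))
})

test_that("extraction yields the exact catalog schema for both modes", {
  f <- fx_small_field()
  both <- extract_features(f$brightfield, f$fluorescent, f$instances)
  expect_equal(colnames(both), c("cell_id", "image_id", feature_catalog(TRUE)))
  expect_equal(nrow(both), length(f$instances$masks))
  bf <- extract_features(f$brightfield, NULL, f$instances)
  expect_equal(colnames(bf), c("cell_id", "image_id", feature_catalog(FALSE)))
})

test_that("zero instances give an empty table with the full header", {
  f <- fx_small_field()
  empty <- instance_set("e", list(), scores = numeric(0))
  tab <- extract_features(f$brightfield, f$fluorescent, empty)
  expect_equal(nrow(tab), 0L)
  expect_equal(colnames(tab), c("cell_id", "image_id", feature_catalog(TRUE)))
})

test_that("vesicle counts land in the ca2+ column", {
  f <- fx_small_field()
  tab <- extract_features(f$brightfield, f$fluorescent, f$instances)
  truth <- as.integer(table(factor(f$vesicles$owner_ids,
                                   levels = f$instances$cell_ids)))
  expect_equal(tab[["ca2+_number_of_vesicles"]], truth)
})

test_that("planted vesicles change only fluorescent-channel features", {
  # same brightfield and masks; fluorescent with and without one planted spot
  dims <- c(140L, 140L)
  mask <- disc_mask(36L, dims = dims, center = c(70, 70))
  set.seed(5)
  bf_px <- matrix(200, dims[1L], dims[2L]); bf_px[mask] <- 120
  bf_px <- bf_px + matrix(rnorm(prod(dims), 0, 3), dims[1L])
  bf <- set_image_id(image_grid(pmax(bf_px, 0), "brightfield"), "inv")
  dm <- as.matrix(EBImage::distmap(mask))
  base <- matrix(0, dims[1L], dims[2L])
  base[mask] <- 60 - 3.2 * (1 - pmin(dm[mask], 16) / 16) +
    rnorm(sum(mask), 0, 0.5)
  fl_clean <- image_grid(base, "fluorescent")
  spot <- base
  ball <- l1_ball(c(70, 70), 3, dims)
  spot[ball] <- spot[ball] + 120
  fl_spot <- image_grid(spot, "fluorescent")
  inst <- instance_set("inv", list(mask))

  a <- extract_features(bf, fl_clean, inst)
  b <- extract_features(bf, fl_spot, inst)
  expect_equal(b[["ca2+_number_of_vesicles"]], 1L)
  expect_equal(a[["ca2+_number_of_vesicles"]], 0L)
  bf_cols <- c(rbcprofiler:::shape_feature_names(),
               paste0(c(rbcprofiler:::intensity_feature_names(),
                        rbcprofiler:::texture_feature_names()), "_bf"))
  expect_identical(a[, bf_cols], b[, bf_cols])
})

test_that("cells touching the border are kept unless drop_border is set", {
  dims <- c(60L, 60L)
  border_mask <- matrix(FALSE, dims[1L], dims[2L])
  border_mask[1:12, 10:22] <- TRUE              # touches row 1
  inner_mask <- disc_mask(8L, dims = dims, center = c(40, 40))
  bf <- set_image_id(image_grid(matrix(100, dims[1L], dims[2L]),
                                "brightfield"), "b")
  inst <- instance_set("b", list(border_mask, inner_mask))
  keep_all <- extract_features(bf, NULL, inst)
  expect_equal(nrow(keep_all), 2L)
  dropped <- extract_features(bf, NULL, inst, drop_border = TRUE)
  expect_equal(nrow(dropped), 1L)
  expect_equal(dropped$cell_id, "b_2")
})

test_that("per-cell failures become NA rows, not errors", {
  # a cell whose fluorescent pixels are all zero: fluorescent features NA,
  # brightfield features still present
  dims <- c(100L, 100L)
  mask <- disc_mask(30L, dims = dims, center = c(50, 50))
  bf <- set_image_id(image_grid(matrix(150, dims[1L], dims[2L]),
                                "brightfield"), "z")
  fl <- image_grid(matrix(0, dims[1L], dims[2L]), "fluorescent")
  tab <- extract_features(bf, fl, instance_set("z", list(mask)))
  expect_equal(nrow(tab), 1L)
  expect_true(is.na(tab[["intensity_mean_fl"]]))
  expect_false(is.na(tab[["shape_pixel_surface"]]))
  expect_false(is.na(tab[["intensity_mean_bf"]]))
})

test_that("feature tables round trip through CSV", {
  f <- fx_small_field()
  tab <- extract_features(f$brightfield, f$fluorescent, f$instances)
  path <- tempfile(fileext = ".csv")
  save_feature_table(tab, path)
  back <- load_feature_table(path)
  expect_equal(colnames(back), colnames(tab))
  expect_equal(back[["shape_pixel_surface"]], tab[["shape_pixel_surface"]])
  expect_equal(back[["glcm_contrast_fl"]], tab[["glcm_contrast_fl"]],
               tolerance = 1e-9)
})
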