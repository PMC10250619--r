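# level matrix with NA outside the region, as the internal routines expect
lev_of <- function(img, mask, bin_width = 25) {
  lev <- rbcprofiler:::discretize_intensities(img, bin_width)
  lev[!mask] <- NA_integer_
  lev
}

test_that("horizontal GLCM of a two-level checkerboard has contrast 1", {
  img <- matrix(c(0, 25), 4, 4)            # alternating rows of levels 1, 2
  img <- img * 0 + outer(1:4, 1:4, function(r, c) ((r + c) %% 2) * 25)
  lev <- lev_of(img, matrix(TRUE, 4, 4))
  # 12 horizontal ordered pairs, all (1,2) or (2,1): contrast = 1, by hand
  m <- rbcprofiler:::glcm_matrix(lev, c(0L, 1L), 2L)
  expect_equal(sum(m), 24)                 # symmetric: 12 pairs counted twice
  expect_equal(m[1, 1], 0); expect_equal(m[2, 2], 0)
  stats <- rbcprofiler:::glcm_stats(m)
  expect_equal(stats[1], 1.0)              # contrast
  expect_equal(stats[13], 0.5)             # joint energy: 2 * 0.5^2
})

test_that("single-level regions take their analytic limits", {
  img <- matrix(10, 6, 6)
  f <- texture_features(img, matrix(TRUE, 6, 6))
  expect_equal(f[["glcm_contrast"]], 0)
  expect_equal(f[["glcm_joint_energy"]], 1)
  expect_true(is.na(f[["glcm_correlation"]]))
  expect_true(is.na(f[["glcm_imc1"]]))
  expect_true(is.na(f[["glcm_mcc"]]))
  expect_equal(f[["glszm_size_zone_non_uniformity"]], 1)  # one zone
  expect_equal(f[["glrlm_low_gray_level_run_emphasis"]], 1)  # level 1 only
  expect_length(f, 42L)
  expect_named(f, rbcprofiler:::texture_feature_names())
})

test_that("GLCM accumulation matches a brute-force pair enumeration", {
  set.seed(4)
  img <- matrix(sample(0:250, 49, replace = TRUE), 7, 7)
  mask <- matrix(TRUE, 7, 7); mask[1, 1] <- FALSE; mask[4, 5] <- FALSE
  lev <- lev_of(img, mask)
  nlev <- max(lev, na.rm = TRUE)
  for (off in list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))) {
    want <- matrix(0, nlev, nlev)
    for (r in 1:7) for (c in 1:7) {
      r2 <- r + off[1L]; c2 <- c + off[2L]
      if (r2 < 1 || r2 > 7 || c2 < 1 || c2 > 7) next
      if (is.na(lev[r, c]) || is.na(lev[r2, c2])) next
      want[lev[r, c], lev[r2, c2]] <- want[lev[r, c], lev[r2, c2]] + 1
      want[lev[r2, c2], lev[r, c]] <- want[lev[r2, c2], lev[r, c]] + 1
    }
    got <- rbcprofiler:::glcm_matrix(lev, off, nlev)
    expect_equal(unname(got), unname(want))
  }
})

test_that("GLSZM zones are 8-connected equal-level components", {
  # two diagonal pixels of one level form a single 8-connected zone
  img <- matrix(0, 4, 4)
  img[1, 1] <- 30; img[2, 2] <- 30
  lev <- lev_of(img, matrix(TRUE, 4, 4))
  z <- rbcprofiler:::glszm_zones_ff(lev)
  z <- z[order(z[, 1], z[, 2]), , drop = FALSE]
  # level-1 background: one zone of 14; level-2: one zone of 2
  expect_equal(nrow(z), 2L)
  expect_equal(z[1, ], c(1, 14))
  expect_equal(z[2, ], c(2, 2))
})

test_that("GLRLM runs match a manual run-length count", {
  img <- matrix(0, 3, 4)
  img[1, ] <- c(0, 0, 30, 30)      # levels 1 1 2 2
  img[2, ] <- c(30, 30, 30, 0)     # levels 2 2 2 1
  img[3, ] <- c(0, 25, 0, 25)      # levels 1 2 1 2
  lev <- lev_of(img, matrix(TRUE, 3, 4))
  runs <- rbcprofiler:::glrlm_runs(lev, c(0L, 1L))
  # horizontal runs: (1,2)(2,2) / (2,3)(1,1) / (1,1)(2,1)(1,1)(2,1)
  runs <- runs[order(runs[, 1], runs[, 2]), ]
  want <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 2), c(2, 1), c(2, 1),
                c(2, 2), c(2, 3))
  expect_equal(unname(runs), want)
})

test_that("masked-out pixels break runs and never contribute", {
  img <- matrix(50, 1, 5)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE), 1, 5)
  runs <- rbcprofiler:::glrlm_runs(lev_of(img, mask), c(0L, 1L))
  expect_equal(unname(runs), rbind(c(3, 2), c(3, 2)))
})

test_that("texture features require at least two in-region pixels", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  expect_error(texture_features(matrix(1, 4, 4), m), ">= 2")
})

test_that("GLDM dependence counts follow the 8-neighbourhood rule", {
  # uniform 3x3 block: center has 8 equal neighbours (dependence 9), edge
  # centers 5 (dependence 6), corners 3 (dependence 4)
  img <- matrix(40, 3, 3)
  f <- rbcprofiler:::gldm_features(lev_of(img, matrix(TRUE, 3, 3)))
  # dependence variance of sizes {9, 6,6,6,6, 4,4,4,4}: mean 49/9
  sizes <- c(9, rep(6, 4), rep(4, 4))
  expect_equal(f[["gldm_dependence_variance"]],
               mean((sizes - mean(sizes))^2))
  expect_equal(f[["gldm_gray_level_non_uniformity"]], 9)  # single level: N^2/N
})
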