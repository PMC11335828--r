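test_that("sRGB white, black, and grays convert to achromatic CIELAB", {
  w <- srgb_to_lab(c(255, 255, 255))
  expect_equal(w$L, 100, tolerance = 1e-3)
  expect_lt(abs(w$a), 0.01)
  expect_lt(abs(w$b), 0.01)
  expect_equal(as.numeric(srgb_to_lab(c(0, 0, 0))), c(0, 0, 0), tolerance = 1e-6)
  g <- srgb_to_lab(c(128, 128, 128))
  expect_lt(abs(g$a), 0.01)
  expect_lt(abs(g$b), 0.01)
})

test_that("conversion agrees with the grDevices reference implementation", {
  set.seed(20)
  rgb <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  mine <- as.matrix(srgb_to_lab(rgb))
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  # small differences stem from the reference's higher-precision primaries
  expect_equal(unname(mine), unname(ref), tolerance = 0.01)
  expect_error(srgb_to_lab(c(-1, 0, 0)), "0, 255")
  expect_error(srgb_to_lab(c(0, 0, 300)), "0, 255")
})

test_that("region_mean averages masked pixels in CIELAB space", {
  # uniform image: any mask returns that pixel's Lab exactly
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 0.2
  img[, , 2] <- 0.5
  img[, , 3] <- 0.7
  mask <- matrix(TRUE, 4, 4)
  expect_equal(
    as.numeric(region_mean(img, mask)),
    as.numeric(srgb_to_lab(255 * c(0.2, 0.5, 0.7)))
  )

  # half white / half black: L* is the Lab-space mean (100 + 0) / 2
  bw <- array(0, dim = c(2, 2, 3))
  bw[1, , ] <- 1
  expect_equal(region_mean(bw, matrix(TRUE, 2, 2))$L, 50, tolerance = 1e-6)

  # single-pixel mask equals the pixel conversion (row 1 is the white row)
  one <- matrix(FALSE, 2, 2)
  one[1, 2] <- TRUE
  expect_equal(
    as.numeric(region_mean(bw, one)),
    as.numeric(srgb_to_lab(c(255, 255, 255)))
  )

  expect_error(region_mean(bw, matrix(FALSE, 2, 2)), "Empty mask")
  expect_error(region_mean(bw, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("region_mean matches a brute-force per-pixel loop", {
  set.seed(21)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  mask <- matrix(runif(64) > 0.4, 8, 8)
  got <- region_mean(img, mask)
  acc <- c(0, 0, 0)
  n <- 0
  for (i in 1:8) {
    for (j in 1:8) {
      if (mask[i, j]) {
        acc <- acc + as.numeric(srgb_to_lab(255 * img[i, j, ]))
        n <- n + 1
      }
    }
  }
  expect_equal(as.numeric(got), acc / n, tolerance = 1e-9)
})

test_that("measure_regions emits the wide region_channel format", {
  img <- array(0.5, dim = c(4, 4, 3))
  masks <- list(cheek = matrix(TRUE, 4, 4), forehead = matrix(TRUE, 4, 4))
  row <- measure_regions(img, masks, specimen_id = "f1")
  expect_named(row, c(
    "specimen_id",
    "cheek_L", "cheek_a", "cheek_b",
    "forehead_L", "forehead_a", "forehead_b"
  ))
  expect_equal(row$cheek_L, row$forehead_L)
})

test_that("mean skin color averages exactly the five skin areas", {
  regions <- c("eye_skin", "brow_skin", "lips_skin", "cheek", "forehead")
  data <- tibble::tibble(specimen_id = "s1")
  for (r in regions) {
    data[[paste0(r, "_L")]] <- 60
    data[[paste0(r, "_a")]] <- 10
    data[[paste0(r, "_b")]] <- 15
  }
  out <- mean_skin_color(data)
  expect_equal(c(out$skin_L, out$skin_a, out$skin_b), c(60, 10, 15))

  data2 <- data
  Ls <- c(50, 55, 60, 65, 70)
  for (i in seq_along(regions)) data2[[paste0(regions[i], "_L")]] <- Ls[i]
  expect_equal(mean_skin_color(data2)$skin_L, 60)

  # permutation-invariance over the five areas
  data3 <- data2
  for (i in seq_along(regions)) data3[[paste0(regions[i], "_L")]] <- rev(Ls)[i]
  expect_equal(mean_skin_color(data3)$skin_L, mean_skin_color(data2)$skin_L)

  expect_error(
    mean_skin_color(data[setdiff(names(data), "forehead_L")]),
    "forehead_L"
  )
})

test_that("Michelson contrast has the documented sign and zero semantics", {
  expect_equal(michelson_contrast(40, 40), 0) # no contrast
  expect_equal(michelson_contrast(20, 60), 0.5) # feature darker
  expect_equal(michelson_contrast(60, 20), -0.5) # feature lighter
  expect_warning(out <- michelson_contrast(5, -5), "Zero denominator")
  expect_true(is.na(out))
})

test_that("contrast is antisymmetric and bounded for non-negative operands", {
  grid <- expand.grid(f = seq(0, 100, by = 10), s = seq(0, 100, by = 10))
  grid <- grid[grid$f + grid$s > 0, ]
  c_fs <- michelson_contrast(grid$f, grid$s)
  c_sf <- michelson_contrast(grid$s, grid$f)
  expect_equal(c_fs, -c_sf)
  expect_true(all(abs(c_fs) <= 1))
  at_bound <- abs(c_fs) == 1
  expect_true(all((grid$f == 0 | grid$s == 0) == at_bound))
})

test_that("contrast_profile computes per-feature contrasts and flags gaps", {
  data <- tibble::tibble(
    specimen_id = c("s1", "s2"), sex = c("F", "M"),
    eye_feature_L = c(20, 30), eye_skin_L = c(60, 60),
    brow_feature_L = c(30, 30), brow_skin_L = c(30, 30),
    eye_feature_a = c(5, 5), eye_skin_a = c(15, 15)
  )
  prof <- contrast_profile(data)
  expect_equal(prof$contrast_eye_L, c(0.5, 1 / 3))
  expect_equal(prof$contrast_brow_L, c(0, 0)) # identical to its skin
  expect_equal(prof$contrast_eye_a, c(0.5, 0.5))
  expect_true(all(is.na(prof$contrast_lips_L))) # region absent -> missing
  expect_true(all(is.na(prof$contrast_brow_a)))
  expect_named(
    contrast_profile(data, channels = "L")[-(1:2)],
    c("contrast_eye_L", "contrast_brow_L", "contrast_lips_L")
  )
})
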