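test_that("the axis is the vector between sex-specific means", {
  data <- tibble::tibble(
    specimen_id = paste0("s", 1:4),
    sex = c("F", "F", "M", "M"),
    v1 = c(0, 0, 1, 1), v2 = c(0, 0, 0, 0)
  )
  ax <- build_axis(data)
  expect_equal(unname(ax$female_mean), c(0, 0))
  expect_equal(unname(ax$male_mean), c(1, 0))
  expect_equal(unname(ax$direction), c(1, 0))

  one <- tibble::tibble(
    sex = c("F", "F", "M", "M"), v = c(2, 4, 4, 6)
  )
  expect_equal(unname(build_axis(one)$direction), 2)

  same <- tibble::tibble(sex = c("F", "F", "M", "M"), v = c(1, 2, 1, 2))
  expect_error(build_axis(same), "Degenerate axis")
  expect_error(build_axis(data[c(1, 3, 4), ]), "at least two")
})

test_that("projection is the plain dot product with MM - FM", {
  data <- tibble::tibble(
    specimen_id = paste0("s", 1:4),
    sex = c("F", "F", "M", "M"),
    v1 = c(0, 0, 1, 1), v2 = c(-1, 1, -1, 1)
  )
  ax <- build_axis(data) # FM = (0,0), MM = (1,0)
  sc <- project_scores(data, ax)
  expect_equal(sc$score, c(0, 0, 1, 1))

  # orthogonal displacement leaves the score unchanged
  probe <- tibble::tibble(sex = c("F", "F", "M", "M"), v1 = 0, v2 = c(5, -5, 1, 2))
  expect_equal(project_scores(probe, ax)$score, rep(0, 4))

  # 1-D arithmetic: direction (2), x = 4 -> score 8
  ax1 <- build_axis(tibble::tibble(sex = c("F", "F", "M", "M"), v = c(2, 4, 4, 6)))
  expect_equal(
    project_scores(tibble::tibble(sex = c("F", "M"), v = c(4, 4)), ax1)$score,
    c(8, 8)
  )

  expect_error(project_scores(data[c("specimen_id", "sex", "v1")], ax), "1 feature")
})

test_that("normalized scoring divides by the axis norm", {
  data <- toy_features()
  ax <- build_axis(data)
  raw <- project_scores(data, ax)
  unit <- project_scores(data, ax, normalize_axis = TRUE)
  expect_equal(unit$score, raw$score / sqrt(sum(ax$direction^2)))
})

test_that("score algebra: sex difference of mean scores is ||MM - FM||^2", {
  set.seed(30)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    p <- sample(2:8, 1)
    data <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n, p)))
    data$sex <- sample(rep(c("F", "M"), c(3, n - 3)))
    ax <- build_axis(data)
    sc <- project_scores(data, ax)
    diff <- mean(sc$score[sc$sex == "M"]) - mean(sc$score[sc$sex == "F"])
    expect_equal(diff, sum(ax$direction^2), tolerance = 1e-9)

    # affine consistency: adding a constant vector c shifts all scores by <c, dir>
    shift <- rnorm(p)
    shifted <- data
    shifted[seq_len(p)] <- sweep(as.matrix(data[seq_len(p)]), 2, shift, `+`)
    sc2 <- project_scores(shifted, ax)
    expect_equal(sc2$score, sc$score + sum(shift * ax$direction), tolerance = 1e-9)
  }
})

test_that("mean_distance is the Euclidean norm of the mean difference", {
  tri <- tibble::tibble(
    sex = c("F", "F", "M", "M"),
    v1 = c(0, 0, 3, 3), v2 = c(0, 0, 4, 4)
  )
  expect_equal(mean_distance(tri), 5)
  expect_equal(
    mean_distance(tibble::tibble(sex = c("F", "F", "M", "M"), v = c(3, 3, 5, 5))), 2
  )
  # invariant to row order and column permutation
  set.seed(31)
  data <- toy_features()
  expect_equal(
    mean_distance(data[sample(nrow(data)), ]),
    mean_distance(data[c("specimen_id", "sex", "v2", "v1")])
  )
})

test_that("rows with missing values are excluded and logged", {
  data <- toy_features()
  data$v1[2] <- NA
  expect_message(ax <- build_axis(data), "Excluding 1 specimen.*s2")
  expect_equal(ax$n_female, 2)
})

test_that("the shape matrix is a pure reshape of the aligned coordinates", {
  spec <- population_spec(n_female = 3, n_male = 3, seed = 12)
  fit <- gpa(generate_landmarks(spec))
  mat <- assemble_sshd_matrix(fit)
  expect_equal(dim(mat), c(6, 3 + 144))
  expect_equal(
    names(mat)[4:9], c("x1", "y1", "x2", "y2", "x3", "y3") # documented order
  )
  id <- mat$specimen_id[1]
  expect_equal(as.numeric(mat[1, c("x5", "y5")]), unname(fit$coords[[id]][5, ]))
})

test_that("the color matrix has the documented default and reduced column sets", {
  spec <- population_spec(n_female = 5, n_male = 5, seed = 13)
  colors <- generate_colors(spec)
  full <- assemble_scod_matrix(colors)
  expect_equal(length(setdiff(names(full), c("specimen_id", "sex", "population"))), 15)
  lum <- assemble_scod_matrix(colors, channels = "L")
  expect_equal(
    setdiff(names(lum), c("specimen_id", "sex", "population")),
    c("cheek_L", "forehead_L", "contrast_eye_L", "contrast_brow_L", "contrast_lips_L")
  )

  # a specimen missing its lips measurement is excluded and reported
  broken <- colors
  broken$lips_feature_L[3] <- NA
  expect_message(
    out <- assemble_scod_matrix(broken),
    paste0("Excluding 1 specimen.*", broken$specimen_id[3])
  )
  expect_equal(attr(out, "excluded"), broken$specimen_id[3])
  expect_equal(nrow(out), 9)

  std <- assemble_scod_matrix(colors, standardize = TRUE)
  expect_equal(unname(colMeans(as.matrix(std[-(1:3)]))), rep(0, 15), tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(std[-(1:3)]), 2, sd)), rep(1, 15), tolerance = 1e-12)
})
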