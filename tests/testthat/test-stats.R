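test_that("Cohen's d matches hand arithmetic and is affine-invariant", {
  # M = {2,4}, F = {0,2}: pooled SD = sqrt(2), difference of means = 2
  expect_equal(
    cohens_d(c(0, 2, 2, 4), c("F", "F", "M", "M")), 2 / sqrt(2)
  )
  expect_equal(cohens_d(c(1, 3, 1, 3), c("F", "F", "M", "M")), 0)
  expect_error(cohens_d(c(0, 0, 1, 1), c("F", "F", "M", "M")), "pooled standard deviation")
  expect_error(cohens_d(c(0, 1, 2), c("F", "M", "M")), "at least two")

  set.seed(40)
  v <- rnorm(20)
  lab <- rep(c("F", "M"), 10)
  d0 <- cohens_d(v, lab)
  expect_equal(cohens_d(3 * v + 7, lab), d0, tolerance = 1e-12)
  expect_equal(cohens_d(-v, lab), -d0, tolerance = 1e-12)
})

test_that("one-way ANOVA agrees with a from-scratch sums-of-squares oracle", {
  m <- c(1, 2, 3)
  f <- c(3, 4, 5)
  out <- anova_oneway(c(f, m), c("F", "F", "F", "M", "M", "M"))

  # independent textbook computation from raw sums of squares
  vals <- c(f, m)
  grand <- mean(vals)
  ssb <- 3 * (mean(f) - grand)^2 + 3 * (mean(m) - grand)^2
  ssw <- sum((f - mean(f))^2) + sum((m - mean(m))^2)
  f_stat <- (ssb / 1) / (ssw / 4)
  expect_equal(out$statistic, f_stat, tolerance = 1e-12)
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 4)
  expect_equal(out$r_squared, ssb / (ssb + ssw), tolerance = 1e-12)
  expect_equal(out$p_value, pf(f_stat, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # identical group distributions: F = 0, R2 = 0
  null <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("F", "M"), each = 3))
  expect_equal(null$statistic, 0)
  expect_equal(null$r_squared, 0)
  expect_error(anova_oneway(rep(5, 6), rep(c("F", "M"), each = 3)), "variance")
})

test_that("two-group ANOVA satisfies the F = t^2 and F = d^2 n1 n2/(n1+n2) identities", {
  set.seed(41)
  for (i in 1:5) {
    n1 <- sample(4:12, 1)
    n2 <- sample(4:12, 1)
    v <- c(rnorm(n1), rnorm(n2, mean = 0.8))
    lab <- rep(c("F", "M"), c(n1, n2))
    out <- anova_oneway(v, lab)
    tt <- t.test(v[lab == "M"], v[lab == "F"], var.equal = TRUE)
    expect_equal(out$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    d <- cohens_d(v, lab)
    expect_equal(out$statistic, d^2 * n1 * n2 / (n1 + n2), tolerance = 1e-9)
  }
})

test_that("Pearson correlation matches the closed-form estimator", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)

  y <- c(2.0, 1.0, 4.5, 3.0, 6.0)
  out <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * pt(abs(t_hand), 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "Zero variance")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("ICC(3,k) equals the two-way mean-square oracle on a small fixture", {
  ratings <- rbind(
    c(2, 3, 4),
    c(4, 5, 6),
    c(1, 2, 2),
    c(6, 6, 7)
  )
  n <- 4
  k <- 3
  grand <- mean(ratings)
  ss_rows <- k * sum((rowMeans(ratings) - grand)^2)
  ss_cols <- n * sum((colMeans(ratings) - grand)^2)
  ss_err <- sum((ratings - grand)^2) - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  out <- icc_3k(ratings)
  expect_equal(out$icc_3k, (bms - ems) / bms, tolerance = 1e-9)
  expect_equal(out$k, 3)
  expect_equal(out$n, 4)
})

test_that("ICC(3,k) is 1 for perfect consistency and shift-invariant", {
  base <- c(1, 4, 2, 6, 3)
  perfect <- cbind(base, base, base)
  expect_equal(icc_3k(perfect)$icc_3k, 1)
  # per-rater additive leniency does not change a consistency ICC
  shifted <- cbind(base, base + 2, base - 1)
  expect_equal(icc_3k(shifted)$icc_3k, 1, tolerance = 1e-12)

  set.seed(42)
  m <- matrix(rnorm(40), 8, 5)
  expect_equal(
    icc_3k(m)$icc_3k,
    icc_3k(sweep(m, 2, c(5, -2, 0, 1, 3), `+`))$icc_3k,
    tolerance = 1e-9
  )

  holes <- m
  holes[2, 3] <- NA
  expect_error(icc_3k(holes), "complete")
  expect_error(icc_3k(m[1, , drop = FALSE]), "at least 2")
})

test_that("the permutation test reports add-one p values from a seeded null", {
  # two point masses: every label shuffle except an exact recovery of the
  # original split yields a strictly smaller distance
  data <- tibble::tibble(
    sex = rep(c("F", "M"), each = 10),
    v1 = rep(c(0, 1), each = 10),
    v2 = 0
  )
  expect_warning(
    out <- permutation_distance_test(data, n_perm = 99, seed = 7),
    "zero pooled SD"
  )
  expect_true(is.na(out$cohens_d)) # perfectly separated point masses
  expect_equal(out$observed_distance, 1)
  expect_true(all(out$perm_distances <= out$observed_distance + 1e-12))
  expect_equal(
    out$p_value,
    (sum(out$perm_distances >= out$observed_distance) + 1) / 100
  )
  expect_equal(out$p_value, 1 / 100) # no exact recovery under this seed

  # determinism: same seed, same result; different seed, different null
  again <- suppressWarnings(permutation_distance_test(data, n_perm = 99, seed = 7))
  expect_identical(tidy(out), tidy(again))
  other <- suppressWarnings(permutation_distance_test(data, n_perm = 99, seed = 8))
  expect_false(identical(out$perm_distances, other$perm_distances))

  expect_error(permutation_distance_test(data, n_perm = 99), "seed")
  expect_error(
    permutation_distance_test(data[data$sex == "F", ], n_perm = 9, seed = 1),
    "at least two|sex"
  )
})

test_that("the projection-based d accompanies the multivariate test", {
  set.seed(43)
  data <- tibble::tibble(
    sex = rep(c("F", "M"), each = 30),
    v1 = rnorm(60) + rep(c(0, 1.5), each = 30),
    v2 = rnorm(60)
  )
  out <- permutation_distance_test(data, n_perm = 199, seed = 9)
  ax <- build_axis(data)
  sc <- project_scores(data, ax)
  expect_equal(out$cohens_d, cohens_d(sc$score, sc$sex), tolerance = 1e-12)
  expect_gt(out$cohens_d, 0)
  expect_lt(out$p_value, 0.05)
})
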