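#' Cohen's d between the sexes
#'
#' Standardized mean difference `(mean_M - mean_F) / s_pooled`, with the
#' pooled standard deviation on `n1 + n2 - 2` degrees of freedom. Positive
#' values mean the male mean is higher.
#'
#' @param values Numeric vector.
#' @param labels Sex labels, `"F"`/`"M"`, same length as `values`.
#' @return A scalar.
#' @export
#' @examples
#' cohens_d(c(0, 2, 2, 4), c("F", "F", "M", "M"))
cohens_d <- function(values, labels) {
  labels <- check_sex(labels)
  stopifnot(length(values) == length(labels), !anyNA(values))
  f <- values[labels == "F"]
  m <- values[labels == "M"]
  if (length(f) < 2 || length(m) < 2) {
    abort("Cohen's d needs at least two values per sex.")
  }
  sp2 <- ((length(f) - 1) * var(f) + (length(m) - 1) * var(m)) /
    (length(f) + length(m) - 2)
  if (sp2 == 0) {
    abort("Zero pooled standard deviation: Cohen's d is undefined.")
  }
  (mean(m) - mean(f)) / sqrt(sp2)
}

#' One-way ANOVA with variance explained
#'
#' Classical one-way fixed-effects ANOVA of a numeric response on a grouping
#' factor, reported with R-squared (`SS_between / SS_total`) and, for the
#' two-group case, Cohen's d. For two groups F equals the squared pooled
#' two-sample t statistic and `df2 = n - 2`.
#'
#' @param values Numeric response.
#' @param labels Grouping labels (typically sex, `"F"`/`"M"`).
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`, `r_squared`,
#'   `cohens_d` (`NA` for more than two groups), `n`.
#' @export
anova_oneway <- function(values, labels) {
  g <- factor(labels)
  stopifnot(length(values) == length(g), !anyNA(values))
  if (any(table(g) < 2)) {
    abort("Each group needs at least two values.")
  }
  if (var(values) == 0) {
    abort("Zero total variance: ANOVA is undefined.")
  }
  fit <- lm(values ~ g)
  an <- stats::anova(fit)
  d <- if (nlevels(g) == 2 && all(levels(g) %in% c("F", "M"))) {
    cohens_d(values, g)
  } else {
    NA_real_
  }
  tibble(
    statistic = an$`F value`[1],
    df1 = an$Df[1],
    df2 = an$Df[2],
    p_value = an$`Pr(>F)`[1],
    r_squared = summary(fit)$r.squared,
    cohens_d = d,
    n = length(values)
  )
}

#' Pearson correlation with a two-sided t-based p value
#'
#' Thin wrapper around [stats::cor.test()] returning a tidy one-row tibble;
#' used for the attractiveness-vs-color correlations.
#'
#' @param x,y Numeric vectors of equal length, at least 3 complete pairs.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    abort("Pearson correlation needs at least 3 complete pairs.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in x or y: correlation is undefined.")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Inter-rater reliability: ICC(3,k)
#'
#' Two-way mixed-effects, consistency, average-measures intraclass
#' correlation (Shrout-Fleiss ICC(3,k)): `(BMS - EMS) / BMS`, where BMS is
#' the between-stimulus mean square and EMS the residual mean square of the
#' additive two-way (stimulus + rater) model.
#'
#' @param ratings Numeric matrix or data frame, stimuli in rows and raters in
#'   columns. The design must be complete (no missing cells); incomplete
#'   rating designs should be subset to their complete block first.
#' @return A one-row tibble: `icc_3k`, `k` (raters), `n` (stimuli).
#' @export
icc_3k <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) {
    abort(paste0(
      "Missing cells in the rating matrix. ICC(3,k) needs a complete ",
      "stimulus x rater design; subset to raters/stimuli with full coverage."
    ))
  }
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) {
    abort("Need at least 2 stimuli and 2 raters.")
  }
  long <- data.frame(
    rating = as.vector(ratings),
    stimulus = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  # only the mean squares are used; suppress anova's F-test caveat on
  # perfect-agreement matrices (zero residual)
  ms <- suppressWarnings(
    stats::anova(lm(rating ~ stimulus + rater, data = long))$`Mean Sq`
  )
  bms <- ms[1]
  ems <- ms[3]
  tibble(icc_3k = (bms - ems) / bms, k = k, n = n)
}

#' Permutation test on the distance between sex-specific means
#'
#' Tests whether the Euclidean distance between the female-mean and male-mean
#' vectors of a multivariate feature matrix (shape coordinates or color
#' measurements) exceeds what random assignment of individuals to sex groups
#' produces. Sex labels are shuffled without replacement `n_perm` times, the
#' distance recomputed each time, and the add-one p value reported:
#' `p = (#{perm >= observed} + 1) / (n_perm + 1)`. The accompanying effect
#' size is Cohen's d of the projection scores along the observed sex axis
#' (the univariate reduction of the same comparison), labelled
#' "d (projection)" in printed output.
#'
#' @param data Feature tibble as in [build_axis()].
#' @param n_perm Number of label permutations (10,000 for publication-grade
#'   inference; at least 99).
#' @param seed Integer seed; mandatory so every result is reproducible.
#' @param space Label carried into the result.
#' @return A `permutation_test` object; see [tidy()] / [glance()].
#' @export
permutation_distance_test <- function(data, n_perm = 10000, seed, space = "feature") {
  if (missing(seed)) {
    abort("`seed` is required: permutation results must be reproducible.")
  }
  if (n_perm < 1) {
    abort("`n_perm` must be at least 1.")
  }
  fm <- feature_matrix(data, quiet = TRUE)
  x <- fm$x
  male <- fm$male
  n_m <- sum(male)
  n_f <- sum(!male)

  totals <- colSums(x)
  dist_for <- function(male_idx) {
    sm <- colSums(x[male_idx, , drop = FALSE])
    sqrt(sum((sm / n_m - (totals - sm) / n_f)^2))
  }
  observed <- dist_for(which(male))

  set.seed(seed)
  perm <- vapply(
    seq_len(n_perm),
    function(i) dist_for(sample(nrow(x), n_m)),
    double(1)
  )
  p <- (sum(perm >= observed) + 1) / (n_perm + 1)

  scores <- as.numeric(x %*% (colMeans(x[male, , drop = FALSE]) -
    colMeans(x[!male, , drop = FALSE])))
  d <- tryCatch(cohens_d(scores, fm$data$sex), error = function(e) {
    warn("Projection scores have zero pooled SD; reporting d = NA.")
    NA_real_
  })

  structure(
    list(
      observed_distance = observed,
      p_value = p,
      n_perm = as.integer(n_perm),
      cohens_d = d,
      seed = as.integer(seed),
      space = space,
      n_female = n_f,
      n_male = n_m,
      perm_distances = perm
    ),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(
    "Permutation test on between-sex mean distance (", x$space, " space)\n",
    "  n (F/M):        ", x$n_female, "/", x$n_male, "\n",
    "  mean distance:  ", format(x$observed_distance, digits = 4), "\n",
    "  permutations:   ", x$n_perm, " (seed ", x$seed, ")\n",
    "  p value:        ", format(x$p_value, digits = 4), "\n",
    "  d (projection): ", format(x$cohens_d, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn permutation_distance_test One-row tibble of the test result.
#' @param x A `permutation_test` object.
#' @param ... Unused.
#' @export
tidy.permutation_test <- function(x, ...) {
  tibble(
    space = x$space,
    mean_distance = x$observed_distance,
    p_value = x$p_value,
    cohens_d = x$cohens_d,
    n_perm = x$n_perm,
    n_female = x$n_female,
    n_male = x$n_male,
    seed = x$seed
  )
}

#' @describeIn permutation_distance_test Alias of [tidy.permutation_test()].
#' @export
glance.permutation_test <- function(x, ...) {
  tidy.permutation_test(x)
}

#' Null-distribution plot for a permutation test
#'
#' @param object A `permutation_test` object.
#' @param ... Unused.
#' @return A ggplot: histogram of permuted distances with the observed
#'   distance marked.
#' @export
autoplot.permutation_test <- function(object, ...) {
  ggplot2::ggplot(
    tibble(distance = object$perm_distances),
    ggplot2::aes(x = .data$distance)
  ) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      xintercept = object$observed_distance,
      colour = "firebrick", linewidth = 1
    ) +
    ggplot2::labs(
      x = "between-sex mean distance (permuted labels)",
      y = "count",
      title = paste0(
        "Permutation null (", object$space, "), p = ",
        format(object$p_value, digits = 3)
      )
    ) +
    ggplot2::theme_minimal()
}
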