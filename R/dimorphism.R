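# Split a feature tibble into identifier columns and the numeric matrix used
# for axis construction, dropping rows with missing values (logged).
feature_matrix <- function(data, quiet = FALSE, min_per_sex = 2) {
  vars <- feature_cols(data)
  if (length(vars) == 0) {
    abort("No numeric feature columns found.")
  }
  if (!"sex" %in% names(data)) {
    abort("`data` must have a `sex` column with levels F and M.")
  }
  data$sex <- check_sex(data$sex)
  keep <- stats::complete.cases(data[vars])
  if (any(!keep)) {
    dropped <- if ("specimen_id" %in% names(data)) {
      data$specimen_id[!keep]
    } else {
      which(!keep)
    }
    if (!quiet) {
      inform(paste0(
        "Excluding ", sum(!keep), " specimen(s) with missing values: ",
        paste(dropped, collapse = ", ")
      ))
    }
    data <- data[keep, ]
  }
  x <- as.matrix(data[vars])
  if (any(table(data$sex) < min_per_sex)) {
    abort("Each sex needs at least two specimens.")
  }
  list(data = data, x = x, vars = vars, male = data$sex == "M")
}

#' Construct the sexual-dimorphism axis of a feature space
#'
#' The axis is the vector joining the sex-specific mean vectors: per-variable
#' female mean FM, male mean MM, and direction MM - FM. Projecting
#' individuals onto this axis yields sex-typicality scores (SShD in shape
#' space, SCoD in color space).
#'
#' @param data Specimen-by-variable tibble: identifier columns
#'   (`specimen_id`, `sex`, optionally `population`) plus numeric feature
#'   columns. Rows with missing feature values are excluded with a message.
#' @param space Label recorded on the axis, e.g. `"shape"` or `"color"`.
#' @return A `dimorphism_axis` object with elements `female_mean`,
#'   `male_mean`, `direction`, `space`, `n_female`, `n_male`.
#' @export
build_axis <- function(data, space = "feature") {
  fm <- feature_matrix(data)
  female_mean <- colMeans(fm$x[!fm$male, , drop = FALSE])
  male_mean <- colMeans(fm$x[fm$male, , drop = FALSE])
  direction <- male_mean - female_mean
  if (sqrt(sum(direction^2)) == 0) {
    abort("Degenerate axis: female and male means are identical.")
  }
  structure(
    list(
      female_mean = female_mean,
      male_mean = male_mean,
      direction = direction,
      space = space,
      n_female = sum(!fm$male),
      n_male = sum(fm$male)
    ),
    class = "dimorphism_axis"
  )
}

#' @export
print.dimorphism_axis <- function(x, ...) {
  cat(
    "Sexual dimorphism axis (", x$space, " space)\n",
    "  variables:            ", length(x$direction), "\n",
    "  n (F/M):              ", x$n_female, "/", x$n_male, "\n",
    "  ||MM - FM|| distance: ", format(sqrt(sum(x$direction^2))), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn build_axis Per-variable tibble of the axis: female mean, male
#'   mean, direction component.
#' @param x A `dimorphism_axis`.
#' @param ... Unused.
#' @export
tidy.dimorphism_axis <- function(x, ...) {
  tibble(
    variable = names(x$direction),
    female_mean = unname(x$female_mean),
    male_mean = unname(x$male_mean),
    direction = unname(x$direction)
  )
}

#' @describeIn build_axis One-row summary with the between-sex mean distance.
#' @export
glance.dimorphism_axis <- function(x, ...) {
  tibble(
    space = x$space,
    n_variables = length(x$direction),
    n_female = x$n_female,
    n_male = x$n_male,
    mean_distance = sqrt(sum(x$direction^2))
  )
}

#' Write a dimorphism axis to JSON
#'
#' @param axis A `dimorphism_axis`.
#' @param path Output path.
#' @return The axis, invisibly.
#' @export
write_axis_json <- function(axis, path) {
  jsonlite::write_json(
    list(
      space = axis$space,
      variables = names(axis$direction),
      female_mean = unname(axis$female_mean),
      male_mean = unname(axis$male_mean),
      direction = unname(axis$direction)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(axis)
}

#' Score individuals along a dimorphism axis
#'
#' Each individual's score is the dot product of its feature vector with the
#' axis direction MM - FM; higher scores are more male-typical. The direction
#' is left unnormalized by default, so the male-female difference in mean
#' scores equals the squared between-sex mean distance.
#'
#' @param data Feature tibble as in [build_axis()] (the axis may come from a
#'   different dataset, e.g. when scoring new faces).
#' @param axis A `dimorphism_axis` whose variables match the feature columns
#'   of `data`.
#' @param normalize_axis If `TRUE`, divide by the axis norm so scores are in
#'   the units of the feature space (projection length). Default `FALSE`.
#' @return A tibble: identifier columns, `score`, and `score_centered`
#'   (mean-centered within population when a `population` column is present,
#'   overall otherwise).
#' @export
project_scores <- function(data, axis, normalize_axis = FALSE) {
  fm <- feature_matrix(data, min_per_sex = 0)
  if (!identical(length(axis$direction), ncol(fm$x))) {
    abort(paste0(
      "Axis has ", length(axis$direction), " variables but data has ",
      ncol(fm$x), " feature columns."
    ))
  }
  if (!is.null(names(axis$direction)) &&
    !identical(names(axis$direction), colnames(fm$x))) {
    abort("Axis variable names do not match the data's feature columns.")
  }
  dir <- axis$direction
  if (normalize_axis) dir <- dir / sqrt(sum(dir^2))
  out <- fm$data[intersect(.id_cols, names(fm$data))]
  out$space <- axis$space
  out$score <- as.numeric(fm$x %*% dir)
  if ("population" %in% names(out)) {
    out <- out |>
      group_by(.data$population) |>
      mutate(score_centered = .data$score - mean(.data$score)) |>
      ungroup()
  } else {
    out$score_centered <- out$score - mean(out$score)
  }
  as_tibble(out)
}

#' Euclidean distance between the sex-specific mean vectors
#'
#' The magnitude of sexual dimorphism in a feature space: the norm of
#' MM - FM. In Procrustes shape space this is the between-sex Procrustes
#' distance; in color space it is in the mixed units of the color matrix.
#'
#' @inheritParams build_axis
#' @return A non-negative scalar.
#' @export
mean_distance <- function(data) {
  fm <- feature_matrix(data, quiet = TRUE, min_per_sex = 1)
  female_mean <- colMeans(fm$x[!fm$male, , drop = FALSE])
  male_mean <- colMeans(fm$x[fm$male, , drop = FALSE])
  sqrt(sum((male_mean - female_mean)^2))
}

#' Assemble the shape feature matrix from a Procrustes fit
#'
#' Reshapes aligned coordinates into one row per specimen with 2k numeric
#' columns named `x1, y1, ..., xk, yk` (for the 72-point face scheme, 144
#' columns), the matrix on which SShD is computed.
#'
#' @param fit A `gpa_fit` from [gpa()].
#' @return A tibble: identifier columns then interleaved coordinate columns.
#' @export
assemble_sshd_matrix <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  k <- nrow(fit$consensus)
  wide <- t(vapply(fit$coords, function(m) as.vector(t(m)), double(2 * k)))
  colnames(wide) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  out <- tibble(specimen_id = names(fit$coords))
  if (!is.null(fit$meta) && ncol(fit$meta) > 1) {
    out <- left_join(out, fit$meta, by = "specimen_id")
  }
  bind_cols(out, as_tibble(as.data.frame(wide)))
}

#' Assemble the color feature matrix (SCoD space)
#'
#' Binds the skin-color measurements from the cheek and forehead with the
#' facial contrasts of the eye, brow, and lips regions. With all three CIELAB
#' channels this is the default 15-column color space: cheek L*/a*/b*,
#' forehead L*/a*/b*, and nine feature contrasts. Rows with any missing value
#' are dropped (listwise deletion) and reported.
#'
#' @param measurements Wide measurement tibble (`<region>_<channel>` columns)
#'   including `specimen_id` and `sex`.
#' @param channels CIELAB channels to include, subset of `c("L", "a", "b")`;
#'   applies to both the skin columns and the contrasts.
#' @param standardize If `TRUE`, z-score each column (useful because L* spans
#'   0-100 while contrasts span -1..1). Default `FALSE`: raw mixed units.
#' @return A feature tibble ready for [build_axis()] / [mean_distance()],
#'   with an `excluded` attribute listing dropped specimens.
#' @export
assemble_scod_matrix <- function(measurements, channels = c("L", "a", "b"),
                                 standardize = FALSE) {
  channels <- match.arg(channels, several.ok = TRUE)
  skin_cols <- as.vector(outer(c("cheek", "forehead"), channels, paste, sep = "_"))
  missing_cols <- setdiff(skin_cols, names(measurements))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing skin columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  contrasts <- contrast_profile(measurements, channels = channels)
  contrast_cols <- setdiff(names(contrasts), .id_cols)
  out <- bind_cols(
    measurements[intersect(.id_cols, names(measurements))],
    measurements[skin_cols],
    contrasts[contrast_cols]
  )
  vars <- c(skin_cols, contrast_cols)
  keep <- stats::complete.cases(out[vars])
  excluded <- out$specimen_id[!keep]
  if (length(excluded) > 0) {
    inform(paste0(
      "Excluding ", length(excluded),
      " specimen(s) with incomplete color measurements: ",
      paste(excluded, collapse = ", ")
    ))
    out <- out[keep, ]
  }
  if (nrow(out) == 0) {
    abort("No specimens with complete color measurements.")
  }
  if (standardize) {
    out <- mutate(out, across(all_of(vars), ~ as.numeric(scale(.x))))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Violin plot of dimorphism scores by sex
#'
#' The standard display of SShD/SCoD score distributions: one violin per sex
#' (and per population when present), with medians and interquartile ranges.
#'
#' @param scores Score tibble from [project_scores()], or several row-bound
#'   together (the `space` column faceting shape vs color).
#' @return A ggplot object.
#' @export
plot_dimorphism_scores <- function(scores) {
  stopifnot(all(c("sex", "score") %in% names(scores)))
  y <- if ("score_centered" %in% names(scores)) "score_centered" else "score"
  p <- ggplot2::ggplot(
    scores,
    ggplot2::aes(x = .data$sex, y = .data[[y]], fill = .data$sex)
  ) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.7) +
    ggplot2::geom_boxplot(width = 0.12, fill = "white", outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "dimorphism score (centered)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  facets <- intersect(c("population", "space"), names(scores))
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_grid(
      rows = if ("space" %in% facets) ggplot2::vars(.data$space) else NULL,
      cols = if ("population" %in% facets) ggplot2::vars(.data$population) else NULL,
      scales = "free_y"
    )
  }
  p
}
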