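#' Generalized Procrustes Analysis
#'
#' Jointly aligns a set of landmark configurations: each is translated so its
#' centroid sits at the origin, scaled to unit centroid size, and rotated
#' (rotations only, no reflections) onto the running consensus; the consensus
#' is recomputed as the mean of the aligned set and the cycle repeats until
#' its root-mean-square change falls below `tol`. After convergence the whole
#' set is rotated so the principal axis of the consensus is vertical, making
#' the output deterministic and independent of input order.
#'
#' @param landmarks Long landmark tibble (`specimen_id`, `point`, `x`, `y`,
#'   plus optional `sex`/`population` carried through to [tidy()] output).
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Maximum number of consensus updates.
#' @return An object of class `gpa_fit` with elements `coords` (named list of
#'   k x 2 aligned matrices), `consensus`, `centroid_sizes` (pre-scaling),
#'   `iterations`, `converged`, and `meta`. Use [tidy()] for a long tibble of
#'   aligned coordinates, [glance()] for a one-row fit summary, and
#'   [assemble_sshd_matrix()] for the specimen-by-variable matrix.
#' @export
gpa <- function(landmarks, tol = 1e-8, max_iter = 100) {
  mats <- landmarks_to_matrices(landmarks)
  if (length(mats) < 2) {
    abort("GPA needs at least two configurations.")
  }
  meta <- landmark_meta(landmarks)

  sizes <- vapply(mats, centroid_size, double(1))
  degenerate <- names(sizes)[sizes < sqrt(.Machine$double.eps)]
  if (length(degenerate) > 0) {
    abort(paste0(
      "Degenerate configuration (zero centroid size): ",
      paste(degenerate, collapse = ", ")
    ))
  }
  scaled <- purrr::map2(mats, sizes, function(m, s) {
    sweep(m, 2, colMeans(m)) / s
  })

  # Initial consensus: the mean of the centered, scaled configurations
  # (renormalized); makes the converged consensus an exact fixed point, so
  # realigning already-aligned data stops after a single iteration.
  consensus <- Reduce(`+`, scaled) / length(scaled)
  consensus <- consensus / centroid_size(consensus)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    scaled <- lapply(scaled, function(m) m %*% rotation_onto(m, consensus))
    new_consensus <- Reduce(`+`, scaled) / length(scaled)
    new_consensus <- new_consensus / centroid_size(new_consensus)
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  # Orientation anchor: principal axis of the consensus vertical, with a
  # deterministic sign so the result does not depend on input order.
  ev <- eigen(crossprod(consensus), symmetric = TRUE)$vectors[, 1]
  if (ev[2] < 0 || (ev[2] == 0 && ev[1] < 0)) ev <- -ev
  anchor <- matrix(c(ev[2], -ev[1], ev[1], ev[2]), 2, 2)
  scaled <- lapply(scaled, function(m) m %*% anchor)
  # reported consensus: plain arithmetic mean of the aligned configurations
  consensus <- Reduce(`+`, scaled) / length(scaled)

  structure(
    list(
      coords = scaled,
      consensus = consensus,
      centroid_sizes = sizes,
      iterations = iterations,
      converged = converged,
      tol = tol,
      meta = meta
    ),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(
    "Generalized Procrustes fit\n",
    "  specimens:  ", length(x$coords), "\n",
    "  points:     ", nrow(x$consensus), "\n",
    "  iterations: ", x$iterations,
    if (x$converged) " (converged)\n" else " (NOT converged)\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn gpa Long tibble of aligned coordinates (one row per landmark),
#'   with specimen metadata joined back in.
#' @param x A `gpa_fit` object.
#' @param ... Unused.
#' @export
tidy.gpa_fit <- function(x, ...) {
  out <- matrices_to_landmarks(x$coords, x$meta)
  cs <- tibble(
    specimen_id = names(x$centroid_sizes),
    centroid_size = unname(x$centroid_sizes)
  )
  left_join(out, cs, by = "specimen_id")
}

#' @describeIn gpa One-row summary: specimen count, iterations, convergence,
#'   mean Procrustes distance to the consensus.
#' @export
glance.gpa_fit <- function(x, ...) {
  d <- vapply(x$coords, function(m) sqrt(sum((m - x$consensus)^2)), double(1))
  tibble(
    n_specimens = length(x$coords),
    n_points = nrow(x$consensus),
    iterations = x$iterations,
    converged = x$converged,
    mean_procrustes_distance = mean(d)
  )
}

#' Export aligned shapes as a wide CSV
#'
#' One row per specimen: identifiers, the 2k aligned coordinates named
#' `x1,y1,...`, and the pre-scaling centroid size.
#'
#' @param fit A `gpa_fit` object.
#' @param path Output CSV path.
#' @return The wide tibble, invisibly.
#' @export
write_aligned_csv <- function(fit, path) {
  wide <- assemble_sshd_matrix(fit)
  wide$centroid_size <- unname(fit$centroid_sizes[wide$specimen_id])
  readr::write_csv(wide, path)
  invisible(wide)
}

#' Plot an aligned shape set
#'
#' Scatter of all aligned configurations with the consensus overlaid --
#' the standard visual check that alignment succeeded.
#'
#' @param object A `gpa_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gpa_fit <- function(object, ...) {
  pts <- tidy.gpa_fit(object)
  cons <- tibble(
    x = object$consensus[, 1], y = object$consensus[, 2],
    point = seq_len(nrow(object$consensus))
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "grey40") +
    ggplot2::geom_point(data = cons, colour = "firebrick", size = 1.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Procrustes-aligned configurations",
      subtitle = "grey: individual faces; red: consensus"
    ) +
    ggplot2::theme_minimal()
}
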