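# Internal conversions between the long landmark tibble (specimen_id, point,
# x, y, + optional metadata) and a named list of k x 2 coordinate matrices.

landmark_meta <- function(landmarks) {
  keep <- intersect(.id_cols, names(landmarks))
  dplyr::distinct(landmarks[keep])
}

landmarks_to_matrices <- function(landmarks) {
  stopifnot(all(c("specimen_id", "point", "x", "y") %in% names(landmarks)))
  if (anyNA(landmarks$x) || anyNA(landmarks$y) ||
    any(!is.finite(landmarks$x)) || any(!is.finite(landmarks$y))) {
    abort("Landmark coordinates must be finite and non-missing.")
  }
  ord <- dplyr::arrange(landmarks, match(.data$specimen_id, unique(landmarks$specimen_id)), .data$point)
  mats <- lapply(
    split(ord[c("x", "y")], factor(ord$specimen_id, levels = unique(ord$specimen_id))),
    function(d) cbind(x = d$x, y = d$y)
  )
  sizes <- lengths(mats) / 2
  if (length(unique(sizes)) > 1) {
    abort("All configurations must have the same number of points.")
  }
  mats
}

matrices_to_landmarks <- function(mats, meta = NULL) {
  out <- purrr::imap(mats, function(m, id) {
    tibble(specimen_id = id, point = seq_len(nrow(m)), x = m[, 1], y = m[, 2])
  })
  out <- bind_rows(out)
  if (!is.null(meta) && ncol(meta) > 1) {
    out <- left_join(out, meta, by = "specimen_id")
  }
  out[union(intersect(.id_cols, names(out)), c("point", "x", "y"))]
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all points from their
#' centroid -- the size measure removed by Procrustes scaling.
#'
#' @param points A k x 2 numeric matrix, or a tibble with `x` and `y` columns.
#' @return A positive scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # unit square
centroid_size <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  centered <- sweep(points, 2, colMeans(points))
  sqrt(sum(centered^2))
}

# Optimal rotation (no reflection) taking row-point matrix A onto B.
rotation_onto <- function(A, B) {
  m <- crossprod(A, B)
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    r <- s$u %*% diag(c(1, -1)) %*% t(s$v)
  }
  r
}

#' Symmetrize a landmark configuration
#'
#' Averages each configuration with its relabeled mirror image, removing
#' fluctuating asymmetry under object symmetry. The configuration is
#' centered, reflected about the vertical midline (x negated), the points of
#' each bilateral pair are swapped, the reflected copy is rotated (rotation
#' only) onto the original by ordinary Procrustes fitting, and the two are
#' averaged pointwise. The operation is idempotent up to numerical tolerance.
#'
#' @param landmarks Long landmark tibble (`specimen_id`, `point`, `x`, `y`);
#'   several specimens may be present.
#' @param pairing Pairing tibble from [face_pairing()] or [read_pairing()].
#' @return A tibble of the same shape with symmetrized coordinates; each
#'   specimen keeps its original centroid position.
#' @export
symmetrize <- function(landmarks, pairing) {
  if (missing(pairing) || is.null(pairing)) {
    abort("`pairing` is required: supply a table built with face_pairing().")
  }
  mats <- landmarks_to_matrices(landmarks)
  k <- nrow(mats[[1]])
  perm <- mirror_permutation(pairing, k)
  meta <- landmark_meta(landmarks)
  sym <- lapply(mats, function(m) {
    centroid <- colMeans(m)
    x <- sweep(m, 2, centroid)
    refl <- x %*% diag(c(-1, 1))
    refl <- refl[perm, , drop = FALSE]
    refl <- refl %*% rotation_onto(refl, x)
    sweep((x + refl) / 2, 2, centroid, `+`)
  })
  matrices_to_landmarks(sym, meta)
}
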