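#' Declare the bilateral pairing of a landmark scheme
#'
#' Frontal faces have object symmetry: most points come in left/right pairs
#' while a few lie on the facial midline. Symmetrization needs to know which
#' is which. The pairing is supplied by the user (digitizing schemes differ);
#' [face_template()] ships a complete example for the 72-point scheme.
#'
#' @param left,right Integer vectors of equal length; `left[i]` and
#'   `right[i]` are the indices of the i-th bilateral pair.
#' @param midline Integer vector of points lying on the midline.
#' @param n_points Total number of points in the scheme. Every index
#'   `1:n_points` must appear in exactly one pair or in `midline`.
#'
#' @return A tibble with columns `left` and `right`; midline points are
#'   stored as rows with `left == right`.
#' @export
#' @examples
#' face_pairing(left = c(1, 3), right = c(2, 4), midline = 5, n_points = 5)
face_pairing <- function(left, right, midline = integer(), n_points) {
  left <- as.integer(left)
  right <- as.integer(right)
  midline <- as.integer(midline)
  if (length(left) != length(right)) {
    abort("`left` and `right` must have the same length.")
  }
  seen <- c(left, right, midline)
  if (anyDuplicated(seen)) {
    abort(paste0(
      "Points listed more than once in the pairing: ",
      paste(unique(seen[duplicated(seen)]), collapse = ", ")
    ))
  }
  missing <- setdiff(seq_len(n_points), seen)
  if (length(missing) > 0) {
    abort(paste0(
      "Points in neither a bilateral pair nor the midline: ",
      paste(missing, collapse = ", ")
    ))
  }
  extra <- setdiff(seen, seq_len(n_points))
  if (length(extra) > 0) {
    abort(paste0("Pairing indices beyond n_points: ", paste(extra, collapse = ", ")))
  }
  tibble(
    left = c(left, midline),
    right = c(right, midline)
  )
}

#' Read a pairing table from CSV
#'
#' Expects columns `left` and `right` (midline points as rows with
#' `left == right`), the on-disk form of [face_pairing()].
#'
#' @param path CSV path.
#' @param n_points Total point count to validate coverage against.
#' @return A validated pairing tibble.
#' @export
read_pairing <- function(path, n_points = 72) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("left", "right") %in% names(tab)))
  mid <- tab$left[tab$left == tab$right]
  face_pairing(
    left = tab$left[tab$left != tab$right],
    right = tab$right[tab$left != tab$right],
    midline = mid, n_points = n_points
  )
}

# Permutation sending each point index to its mirror partner.
mirror_permutation <- function(pairing, n_points) {
  perm <- integer(n_points)
  perm[pairing$left] <- pairing$right
  perm[pairing$right] <- pairing$left
  if (any(perm == 0)) {
    abort("Pairing does not cover every point; rebuild it with face_pairing().")
  }
  perm
}
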