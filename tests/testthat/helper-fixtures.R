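# Shared fixtures: tiny configurations, random-config generators, and a
# similarity-transform helper used across the shape tests.

# Unit square, corners counterclockwise from the origin.
square_config <- function(id = "sq") {
  tibble::tibble(
    specimen_id = id, point = 1:4,
    x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)
  )
}

# Random k-point configuration as a long tibble.
random_config <- function(id, k = 12, sd = 1) {
  tibble::tibble(
    specimen_id = id, point = seq_len(k),
    x = stats::rnorm(k, sd = sd), y = stats::rnorm(k, sd = sd)
  )
}

# Apply a similarity transform (rotation deg, positive scale, translation)
# to one configuration's coordinates.
apply_similarity <- function(config, angle_deg = 0, scale = 1, shift = c(0, 0)) {
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  xy <- cbind(config$x, config$y) %*% rot * scale
  config$x <- xy[, 1] + shift[1]
  config$y <- xy[, 2] + shift[2]
  config
}

# Mirror-symmetric 4-point fixture: two bilateral pairs, no midline.
sym4_pairing <- function() face_pairing(left = c(2, 4), right = c(1, 3), n_points = 4)

sym4_config <- function(id = "s") {
  tibble::tibble(
    specimen_id = id, point = 1:4,
    x = c(1, -1, 0.5, -0.5), y = c(1, 1, -1, -1)
  )
}

# Small two-sex feature tibble with exact group means.
toy_features <- function() {
  tibble::tibble(
    specimen_id = paste0("s", 1:6),
    sex = c("F", "F", "F", "M", "M", "M"),
    v1 = c(0, 1, -1, 3, 4, 2),
    v2 = c(1, 0, -1, 4, 5, 3)
  )
}

# Independent reflection-average oracle for symmetrize(): centers, reflects
# and relabels, then finds the aligning rotation by 1-D numerical
# optimization over the angle (no SVD), and averages.
symmetrize_oracle <- function(xy, perm) {
  centroid <- colMeans(xy)
  x <- sweep(xy, 2, centroid)
  refl <- (x %*% diag(c(-1, 1)))[perm, , drop = FALSE]
  obj <- function(th) {
    rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    sum((refl %*% rot - x)^2)
  }
  th <- stats::optimize(obj, c(-pi, pi), tol = 1e-12)$minimum
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  sweep((x + refl %*% rot) / 2, 2, centroid, `+`)
}
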