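# ---- Face template ---------------------------------------------------------

# Right-half feature points of the 72-point frontal-face scheme. The template
# is built from 8 midline points and 32 bilateral pairs; "kind" distinguishes
# anatomical landmarks from outline/curve semilandmarks (36 of each).
.template_halves <- function() {
  midline <- tibble(
    x = 0,
    y = c(1.00, 0.55, 0.35, 0.00, -0.25, -0.35, -0.50, -0.95),
    kind = "landmark",
    part = c(
      "forehead", "glabella", "nose_bridge", "nose_tip",
      "philtrum", "upper_lip", "lower_lip", "chin"
    )
  )
  outline_angle <- seq(80, -75, length.out = 14) * pi / 180
  right <- bind_rows(
    tibble( # facial outline, forehead to jawline (semilandmarks)
      x = 0.75 * cos(outline_angle),
      y = 1.00 * sin(outline_angle),
      kind = "semilandmark", part = "outline"
    ),
    tibble( # brow: 3 landmarks + 2 curve semilandmarks
      x = c(0.15, 0.35, 0.55, 0.25, 0.45),
      y = c(0.60, 0.66, 0.60, 0.64, 0.64),
      kind = c(rep("landmark", 3), rep("semilandmark", 2)),
      part = "brow"
    ),
    tibble( # eye corners and lids
      x = c(0.18, 0.33, 0.48, 0.33),
      y = c(0.42, 0.47, 0.42, 0.38),
      kind = "landmark", part = "eye"
    ),
    tibble( # nose wing
      x = c(0.12, 0.18),
      y = c(0.08, -0.05),
      kind = "landmark", part = "nose"
    ),
    tibble( # mouth corner, lip peak + 2 lip-curve semilandmarks
      x = c(0.35, 0.12, 0.24, 0.20),
      y = c(-0.42, -0.33, -0.37, -0.47),
      kind = c("landmark", "landmark", "semilandmark", "semilandmark"),
      part = "lips"
    ),
    tibble(x = 0.55, y = 0.05, kind = "landmark", part = "cheek"),
    tibble( # jaw angle and lower jaw
      x = c(0.55, 0.35),
      y = c(-0.55, -0.80),
      kind = "landmark", part = "jaw"
    )
  )
  list(midline = midline, right = right)
}

#' Synthetic 72-point face template
#'
#' A bilaterally symmetric frontal-face landmark scheme: 36 landmarks and 36
#' semilandmarks arranged as 8 midline points plus 32 left/right pairs over
#' the facial outline, brows, eyes, nose, lips, cheeks, and jaw. It is a
#' synthetic stand-in geometry for digitized faces, intended for simulation
#' and testing; the pairing table it carries is a complete worked example of
#' the format [symmetrize()] requires.
#'
#' @param style `"oval"` (default) or `"narrow"` (the same scheme with a 15%
#'   narrower face).
#' @return A list with `landmarks` (tibble: `point`, `x`, `y`, `kind`,
#'   `part`) and `pairing` (see [face_pairing()]). The configuration is
#'   centered with unit centroid size.
#' @export
face_template <- function(style = c("oval", "narrow")) {
  style <- match.arg(style)
  halves <- .template_halves()
  mid <- halves$midline
  right <- halves$right
  n_pairs <- nrow(right)

  pts <- bind_rows(
    mutate(mid, point = seq_len(nrow(mid))),
    # pairs interleaved right (odd) / left (even) after the midline block
    tibble(
      point = nrow(mid) + seq_len(2 * n_pairs),
      x = as.vector(rbind(right$x, -right$x)),
      y = as.vector(rbind(right$y, right$y)),
      kind = rep(right$kind, each = 2),
      part = rep(right$part, each = 2)
    )
  )
  if (style == "narrow") pts$x <- pts$x * 0.85

  xy <- cbind(pts$x, pts$y)
  xy <- sweep(xy, 2, colMeans(xy))
  xy <- xy / centroid_size(xy)
  pts$x <- xy[, 1]
  pts$y <- xy[, 2]

  pairing <- face_pairing(
    left = nrow(mid) + seq(2, 2 * n_pairs, by = 2),
    right = nrow(mid) + seq(1, 2 * n_pairs, by = 2),
    midline = seq_len(nrow(mid)),
    n_points = nrow(pts)
  )
  list(landmarks = pts[c("point", "x", "y", "kind", "part")], pairing = pairing)
}

# Default male shape-displacement field: wider jaw and lower outline, lowered
# brows, slightly longer chin. Symmetric (built from the template's own
# pairing), centered, and normalized to unit Euclidean norm over all 144
# coordinates, so `m_shape` sets its Procrustes-scale magnitude directly.
default_shape_dimorphism <- function(template) {
  pts <- template$landmarks
  dx <- numeric(nrow(pts))
  dy <- numeric(nrow(pts))
  jaw <- pts$part %in% c("jaw", "outline") & pts$y < -0.05
  dx[jaw] <- 0.6 * sign(pts$x[jaw])
  brow <- pts$part == "brow"
  dy[brow] <- -0.5
  chin <- pts$part == "chin"
  dy[chin] <- -0.4
  delta <- cbind(dx, dy)
  delta <- sweep(delta, 2, colMeans(delta))
  delta / sqrt(sum(delta^2))
}

# ---- Population specification ---------------------------------------------

# Female region means (L*, a*, b*) for a light-skinned reference population;
# features are darker than the surrounding skin, lips redder.
default_color_means <- function() {
  list(
    cheek = c(L = 62, a = 13, b = 16),
    forehead = c(L = 63, a = 13, b = 17),
    eye_skin = c(L = 60, a = 13, b = 16),
    brow_skin = c(L = 58, a = 13, b = 16),
    lips_skin = c(L = 61, a = 14, b = 16),
    eye_feature = c(L = 32, a = 5, b = 8),
    brow_feature = c(L = 28, a = 8, b = 10),
    lips_feature = c(L = 48, a = 22, b = 14)
  )
}

# Male offsets: darker and slightly yellower skin, darker brows.
default_color_dimorphism <- function() {
  list(
    cheek = c(L = -2.5, a = 0, b = 1),
    forehead = c(L = -2.5, a = 0, b = 1),
    eye_skin = c(L = -2.5, a = 0, b = 1),
    brow_skin = c(L = -2.5, a = 0, b = 1),
    lips_skin = c(L = -2.5, a = 0, b = 1),
    eye_feature = c(L = -1, a = 0, b = 0),
    brow_feature = c(L = -2, a = 0, b = 0),
    lips_feature = c(L = -1, a = 0, b = 0)
  )
}

#' Specify a synthetic two-sex face population
#'
#' Collects every parameter of the synthetic generators: sample sizes, the
#' template geometry and the male shape-displacement field, landmark noise
#' and similarity-transform nuisance, per-region color means and male
#' offsets, color noise, and the rating-study design. Defaults emulate a
#' moderately dimorphic population of about a hundred faces: a between-sex
#' Procrustes displacement of 0.03 units against per-coordinate landmark
#' noise of 0.01, skin about 2.5 L* units darker in males, and raters
#' agreeing at ICC(3,k) above 0.95.
#'
#' @param name Population label.
#' @param n_female,n_male Sample sizes.
#' @param shape_template A [face_template()] (or compatible list).
#' @param shape_dimorphism 72 x 2 matrix, the unit-norm male displacement
#'   field; default built from the template (wider jaw, lower brow).
#' @param m_shape Magnitude of the male shape displacement, in units of the
#'   unit-centroid-size template.
#' @param landmark_noise_sd Per-coordinate isotropic Gaussian noise SD.
#' @param nuisance List of ranges for the similarity transform applied to
#'   each raw configuration: `rotation` (degrees), `scale`, `translation`.
#' @param color_means Named list: region -> c(L, a, b) female means.
#' @param color_dimorphism Named list: region -> c(L, a, b) male offsets.
#' @param color_noise_sd Per-channel SD of the individual complexion
#'   deviation, shared across regions within a face (a person who is lighter
#'   is lighter everywhere).
#' @param region_noise_sd Per-channel SD of independent per-region
#'   measurement noise.
#' @param rating_spec List: `k_raters`, `stimulus_sd`, `rater_sd`,
#'   `noise_sd`, `scale_points` (ratings are rounded and clamped to
#'   `1..scale_points`).
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name = "synthetic",
                            n_female = 50, n_male = 50,
                            shape_template = face_template("oval"),
                            shape_dimorphism = NULL,
                            m_shape = 0.03,
                            landmark_noise_sd = 0.01,
                            nuisance = list(
                              rotation = c(-15, 15),
                              scale = c(0.8, 1.2),
                              translation = c(-0.5, 0.5)
                            ),
                            color_means = default_color_means(),
                            color_dimorphism = default_color_dimorphism(),
                            color_noise_sd = c(L = 3, a = 1.2, b = 1.5),
                            region_noise_sd = c(L = 0.5, a = 0.3, b = 0.3),
                            rating_spec = list(
                              k_raters = 30, stimulus_sd = 1,
                              rater_sd = 0.5, noise_sd = 1,
                              scale_points = 7
                            ),
                            seed = 1) {
  stopifnot(
    n_female >= 0, n_male >= 0,
    m_shape >= 0, landmark_noise_sd >= 0,
    all(color_noise_sd >= 0), all(region_noise_sd >= 0)
  )
  if (is.null(shape_dimorphism)) {
    shape_dimorphism <- default_shape_dimorphism(shape_template)
  }
  structure(
    list(
      name = name, n_female = n_female, n_male = n_male,
      shape_template = shape_template,
      shape_dimorphism = shape_dimorphism,
      m_shape = m_shape,
      landmark_noise_sd = landmark_noise_sd,
      nuisance = nuisance,
      color_means = color_means,
      color_dimorphism = color_dimorphism,
      color_noise_sd = color_noise_sd,
      region_noise_sd = region_noise_sd,
      rating_spec = rating_spec,
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

specimen_ids <- function(spec) {
  c(
    sprintf("%s_F%03d", spec$name, seq_len(spec$n_female)),
    sprintf("%s_M%03d", spec$name, seq_len(spec$n_male))
  )
}

specimen_sexes <- function(spec) {
  c(rep("F", spec$n_female), rep("M", spec$n_male))
}

# ---- Generators ------------------------------------------------------------

#' Generate landmark configurations for a synthetic population
#'
#' Females are the template plus isotropic Gaussian landmark noise; males
#' additionally receive the displacement `m_shape * shape_dimorphism`. Each
#' configuration is then rotated, scaled, and translated within the nuisance
#' ranges, emulating arbitrary digitizing frames that GPA must remove.
#'
#' @param spec A [population_spec()].
#' @return Long landmark tibble (`specimen_id`, `sex`, `population`, `point`,
#'   `x`, `y`), deterministic given `spec$seed`.
#' @export
generate_landmarks <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  base <- cbind(spec$shape_template$landmarks$x, spec$shape_template$landmarks$y)
  k <- nrow(base)
  ids <- specimen_ids(spec)
  sexes <- specimen_sexes(spec)
  nu <- spec$nuisance

  configs <- lapply(seq_along(ids), function(i) {
    m <- base
    if (sexes[i] == "M") m <- m + spec$m_shape * spec$shape_dimorphism
    m <- m + matrix(rnorm(2 * k, sd = spec$landmark_noise_sd), k, 2)
    theta <- runif(1, nu$rotation[1], nu$rotation[2]) * pi / 180
    rot <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    s <- runif(1, nu$scale[1], nu$scale[2])
    tr <- runif(2, nu$translation[1], nu$translation[2])
    sweep(s * (m %*% rot), 2, tr, `+`)
  })
  names(configs) <- ids
  out <- matrices_to_landmarks(configs)
  meta <- tibble(specimen_id = ids, sex = sexes, population = spec$name)
  left_join(out, meta, by = "specimen_id")[
    c("specimen_id", "sex", "population", "point", "x", "y")
  ]
}

#' Generate color measurements for a synthetic population
#'
#' Each face's region value is the female region mean, plus the male offset
#' for males, plus an individual complexion deviation (one draw per channel,
#' shared across all regions of that face) and independent per-region
#' measurement noise.
#'
#' @param spec A [population_spec()].
#' @return Wide measurement tibble: `specimen_id`, `sex`, `population`, then
#'   `<region>_<channel>` columns for every region in `spec$color_means`.
#' @export
generate_colors <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed + 1L)
  ids <- specimen_ids(spec)
  sexes <- specimen_sexes(spec)
  n <- length(ids)
  regions <- names(spec$color_means)
  channels <- c("L", "a", "b")

  indiv <- vapply(
    channels,
    function(ch) rnorm(n, sd = spec$color_noise_sd[[ch]]),
    double(n)
  )
  out <- tibble(specimen_id = ids, sex = sexes, population = spec$name)
  for (region in regions) {
    for (ch in channels) {
      mu <- spec$color_means[[region]][[ch]] +
        ifelse(sexes == "M", spec$color_dimorphism[[region]][[ch]], 0)
      out[[paste0(region, "_", ch)]] <-
        mu + indiv[, ch] + rnorm(n, sd = spec$region_noise_sd[[ch]])
    }
  }
  out
}

#' Generate a stimulus-by-rater rating matrix
#'
#' Ratings follow a two-way additive model -- a stimulus effect (the
#' "true" attractiveness), a rater leniency shift, and residual noise --
#' rounded and clamped to the discrete 1..7 scale. The expected ICC(3,k) of
#' the continuous model is
#' `stimulus_sd^2 / (stimulus_sd^2 + noise_sd^2 / k)`; rounding and clamping
#' attenuate it slightly.
#'
#' @param spec A [population_spec()] (its `rating_spec` element is used).
#' @param stimuli Character vector of stimulus ids (row names).
#' @return An integer matrix, stimuli x raters, deterministic given
#'   `spec$seed`.
#' @export
generate_ratings <- function(spec, stimuli) {
  stopifnot(inherits(spec, "population_spec"), length(stimuli) >= 2)
  rs <- spec$rating_spec
  if (rs$k_raters < 2) {
    abort("Need at least 2 raters.")
  }
  set.seed(spec$seed + 2L)
  n <- length(stimuli)
  k <- rs$k_raters
  midpoint <- (rs$scale_points + 1) / 2
  stim <- rnorm(n, sd = rs$stimulus_sd)
  rater <- rnorm(k, sd = rs$rater_sd)
  raw <- midpoint + outer(stim, rater, `+`) +
    matrix(rnorm(n * k, sd = rs$noise_sd), n, k)
  ratings <- pmin(pmax(round(raw), 1), rs$scale_points)
  dimnames(ratings) <- list(stimuli, sprintf("rater%03d", seq_len(k)))
  ratings
}

#' Simulate a complete synthetic study
#'
#' Runs all three generators for one population: landmarks, color
#' measurements, and one rating matrix per stimulus sex (opposite-sex raters,
#' as in a standard attractiveness-rating design).
#'
#' @param spec A [population_spec()].
#' @return A list: `spec`, `landmarks`, `colors`, `ratings` (list with `F`
#'   and `M` stimulus matrices), `pairing`.
#' @export
simulate_study <- function(spec) {
  landmarks <- generate_landmarks(spec)
  colors <- generate_colors(spec)
  ids <- specimen_ids(spec)
  sexes <- specimen_sexes(spec)
  # distinct rater samples for the two stimulus sets: offset the seed so the
  # two matrices are independent draws from the same rating model
  spec_m <- spec
  spec_m$seed <- spec$seed + 1L
  ratings <- list(
    F = generate_ratings(spec, ids[sexes == "F"]),
    M = generate_ratings(spec_m, ids[sexes == "M"])
  )
  list(
    spec = spec, landmarks = landmarks, colors = colors,
    ratings = ratings, pairing = spec$shape_template$pairing
  )
}
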