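# sRGB (IEC 61966-2-1, D65 white, 2 degree observer) -> CIELAB.
# Fast matrix path used per pixel; the public wrapper returns a tibble.
.srgb_to_lab_matrix <- function(rgb) {
  c_ <- rgb / 255
  lin <- ifelse(c_ <= 0.04045, c_ / 12.92, ((c_ + 0.055) / 1.055)^2.4)
  m <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), nrow = 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  white <- c(0.95047, 1.00000, 1.08883)
  xyz <- sweep(xyz, 2, white, `/`)
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
}

#' Convert sRGB colors to CIELAB
#'
#' Standard conversion: sRGB electro-optical transfer function, linear RGB to
#' XYZ under the D65 white point (2 degree observer), then CIELAB. L* runs
#' 0-100; a* is the green-red axis; b* the blue-yellow axis.
#'
#' @param rgb Either a length-3 vector `c(r, g, b)` or an n x 3 matrix /
#'   data frame of sRGB components in 0-255.
#' @return A tibble with columns `L`, `a`, `b`, one row per input color.
#' @export
#' @examples
#' srgb_to_lab(c(255, 255, 255)) # white: L* = 100
#' srgb_to_lab(rbind(c(0, 0, 0), c(128, 128, 128)))
srgb_to_lab <- function(rgb) {
  if (is.data.frame(rgb)) rgb <- as.matrix(rgb)
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  if (ncol(rgb) != 3) {
    abort("`rgb` must have three components (r, g, b).")
  }
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 255)) {
    abort("sRGB components must lie in [0, 255].")
  }
  as_tibble(as.data.frame(.srgb_to_lab_matrix(rgb)))
}

#' Mean CIELAB color of a masked image region
#'
#' Converts each selected pixel from sRGB to CIELAB and averages in CIELAB
#' space (convert first, then average), mirroring measurement on a
#' Lab-transformed image.
#'
#' @param image An h x w x 3 array of sRGB values, either in 0-1 (as read by
#'   `png::readPNG()`) or 0-255.
#' @param mask An h x w matrix (logical or numeric); nonzero pixels are
#'   selected. Must match the image dimensions and select at least one pixel.
#' @return A one-row tibble with columns `L`, `a`, `b`.
#' @export
region_mean <- function(image, mask) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    abort("`image` must be an h x w x 3 array.")
  }
  if (!all(dim(mask)[1:2] == dim(image)[1:2])) {
    abort("`mask` dimensions must match the image.")
  }
  sel <- which(as.logical(mask) & !is.na(mask))
  if (length(sel) == 0) {
    abort("Empty mask: no pixels selected.")
  }
  px <- cbind(image[, , 1][sel], image[, , 2][sel], image[, , 3][sel])
  if (max(px) <= 1) px <- px * 255
  lab <- .srgb_to_lab_matrix(px)
  tibble(L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]))
}

#' Measure several regions of one face image
#'
#' Applies [region_mean()] to a named list of masks and returns the wide
#' one-row measurement format used throughout the package
#' (`<region>_<channel>` columns).
#'
#' @param image An sRGB image array (see [region_mean()]).
#' @param masks Named list of mask matrices; names become region prefixes,
#'   e.g. `cheek` yields `cheek_L`, `cheek_a`, `cheek_b`.
#' @param specimen_id Identifier stored in the output row.
#' @return A one-row tibble: `specimen_id` then one column per region and
#'   channel.
#' @export
measure_regions <- function(image, masks, specimen_id = "specimen") {
  stopifnot(length(masks) > 0, !is.null(names(masks)))
  vals <- purrr::imap(masks, function(mask, region) {
    m <- region_mean(image, mask)
    setNames(as.numeric(m), paste0(region, "_", c("L", "a", "b")))
  })
  bind_cols(
    tibble(specimen_id = specimen_id),
    as_tibble(as.list(do.call(c, unname(vals))))
  )
}

# The five skin areas averaged into overall skin color.
skin_regions <- c("eye_skin", "brow_skin", "lips_skin", "cheek", "forehead")

#' Overall skin color from the five measured skin areas
#'
#' Unweighted per-channel mean over the eye-area skin, brow-area skin,
#' lips-area skin, cheek, and forehead measurements, giving one overall skin
#' L*, a*, b* per face.
#'
#' @param data Wide measurement tibble with `<region>_<channel>` columns for
#'   all five skin regions (see [measure_regions()] for the naming).
#' @return `data` with `skin_L`, `skin_a`, `skin_b` columns appended.
#' @export
mean_skin_color <- function(data) {
  needed <- as.vector(outer(skin_regions, c("L", "a", "b"), paste, sep = "_"))
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "Missing skin-region columns: ", paste(missing, collapse = ", ")
    ))
  }
  for (ch in c("L", "a", "b")) {
    cols <- paste0(skin_regions, "_", ch)
    data[[paste0("skin_", ch)]] <- rowMeans(data[cols])
  }
  data
}

#' Adapted Michelson contrast between a feature and its surrounding skin
#'
#' `C_f = (skin - feature) / (feature + skin)`. Zero means no contrast;
#' positive values mean the feature is darker (for L*; greener/bluer for
#' a*/b*) than the surrounding skin, negative that it is lighter
#' (redder/yellower). For non-negative operands such as L* the value lies in
#' \[-1, 1\]; a*/b* contrasts use the same formula and are not clipped.
#'
#' @param feature,skin Numeric vectors of feature and surrounding-skin values
#'   in a single CIELAB channel.
#' @return Numeric vector of contrasts. A zero denominator gives `NA` with a
#'   warning (an undefined contrast, treated as missing downstream).
#' @export
#' @examples
#' michelson_contrast(feature = 20, skin = 60) # 0.5: feature darker
#' michelson_contrast(feature = 60, skin = 20) # -0.5: feature lighter
michelson_contrast <- function(feature, skin) {
  denom <- feature + skin
  out <- (skin - feature) / denom
  bad <- !is.na(denom) & denom == 0
  if (any(bad)) {
    warn("Zero denominator in Michelson contrast; returning NA.")
    out[bad] <- NA_real_
  }
  out
}

contrast_features <- c("eye", "brow", "lips")

#' Facial contrasts for the eye, brow, and lips regions
#'
#' Computes the adapted Michelson contrast of each facial feature against its
#' own surrounding-skin area, per CIELAB channel: luminance (L*), red (a*),
#' and yellow (b*). Features whose measurement columns are absent yield `NA`
#' contrasts rather than errors, so partially measured faces stay in the
#' table.
#'
#' @param data Wide measurement tibble with `<feature>_feature_<channel>` and
#'   `<feature>_skin_<channel>` columns.
#' @param channels CIELAB channels to compute, subset of `c("L", "a", "b")`.
#' @return A tibble with the identifier columns of `data` plus
#'   `contrast_<feature>_<channel>` columns.
#' @export
contrast_profile <- function(data, channels = c("L", "a", "b")) {
  channels <- match.arg(channels, several.ok = TRUE)
  out <- data[intersect(.id_cols, names(data))]
  for (feat in contrast_features) {
    for (ch in channels) {
      fcol <- paste0(feat, "_feature_", ch)
      scol <- paste0(feat, "_skin_", ch)
      val <- if (all(c(fcol, scol) %in% names(data))) {
        michelson_contrast(data[[fcol]], data[[scol]])
      } else {
        rep(NA_real_, nrow(data))
      }
      out[[paste0("contrast_", feat, "_", ch)]] <- val
    }
  }
  as_tibble(out)
}

#' Read a wide color-measurement table
#'
#' CSV with `specimen_id`, optional `sex` and `population`, then
#' `<region>_<channel>` columns (`cheek_L`, `eye_feature_b`, ...).
#'
#' @param path CSV path.
#' @return A tibble; `sex`, when present, is validated as F/M.
#' @export
read_color_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("specimen_id" %in% names(data))
  if ("sex" %in% names(data)) data$sex <- check_sex(data$sex)
  data
}
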