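#' Read landmark configurations from a TPS file
#'
#' Parses the plain-text TPS format used by tpsDig and related digitizing
#' tools. Each record starts with `LM=<n>`, followed by `n` lines of
#' whitespace-separated x/y coordinates and then keyword lines (`ID=`,
#' `IMAGE=`, `SCALE=`). When a `SCALE=` line is present its value multiplies
#' the record's coordinates, converting digitizer units to physical units.
#'
#' @param path Path to a TPS file.
#' @param expected_points Number of points each record is expected to carry
#'   (default 72, the standard frontal-face scheme of 36 landmarks and 36
#'   semilandmarks). Records with a different count are returned with a
#'   warning so the caller can decide how to handle them.
#'
#' @return A tibble with one row per landmark: `specimen_id`, `point`
#'   (1-based index in digitizing order), `x`, `y`. Records without an `ID=`
#'   line are named `<file stem>_<record number>`.
#'
#' @seealso [write_tps()] for the inverse operation.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tps")
#' writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=s1"), tf)
#' read_tps(tf, expected_points = 3)
read_tps <- function(path, expected_points = 72) {
  if (!file.exists(path)) {
    abort(paste0("TPS file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lm_at <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(lm_at) == 0) {
    if (all(lines == "")) {
      return(tibble(
        specimen_id = character(), point = integer(),
        x = double(), y = double()
      ))
    }
    abort(paste0("No LM= records found in ", path))
  }
  ends <- c(lm_at[-1] - 1L, length(lines))
  stem <- sub("\\.[^.]*$", "", basename(path))

  records <- purrr::map2(seq_along(lm_at), seq_along(lm_at), function(i, j) {
    block <- lines[lm_at[i]:ends[i]]
    n <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1],
      ignore.case = TRUE
    )))
    if (is.na(n) || n < 0) {
      abort(paste0("Record ", i, " in ", path, ": unreadable LM= count."))
    }
    body <- block[-1]
    is_kw <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_kw & body != ""]
    if (length(coord_lines) != n) {
      abort(paste0(
        "Record ", i, " in ", path, ": LM=", n, " but ",
        length(coord_lines), " coordinate lines found."
      ))
    }
    kw <- body[is_kw]
    get_kw <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), kw, ignore.case = TRUE, value = TRUE)
      if (length(hit) == 0) NULL else trimws(sub("^[A-Za-z]+\\s*=", "", hit[1]))
    }
    id <- get_kw("ID") %||% paste0(stem, "_", i)
    scale <- get_kw("SCALE")
    scale <- if (is.null(scale)) 1 else as.numeric(scale)
    if (is.na(scale)) {
      abort(paste0("Record ", i, " in ", path, ": unreadable SCALE= value."))
    }
    if (n == 0) {
      return(tibble(
        specimen_id = character(), point = integer(),
        x = double(), y = double()
      ))
    }
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    if (ncol(xy) != 2 || anyNA(xy)) {
      abort(paste0("Record ", i, " in ", path, ": non-numeric or non-2D coordinates."))
    }
    tibble(
      specimen_id = id, point = seq_len(n),
      x = xy[, 1] * scale, y = xy[, 2] * scale
    )
  })
  out <- bind_rows(records)

  counts <- dplyr::count(out, .data$specimen_id)
  off <- counts$specimen_id[counts$n != expected_points]
  if (length(off) > 0) {
    warn(paste0(
      "TPS records with a point count other than ", expected_points, ": ",
      paste(off, collapse = ", ")
    ))
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: one `LM=` record per specimen, coordinates in
#' point order, followed by an `ID=` line. Coordinates are written at full
#' double precision so a write/read round trip reproduces them exactly.
#'
#' @param landmarks Tibble with columns `specimen_id`, `point`, `x`, `y`
#'   (extra columns are ignored).
#' @param path Output path.
#' @return `landmarks`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  if (nrow(landmarks) == 0) {
    writeLines(character(), path)
    return(invisible(landmarks))
  }
  stopifnot(all(c("specimen_id", "point", "x", "y") %in% names(landmarks)))
  ordered <- dplyr::arrange(
    landmarks,
    match(.data$specimen_id, unique(landmarks$specimen_id)), .data$point
  )
  recs <- split(
    ordered,
    factor(ordered$specimen_id, levels = unique(ordered$specimen_id))
  )
  txt <- unlist(lapply(recs, function(r) {
    c(
      paste0("LM=", nrow(r)),
      sprintf("%.17g %.17g", r$x, r$y),
      paste0("ID=", r$specimen_id[1]),
      ""
    )
  }), use.names = FALSE)
  writeLines(txt, path)
  invisible(landmarks)
}
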