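#' Read a run configuration from YAML or JSON
#'
#' A run configuration collects input paths (TPS landmarks, color CSV,
#' rating CSVs, pairing CSV), analysis options (`scod_channels`,
#' `normalize_axis`, `standardize`, `n_perm`), the mandatory `seed`, and an
#' optional `output_dir`. Defaults are filled in by
#' [run_population_analysis()] and echoed into the report for provenance.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

default_config <- function(config) {
  defaults <- list(
    name = "population",
    scod_channels = c("L", "a", "b"),
    normalize_axis = FALSE,
    standardize = FALSE,
    n_perm = 10000,
    output_dir = NULL
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$seed)) {
    abort("`seed` is required in the run configuration.")
  }
  if (config$n_perm < 99) {
    abort("`n_perm` must be at least 99.")
  }
  config
}

# Load landmarks/colors/ratings/pairing either from in-memory objects in the
# config or from the file paths it names.
load_inputs <- function(config) {
  landmarks <- config[["landmarks"]]
  if (is.null(landmarks) && !is.null(config$tps_path)) {
    landmarks <- read_tps(config$tps_path)
    if (!is.null(config$labels_path)) {
      labels <- readr::read_csv(config$labels_path, show_col_types = FALSE)
      orphans <- setdiff(unique(landmarks$specimen_id), labels$specimen_id)
      if (length(orphans) > 0) {
        abort(paste0(
          "Specimens in the TPS file but not in the labels table: ",
          paste(orphans, collapse = ", ")
        ))
      }
      landmarks <- left_join(landmarks, labels, by = "specimen_id")
    }
  }
  colors <- config[["colors"]]
  if (is.null(colors) && !is.null(config$color_csv)) {
    colors <- read_color_csv(config$color_csv)
  }
  pairing <- config[["pairing"]]
  if (is.null(pairing) && !is.null(config$pairing_path)) {
    pairing <- read_pairing(config$pairing_path)
  }
  ratings <- config[["ratings"]]
  if (is.null(ratings) && !is.null(config$ratings_paths)) {
    ratings <- lapply(config$ratings_paths, function(p) {
      tab <- readr::read_csv(p, show_col_types = FALSE)
      m <- as.matrix(tab[-1])
      rownames(m) <- tab[[1]]
      m
    })
  }
  if (!is.null(landmarks) && !is.null(colors)) {
    shared <- intersect(unique(landmarks$specimen_id), colors$specimen_id)
    if (length(shared) == 0) {
      abort("Landmark and color tables share no specimen ids.")
    }
  }
  list(landmarks = landmarks, colors = colors, pairing = pairing, ratings = ratings)
}

#' Run the full per-population dimorphism analysis
#'
#' Orchestrates the whole pipeline for one population: symmetrization and
#' joint Procrustes alignment of the landmarks; SShD axis, scores, and
#' permutation test; overall skin color and per-channel ANOVA; facial
#' contrasts and per-feature ANOVA; SCoD axis, scores, and permutation test;
#' attractiveness correlations against skin color; and ICC(3,k) per rating
#' matrix. Every stochastic step uses `config$seed` and the report records
#' all options and exclusions.
#'
#' @param config A named list (or the result of [read_run_config()]). Inputs
#'   may be given as file paths (`tps_path`, `labels_path`, `color_csv`,
#'   `pairing_path`, `ratings_paths`) or as in-memory objects (`landmarks`,
#'   `colors`, `pairing`, `ratings`), e.g. straight from [simulate_study()].
#'   Options: `name`, `scod_channels`, `normalize_axis`, `standardize`,
#'   `n_perm` (default 10,000), `seed` (required), `output_dir`.
#' @return A `dimorphism_report` list: `summary` (tidy permutation results
#'   for both spaces), `scores`, `anova_skin`, `anova_contrast`,
#'   `correlations`, `icc`, `exclusions`, `gpa` (the fit), `config`.
#'   When `output_dir` is set, CSV/JSON reports and a violin-plot figure are
#'   written there.
#' @export
run_population_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- default_config(config)
  inputs <- load_inputs(config)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  exclusions <- tibble(specimen_id = character(), stage = character(), reason = character())

  # --- shape space ---------------------------------------------------------
  shape <- NULL
  fit <- NULL
  if (!is.null(inputs$landmarks)) {
    if (is.null(inputs$pairing)) {
      abort("Landmark analysis needs a `pairing` table (or `pairing_path`).")
    }
    note("landmarks in: ", length(unique(inputs$landmarks$specimen_id)), " specimens")
    sym <- symmetrize(inputs$landmarks, inputs$pairing)
    fit <- gpa(sym)
    shape_mat <- assemble_sshd_matrix(fit)
    shape_test <- permutation_distance_test(
      shape_mat,
      n_perm = config$n_perm, seed = config$seed, space = "shape"
    )
    shape_axis <- build_axis(shape_mat, space = "shape")
    shape_scores <- project_scores(shape_mat, shape_axis,
      normalize_axis = config$normalize_axis
    )
    shape <- list(test = shape_test, axis = shape_axis, scores = shape_scores)
    note("shape analysis: ", nrow(shape_mat), " specimens aligned, ",
      fit$iterations, " GPA iterations")
  }

  # --- color space ---------------------------------------------------------
  color <- NULL
  anova_skin <- NULL
  anova_contrast <- NULL
  if (!is.null(inputs$colors)) {
    colors <- mean_skin_color(inputs$colors)
    note("colors in: ", nrow(colors), " specimens")
    anova_skin <- purrr::map_dfr(c("L", "a", "b"), function(ch) {
      bind_cols(
        tibble(measure = paste0("skin_", ch)),
        anova_oneway(colors[[paste0("skin_", ch)]], colors$sex)
      )
    })
    contrasts <- contrast_profile(colors, channels = config$scod_channels)
    anova_contrast <- purrr::map_dfr(
      setdiff(names(contrasts), .id_cols),
      function(col) {
        ok <- !is.na(contrasts[[col]])
        if (sum(ok) < 4 || length(unique(colors$sex[ok])) < 2) {
          return(tibble())
        }
        bind_cols(
          tibble(measure = col),
          anova_oneway(contrasts[[col]][ok], colors$sex[ok])
        )
      }
    )
    scod_mat <- assemble_scod_matrix(colors,
      channels = config$scod_channels,
      standardize = config$standardize
    )
    dropped <- attr(scod_mat, "excluded")
    if (length(dropped) > 0) {
      exclusions <- bind_rows(exclusions, tibble(
        specimen_id = dropped, stage = "scod_matrix",
        reason = "incomplete color measurements"
      ))
    }
    color_test <- permutation_distance_test(
      scod_mat,
      n_perm = config$n_perm, seed = config$seed, space = "color"
    )
    color_axis <- build_axis(scod_mat, space = "color")
    color_scores <- project_scores(scod_mat, color_axis,
      normalize_axis = config$normalize_axis
    )
    color <- list(
      test = color_test, axis = color_axis, scores = color_scores,
      skin = colors
    )
    note("color analysis: ", nrow(scod_mat), " specimens in SCoD matrix (",
      length(dropped), " excluded)")
  }

  # --- ratings -------------------------------------------------------------
  icc <- NULL
  correlations <- NULL
  if (!is.null(inputs$ratings)) {
    icc <- purrr::imap_dfr(inputs$ratings, function(m, set) {
      bind_cols(tibble(rater_set = set), icc_3k(m))
    })
    if (!is.null(color)) {
      attract <- purrr::imap_dfr(inputs$ratings, function(m, set) {
        tibble(
          rater_set = set,
          specimen_id = rownames(m),
          attractiveness = rowMeans(m)
        )
      })
      merged <- left_join(attract, color$skin, by = "specimen_id")
      correlations <- purrr::map_dfr(
        split(merged, merged$rater_set),
        function(d) {
          purrr::map_dfr(c("skin_L", "skin_a", "skin_b"), function(ch) {
            if (sum(stats::complete.cases(d$attractiveness, d[[ch]])) < 3) {
              return(tibble())
            }
            bind_cols(
              tibble(rater_set = d$rater_set[1], measure = ch),
              pearson_r(d$attractiveness, d[[ch]])
            )
          })
        }
      )
    }
    note("ratings: ", length(inputs$ratings), " rater set(s)")
  }

  summary <- bind_rows(
    if (!is.null(shape)) tidy(shape$test),
    if (!is.null(color)) tidy(color$test)
  )
  if (nrow(summary) > 0) summary$population <- config$name

  scores <- bind_rows(
    if (!is.null(shape)) shape$scores,
    if (!is.null(color)) color$scores
  )

  report <- structure(
    list(
      summary = summary,
      scores = scores,
      anova_skin = anova_skin,
      anova_contrast = anova_contrast,
      correlations = correlations,
      icc = icc,
      exclusions = exclusions,
      gpa = fit,
      axes = list(
        shape = if (!is.null(shape)) shape$axis,
        color = if (!is.null(color)) color$axis
      ),
      log = log_lines,
      config = config[setdiff(
        names(config),
        c("landmarks", "colors", "ratings", "pairing")
      )]
    ),
    class = "dimorphism_report"
  )

  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  report
}

#' @export
print.dimorphism_report <- function(x, ...) {
  cat("Facial dimorphism report:", x$config$name %||% "population", "\n")
  if (!is.null(x$summary) && nrow(x$summary) > 0) print(x$summary)
  cat("\nlog:\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

# Serialize a report into CSV + JSON + figure under `dir`.
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$summary)) {
    readr::write_csv(report$summary, file.path(dir, "dimorphism_summary.csv"))
  }
  if (!is.null(report$scores) && nrow(report$scores) > 0) {
    readr::write_csv(report$scores, file.path(dir, "scores.csv"))
  }
  if (!is.null(report$anova_skin)) {
    readr::write_csv(report$anova_skin, file.path(dir, "anova_skin.csv"))
  }
  if (!is.null(report$anova_contrast) && nrow(report$anova_contrast) > 0) {
    readr::write_csv(report$anova_contrast, file.path(dir, "anova_contrast.csv"))
  }
  for (space in names(report$axes)) {
    if (!is.null(report$axes[[space]])) {
      write_axis_json(report$axes[[space]], file.path(dir, paste0("axis_", space, ".json")))
    }
  }
  json <- list(
    # output_dir is machine-specific; leave it out so identical runs give
    # byte-identical reports
    config = report$config[setdiff(names(report$config), "output_dir")],
    summary = report$summary,
    anova_skin = report$anova_skin,
    anova_contrast = report$anova_contrast,
    correlations = report$correlations,
    icc = report$icc,
    exclusions = report$exclusions,
    log = report$log
  )
  jsonlite::write_json(
    json[!vapply(json, is.null, logical(1))],
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(report$scores) && nrow(report$scores) > 0) {
    p <- plot_dimorphism_scores(report$scores)
    ggplot2::ggsave(file.path(dir, "dimorphism_violins.pdf"), p,
      width = 7, height = 5
    )
  }
  invisible(report)
}

#' Validation suite: statistical calibration of the pipeline
#'
#' Re-derives the pipeline's key statistical guarantees by simulation:
#' type-I error of the permutation test under exchangeable labels, recovery
#' of a known color effect size, recovery of a known shape displacement
#' magnitude, and recovery of a known rater-agreement level. Each check is
#' compared against its tolerance and reported pass/fail.
#'
#' @param config Optional list: `seed` (default 1), `n_perm` (default 199;
#'   reduced mode for quick runs), `n_datasets` (type-I-error replicates,
#'   default 200), `n_shape` (faces per sex for shape recovery, default 1000
#'   -- the bias of the plain between-mean distance shrinks with n and needs
#'   samples this large to sit within the 5% recovery band),
#'   `targets` (named list overriding the expected values, mainly useful for
#'   injecting deliberate failures when testing the suite itself).
#' @return A tibble: `check`, `value`, `target`, `tolerance`, `pass`.
#' @export
run_validation_suite <- function(config = list()) {
  seed <- config$seed %||% 1L
  n_perm <- config$n_perm %||% 199
  n_datasets <- config$n_datasets %||% 200
  n_shape <- config$n_shape %||% 1000
  targets <- config$targets %||% list()

  # 1. type-I error of the permutation test at alpha = 0.05
  set.seed(seed)
  alpha <- 0.05
  rejections <- vapply(seq_len(n_datasets), function(i) {
    data <- tibble(
      sex = rep(c("F", "M"), each = 10)[sample(20)],
      v1 = rnorm(20), v2 = rnorm(20), v3 = rnorm(20)
    )
    permutation_distance_test(data, n_perm = n_perm, seed = seed + i)$p_value <= alpha
  }, logical(1))
  t1_rate <- mean(rejections)
  t1_tol <- 2 * sqrt(alpha * (1 - alpha) / n_datasets)

  # 2. color effect-size recovery: Delta L* / sigma = 2
  color_spec <- population_spec(
    name = "val_color", n_female = 200, n_male = 200,
    color_dimorphism = lapply(
      default_color_dimorphism(),
      function(x) c(L = -4, a = 0, b = 0)
    ),
    color_noise_sd = c(L = 2, a = 1.2, b = 1.5),
    seed = seed + 1000
  )
  colors <- mean_skin_color(generate_colors(color_spec))
  d_hat <- abs(cohens_d(colors$skin_L, colors$sex))

  # 3. shape displacement recovery: noiseless two-face run gives the true
  # Procrustes magnitude; a noisy population must recover it
  tmpl <- face_template("oval")
  truth_spec <- population_spec(
    name = "truth", n_female = 1, n_male = 1,
    shape_template = tmpl, landmark_noise_sd = 0, seed = seed + 2000
  )
  truth <- mean_distance(assemble_sshd_matrix(gpa(generate_landmarks(truth_spec))))
  pop_spec <- population_spec(
    name = "val_shape", n_female = n_shape, n_male = n_shape,
    shape_template = tmpl, seed = seed + 3000
  )
  recovered <- mean_distance(assemble_sshd_matrix(gpa(generate_landmarks(pop_spec))))
  shape_err <- abs(recovered - truth) / truth

  # 4. ICC recovery at expected ICC(3,k) = 0.95
  rs <- list(k_raters = 30, stimulus_sd = 1, rater_sd = 0.3, noise_sd = sqrt(30 / 19), scale_points = 7)
  icc_expected <- rs$stimulus_sd^2 / (rs$stimulus_sd^2 + rs$noise_sd^2 / rs$k_raters)
  icc_spec <- population_spec(
    name = "val_icc", n_female = 50, n_male = 50,
    rating_spec = rs, seed = seed + 4000
  )
  icc_hat <- icc_3k(generate_ratings(icc_spec, sprintf("s%03d", 1:100)))$icc_3k

  checks <- tibble(
    check = c(
      "type_I_error_rate", "color_cohens_d", "shape_distance_rel_error",
      "icc_3k_recovery"
    ),
    value = c(t1_rate, d_hat, shape_err, icc_hat),
    target = c(
      targets$type_I_error %||% alpha,
      targets$color_d %||% 2,
      targets$shape_rel_error %||% 0,
      targets$icc %||% icc_expected
    ),
    tolerance = c(t1_tol, 0.35, 0.05, 0.03)
  )
  checks$pass <- abs(checks$value - checks$target) <= checks$tolerance
  checks
}
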