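DEPOTS <- c("sc", "vc")
METHODS <- c("histology", "collagenase")
PARAMETERS <- c("area", "diameter", "volume", "surface")

#' Validate and normalize a long cell table
#'
#' Checks the canonical long schema (`subject_id`, `depot`, `method`,
#' `parameter`, `value`, optional `unit`), normalizes the categorical columns
#' to lower case, and rejects malformed rows with their row indices so bad
#' input is traceable to the file.
#'
#' @param cells a data frame in long form.
#' @return the validated tibble.
#' @export
validate_cells <- function(cells) {
  required <- c("subject_id", "depot", "method", "parameter", "value")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    stop(sprintf("cell table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cells <- tibble::as_tibble(cells)
  cells$subject_id <- as.character(cells$subject_id)
  cells$depot <- tolower(trimws(as.character(cells$depot)))
  cells$method <- tolower(trimws(as.character(cells$method)))
  cells$parameter <- tolower(trimws(as.character(cells$parameter)))
  complain <- function(bad, what) {
    if (any(bad)) {
      stop(sprintf("%s in row(s): %s", what,
                   paste(utils::head(which(bad), 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  complain(!cells$depot %in% DEPOTS, "unknown depot")
  complain(!cells$method %in% METHODS, "unknown method")
  complain(!cells$parameter %in% PARAMETERS, "unknown sizing parameter")
  complain(!is.finite(cells$value) | cells$value <= 0,
           "non-positive or non-numeric size value")
  cells
}

#' Read a cell size table from CSV
#'
#' The canonical format is long: one row per cell with columns `subject_id`,
#' `depot`, `method`, `parameter`, `value`, and optionally `unit`. A wide
#' format — one column per sizing parameter (`area`, `diameter`, ...) instead
#' of `parameter`/`value` — is accepted on read and converted to long form.
#' Depot and method labels are case-insensitive.
#'
#' @param path CSV file path.
#' @return validated long tibble.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  wide_cols <- intersect(PARAMETERS, tolower(names(raw)))
  if (!"value" %in% names(raw) && length(wide_cols)) {
    names(raw) <- tolower(names(raw))
    raw <- tidyr::pivot_longer(raw, dplyr::all_of(wide_cols),
                               names_to = "parameter", values_to = "value")
    raw <- raw[!is.na(raw$value), , drop = FALSE]
  }
  validate_cells(raw)
}

#' Read a subject phenotype table from CSV
#'
#' Expects `subject_id` plus any of `age`, `sex`, `bmi`, `t2d`, `glucose`,
#' `hba1c`, `cholesterol`, `ldl`, `hdl`, `triglycerides`. `sex` and `t2d`
#' labels are normalized to lower case; BMI must be positive where present.
#'
#' @param path CSV file path.
#' @return validated tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  p <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(p)) {
    stop("phenotype table needs a subject_id column", call. = FALSE)
  }
  p$subject_id <- as.character(p$subject_id)
  if ("sex" %in% names(p)) {
    p$sex <- tolower(as.character(p$sex))
    bad <- !is.na(p$sex) & !p$sex %in% c("female", "male")
    if (any(bad)) {
      stop(sprintf("unknown sex label in row(s): %s",
                   paste(utils::head(which(bad), 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  if ("t2d" %in% names(p)) {
    p$t2d <- tolower(as.character(p$t2d))
    bad <- !is.na(p$t2d) & !p$t2d %in% c("yes", "no", "unknown")
    if (any(bad)) {
      stop(sprintf("unknown t2d label in row(s): %s",
                   paste(utils::head(which(bad), 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  if ("bmi" %in% names(p) && any(!is.na(p$bmi) & p$bmi <= 0)) {
    stop("bmi must be positive where present", call. = FALSE)
  }
  tibble::as_tibble(p)
}

#' Read a respirometry table from CSV
#'
#' Expects `subject_id`, `depot`, and the four respiratory state columns
#' `free_oxphos`, `oxphos`, `ets`, `leak` (pmol O2 s^-1 ng DNA^-1, all
#' non-negative).
#'
#' @param path CSV file path.
#' @return validated tibble.
#' @export
read_respirometry <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "depot", "free_oxphos", "oxphos", "ets", "leak")
  missing_cols <- setdiff(required, names(r))
  if (length(missing_cols)) {
    stop(sprintf("respirometry table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  r$subject_id <- as.character(r$subject_id)
  r$depot <- tolower(as.character(r$depot))
  if (any(!r$depot %in% DEPOTS)) stop("unknown depot in respirometry table", call. = FALSE)
  states <- c("free_oxphos", "oxphos", "ets", "leak")
  for (s in states) {
    if (any(!is.na(r[[s]]) & r[[s]] < 0)) {
      stop(sprintf("negative %s values", s), call. = FALSE)
    }
  }
  tibble::as_tibble(r)
}

#' Pipeline run configuration
#'
#' @param k_histology,k_collagenase cells sampled per subject for each method.
#' @param k_reduced reduced cell count for the sensitivity analysis.
#' @param filter_bounds inclusive histology area retention window (µm²).
#' @param alpha significance threshold for interpretation.
#' @param seed master seed; all pipeline randomness derives from it.
#' @param parameters sizing parameters to analyze from histology areas.
#' @param out_dir optional directory for CSV outputs and the run manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(k_histology = 500, k_collagenase = 100,
                       k_reduced = 200, filter_bounds = c(200, 16000),
                       alpha = 0.05, seed = 1,
                       parameters = c("area", "diameter", "volume", "surface"),
                       out_dir = NULL) {
  stopifnot(k_histology > 0, k_collagenase > 0, k_reduced > 0,
            filter_bounds[1] <= filter_bounds[2], alpha > 0, alpha < 1)
  structure(list(
    k_histology = k_histology, k_collagenase = k_collagenase,
    k_reduced = k_reduced, filter_bounds = filter_bounds, alpha = alpha,
    seed = seed, parameters = parameters, out_dir = out_dir
  ), class = "run_config")
}

#' Run the end-to-end adipocyte size analysis
#'
#' Orchestrates the full analysis on a cell table, phenotype table, and
#' optional respirometry table: per-subject descriptor panels and cohort
#' summaries for every sizing parameter, pooled cohort panels, the
#' histology-vs-collagenase method comparison (Pearson concordance and
#' Bland-Altman), the Bonferroni-corrected per-depot correlation matrices,
#' BMI-adjusted respirometry associations, and the cell-count sensitivity
#' analysis. All randomness flows from `config$seed`. When `config$out_dir`
#' is set, every table is written as CSV along with a manifest recording
#' stage parameters and file checksums; reruns with the same inputs and seed
#' produce identical checksums.
#'
#' @param cells long cell tibble or CSV path.
#' @param phenotypes phenotype tibble or CSV path (optional).
#' @param respirometry respirometry tibble or CSV path (optional).
#' @param config a [run_config()].
#' @return list with `panels`, `summary`, `pooled`, `paired`, `bland_altman`,
#'   `concordance`, `associations`, `respirometry`, `sensitivity`,
#'   `manifest`.
#' @export
run_pipeline <- function(cells, phenotypes = NULL, respirometry = NULL,
                         config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.character(cells)) cells <- read_cells(cells)
  cells <- validate_cells(cells)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(respirometry)) respirometry <- read_respirometry(respirometry)

  k_by_method <- list(histology = config$k_histology,
                      collagenase = config$k_collagenase)
  panels <- list()
  summaries <- list()
  pooled <- list()
  sizes <- list()
  for (par in config$parameters) {
    ps <- stage(paste0("per_subject_panels/", par), per_subject_panels(
      cells, par, k_by_method, seed = config$seed,
      filter_bounds = config$filter_bounds, shapiro = TRUE
    ))
    panels[[par]] <- ps$panels
    summaries[[par]] <- ps$summary
  }
  panels <- dplyr::bind_rows(panels)
  summaries <- dplyr::bind_rows(summaries)
  combos <- unique(cells[, c("depot", "method")])
  for (i in seq_len(nrow(combos))) {
    dep <- combos$depot[i]
    met <- combos$method[i]
    for (par in if (met == "histology") config$parameters else "diameter") {
      pp <- stage(sprintf("pooled_panel/%s/%s/%s", dep, met, par),
                  suppressMessages(pooled_panel(
                    cells, dep, met, par, k_by_method[[met]],
                    seed = config$seed, filter_bounds = config$filter_bounds
                  )))
      pooled[[length(pooled) + 1L]] <- pp$panel
    }
    sizes[[paste(dep, met)]] <- stage(
      sprintf("subject_mean_sizes/%s/%s", dep, met),
      subject_mean_sizes(cells, dep, met, "diameter", k_by_method[[met]],
                         seed = config$seed,
                         filter_bounds = config$filter_bounds)
    )
  }
  pooled <- dplyr::bind_rows(pooled)
  sizes <- dplyr::bind_rows(sizes)

  hist_sizes <- sizes[sizes$method == "histology", , drop = FALSE]
  coll_sizes <- sizes[sizes$method == "collagenase", , drop = FALSE]
  paired <- NULL
  ba <- NULL
  conc <- NULL
  if (nrow(hist_sizes) && nrow(coll_sizes)) {
    paired <- stage("pair_subjects",
                    pair_subjects(hist_sizes, coll_sizes, pool_depots = TRUE))
    ba <- stage("bland_altman", bland_altman(paired))
    conc <- stage("method_concordance", method_concordance(paired))
  }

  assoc <- NULL
  if (!is.null(phenotypes)) {
    assoc <- dplyr::bind_rows(lapply(unique(cells$depot), function(dep) {
      long <- dplyr::bind_rows(lapply(config$parameters, function(par) {
        stage(sprintf("subject_mean_sizes/%s/%s", dep, par),
              subject_mean_sizes(cells, dep, "histology", par,
                                 config$k_histology, seed = config$seed,
                                 filter_bounds = config$filter_bounds))
      }))
      out <- stage(paste0("correlation_matrix/", dep),
                   correlation_matrix(long, phenotypes))
      tibble::tibble(depot = dep, out,
                     family_size = attr(out, "family_size"))
    }))
  }

  resp_assoc <- NULL
  if (!is.null(respirometry)) {
    resp_assoc <- stage("respirometry_associations", respirometry_associations(
      respirometry, hist_sizes, phenotypes = phenotypes
    ))
  }

  sens <- stage("cell_count_sensitivity", cell_count_sensitivity(
    cells, "diameter", k_full = config$k_histology,
    k_reduced = config$k_reduced, seed = config$seed,
    filter_bounds = config$filter_bounds
  ))

  result <- list(
    panels = panels, summary = summaries, pooled = pooled, sizes = sizes,
    paired = paired, bland_altman = ba, concordance = conc,
    associations = assoc, respirometry = resp_assoc, sensitivity = sens,
    config = config, manifest = NULL
  )
  if (!is.null(config$out_dir)) {
    result$manifest <- write_results(result, config$out_dir)
  }
  result
}

#' Write pipeline results as CSV files with a manifest
#'
#' @param result output of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return the manifest tibble (file, md5).
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    panels = result$panels,
    cohort_summary = result$summary,
    pooled_panels = result$pooled,
    subject_mean_sizes = result$sizes,
    paired_methods = result$paired,
    bland_altman = if (!is.null(result$bland_altman)) {
      tibble::tibble(
        n_pairs = result$bland_altman$n_pairs,
        bias = result$bland_altman$bias,
        sd_diff = result$bland_altman$sd_diff,
        loa_low = result$bland_altman$loa_low,
        loa_high = result$bland_altman$loa_high
      )
    },
    associations = result$associations,
    respirometry_associations = result$respirometry,
    sensitivity = if (!is.null(result$sensitivity)) result$sensitivity$table
  )
  files <- character()
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    f <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], f)
    files <- c(files, f)
  }
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    seed = result$config$seed,
    k_histology = result$config$k_histology,
    k_collagenase = result$config$k_collagenase
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Write a simulated cohort to CSV with a provenance record
#'
#' @param cohort output of [simulate_cohort()].
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$cells, file.path(out_dir, "cells.csv"))
  readr::write_csv(cohort$phenotypes, file.path(out_dir, "phenotypes.csv"))
  readr::write_csv(cohort$respirometry, file.path(out_dir, "respirometry.csv"))
  prov <- c(
    sprintf("seed: %d", cohort$seed),
    sprintf("n_subjects: %d", cohort$config$n_subjects),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("adipodist")))
  )
  writeLines(prov, file.path(out_dir, "provenance.yaml"))
  invisible(file.path(out_dir, c("cells.csv", "phenotypes.csv",
                                 "respirometry.csv", "provenance.yaml")))
}
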