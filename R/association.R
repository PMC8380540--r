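#' Subject-level mean sizes from a cell table
#'
#' The association analyses operate on one number per subject: the mean of a
#' fixed-size random sample of that subject's cells, converted to the
#' requested sizing parameter. Subjects with fewer than `k` cells (after the
#' histology artifact filter) are excluded.
#'
#' @inheritParams pooled_panel
#' @return tibble with `subject_id`, `depot`, `method`, `parameter`, `n_cells`,
#'   `mean`.
#' @export
subject_mean_sizes <- function(cells, depot, method, parameter, k, seed,
                               filter_bounds = c(200, 16000)) {
  vals <- subject_values(cells, depot, method, parameter, filter_bounds)
  counts <- vapply(vals, length, integer(1))
  keep <- names(vals)[counts >= k]
  if (!length(keep)) stop(sprintf("no subject has >= %d cells", k), call. = FALSE)
  means <- withr::with_seed(seed, vapply(vals[keep], function(v) {
    mean(v[sample.int(length(v), k)])
  }, numeric(1)))
  tibble::tibble(
    subject_id = keep, depot = depot, method = method, parameter = parameter,
    n_cells = k, mean = unname(means)
  )
}

#' Bonferroni-corrected correlation matrix of size vs phenotype
#'
#' Pearson correlations between subject mean sizes (one row per sizing
#' parameter) and continuous phenotype variables, with pairwise-complete
#' deletion: each pair uses every subject with both values present, so
#' different pairs can have different `n`. P values are Bonferroni corrected
#' within the family of all *tested* pairs in the matrix
#' (`p_adjusted = min(1, m * p)`); pairs with fewer than 3 complete
#' observations are reported as untested rather than silently dropped and do
#' not count toward the family size `m`.
#'
#' @param sizes long tibble of subject means with columns `subject_id`,
#'   `parameter`, `mean` (e.g. several calls to [subject_mean_sizes()] bound
#'   together), already restricted to one depot.
#' @param phenotypes tibble with `subject_id` and the variables to test.
#' @param variables character vector of phenotype columns; defaults to all
#'   numeric columns except `subject_id`.
#' @return tibble with `size_parameter`, `variable`, `n`, `estimate`,
#'   `statistic`, `p`, `p_adjusted`, `method`, `tested`; attribute
#'   `family_size` records `m`.
#' @export
correlation_matrix <- function(sizes, phenotypes, variables = NULL) {
  if (is.null(variables)) {
    num <- vapply(phenotypes, is.numeric, logical(1))
    variables <- setdiff(names(phenotypes)[num], "subject_id")
  }
  params <- unique(sizes$parameter)
  rows <- list()
  for (p in params) {
    sp <- sizes[sizes$parameter == p, c("subject_id", "mean")]
    joined <- dplyr::inner_join(sp, phenotypes, by = "subject_id")
    for (v in variables) {
      x <- joined$mean
      y <- joined[[v]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          size_parameter = p, variable = v, n = n, estimate = NA_real_,
          statistic = NA_real_, p = NA_real_, method = "pearson",
          tested = FALSE
        )
      } else {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          size_parameter = p, variable = v, n = n,
          estimate = unname(ct$estimate), statistic = unname(ct$statistic),
          p = ct$p.value, method = "pearson", tested = TRUE
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  m <- sum(out$tested)
  out$p_adjusted <- ifelse(out$tested, pmin(1, m * out$p), NA_real_)
  out <- out[, c("size_parameter", "variable", "n", "estimate", "statistic",
                 "p", "p_adjusted", "method", "tested")]
  attr(out, "family_size") <- m
  out
}

#' BMI-adjusted multiple linear regression
#'
#' Ordinary least squares of a response (subject mean size, or a respiratory
#' state) on BMI and optional further covariates, used to check whether a
#' size–phenotype association survives adjustment for body mass. Categorical
#' covariates `sex` and `t2d` are coded 0/1 with `female` and `no` (non-T2D)
#' as reference levels. Complete-case analysis per model.
#'
#' @param data tibble containing the response and covariates.
#' @param response name of the response column.
#' @param covariates character vector of covariate column names.
#' @return tibble with one row per coefficient: `response`, `term`,
#'   `estimate`, `se`, `statistic`, `p`, `n` (complete cases used).
#' @export
adjusted_regression <- function(data, response, covariates) {
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  df <- data[, c(response, covariates)]
  if ("sex" %in% covariates) {
    df$sex <- as.integer(factor(df$sex, levels = c("female", "male"))) - 1L
  }
  if ("t2d" %in% covariates) {
    t <- as.character(df$t2d)
    t[t == "unknown"] <- NA
    df$t2d <- as.integer(factor(t, levels = c("no", "yes"))) - 1L
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(covariates) + 2) {
    stop("too few complete cases for the requested model", call. = FALSE)
  }
  X <- as.matrix(cbind(`(Intercept)` = 1, df[, covariates, drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fml <- stats::reformulate(covariates, response = response)
  fit <- stats::lm(fml, data = df)
  cf <- summary(fit)$coefficients
  tibble::tibble(
    response = response,
    term = rownames(cf),
    estimate = unname(cf[, 1]),
    se = unname(cf[, 2]),
    statistic = unname(cf[, 3]),
    p = unname(cf[, 4]),
    n = nrow(df)
  )
}

#' Respirometry vs adipocyte size associations
#'
#' Pearson correlations between each mitochondrial respiratory state (free
#' OXPHOS, OXPHOS, ETS capacity, leak respiration; pmol O2 s^-1 ng DNA^-1)
#' and subject mean adipocyte diameter, per depot. These p values are
#' reported uncorrected — the respirometry subset is small and each state is
#' a separate a priori question — unlike the phenotype matrix, which is
#' Bonferroni corrected. When `phenotypes` (with a `bmi` column) is supplied,
#' a BMI-adjusted regression of each state on diameter + BMI is appended.
#'
#' @param respirometry tibble with `subject_id`, `depot`, and state columns
#'   `free_oxphos`, `oxphos`, `ets`, `leak`.
#' @param sizes tibble of subject mean diameters with `subject_id`, `depot`,
#'   `mean`.
#' @param phenotypes optional tibble with `subject_id`, `bmi`.
#' @param states state columns to test.
#' @return tibble in the [correlation_matrix()] row format, method
#'   `"pearson"` for correlations and `"ols"` for adjusted diameter
#'   coefficients.
#' @export
respirometry_associations <- function(respirometry, sizes, phenotypes = NULL,
                                      states = c("free_oxphos", "oxphos",
                                                 "ets", "leak")) {
  rows <- list()
  for (dep in unique(respirometry$depot)) {
    r_d <- respirometry[respirometry$depot == dep, , drop = FALSE]
    s_d <- sizes[sizes$depot == dep, c("subject_id", "mean")]
    joined <- dplyr::inner_join(r_d, s_d, by = "subject_id")
    if (nrow(joined) < 3) {
      stop(sprintf("fewer than 3 joined subjects in depot '%s'", dep),
           call. = FALSE)
    }
    if (!is.null(phenotypes)) {
      joined <- dplyr::left_join(joined,
                                 phenotypes[, c("subject_id", "bmi")],
                                 by = "subject_id")
    }
    for (st in states) {
      ok <- is.finite(joined[[st]]) & is.finite(joined$mean)
      n <- sum(ok)
      if (n < 3 || stats::sd(joined[[st]][ok]) == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          depot = dep, size_parameter = "diameter", variable = st, n = n,
          estimate = NA_real_, statistic = NA_real_, p = NA_real_,
          p_adjusted = NA_real_, method = "pearson", tested = FALSE
        )
        next
      }
      ct <- stats::cor.test(joined$mean[ok], joined[[st]][ok])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        depot = dep, size_parameter = "diameter", variable = st, n = n,
        estimate = unname(ct$estimate), statistic = unname(ct$statistic),
        p = ct$p.value, p_adjusted = ct$p.value, method = "pearson",
        tested = TRUE
      )
      if (!is.null(phenotypes)) {
        dat <- joined[ok, , drop = FALSE]
        dat$diameter <- dat$mean
        reg <- tryCatch(
          adjusted_regression(dat, st, c("diameter", "bmi")),
          error = function(e) NULL
        )
        if (!is.null(reg)) {
          dia <- reg[reg$term == "diameter", , drop = FALSE]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            depot = dep, size_parameter = "diameter",
            variable = paste0(st, "_bmi_adjusted"), n = dia$n,
            estimate = dia$estimate, statistic = dia$statistic, p = dia$p,
            p_adjusted = dia$p, method = "ols", tested = TRUE
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Sensitivity of subject mean diameter to the sampled cell count
#'
#' Per-subject mean sizes are computed from a fixed random sample of cells;
#' requiring many cells excludes subjects with little tissue. This analysis
#' quantifies how much the subject means move when the sample is reduced:
#' for every subject × depot with at least `k_full` cells it draws `k_full`
#' cells, then a nested random subset of `k_reduced` of those same cells, and
#' correlates the two mean vectors across subjects. Under the nested design
#' the expected correlation is
#' \eqn{\sqrt{(\sigma_b^2 + \sigma_w^2/k_{full}) / (\sigma_b^2 + \sigma_w^2/k_{red})}}
#' for between/within-subject variances \eqn{\sigma_b^2, \sigma_w^2}.
#'
#' @inheritParams pooled_panel
#' @param k_full,k_reduced full and reduced cell counts (defaults 500 / 200).
#' @return list with `r`, `p`, `n_subjects`, and `table` of per-subject means.
#' @export
cell_count_sensitivity <- function(cells, parameter = "diameter",
                                   k_full = 500, k_reduced = 200, seed = 1,
                                   method = "histology",
                                   filter_bounds = c(200, 16000)) {
  stopifnot(k_reduced <= k_full)
  cells <- validate_cells(cells)
  depots <- unique(cells$depot[cells$method == method])
  per <- list()
  for (dep in depots) {
    vals <- subject_values(cells, dep, method, parameter, filter_bounds)
    counts <- vapply(vals, length, integer(1))
    keep <- names(vals)[counts >= k_full]
    if (!length(keep)) next
    res <- withr::with_seed(seed + match(dep, depots), {
      lapply(vals[keep], function(v) {
        full <- v[sample.int(length(v), k_full)]
        reduced <- full[sample.int(k_full, k_reduced)]
        c(mean(full), mean(reduced))
      })
    })
    per[[dep]] <- tibble::tibble(
      subject_id = keep, depot = dep,
      mean_full = vapply(res, `[`, numeric(1), 1),
      mean_reduced = vapply(res, `[`, numeric(1), 2)
    )
  }
  tab <- dplyr::bind_rows(per)
  if (nrow(tab) < 3) stop("fewer than 3 subjects qualify", call. = FALSE)
  if (identical(k_full, k_reduced) || stats::sd(tab$mean_full - tab$mean_reduced) == 0) {
    return(list(r = 1, p = 0, n_subjects = nrow(tab), table = tab))
  }
  ct <- stats::cor.test(tab$mean_full, tab$mean_reduced)
  list(r = unname(ct$estimate), p = ct$p.value, n_subjects = nrow(tab),
       table = tab)
}

#' Simulation of the 500-vs-200-cell sensitivity analysis
#'
#' Standalone simulation of the nested-subsampling design at published
#' subject-level diameter statistics: subject mean diameters are drawn
#' Normal(`mu_between`, `sd_between`), each subject receives `k_full` cell
#' diameters Normal(subject mean, `sd_within`), and per replicate the Pearson
#' correlation between means of the full sample and a nested `k_reduced`
#' subset is computed across subjects. The default within-subject SD of 29 µm
#' makes the per-subject interdecile range ~74.6 µm under normality
#' (IDR = 2.5631 sigma). Returns per-replicate correlations and their mean.
#'
#' @param n_subjects subjects per replicate.
#' @param mu_between,sd_between mean and SD of subject mean diameters (µm).
#' @param sd_within within-subject cell diameter SD (µm).
#' @param k_full,k_reduced full and nested sample sizes.
#' @param replicates number of seeded replicates.
#' @param seed integer seed.
#' @return list with `mean_r`, `r` (per replicate), `expected_r` (analytic
#'   value under the nested design), `n_subjects`.
#' @export
cell_count_sensitivity_sim <- function(n_subjects = 146, mu_between = 59.6,
                                       sd_between = 7.8, sd_within = 29,
                                       k_full = 500, k_reduced = 200,
                                       replicates = 100, seed = 1) {
  r <- withr::with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      mu <- stats::rnorm(n_subjects, mu_between, sd_between)
      cells <- matrix(stats::rnorm(n_subjects * k_full, mu, sd_within),
                      nrow = n_subjects)
      idx <- sample.int(k_full, k_reduced)
      stats::cor(rowMeans(cells), rowMeans(cells[, idx, drop = FALSE]))
    }, numeric(1))
  })
  vb <- sd_between^2
  vw <- sd_within^2
  expected <- (vb + vw / k_full) /
    sqrt((vb + vw / k_full) * (vb + vw / k_reduced))
  list(mean_r = mean(r), r = r, expected_r = expected,
       n_subjects = n_subjects)
}
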