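# Brute-force re-implementations of the descriptor definitions, written as
# explicit loops so they stay independent of the package's vectorized code.

brute_moment <- function(x, j) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^j
  s / length(x)
}

brute_quantile_type7 <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

brute_panel <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  m2 <- brute_moment(x, 2)
  list(
    mean = m,
    median = brute_quantile_type7(x, 0.5),
    d1 = brute_quantile_type7(x, 0.1),
    d9 = brute_quantile_type7(x, 0.9),
    idr = brute_quantile_type7(x, 0.9) - brute_quantile_type7(x, 0.1),
    skewness = brute_moment(x, 3) / m2^1.5,
    kurtosis = brute_moment(x, 4) / m2^2
  )
}

# Minimal long cell table: one subject/depot/method with given values.
make_cells <- function(values, subject_id = "S1", depot = "sc",
                       method = "histology", parameter = "area") {
  unit <- switch(parameter, area = "um2", diameter = "um", volume = "pl",
                 surface = "um2")
  tibble::tibble(
    subject_id = subject_id, depot = depot, method = method,
    parameter = parameter, value = values, unit = unit
  )
}

# Multi-subject histology table: one row block per subject, lognormal areas.
make_cohort_cells <- function(n_subjects, n_cells, meanlog = 8, sdlog = 0.35,
                              depot = "sc", seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
      make_cells(
        pmin(pmax(stats::rlnorm(n_cells, meanlog, sdlog), 201), 15999),
        subject_id = sprintf("S%02d", i), depot = depot
      )
    }))
  })
}

# Down-scaled generator configuration for fast pipeline tests.
small_config <- function() {
  synthetic_config(overrides = list(
    n_subjects = 30,
    n_male = 9,
    availability = list(
      sc_histology = 26, vc_histology = 30,
      sc_collagenase = 14, vc_collagenase = 16,
      sc_respirometry = 6, vc_respirometry = 8
    ),
    histology = {
      h <- synthetic_config()$histology
      h$cells_per_subject <- 120
      h
    },
    collagenase = {
      cc <- synthetic_config()$collagenase
      cc$cells_per_subject <- 40
      cc
    }
  ))
}
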