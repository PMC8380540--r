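#' Distribution descriptor panel for a sample of cell sizes
#'
#' Adipocyte size distributions are often strongly right-skewed, so a mean or
#' median alone misrepresents the cell population. `describe_distribution()`
#' computes the full descriptor panel: sample size, arithmetic mean, median,
#' first and ninth deciles, interdecile range (IDR, a tail-robust dispersion
#' measure), skewness, kurtosis, modal size, and an optional Shapiro-Wilk
#' normality test.
#'
#' Conventions, fixed so results are bit-stable:
#' * quantiles by linear interpolation of order statistics,
#'   \eqn{h = (n-1)p + 1} (R's default type 7);
#' * skewness \eqn{g_1 = m_3 / m_2^{3/2}} and Pearson kurtosis
#'   \eqn{m_4 / m_2^2} (normal \eqn{\to} 3), with central moments
#'   \eqn{m_j = \frac{1}{n}\sum (x_i - \bar x)^j};
#' * mode as the argmax of a Gaussian kernel density estimate with Silverman's
#'   bandwidth on a 512-point grid over \[min, max\].
#'
#' Skewness and kurtosis are invariant under positive linear rescaling, which
#' is why cross-sectional area and surface area (= 4 × area) always share
#' identical shape statistics. A zero-variance sample yields `NA` skewness and
#' kurtosis, and the mode equals the constant value.
#'
#' @param values numeric vector of sizes (all one parameter and unit).
#' @param units unit label carried into the result (e.g. `"um2"`, `"um"`,
#'   `"pl"`).
#' @param shapiro compute the Shapiro-Wilk test? Only valid for
#'   \eqn{3 \le n \le 5000}; larger samples must be subsampled first (see
#'   [normality_test()]).
#' @return a one-row tibble with columns `n`, `mean`, `median`, `d1`, `d9`,
#'   `idr`, `skewness`, `kurtosis`, `mode`, `shapiro_w`, `shapiro_p`, `units`.
#' @examples
#' describe_distribution(c(0, 0, 0, 1))$skewness # 1.1547
#' @export
describe_distribution <- function(values, units = NA_character_, shapiro = FALSE) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("values must be finite numeric", call. = FALSE)
  }
  n <- length(values)
  if (n < 3) stop("need at least 3 values to describe a distribution", call. = FALSE)
  if (n < 10) {
    warning("deciles are unstable below n = 10", call. = FALSE)
  }
  m <- mean(values)
  dev <- values - m
  m2 <- mean(dev^2)
  if (m2 > 0) {
    skew <- mean(dev^3) / m2^1.5
    kurt <- mean(dev^4) / m2^2
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  q <- stats::quantile(values, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  sw <- c(NA_real_, NA_real_)
  if (shapiro) {
    t <- normality_test(values)
    sw <- c(t$statistic, t$p.value)
  }
  tibble::tibble(
    n = n,
    mean = m,
    median = q[2],
    d1 = q[1],
    d9 = q[3],
    idr = interdecile_range(q[1], q[3]),
    skewness = skew,
    kurtosis = kurt,
    mode = modal_size(values),
    shapiro_w = sw[1],
    shapiro_p = sw[2],
    units = units
  )
}

#' Interdecile range
#'
#' The difference between the ninth and first decile, used as a dispersion
#' measure that is robust to the long right tail of adipocyte area and volume
#' distributions. Because the IDR is linear in the deciles, the cohort mean of
#' per-subject IDRs equals the difference of the cohort mean deciles.
#'
#' @param d1,d9 first and ninth decile (same units).
#' @return `d9 - d1`.
#' @examples
#' interdecile_range(443.2, 7726.3) # 7283.1
#' @export
interdecile_range <- function(d1, d9) {
  if (any(d9 < d1)) {
    stop("ninth decile below first decile: quantiles are inconsistent", call. = FALSE)
  }
  d9 - d1
}

#' Modal size of a sample
#'
#' The most frequent cell size, estimated as the argmax of a Gaussian kernel
#' density estimate (Silverman's rule-of-thumb bandwidth, 512-point grid over
#' the sample range). For right-skewed distributions the mode lies below the
#' median and mean and better represents the bulk of the cell population.
#'
#' @param values numeric sample, `n >= 10` recommended.
#' @return the location of the density maximum; for a zero-variance sample,
#'   the constant value itself.
#' @export
modal_size <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("values must be finite numeric", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    return(values[1])
  }
  d <- stats::density(values, bw = "nrd0", n = 512,
                      from = min(values), to = max(values))
  d$x[which.max(d$y)]
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with the pipeline's size
#' contract made explicit: the test is defined for \eqn{3 \le n \le 5000}.
#' Pooled cohort samples routinely exceed 5000 values; subsample them first
#' (as [pooled_panel()] does, with a seeded draw and a logged note) rather
#' than testing the full pool.
#'
#' @param values numeric sample.
#' @return the `htest` object from [stats::shapiro.test()].
#' @export
normality_test <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop(sprintf(
      "Shapiro-Wilk requires 3 <= n <= 5000 (got %d); subsample larger pools",
      n
    ), call. = FALSE)
  }
  stats::shapiro.test(values)
}

#' Normal quantile-quantile table
#'
#' Returns the points of a normal QQ plot as data rather than a drawing:
#' theoretical quantiles at plotting positions \eqn{(i - 0.5)/n} against the
#' standardized, sorted sample. Right-skewed samples show a convex departure
#' (upper-tail sample quantiles above the theoretical line).
#'
#' @param values numeric sample, `n >= 3`.
#' @return tibble with `theoretical` and `sample` columns, one row per value.
#' @export
qq_points <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values for a QQ table", call. = FALSE)
  s <- stats::sd(values)
  z <- if (s > 0) (sort(values) - mean(values)) / s else sort(values) * 0
  tibble::tibble(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = z
  )
}

#' Fixed-width histogram table
#'
#' @param values numeric sample.
#' @param binwidth bin width in the sample's units (defaults: 250 µm² for
#'   areas, 2.5 µm for diameters — see [default_binwidth()]).
#' @return tibble with `bin_mid`, `count`, `density` per bin.
#' @export
histogram_table <- function(values, binwidth) {
  lo <- floor(min(values) / binwidth) * binwidth
  hi <- ceiling(max(values) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  tibble::tibble(bin_mid = h$mids, count = h$counts, density = h$density)
}

#' Default histogram bin width per sizing parameter
#'
#' @param parameter one of `"area"`, `"diameter"`, `"volume"`, `"surface"`.
#' @return bin width in the parameter's units.
#' @export
default_binwidth <- function(parameter) {
  switch(match.arg(parameter, c("area", "diameter", "volume", "surface")),
    area = 250, diameter = 2.5, volume = 25, surface = 1000
  )
}

#' Kernel density table
#'
#' @param values numeric sample.
#' @param n grid size.
#' @return tibble with `x` and `density`.
#' @export
density_table <- function(values, n = 512) {
  d <- stats::density(values, bw = "nrd0", n = n)
  tibble::tibble(x = d$x, density = d$y)
}

unit_of <- function(parameter) {
  switch(parameter, area = "um2", diameter = "um", volume = "pl",
         surface = "um2")
}

# Split a long cell table into per-subject value vectors for one
# depot/method/parameter, applying the histology artifact filter and the
# spherical conversion to the requested parameter.
subject_values <- function(cells, depot, method, parameter,
                           filter_bounds = c(200, 16000)) {
  cells <- validate_cells(cells)
  sel <- cells[cells$depot == depot & cells$method == method, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop(sprintf("no cells for depot '%s', method '%s'", depot, method),
         call. = FALSE)
  }
  native <- unique(sel$parameter)
  if (length(native) != 1) {
    stop("cell table mixes sizing parameters within one depot/method",
         call. = FALSE)
  }
  vals <- split(sel$value, sel$subject_id, drop = TRUE)
  excluded_low <- 0L
  excluded_high <- 0L
  if (method == "histology" && native == "area" && !is.null(filter_bounds)) {
    vals <- lapply(vals, function(v) {
      f <- filter_histology_areas(v, filter_bounds[1], filter_bounds[2])
      excluded_low <<- excluded_low + f$n_excluded_low
      excluded_high <<- excluded_high + f$n_excluded_high
      f$kept
    })
  }
  vals <- lapply(vals, convert_size, from = native, to = parameter)
  attr(vals, "n_excluded_low") <- excluded_low
  attr(vals, "n_excluded_high") <- excluded_high
  vals
}

#' Pooled cohort distribution panel
#'
#' Builds the cohort-level distribution for one depot, method and sizing
#' parameter with every subject equally represented: exactly `k` cells are
#' sampled (without replacement, seeded) from each subject with at least `k`
#' cells, concatenated, and described. Subjects with fewer than `k` cells are
#' excluded and named in the result so the attrition is auditable. Pools
#' larger than 5000 values are subsampled (seeded) for the Shapiro-Wilk test
#' only; all other descriptors use the full pool.
#'
#' @param cells long cell table (see [read_cells()] for the schema).
#' @param depot `"sc"` or `"vc"`.
#' @param method `"histology"` or `"collagenase"`.
#' @param parameter sizing parameter to describe; histology areas are
#'   converted on the fly.
#' @param k cells per subject.
#' @param seed integer seed controlling the per-subject draws.
#' @param filter_bounds inclusive histology area retention window in µm², or
#'   `NULL` to skip filtering.
#' @return a list with `pooled` (tibble of subject_id/value), `panel`
#'   (descriptor row), `histogram`, `density`, `retained`, `excluded`.
#' @export
pooled_panel <- function(cells, depot, method, parameter, k, seed,
                         filter_bounds = c(200, 16000)) {
  vals <- subject_values(cells, depot, method, parameter, filter_bounds)
  counts <- vapply(vals, length, integer(1))
  retained <- names(vals)[counts >= k]
  excluded <- names(vals)[counts < k]
  if (length(excluded)) {
    message(sprintf(
      "pooled_panel: excluding %d subject(s) with < %d cells: %s",
      length(excluded), k, paste(excluded, collapse = ", ")
    ))
  }
  if (!length(retained)) {
    stop(sprintf("no subject has >= %d cells", k), call. = FALSE)
  }
  sampled <- withr::with_seed(seed, {
    lapply(vals[retained], function(v) v[sample.int(length(v), k)])
  })
  pooled <- tibble::tibble(
    subject_id = rep(retained, each = k),
    value = unlist(sampled, use.names = FALSE)
  )
  test_values <- pooled$value
  if (length(test_values) > 5000) {
    message(sprintf(
      "pooled_panel: subsampling %d pooled values to 5000 for Shapiro-Wilk",
      length(test_values)
    ))
    test_values <- sample_cells(test_values, 5000, seed = seed)
  }
  panel <- describe_distribution(pooled$value, units = unit_of(parameter))
  sw <- normality_test(test_values)
  panel$shapiro_w <- unname(sw$statistic)
  panel$shapiro_p <- sw$p.value
  list(
    pooled = pooled,
    panel = tibble::tibble(depot = depot, method = method,
                           parameter = parameter, panel),
    histogram = histogram_table(pooled$value, default_binwidth(parameter)),
    density = density_table(pooled$value),
    retained = retained,
    excluded = excluded
  )
}

#' Per-subject descriptor panels and cohort summary
#'
#' Computes one descriptor panel per subject × depot × method from `k`
#' sampled cells each, then summarises the cohort as the arithmetic mean and
#' SD of every descriptor across subjects — the form in which cohort tables
#' of adipocyte size are conventionally reported.
#'
#' @inheritParams pooled_panel
#' @param shapiro run the per-subject Shapiro-Wilk test (requires
#'   \eqn{k \le 5000}).
#' @return list with `panels` (one row per subject × depot × method) and
#'   `summary` (mean ± SD of each descriptor by depot × method).
#' @export
per_subject_panels <- function(cells, parameter, k, seed,
                               filter_bounds = c(200, 16000),
                               shapiro = TRUE) {
  cells <- validate_cells(cells)
  combos <- unique(cells[, c("depot", "method")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    depot <- combos$depot[i]
    method <- combos$method[i]
    kk <- if (is.list(k)) k[[method]] else k
    vals <- subject_values(cells, depot, method, parameter, filter_bounds)
    counts <- vapply(vals, length, integer(1))
    keep <- names(vals)[counts >= kk]
    if (!length(keep)) next
    sampled <- withr::with_seed(seed + i, {
      lapply(vals[keep], function(v) v[sample.int(length(v), kk)])
    })
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(lapply(keep, function(s) {
      tibble::tibble(
        subject_id = s, depot = depot, method = method, parameter = parameter,
        describe_distribution(sampled[[s]], units = unit_of(parameter),
                              shapiro = shapiro)
      )
    }))
  }
  if (!length(rows)) stop("no subject qualifies in any depot/method", call. = FALSE)
  panels <- dplyr::bind_rows(rows)
  descriptors <- c("mean", "median", "d1", "d9", "idr", "skewness",
                   "kurtosis", "mode")
  summary <- panels |>
    tidyr::pivot_longer(dplyr::all_of(descriptors),
                        names_to = "descriptor", values_to = "value") |>
    dplyr::group_by(.data$depot, .data$method, .data$parameter,
                    .data$descriptor) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      cohort_mean = mean(.data$value),
      cohort_sd = stats::sd(.data$value),
      .groups = "drop"
    )
  list(panels = panels, summary = summary)
}
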