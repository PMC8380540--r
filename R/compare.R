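#' Pair subject mean sizes measured by two methods
#'
#' Inner-joins subject-level mean diameters from histology and collagenase
#' digestion. With `pool_depots = TRUE` (the conventional choice for method
#' comparison) each subject × depot combination contributes one observation,
#' so a subject measured in both depots appears twice.
#'
#' @param histology,collagenase tibbles with columns `subject_id`, `depot`,
#'   and a mean-size column named in `value_col`.
#' @param value_col name of the mean-size column in both inputs.
#' @param pool_depots keep sc and vc pairs as separate observations (`TRUE`)
#'   or restrict to a single depot already selected by the caller.
#' @return tibble with `subject_id`, `depot`, `histology`, `collagenase`.
#' @export
pair_subjects <- function(histology, collagenase, value_col = "mean",
                          pool_depots = TRUE) {
  keys <- c("subject_id", "depot")
  h <- histology[, c(keys, value_col)]
  c_ <- collagenase[, c(keys, value_col)]
  names(h)[3] <- "histology"
  names(c_)[3] <- "collagenase"
  paired <- dplyr::inner_join(h, c_, by = keys)
  if (!pool_depots && length(unique(paired$depot)) > 1) {
    stop("multiple depots present; set pool_depots = TRUE or pre-filter",
         call. = FALSE)
  }
  if (nrow(paired) == 0) {
    stop("no subject measured by both methods", call. = FALSE)
  }
  paired
}

#' Bland-Altman agreement between histology and collagenase mean diameters
#'
#' Classical method-agreement analysis on paired subject means: the bias is
#' the mean of the per-pair differences (fixed direction: histology minus
#' collagenase, so a histology method reading systematically smaller gives a
#' negative bias) and the limits of agreement are bias ± 1.96 × SD of the
#' differences. The bias equals the difference of the two sample means
#' exactly, and swapping the method order negates the bias and mirrors the
#' limits.
#'
#' @param paired output of [pair_subjects()].
#' @param loa_mult limit-of-agreement multiplier (1.96 for 95% limits).
#' @return list with `n_pairs`, `bias`, `sd_diff`, `loa_low`, `loa_high`, and
#'   `points` (tibble of pair means vs differences for plotting).
#' @examples
#' paired <- pair_subjects(
#'   tibble::tibble(subject_id = 1:3, depot = "sc", mean = c(50, 60, 70)),
#'   tibble::tibble(subject_id = 1:3, depot = "sc", mean = c(100, 106, 118))
#' )
#' bland_altman(paired) # bias -48, limits [-51.92, -44.08]
#' @export
bland_altman <- function(paired, loa_mult = 1.96) {
  if (nrow(paired) < 3) stop("need at least 3 pairs", call. = FALSE)
  diff <- paired$histology - paired$collagenase
  bias <- mean(diff)
  sd_diff <- stats::sd(diff)
  list(
    n_pairs = nrow(paired),
    bias = bias,
    sd_diff = sd_diff,
    loa_low = bias - loa_mult * sd_diff,
    loa_high = bias + loa_mult * sd_diff,
    points = tibble::tibble(
      subject_id = paired$subject_id,
      depot = paired$depot,
      pair_mean = (paired$histology + paired$collagenase) / 2,
      difference = diff
    )
  )
}

#' Pearson concordance between paired method means
#'
#' @param paired output of [pair_subjects()].
#' @param ... passed on to [stats::cor.test()].
#' @return list with `n_pairs`, `r`, `p` (two-sided, from the t statistic
#'   \eqn{t = r\sqrt{(n-2)/(1-r^2)}}); `r` is `NA` when either method has zero
#'   variance.
#' @export
method_concordance <- function(paired, ...) {
  if (nrow(paired) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(paired$histology) == 0 || stats::sd(paired$collagenase) == 0) {
    return(list(n_pairs = nrow(paired), r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(paired$histology, paired$collagenase,
                        method = "pearson", ...)
  list(n_pairs = nrow(paired), r = unname(ct$estimate), p = ct$p.value)
}
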