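test_that("descriptor panel matches hand-computed moment values", {
  p <- suppressWarnings(describe_distribution(c(1, 2, 3)))
  expect_equal(p$mean, 2)
  expect_equal(p$median, 2)
  expect_equal(p$skewness, 0)

  p <- suppressWarnings(describe_distribution(c(0, 0, 0, 1)))
  expect_equal(p$skewness, 0.09375 / 0.1875^1.5, tolerance = 1e-12)
  expect_equal(p$skewness, 1.1547005, tolerance = 1e-7)
  expect_equal(p$kurtosis, 7 / 3, tolerance = 1e-12)

  p <- suppressWarnings(describe_distribution(c(-1, 1, -1, 1)))
  expect_equal(p$kurtosis, 1)
  expect_equal(p$skewness, 0)

  expect_error(describe_distribution(c(1, 2)), "at least 3")
  expect_warning(describe_distribution(c(1, 2, 3)), "deciles")
})

test_that("kurtosis of a large normal sample is near 3 (Pearson convention)", {
  x <- withr::with_seed(101, stats::rnorm(1e5))
  expect_equal(describe_distribution(x)$kurtosis, 3, tolerance = 0.05 / 3)
})

test_that("descriptors agree with a brute-force oracle on small samples", {
  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(10:50, 1))
    x <- withr::with_seed(seed + 100, stats::rlnorm(n, 8, 0.5))
    p <- describe_distribution(x)
    o <- brute_panel(x)
    for (f in names(o)) {
      expect_equal(p[[f]], o[[f]], tolerance = 1e-10,
                   label = sprintf("%s (seed %d)", f, seed))
    }
  }
})

test_that("skewness and kurtosis match the e1071 moment estimators", {
  x <- withr::with_seed(77, stats::rlnorm(300, 8, 0.4))
  p <- describe_distribution(x)
  expect_equal(p$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(p$kurtosis, e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
})

test_that("shape statistics are invariant under positive rescaling", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, stats::rlnorm(200, 8, 0.35))
    p <- describe_distribution(x)
    for (c_ in c(4, 0.001, 273.15)) {
      q <- describe_distribution(c_ * x)
      expect_equal(q$skewness, p$skewness, tolerance = 1e-12)
      expect_equal(q$kurtosis, p$kurtosis, tolerance = 1e-12)
      # location statistics scale linearly
      expect_equal(q$mean, c_ * p$mean, tolerance = 1e-12)
      expect_equal(q$d1, c_ * p$d1, tolerance = 1e-12)
      expect_equal(q$d9, c_ * p$d9, tolerance = 1e-12)
      expect_equal(q$idr, c_ * p$idr, tolerance = 1e-12)
      expect_equal(q$mode, c_ * p$mode, tolerance = 1e-8)
    }
  }
})

test_that("zero-variance samples yield undefined shape, constant mode", {
  p <- describe_distribution(rep(5, 20))
  expect_true(is.na(p$skewness))
  expect_true(is.na(p$kurtosis))
  expect_equal(p$mode, 5)
  expect_equal(p$idr, 0)
})

test_that("interdecile range is the decile difference with ordering enforced", {
  expect_equal(interdecile_range(443.2, 7726.3), 7283.1)
  expect_error(interdecile_range(5, 4), "inconsistent")

  x <- 1:10
  p <- describe_distribution(x)
  expect_equal(p$d1, 1.9)
  expect_equal(p$d9, 9.1)
  expect_equal(p$idr, 7.2)
})

test_that("modal size finds the density peak", {
  expect_equal(modal_size(c(1, 2, 2, 3)), 2, tolerance = 0.05)
  x <- withr::with_seed(21, stats::rlnorm(5000, 8, 0.5))
  p <- describe_distribution(x)
  expect_lt(p$mode, p$median)
  expect_lt(p$median, p$mean)
})

test_that("normality test enforces the Shapiro-Wilk size range", {
  expect_error(normality_test(c(1, 2)), "3 <= n <= 5000")
  expect_error(normality_test(stats::rnorm(5001)), "subsample")
  lognormal_p <- withr::with_seed(31, {
    vapply(1:100, function(i) {
      normality_test(stats::rlnorm(500, 0, 0.35))$p.value
    }, numeric(1))
  })
  expect_true(all(lognormal_p < 0.001))
})

test_that("qq table uses (i - 0.5)/n positions and flags skewed tails", {
  expect_equal(nrow(qq_points(c(1, 2, 3))), 3)

  z <- stats::qnorm((seq_len(200) - 0.5) / 200)
  q <- qq_points(z)
  expect_equal(q$theoretical, z)
  expect_gt(stats::cor(q$theoretical, q$sample), 1 - 1e-9)
  expect_lt(max(abs(q$sample - q$theoretical)), 0.05)

  x <- withr::with_seed(13, stats::rlnorm(500, 0, 0.5))
  q <- qq_points(x)
  expect_gt(q$sample[500], q$theoretical[500]) # convex upper-tail departure
})

test_that("pooled panel equally represents retained subjects and logs exclusions", {
  cells <- make_cohort_cells(2, 60, seed = 2)
  res <- suppressMessages(pooled_panel(cells, "sc", "histology", "area",
                                       k = 60, seed = 1))
  expect_equal(nrow(res$pooled), 120)
  expect_equal(as.integer(table(res$pooled$subject_id)), c(60L, 60L))

  short <- dplyr::bind_rows(cells, make_cells(stats::runif(10, 300, 5000),
                                              subject_id = "S99"))
  expect_message(
    res <- pooled_panel(short, "sc", "histology", "area", k = 60, seed = 1),
    "S99"
  )
  expect_false("S99" %in% res$pooled$subject_id)
  expect_true("S99" %in% res$excluded)
  expect_error(
    suppressMessages(pooled_panel(cells, "sc", "histology", "area",
                                  k = 1000, seed = 1)),
    "no subject"
  )
})

test_that("pooled skewness tracks per-subject skewness for identical subjects", {
  skews <- withr::with_seed(51, {
    vapply(1:5, function(i) {
      cells <- make_cohort_cells(8, 200, meanlog = 8, sdlog = 0.35,
                                 seed = i + 60)
      res <- pooled_panel(cells, "sc", "histology", "area", k = 200, seed = i)
      per <- vapply(split(res$pooled$value, res$pooled$subject_id),
                    function(v) describe_distribution(v)$skewness, numeric(1))
      res$panel$skewness - mean(per)
    }, numeric(1))
  })
  expect_lt(mean(abs(skews)), 0.25)
})

test_that("per-subject panels aggregate by mean and SD with exact IDR linearity", {
  cells <- make_cohort_cells(6, 80, seed = 9)
  res <- per_subject_panels(cells, "area", k = 80, seed = 3, shapiro = FALSE)
  expect_equal(nrow(res$panels), 6)
  s <- res$summary
  expect_equal(
    s$cohort_mean[s$descriptor == "idr"],
    s$cohort_mean[s$descriptor == "d9"] - s$cohort_mean[s$descriptor == "d1"],
    tolerance = 1e-12
  )

  # identical subjects: SD of every descriptor is ~0
  one <- withr::with_seed(4, stats::rlnorm(50, 8, 0.3))
  same <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_cells(one, subject_id = paste0("T", i))
  }))
  res <- per_subject_panels(same, "area", k = 50, seed = 5, shapiro = FALSE)
  expect_true(all(res$summary$cohort_sd < 1e-9))
})
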