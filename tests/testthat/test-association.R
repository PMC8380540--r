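sizes_long <- function(ids, values, parameter = "diameter") {
  tibble::tibble(subject_id = ids, parameter = parameter, mean = values)
}

test_that("correlation matrix handles perfect, missing, and untested pairs", {
  ids <- sprintf("S%02d", 1:20)
  x <- withr::with_seed(1, stats::rnorm(20, 60, 8))
  phen <- tibble::tibble(
    subject_id = ids,
    same = x,
    allmiss = NA_real_,
    noisy = withr::with_seed(2, stats::rnorm(20))
  )
  out <- correlation_matrix(sizes_long(ids, x), phen)
  same_row <- out[out$variable == "same", ]
  expect_equal(same_row$estimate, 1, tolerance = 1e-12)
  expect_lt(same_row$p, 1e-12)

  miss_row <- out[out$variable == "allmiss", ]
  expect_false(miss_row$tested)
  expect_true(is.na(miss_row$estimate))

  # family size counts only tested pairs
  expect_equal(attr(out, "family_size"), 2)
  expect_equal(out$p_adjusted[out$tested], pmin(1, 2 * out$p[out$tested]))
})

test_that("pairwise-complete n matches a brute-force recount", {
  ids <- sprintf("S%02d", 1:30)
  x <- withr::with_seed(3, stats::rnorm(30))
  y <- withr::with_seed(4, stats::rnorm(30))
  y[c(2, 5, 11, 28)] <- NA
  out <- correlation_matrix(sizes_long(ids, x),
                            tibble::tibble(subject_id = ids, y = y))
  n_brute <- 0
  for (i in 1:30) if (!is.na(x[i]) && !is.na(y[i])) n_brute <- n_brute + 1
  expect_equal(out$n, n_brute)
  expect_equal(out$estimate, stats::cor(x, y, use = "pairwise.complete.obs"),
               tolerance = 1e-12)
})

test_that("Bonferroni adjustment is min(1, m*p) and monotone in p", {
  ids <- sprintf("S%02d", 1:25)
  x <- withr::with_seed(5, stats::rnorm(25))
  phen <- tibble::tibble(subject_id = ids)
  for (v in paste0("v", 1:6)) {
    phen[[v]] <- withr::with_seed(match(v, paste0("v", 1:6)) + 10,
                                  stats::rnorm(25))
  }
  out <- correlation_matrix(sizes_long(ids, x), phen)
  m <- attr(out, "family_size")
  expect_equal(m, 6)
  expect_equal(out$p_adjusted, pmin(1, m * out$p))
  o <- order(out$p)
  expect_true(all(diff(out$p_adjusted[o]) >= -1e-15))
})

test_that("association estimates are invariant to subject-row permutation", {
  ids <- sprintf("S%02d", 1:40)
  x <- withr::with_seed(6, stats::rnorm(40, 60, 8))
  phen <- tibble::tibble(subject_id = ids,
                         bmi = withr::with_seed(7, stats::rnorm(40, 40, 10)))
  a <- correlation_matrix(sizes_long(ids, x), phen)
  perm <- withr::with_seed(8, sample(40))
  b <- correlation_matrix(sizes_long(ids, x)[perm, ], phen)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("regression recovers exact and near-exact coefficients", {
  bmi <- seq(20, 60, length.out = 30)
  d <- tibble::tibble(y = 2 + 3 * bmi, bmi = bmi)
  fit <- suppressWarnings(adjusted_regression(d, "y", "bmi"))
  expect_equal(fit$estimate, c(2, 3), tolerance = 1e-10)

  # orthogonal two-covariate design with tiny noise
  x1 <- rep(c(-1, 1), 20)
  x2 <- rep(c(-1, -1, 1, 1), 10)
  y <- 1.5 - 2 * x1 + 0.75 * x2 +
    withr::with_seed(9, stats::rnorm(40, 0, 1e-5))
  fit <- adjusted_regression(tibble::tibble(y = y, x1 = x1, x2 = x2),
                             "y", c("x1", "x2"))
  expect_equal(fit$estimate, c(1.5, -2, 0.75), tolerance = 1e-3)

  expect_error(
    adjusted_regression(tibble::tibble(y = y, x1 = x1, x1b = 2 * x1),
                        "y", c("x1", "x1b")),
    "collinear.*x1b"
  )
})

test_that("standardized single-covariate regression equals the correlation", {
  x <- withr::with_seed(10, stats::rnorm(50))
  y <- withr::with_seed(11, 0.4 * x + stats::rnorm(50))
  sx <- (x - mean(x)) / stats::sd(x)
  sy <- (y - mean(y)) / stats::sd(y)
  fit <- adjusted_regression(tibble::tibble(y = sy, x = sx), "y", "x")
  expect_equal(fit$estimate[fit$term == "x"], stats::cor(x, y),
               tolerance = 1e-10)
})

test_that("categorical covariates are coded with female/non-T2D reference", {
  set.seed(12)
  d <- tibble::tibble(
    y = stats::rnorm(40, 60, 2),
    bmi = stats::rnorm(40, 40, 8),
    sex = rep(c("female", "male"), 20),
    t2d = rep(c("no", "no", "yes", "unknown"), 10)
  )
  d$y <- d$y + 5 * (d$sex == "male")
  fit <- adjusted_regression(d, "y", c("bmi", "sex", "t2d"))
  expect_equal(fit$n[1], 30) # unknown T2D rows dropped as incomplete
  expect_lt(abs(fit$estimate[fit$term == "sex"] - 5), 1.5)
})

test_that("respirometry associations recover signs and handle nulls", {
  ids <- sprintf("S%02d", 1:24)
  d <- withr::with_seed(13, stats::rnorm(24, 60, 8))
  sizes <- tibble::tibble(subject_id = ids, depot = "sc", mean = d)
  resp <- tibble::tibble(
    subject_id = ids, depot = "sc",
    free_oxphos = -d + 200, oxphos = -d + 210, ets = -d + 220,
    leak = withr::with_seed(14, stats::rnorm(24, 0.4, 0.1))
  )
  out <- respirometry_associations(resp, sizes)
  expect_equal(out$estimate[out$variable == "free_oxphos"], -1,
               tolerance = 1e-12)
  expect_equal(out$estimate[out$variable == "ets"], -1, tolerance = 1e-12)

  # permutation null: p values center on 0.5, |r| stays small on average
  rs <- withr::with_seed(15, {
    vapply(1:200, function(i) {
      shuf <- resp
      shuf$leak <- shuf$leak[sample(24)]
      out <- respirometry_associations(shuf, sizes, states = "leak")
      c(out$estimate, out$p)
    }, numeric(2))
  })
  expect_lt(mean(abs(rs[1, ])), 0.25)
  expect_gt(mean(rs[2, ]), 0.35)
  expect_lt(mean(rs[2, ]), 0.65)

  expect_error(respirometry_associations(resp[1:2, ], sizes), "fewer than 3")
})

test_that("cell-count sensitivity returns r = 1 in degenerate designs", {
  cells <- make_cohort_cells(6, 120, seed = 16)
  same <- cell_count_sensitivity(cells, "diameter", k_full = 100,
                                 k_reduced = 100, seed = 1)
  expect_equal(same$r, 1)

  const <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_cells(rep(1000 * i, 50), subject_id = paste0("C", i))
  }))
  res <- cell_count_sensitivity(const, "diameter", k_full = 50,
                                k_reduced = 20, seed = 1)
  expect_equal(res$r, 1)

  expect_error(cell_count_sensitivity(cells[1:100, ], k_full = 1000),
               "fewer than 3")
})

test_that("nested subsampling correlation matches the closed form", {
  sim <- cell_count_sensitivity_sim(n_subjects = 120, replicates = 30,
                                    seed = 5)
  vb <- 7.8^2
  vw <- 29^2
  expected <- sqrt((vb + vw / 500) / (vb + vw / 200))
  expect_equal(sim$expected_r, expected, tolerance = 1e-12)
  expect_equal(sim$mean_r, expected, tolerance = 0.02)
})
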