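# Truncated-normal helpers used by the cohort generator. The quantile map is
# the inverse-CDF of a Normal(mu, sd) restricted to [a, b].
qtnorm <- function(u, mu, sd, a, b) {
  pa <- stats::pnorm(a, mu, sd)
  pb <- stats::pnorm(b, mu, sd)
  stats::qnorm(pa + u * (pb - pa), mu, sd)
}

tnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

# Location parameter such that the truncated-normal mean equals `target`.
# Truncation shifts the mean toward the middle of [a, b]; this small
# recentering keeps the generated marginal means on the configured values.
tnorm_recenter <- function(target, sd, a, b) {
  stats::uniroot(function(mu) tnorm_mean(mu, sd, a, b) - target,
                 interval = c(target - 2 * sd, target + 2 * sd),
                 tol = 1e-10)$root
}

# Lognormal calibration: within-subject log-scale SD solved from the target
# per-subject skewness via skew = (w + 2) * sqrt(w - 1), w = exp(s^2);
# between-subject log-scale SD from the coefficient of variation of subject
# mean sizes; location from the target cohort mean.
lognormal_sigma_from_skew <- function(skew) {
  stats::uniroot(function(s) {
    w <- exp(s^2)
    (w + 2) * sqrt(w - 1) - skew
  }, interval = c(0.01, 1.5), tol = 1e-10)$root
}

calibrate_histology <- function(mean_area, sd_mean_area, skewness) {
  sigma_w <- lognormal_sigma_from_skew(skewness)
  sigma_b <- sqrt(log(1 + (sd_mean_area / mean_area)^2))
  mu <- log(mean_area) - sigma_w^2 / 2 - sigma_b^2 / 2
  list(mu = mu, sigma_b = sigma_b, sigma_w = sigma_w)
}

#' Configuration of the synthetic adipocyte-size cohort
#'
#' Bundles every generator parameter with defaults calibrated to the
#' published cohort: marginal phenotype distributions (truncated normals with
#' the printed mean, SD and range), per-variable missingness chosen to
#' reproduce the printed per-variable sample sizes, per-depot histology and
#' collagenase availability, cell-level distribution families, and the
#' subject-level coupling structure (a Gaussian copula correlation matrix
#' over phenotypes and latent depot size factors).
#'
#' Cell-level defaults: histology cross-sectional areas are truncated
#' lognormal (right-skewed, strictly positive — the simplest family matching
#' the observed positive skew), with within-subject log-SD solved from the
#' target per-subject skewness (1.1 sc / 1.3 vc), between-subject log-SD from
#' the CV of subject mean areas, and truncation at the artifact filter window
#' so the filter is exercised on in-range data. Collagenase diameters are
#' normal per subject, with the subject mean affinely linked to the latent
#' size factor at the configured inter-method correlation.
#'
#' Respirometry state means and SDs (pmol O2 s^-1 ng DNA^-1) are synthetic
#' plausible values — the source cohort's respirometry scale is not published
#' — while the size couplings use published correlation values.
#'
#' @param n_subjects cohort size.
#' @param seed_default default seed used by [simulate_cohort()].
#' @param overrides named list of components to replace (advanced use; the
#'   result is re-validated).
#' @return a `synthetic_config` list, validated (positive SDs, correlations
#'   in (-1, 1), positive semi-definite copula matrix).
#' @export
synthetic_config <- function(n_subjects = 188, seed_default = 1,
                             overrides = list()) {
  marginals <- list(
    age          = list(mean = 48,   sd = 13,   min = 18,   max = 78,   n_obs = 188),
    bmi          = list(mean = 43.6, sd = 13.3, min = 18.2, max = 83.3, n_obs = 184),
    glucose      = list(mean = 6.0,  sd = 3.0,  min = 2.2,  max = 22.1, n_obs = 139),
    hba1c        = list(mean = 6.0,  sd = 1.2,  min = 4.6,  max = 11.5, n_obs = 99),
    cholesterol  = list(mean = 5.1,  sd = 1.0,  min = 1.4,  max = 8.0,  n_obs = 97),
    ldl          = list(mean = 3.1,  sd = 0.8,  min = 1.3,  max = 5.3,  n_obs = 92),
    hdl          = list(mean = 1.3,  sd = 0.4,  min = 0.6,  max = 2.4,  n_obs = 94),
    triglycerides = list(mean = 1.9, sd = 1.0,  min = 0.6,  max = 6.8,  n_obs = 96)
  )
  vars <- c(names(marginals), "sex", "t2d", "size_sc", "size_vc")
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  # background clinical structure (plausible, not fitted to the source data)
  set_r("glucose", "hba1c", 0.6)
  set_r("cholesterol", "ldl", 0.85)
  set_r("cholesterol", "hdl", 0.15)
  set_r("cholesterol", "triglycerides", 0.3)
  set_r("ldl", "triglycerides", 0.2)
  set_r("hdl", "triglycerides", -0.3)
  set_r("bmi", "glucose", 0.2)
  set_r("bmi", "hba1c", 0.2)
  set_r("bmi", "hdl", -0.2)
  set_r("bmi", "triglycerides", 0.15)
  set_r("age", "glucose", 0.15)
  set_r("age", "hba1c", 0.15)
  set_r("t2d", "glucose", 0.5)
  set_r("t2d", "hba1c", 0.6)
  set_r("t2d", "bmi", 0.15)
  set_r("sex", "hdl", -0.3)
  # size couplings: BMI in both depots; lab values in the visceral depot only
  set_r("size_sc", "size_vc", 0.7)
  set_r("size_sc", "bmi", 0.47)
  set_r("size_vc", "bmi", 0.47)
  set_r("size_vc", "glucose", 0.26)
  set_r("size_vc", "hba1c", 0.31)
  set_r("size_vc", "hdl", -0.32)
  set_r("size_vc", "t2d", 0.25)
  set_r("size_vc", "sex", 0.2)
  set_r("size_vc", "age", 0.15)

  config <- list(
    n_subjects = n_subjects,
    seed_default = seed_default,
    marginals = marginals,
    n_male = 59,
    t2d_prevalence = 45 / 185,
    n_t2d_unknown = 3,
    latent_correlation = R,
    availability = list(
      sc_histology = 161, vc_histology = 188,
      sc_collagenase = 84, vc_collagenase = 97,
      sc_respirometry = 24, vc_respirometry = 35
    ),
    histology = list(
      sc = calibrate_histology(3472.0, 886.8, 1.1),
      vc = calibrate_histology(2748.8, 863.6, 1.3),
      cells_per_subject = 550,
      area_bounds = c(200, 16000)
    ),
    collagenase = list(
      sc = list(mean = 105.6, sd_means = 14.7, sd_within = 65.9 / 2.5631),
      vc = list(mean = 98.3, sd_means = 15.3, sd_within = 61.2 / 2.5631),
      cells_per_subject = 100,
      inter_method_r = 0.46
    ),
    respirometry = list(
      states = list(
        free_oxphos = list(mean = 0.8,  sd = 0.25),
        oxphos      = list(mean = 1.3,  sd = 0.30),
        ets         = list(mean = 1.9,  sd = 0.35),
        leak        = list(mean = 0.35, sd = 0.12)
      ),
      couplings = list(
        sc = c(free_oxphos = -0.41, oxphos = -0.53, ets = -0.59, leak = -0.45),
        vc = c(free_oxphos = -0.20, oxphos = -0.36, ets = -0.30, leak = -0.35)
      ),
      shared_factor_loading = 0.6
    )
  )
  config[names(overrides)] <- overrides
  validate_synthetic_config(config)
}

validate_synthetic_config <- function(config) {
  R <- config$latent_correlation
  if (!isSymmetric(R)) stop("latent correlation matrix is not symmetric", call. = FALSE)
  off <- R[upper.tri(R)]
  if (any(abs(off) >= 1)) stop("latent correlations must be in (-1, 1)", call. = FALSE)
  if (config$n_male < 0 || config$n_male > config$n_subjects) {
    stop("n_male must lie in [0, n_subjects]", call. = FALSE)
  }
  if (config$t2d_prevalence < 0 || config$t2d_prevalence > 1) {
    stop("t2d_prevalence must lie in [0, 1]", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    big <- which(abs(R) == max(abs(off)) & upper.tri(R), arr.ind = TRUE)[1, ]
    stop(sprintf(
      paste0("latent correlation matrix is not positive semi-definite ",
             "(min eigenvalue %.3g); reduce the strongest couplings, ",
             "e.g. %s-%s = %.2f"),
      min(ev), rownames(R)[big[1]], colnames(R)[big[2]],
      R[big[1], big[2]]
    ), call. = FALSE)
  }
  for (s in names(config$respirometry$states)) {
    if (config$respirometry$states[[s]]$sd < 0) {
      stop("respirometry state SDs must be non-negative", call. = FALSE)
    }
  }
  for (dep in c("sc", "vc")) {
    rho <- config$respirometry$couplings[[dep]]
    lam <- config$respirometry$shared_factor_loading
    if (any(rho^2 + lam^2 > 1)) {
      stop(sprintf(
        "infeasible respirometry couplings in %s: rho^2 + loading^2 > 1", dep
      ), call. = FALSE)
    }
  }
  structure(config, class = "synthetic_config")
}

#' Generate subject phenotypes from a Gaussian copula
#'
#' Draws one latent multivariate-normal vector per subject with the
#' configured correlation structure, then maps each margin to its target
#' distribution: continuous variables to truncated normals via the
#' probability integral transform (with a recentered location so the
#' post-truncation mean equals the configured mean), sex and T2D by
#' thresholding their latent scores at the configured prevalences.
#' Missingness is applied completely at random at the per-variable rates
#' implied by the configured per-variable sample sizes.
#'
#' The latent depot size factors (`size_sc`, `size_vc`) that carry the
#' size–phenotype couplings are attached as the `"latent_size"` attribute and
#' consumed by [generate_cells()].
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return tibble with `subject_id`, `age`, `sex`, `bmi`, `t2d`, `glucose`,
#'   `hba1c`, `cholesterol`, `ldl`, `hdl`, `triglycerides`.
#' @export
generate_phenotypes <- function(config, seed = config$seed_default) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  R <- config$latent_correlation
  L <- chol(R + diag(1e-10, nrow(R)))
  z <- withr::with_seed(seed, {
    matrix(stats::rnorm(n * nrow(R)), n, nrow(R)) %*% L
  })
  colnames(z) <- colnames(R)
  ids <- sprintf("S%03d", seq_len(n))
  out <- tibble::tibble(subject_id = ids)
  for (v in names(config$marginals)) {
    m <- config$marginals[[v]]
    mu <- tnorm_recenter(m$mean, m$sd, m$min, m$max)
    out[[v]] <- qtnorm(stats::pnorm(z[, v]), mu, m$sd, m$min, m$max)
  }
  out$sex <- ifelse(z[, "sex"] > stats::qnorm(1 - config$n_male / n),
                    "male", "female")
  out$t2d <- ifelse(z[, "t2d"] > stats::qnorm(1 - config$t2d_prevalence),
                    "yes", "no")
  # MCAR missingness at the configured per-variable rates
  out <- withr::with_seed(seed + 1L, {
    for (v in names(config$marginals)) {
      miss <- config$n_subjects - config$marginals[[v]]$n_obs
      if (miss > 0) {
        out[[v]][sample.int(n, miss)] <- NA_real_
      }
    }
    if (config$n_t2d_unknown > 0) {
      out$t2d[sample.int(n, config$n_t2d_unknown)] <- "unknown"
    }
    out
  })
  out <- out[, c("subject_id", "age", "sex", "bmi", "t2d", "glucose",
                 "hba1c", "cholesterol", "ldl", "hdl", "triglycerides")]
  attr(out, "latent_size") <- tibble::tibble(
    subject_id = ids, size_sc = z[, "size_sc"], size_vc = z[, "size_vc"]
  )
  out
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rlnorm(length(bad), meanlog[bad], sdlog)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate per-cell size measurements
#'
#' Histology: per available subject and depot, cross-sectional areas are
#' drawn from a lognormal with subject location
#' \eqn{\mu_i = \mu_{depot} + \sigma_b z_i} (where \eqn{z_i} is the subject's
#' latent depot size factor, which carries the BMI and lab couplings) and
#' within-subject log-SD \eqn{\sigma_w}, truncated by rejection to the
#' artifact window. Collagenase: per available subject, diameters are normal
#' around a subject mean affinely linked to the same latent factor at the
#' configured inter-method correlation and systematically larger offset.
#'
#' @param config a [synthetic_config()].
#' @param phenotypes output of [generate_phenotypes()] (its `latent_size`
#'   attribute is required).
#' @param seed integer seed.
#' @return long cell tibble with columns `subject_id`, `depot`, `method`,
#'   `parameter`, `value`, `unit`.
#' @export
generate_cells <- function(config, phenotypes, seed = config$seed_default) {
  stopifnot(inherits(config, "synthetic_config"))
  latent <- attr(phenotypes, "latent_size")
  if (is.null(latent)) {
    stop("phenotypes lack the latent_size attribute; use generate_phenotypes()",
         call. = FALSE)
  }
  n <- nrow(latent)
  av <- config$availability
  withr::with_seed(seed + 2L, {
    pieces <- list()
    for (dep in c("sc", "vc")) {
      zi <- latent[[paste0("size_", dep)]]
      # histology areas
      n_avail <- av[[paste0(dep, "_histology")]]
      idx <- if (n_avail >= n) seq_len(n) else sort(sample.int(n, n_avail))
      cal <- config$histology[[dep]]
      k <- config$histology$cells_per_subject
      mu_i <- cal$mu + cal$sigma_b * zi[idx]
      areas <- rlnorm_trunc(
        length(idx) * k, rep(mu_i, each = k), cal$sigma_w,
        config$histology$area_bounds[1], config$histology$area_bounds[2]
      )
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        subject_id = rep(latent$subject_id[idx], each = k),
        depot = dep, method = "histology", parameter = "area",
        value = areas, unit = "um2"
      )
      # collagenase diameters
      n_coll <- av[[paste0(dep, "_collagenase")]]
      cidx <- sort(sample.int(n, n_coll))
      cc <- config$collagenase[[dep]]
      kc <- config$collagenase$cells_per_subject
      r_m <- config$collagenase$inter_method_r
      sd_b <- sqrt(max(cc$sd_means^2 - cc$sd_within^2 / kc, 1e-8))
      m_i <- cc$mean + sd_b * (r_m * zi[cidx] +
                                 sqrt(1 - r_m^2) * stats::rnorm(n_coll))
      d <- stats::rnorm(n_coll * kc, rep(m_i, each = kc), cc$sd_within)
      bad <- which(d <= 0)
      while (length(bad)) {
        d[bad] <- stats::rnorm(length(bad), rep(m_i, each = kc)[bad],
                               cc$sd_within)
        bad <- bad[d[bad] <= 0]
      }
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        subject_id = rep(latent$subject_id[cidx], each = kc),
        depot = dep, method = "collagenase", parameter = "diameter",
        value = d, unit = "um"
      )
    }
    dplyr::bind_rows(pieces)
  })
}

#' Generate mitochondrial respirometry profiles
#'
#' Each respiratory state (free OXPHOS, OXPHOS, ETS capacity, leak) is drawn
#' per subject and depot from a linear model in the subject's standardized
#' mean adipocyte diameter: a negative configured coupling makes respiration
#' fall with adipocyte hypertrophy. A shared mitochondrial-quality factor
#' induces realistic positive correlation among the four states. The
#' biochemical state ordering (ETS >= OXPHOS >= free OXPHOS >= 0 and
#' leak <= OXPHOS) is enforced by clipping, with the number of clipped values
#' reported in a message.
#'
#' @param config a [synthetic_config()].
#' @param phenotypes output of [generate_phenotypes()].
#' @param sizes tibble of subject mean diameters (`subject_id`, `depot`,
#'   `mean`), e.g. from [subject_mean_sizes()].
#' @param seed integer seed.
#' @return tibble with `subject_id`, `depot`, `free_oxphos`, `oxphos`, `ets`,
#'   `leak` (pmol O2 s^-1 ng DNA^-1).
#' @export
generate_respirometry <- function(config, phenotypes, sizes,
                                  seed = config$seed_default) {
  stopifnot(inherits(config, "synthetic_config"))
  lam <- config$respirometry$shared_factor_loading
  withr::with_seed(seed + 3L, {
    pieces <- list()
    n_clipped <- 0L
    for (dep in c("sc", "vc")) {
      s_d <- sizes[sizes$depot == dep, , drop = FALSE]
      n_resp <- config$availability[[paste0(dep, "_respirometry")]]
      if (nrow(s_d) < n_resp) {
        stop(sprintf("not enough subjects with %s mean diameters", dep),
             call. = FALSE)
      }
      pick <- sort(sample.int(nrow(s_d), n_resp))
      zd <- as.numeric(scale(s_d$mean[pick]))
      f <- stats::rnorm(n_resp)
      rho <- config$respirometry$couplings[[dep]]
      st <- lapply(names(config$respirometry$states), function(s) {
        p <- config$respirometry$states[[s]]
        resid <- sqrt(1 - rho[[s]]^2 - lam^2)
        p$mean + p$sd * (rho[[s]] * zd + lam * f + resid * stats::rnorm(n_resp))
      })
      names(st) <- names(config$respirometry$states)
      before <- unlist(st)
      st$free_oxphos <- pmax(st$free_oxphos, 0)
      st$oxphos <- pmax(st$oxphos, st$free_oxphos)
      st$ets <- pmax(st$ets, st$oxphos)
      st$leak <- pmin(pmax(st$leak, 0), st$oxphos)
      n_clipped <- n_clipped + sum(unlist(st) != before)
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        subject_id = s_d$subject_id[pick], depot = dep,
        free_oxphos = st$free_oxphos, oxphos = st$oxphos,
        ets = st$ets, leak = st$leak
      )
    }
    if (n_clipped > 0) {
      message(sprintf(
        "generate_respirometry: clipped %d value(s) to enforce state ordering",
        n_clipped
      ))
    }
    dplyr::bind_rows(pieces)
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the three generator stages with sub-seeds derived from one master
#' seed: phenotypes, per-cell sizes, and respirometry (the latter coupled to
#' subject mean diameters computed from the generated histology cells).
#' Identical seed and config give byte-identical tables.
#'
#' @param config a [synthetic_config()].
#' @param seed master integer seed.
#' @param k_diameter cells per subject used for the mean diameters that drive
#'   the respirometry couplings.
#' @return list with `phenotypes`, `cells`, `respirometry`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = synthetic_config(),
                            seed = config$seed_default, k_diameter = 500) {
  phen <- generate_phenotypes(config, seed)
  cells <- generate_cells(config, phen, seed)
  sizes <- dplyr::bind_rows(lapply(c("sc", "vc"), function(dep) {
    subject_mean_sizes(cells, dep, "histology", "diameter", k_diameter,
                       seed = seed + 4L,
                       filter_bounds = config$histology$area_bounds)
  }))
  resp <- generate_respirometry(config, phen, sizes, seed)
  list(phenotypes = phen, cells = cells, respirometry = resp,
       config = config, seed = seed)
}
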