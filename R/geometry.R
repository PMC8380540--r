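#' Spherical-model conversions between adipocyte sizing parameters
#'
#' Mature adipocytes are approximately spherical, so a single size measurement
#' determines all others. Histology reports the cross-sectional area A (µm²) of
#' a cell profile; under the spherical model the diameter is
#' \eqn{d = \sqrt{4A/\pi}} (µm), the volume is \eqn{V = \pi d^3 / 6} (reported
#' in picolitres; 1 µm³ = 1 fl), and the surface area equals four times the
#' largest cross-sectional area, \eqn{S = 4A}. Diameter acts as the hub
#' parameter: every conversion is defined through it, so composed conversions
#' are exactly consistent (e.g. `area_to_volume()` equals
#' `diameter_to_volume(area_to_diameter())`).
#'
#' Because the square root is concave and the cube convex, Jensen's inequality
#' implies `mean(area_to_diameter(A)) < area_to_diameter(mean(A))` and
#' `mean(diameter_to_volume(d)) > diameter_to_volume(mean(d))` on any
#' non-degenerate sample: cohort mean diameter or volume cannot be obtained by
#' transforming the cohort mean area.
#'
#' @param area cross-sectional area(s) in µm²; must be positive and finite
#'   (non-negative for `area_to_surface()`).
#' @param diameter cell diameter(s) in µm; must be non-negative and finite.
#' @param volume cell volume(s) in pl; must be non-negative and finite.
#' @return numeric vector of the converted parameter: µm for diameters,
#'   µm² for areas and surface areas, pl for volumes.
#' @examples
#' area_to_diameter(400 * pi)   # 40 µm
#' diameter_to_volume(100)      # 523.6 pl
#' area_to_surface(2748.8)      # 10995.2 µm²
#' @name spherical_conversions
NULL

check_size <- function(x, what, allow_zero = FALSE) {
  if (!is.numeric(x)) {
    stop(sprintf("%s must be numeric", what), call. = FALSE)
  }
  bad <- if (allow_zero) !is.finite(x) | x < 0 else !is.finite(x) | x <= 0
  if (any(bad)) {
    idx <- which(bad)
    stop(sprintf(
      "invalid %s at position%s %s: values must be %s and finite",
      what, if (length(idx) > 1) "s" else "",
      paste(utils::head(idx, 5), collapse = ", "),
      if (allow_zero) "non-negative" else "positive"
    ), call. = FALSE)
  }
  invisible(x)
}

#' @rdname spherical_conversions
#' @export
area_to_diameter <- function(area) {
  check_size(area, "area")
  sqrt(4 * area / pi)
}

#' @rdname spherical_conversions
#' @export
diameter_to_area <- function(diameter) {
  check_size(diameter, "diameter", allow_zero = TRUE)
  pi / 4 * diameter^2
}

#' @rdname spherical_conversions
#' @export
diameter_to_volume <- function(diameter) {
  check_size(diameter, "diameter", allow_zero = TRUE)
  (pi / 6) * diameter^3 / 1000
}

#' @rdname spherical_conversions
#' @export
volume_to_diameter <- function(volume) {
  check_size(volume, "volume", allow_zero = TRUE)
  (6000 * volume / pi)^(1 / 3)
}

#' @rdname spherical_conversions
#' @export
area_to_volume <- function(area) {
  diameter_to_volume(area_to_diameter(area))
}

#' @rdname spherical_conversions
#' @export
area_to_surface <- function(area) {
  check_size(area, "area", allow_zero = TRUE)
  4 * area
}

#' @rdname spherical_conversions
#' @export
diameter_to_surface <- function(diameter) {
  check_size(diameter, "diameter", allow_zero = TRUE)
  pi * diameter^2
}

#' Convert a vector of one sizing parameter into another
#'
#' Dispatches between the pairwise spherical conversions with diameter as the
#' hub, so any of `"area"`, `"diameter"`, `"volume"`, `"surface"` can be
#' converted into any other.
#'
#' @param values numeric vector of sizes.
#' @param from,to one of `"area"`, `"diameter"`, `"volume"`, `"surface"`.
#' @return numeric vector in the units of `to` (µm² for area/surface, µm for
#'   diameter, pl for volume).
#' @export
convert_size <- function(values, from, to) {
  pars <- c("area", "diameter", "volume", "surface")
  from <- match.arg(from, pars)
  to <- match.arg(to, pars)
  if (from == to) {
    check_size(values, from, allow_zero = TRUE)
    return(values)
  }
  d <- switch(from,
    area = area_to_diameter(values),
    diameter = {
      check_size(values, "diameter", allow_zero = TRUE)
      values
    },
    volume = volume_to_diameter(values),
    surface = area_to_diameter(values / 4)
  )
  switch(to,
    area = diameter_to_area(d),
    diameter = d,
    volume = diameter_to_volume(d),
    surface = diameter_to_surface(d)
  )
}

#' Exclude histology artifacts by cross-sectional area
#'
#' Histological sections contain processing artifacts that masquerade as very
#' small or very large objects. Cells with a cross-sectional area below
#' `lower` or above `upper` are removed before analysis; the default window is
#' 200–16,000 µm². The bounds themselves are kept (the exclusion rule removes
#' only strictly smaller / strictly larger objects).
#'
#' @param areas numeric vector of cross-sectional areas in µm².
#' @param lower,upper inclusive retention bounds in µm².
#' @return a list with `kept` (input order preserved), `n_excluded_low`, and
#'   `n_excluded_high`.
#' @examples
#' filter_histology_areas(c(100, 200, 5000, 16000, 20000))
#' @export
filter_histology_areas <- function(areas, lower = 200, upper = 16000) {
  if (length(areas) && (!is.numeric(areas) || any(!is.finite(areas)))) {
    stop("areas must be finite numeric values", call. = FALSE)
  }
  stopifnot(lower <= upper)
  low <- areas < lower
  high <- areas > upper
  list(
    kept = areas[!low & !high],
    n_excluded_low = sum(low),
    n_excluded_high = sum(high)
  )
}

#' Draw a reproducible simple random sample of cells
#'
#' Per-subject analyses use a fixed number of cells (500 histology areas, 100
#' collagenase diameters by default) so every subject is equally represented.
#' Sampling is without replacement; subjects with fewer than `n` cells cannot
#' be padded and should be excluded by the caller (see [pooled_panel()]).
#'
#' @param cells a vector (or anything `length()`/`[`-indexable) of cell values.
#' @param n number of cells to draw; must not exceed `length(cells)`.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return a vector of `n` sampled cells.
#' @export
sample_cells <- function(cells, n, seed = NULL) {
  if (n > length(cells)) {
    stop(sprintf(
      "insufficient cells: requested %d but only %d available",
      n, length(cells)
    ), call. = FALSE)
  }
  draw <- function() cells[sample.int(length(cells), n)]
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
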