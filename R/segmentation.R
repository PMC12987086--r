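# Threshold segmentation.
#
# The refined index supports a single fixed rule: presence where PKI >= 1.0
# and red reflectance > 0.05 (the red floor suppresses dark surfaces - water,
# shadow, moist soil - whose small green denominator can inflate any ratio
# index). Benchmark indices have no universal threshold, so they are segmented
# by a per-index, per-year interval derived from the boxplot whiskers of the
# target-class sample distribution.

#' Fixed segmentation rule for the refined index
#'
#' @param pki_threshold decision threshold on the index value, default 1.0;
#'   comparison is inclusive (`>=`).
#' @param red_min red-reflectance floor, default 0.05; comparison is strict
#'   (`>`), so pixels at or below the floor are suppressed as dark-surface
#'   artifacts.
#' @return an object of class `pki_fixed_rule`.
#' @export
fixed_rule <- function(pki_threshold = 1.0, red_min = 0.05) {
  if (red_min < 0) stop("`red_min` must be >= 0")
  structure(list(pki_threshold = pki_threshold, red_min = red_min),
            class = "pki_fixed_rule")
}

#' Segment an index map with the fixed rule
#'
#' `presence(x) = (index(x) >= threshold) AND (red(x) > red_min)`; invalid
#' index pixels and scene nodata are absent.
#'
#' @param pki a [index_map()], normally the opened PKI (segment the raw index
#'   only for refinement-ablation comparisons).
#' @param scene the source [scene()] (provides the red band and nodata mask).
#' @param rule a [fixed_rule()].
#' @param year optional integer year tag for the output map.
#' @return a [binary_map()].
#' @export
classify_fixed <- function(pki, scene, rule = fixed_rule(), year = NA_integer_) {
  if (!inherits(pki, "pki_index_map")) stop("`pki` must be a pki_index_map")
  stopifnot_scene(scene)
  if (!inherits(rule, "pki_fixed_rule")) stop("`rule` must be a fixed_rule()")
  if (!all(dim(pki) == dim(scene))) stop("index and scene grids are misaligned")
  require_bands(scene, "red")
  pres <- pki$valid_mask & !scene$nodata_mask &
    !is.na(pki$values) & pki$values >= rule$pki_threshold &
    scene$bands$red > rule$red_min
  pres[is.na(pres)] <- FALSE
  binary_map(pres, year = year,
             rule_descriptor = sprintf("fixed: %s >= %g & red > %g",
                                       pki$index_name, rule$pki_threshold,
                                       rule$red_min),
             pixel_size = pki$pixel_size, geotransform = pki$geotransform,
             crs_id = pki$crs_id)
}

#' Interval segmentation rule
#'
#' @param lower,upper closed interval bounds (`upper` may be `Inf`).
#' @param index_name,year provenance tags.
#' @return an object of class `pki_range_rule`.
#' @export
range_rule <- function(lower, upper, index_name = NA_character_,
                       year = NA_integer_) {
  if (lower > upper) stop("`lower` must be <= `upper`")
  structure(list(lower = lower, upper = upper, index_name = index_name,
                 year = as.integer(year)),
            class = "pki_range_rule")
}

#' @export
print.pki_range_rule <- function(x, ...) {
  cat(sprintf("<pki_range_rule> [%g, %g] (%s, year %s)\n", x$lower, x$upper,
              ifelse(is.na(x$index_name), "?", x$index_name),
              ifelse(is.na(x$year), "?", x$year)))
  invisible(x)
}

#' Whisker-derived segmentation interval
#'
#' Computes the Tukey boxplot whiskers of the target-class index values: the
#' most extreme sample values inside the fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by linear interpolation
#' (type 7). The resulting closed interval is the semi-automatic segmentation
#' rule for benchmark indices, computed per index and per year on target-class
#' samples only.
#'
#' @param values numeric vector of target-class (PK) index samples, or a
#'   [extract_samples()] result from which PK values are taken.
#' @param index_name,year provenance tags attached to the rule.
#' @return a [range_rule()].
#' @examples
#' whisker_range(c(1, 2, 3, 4, 100))  # upper whisker stops at 4
#' @export
whisker_range <- function(values, index_name = NA_character_,
                          year = NA_integer_) {
  if (inherits(values, "pki_class_samples")) {
    if (is.na(index_name)) index_name <- attr(values, "index_name")
    values <- values$value[values$class == "PK"]
  }
  values <- values[is.finite(values)]
  if (length(values) < 4)
    stop("whisker_range needs at least 4 target-class sample values")
  if (diff(range(values)) == 0) {
    warning("all sample values identical; degenerate rule lower = upper")
    return(range_rule(values[1], values[1], index_name, year))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[2] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  range_rule(min(inside), max(inside), index_name, year)
}

#' Segment an index map with an interval rule
#'
#' `presence(x) = lower <= value(x) <= upper` (closed interval); invalid
#' pixels are absent.
#'
#' @param index a [index_map()].
#' @param rule a [range_rule()], e.g. from [whisker_range()].
#' @return a [binary_map()] tagged with the rule's year.
#' @export
classify_range <- function(index, rule) {
  if (!inherits(index, "pki_index_map")) stop("`index` must be a pki_index_map")
  if (!inherits(rule, "pki_range_rule")) stop("`rule` must be a range_rule()")
  pres <- index$valid_mask & !is.na(index$values) &
    index$values >= rule$lower & index$values <= rule$upper
  pres[is.na(pres)] <- FALSE
  binary_map(pres, year = rule$year,
             rule_descriptor = sprintf("whisker: %g <= %s <= %g", rule$lower,
                                       ifelse(is.na(rule$index_name), "index",
                                              rule$index_name), rule$upper),
             pixel_size = index$pixel_size, geotransform = index$geotransform,
             crs_id = index$crs_id)
}
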