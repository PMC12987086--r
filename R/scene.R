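# Band vocabulary follows the 8-band SuperDove (PSB.SD) convention.
PKI_ALL_BANDS <- c("coastal_blue", "blue", "green_i", "green", "yellow",
                   "red", "red_edge", "nir")
PKI_REQUIRED_BANDS <- c("blue", "green", "red", "red_edge", "nir")

#' Construct a multiband reflectance scene
#'
#' A scene is an aligned stack of named 2-D reflectance grids (unitless,
#' expected in \[0, 1\]) plus a shared nodata mask and georeferencing. At least
#' the blue, green, red, red_edge and nir bands must be present for index
#' computation; the remaining SuperDove bands (coastal_blue, green_i, yellow)
#' are accepted but unused by any implemented formula.
#'
#' @param bands named list of numeric matrices, all with identical dimensions.
#'   Names must come from the SuperDove vocabulary
#'   (coastal_blue, blue, green_i, green, yellow, red, red_edge, nir).
#' @param nodata_mask logical matrix, `TRUE` where a pixel carries no data.
#'   Defaults to all-`FALSE`. Non-finite values in any band are also flagged.
#' @param pixel_size pixel side length in meters (default 3, the SuperDove
#'   ground sample distance).
#' @param geotransform numeric vector `c(xmin, ymax, xres, yres)` placing the
#'   grid: the outer corner of pixel (row 1, col 1) is `(xmin, ymax)` and
#'   rows advance downward (south) by `yres`.
#' @param crs_id optional coordinate reference identifier (e.g. an EPSG code);
#'   carried through I/O, never interpreted.
#' @return an object of class `pki_scene`.
#' @examples
#' b <- matrix(0.05, 4, 4)
#' sc <- scene(list(blue = b, green = b * 2, red = b, red_edge = b * 4,
#'                  nir = b * 6))
#' dim(sc)
#' @export
scene <- function(bands, nodata_mask = NULL, pixel_size = 3,
                  geotransform = NULL, crs_id = NA_character_) {
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stop("`bands` must be a named list of matrices")
  unknown <- setdiff(names(bands), PKI_ALL_BANDS)
  if (length(unknown))
    stop("unknown band name(s): ", paste(unknown, collapse = ", "),
         "; expected names among: ", paste(PKI_ALL_BANDS, collapse = ", "))
  dims <- lapply(bands, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("all bands must be matrices")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == d0), logical(1))))
    stop("all band grids must share identical dimensions")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, d0[1], d0[2])
  } else {
    if (!is.logical(nodata_mask) || !all(dim(nodata_mask) == d0))
      stop("`nodata_mask` must be a logical matrix matching the band grids")
  }
  for (b in bands) nodata_mask <- nodata_mask | !is.finite(b)
  if (is.null(geotransform))
    geotransform <- c(xmin = 0, ymax = d0[1] * pixel_size,
                      xres = pixel_size, yres = pixel_size)
  else {
    geotransform <- as.numeric(geotransform)
    if (length(geotransform) != 4)
      stop("`geotransform` must be c(xmin, ymax, xres, yres)")
    names(geotransform) <- c("xmin", "ymax", "xres", "yres")
  }
  vals <- unlist(lapply(bands, function(b) range(b[!nodata_mask], na.rm = TRUE)))
  if (length(vals) && any(is.finite(vals)) &&
      (min(vals, na.rm = TRUE) < 0 || max(vals, na.rm = TRUE) > 1))
    warning("reflectance values outside [0, 1] detected; passed through unmodified")
  structure(list(bands = bands, nodata_mask = nodata_mask,
                 pixel_size = pixel_size, geotransform = geotransform,
                 crs_id = crs_id),
            class = "pki_scene")
}

#' @export
dim.pki_scene <- function(x) dim(x$bands[[1]])

#' @export
print.pki_scene <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pki_scene> %d x %d pixels, %g m/pixel\n", d[1], d[2],
              x$pixel_size))
  cat("  bands:", paste(names(x$bands), collapse = ", "), "\n")
  cat(sprintf("  nodata pixels: %d\n", sum(x$nodata_mask)))
  invisible(x)
}

# Checks a scene holds the bands a formula needs.
require_bands <- function(scene, needed) {
  miss <- setdiff(needed, names(scene$bands))
  if (length(miss))
    stop("required band absent: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

stopifnot_scene <- function(x) {
  if (!inherits(x, "pki_scene")) stop("expected a `pki_scene` object")
  invisible(TRUE)
}

#' Construct a continuous index map
#'
#' Single-band continuous raster aligned to the scene it was computed from.
#' Pixels where the formula is undefined (zero denominator, nodata input) are
#' flagged in `valid_mask` rather than carrying sentinel values.
#'
#' @param values numeric matrix of index values.
#' @param valid_mask logical matrix, `TRUE` where the value is meaningful.
#' @param index_name label such as `"PKI"`, `"PKI_raw"` or `"NDVI"`.
#' @param pixel_size,geotransform,crs_id georeferencing, normally inherited
#'   from the source scene.
#' @return an object of class `pki_index_map`.
#' @export
index_map <- function(values, valid_mask = NULL, index_name = "index",
                      pixel_size = 3, geotransform = NULL,
                      crs_id = NA_character_) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  if (!is.logical(valid_mask) || !all(dim(valid_mask) == dim(values)))
    stop("`valid_mask` must be a logical matrix matching `values`")
  valid_mask <- valid_mask & is.finite(values)
  values[!valid_mask] <- NA_real_
  if (is.null(geotransform))
    geotransform <- c(xmin = 0, ymax = nrow(values) * pixel_size,
                      xres = pixel_size, yres = pixel_size)
  structure(list(values = values, valid_mask = valid_mask,
                 index_name = index_name, pixel_size = pixel_size,
                 geotransform = geotransform, crs_id = crs_id),
            class = "pki_index_map")
}

#' @export
dim.pki_index_map <- function(x) dim(x$values)

#' @export
print.pki_index_map <- function(x, ...) {
  rng <- range(x$values[x$valid_mask])
  cat(sprintf("<pki_index_map> %s, %d x %d, range [%.4g, %.4g], %d invalid\n",
              x$index_name, nrow(x$values), ncol(x$values), rng[1], rng[2],
              sum(!x$valid_mask)))
  invisible(x)
}

#' Construct a binary presence map
#'
#' @param presence logical matrix, `TRUE` where the target species is mapped
#'   present. `NA` is coerced to `FALSE` (absence).
#' @param year integer year label (optional).
#' @param rule_descriptor free-text provenance of the segmentation rule.
#' @param pixel_size,geotransform,crs_id georeferencing.
#' @return an object of class `pki_binary_map`.
#' @export
binary_map <- function(presence, year = NA_integer_,
                       rule_descriptor = "", pixel_size = 3,
                       geotransform = NULL, crs_id = NA_character_) {
  if (!is.matrix(presence)) stop("`presence` must be a matrix")
  presence <- matrix(as.logical(presence), nrow(presence), ncol(presence))
  presence[is.na(presence)] <- FALSE
  if (is.null(geotransform))
    geotransform <- c(xmin = 0, ymax = nrow(presence) * pixel_size,
                      xres = pixel_size, yres = pixel_size)
  structure(list(presence = presence, year = as.integer(year),
                 rule_descriptor = rule_descriptor, pixel_size = pixel_size,
                 geotransform = geotransform, crs_id = crs_id),
            class = "pki_binary_map")
}

#' @export
dim.pki_binary_map <- function(x) dim(x$presence)

#' @export
print.pki_binary_map <- function(x, ...) {
  cat(sprintf("<pki_binary_map> year %s, %d x %d, %d presence pixels\n",
              ifelse(is.na(x$year), "?", x$year), nrow(x$presence),
              ncol(x$presence), sum(x$presence)))
  if (nzchar(x$rule_descriptor)) cat("  rule:", x$rule_descriptor, "\n")
  invisible(x)
}

# Geographic x/y -> 1-based (row, col) under the pixel-center convention.
xy_to_rowcol <- function(x, y, geotransform) {
  col <- floor((x - geotransform[["xmin"]]) / geotransform[["xres"]]) + 1
  row <- floor((geotransform[["ymax"]] - y) / geotransform[["yres"]]) + 1
  cbind(row = row, col = col)
}
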