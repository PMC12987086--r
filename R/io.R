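# Raster I/O.
#
# Rasters are stored as TIFF with one band per directory (page), 32-bit float
# samples, plus a JSON sidecar "<path>.aux.json" carrying band order,
# georeferencing, CRS, nodata and (for index maps) the affine value scaling.
# Float TIFF samples are stored in [0, 1]; index values are mapped there with
# scale/offset recorded in the sidecar, so round-trip error is bounded by
# (value range) * 2^-24. Binary maps round-trip exactly.

aux_path <- function(path) paste0(path, ".aux.json")

write_aux <- function(path, meta) {
  jsonlite::write_json(meta, aux_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
}

read_aux <- function(path) {
  ap <- aux_path(path)
  if (!file.exists(ap)) return(NULL)
  jsonlite::read_json(ap, simplifyVector = TRUE)
}

geotransform_from_meta <- function(meta, nr, pixel_size) {
  if (!is.null(meta$geotransform)) {
    gt <- as.numeric(meta$geotransform)
    names(gt) <- c("xmin", "ymax", "xres", "yres")
    gt
  } else {
    c(xmin = 0, ymax = nr * pixel_size, xres = pixel_size, yres = pixel_size)
  }
}

#' Write a scene to a multiband TIFF
#'
#' Bands are written as one 32-bit float TIFF directory each, followed by a
#' final directory holding the nodata mask (1 = nodata). Band order,
#' georeferencing and CRS go to a `<path>.aux.json` sidecar.
#'
#' @param scene a [scene()].
#' @param path output file path (conventionally `.tif`).
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot_scene(scene)
  pages <- lapply(scene$bands, function(b) {
    b[scene$nodata_mask] <- 0
    b[!is.finite(b)] <- 0
    b
  })
  pages <- c(pages, list(nodata = scene$nodata_mask * 1))
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L, reduce = FALSE)
  write_aux(path, list(
    type = "scene", band_names = names(scene$bands), has_nodata_page = TRUE,
    pixel_size = scene$pixel_size, geotransform = unname(scene$geotransform),
    crs_id = scene$crs_id))
  invisible(path)
}

#' Read a multiband reflectance scene
#'
#' Reads a band-per-page TIFF into a [scene()]. Band identity is taken from
#' the sidecar written by [write_scene()] when present; otherwise
#' `band_mapping` must name the page holding each band. Scaled-integer
#' products (values up to 10000) are detected by their maximum value and
#' rescaled to reflectance when `rescale = "auto"` (a message reports this;
#' the heuristic can be forced on/off).
#'
#' @param path TIFF file path.
#' @param band_mapping named integer vector, band name to page ordinal, e.g.
#'   `c(blue = 2, green = 4, red = 6, red_edge = 7, nir = 8)`. Must cover at
#'   least the five required bands when no sidecar is available.
#' @param nodata optional numeric: pixels equal to this value in every mapped
#'   band are flagged as nodata (e.g. 0 for zero-filled products).
#' @param rescale `"auto"` (detect 0-10000 scaled integers), `TRUE` (divide by
#'   10000) or `FALSE` (never rescale).
#' @return a [scene()].
#' @export
read_scene <- function(path, band_mapping = NULL, nodata = NULL,
                       rescale = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  meta <- read_aux(path)
  mask <- NULL
  if (!is.null(meta) && identical(meta$type, "scene")) {
    nb <- length(meta$band_names)
    bands <- pages[seq_len(nb)]
    names(bands) <- meta$band_names
    if (isTRUE(meta$has_nodata_page)) mask <- pages[[nb + 1]] > 0.5
    if (!is.null(band_mapping)) bands <- bands[names(band_mapping)]
    pixel_size <- meta$pixel_size
    gt <- geotransform_from_meta(meta, nrow(bands[[1]]), pixel_size)
    crs <- if (is.null(meta$crs_id)) NA_character_ else meta$crs_id
  } else {
    if (is.null(band_mapping))
      stop("no sidecar metadata; `band_mapping` is required")
    miss <- setdiff(PKI_REQUIRED_BANDS, names(band_mapping))
    if (length(miss))
      stop("required band absent from `band_mapping`: ",
           paste(miss, collapse = ", "))
    if (any(band_mapping > length(pages)))
      stop("band ordinal exceeds page count (", length(pages), ")")
    bands <- lapply(band_mapping, function(i) pages[[i]])
    pixel_size <- 3
    gt <- NULL
    crs <- NA_character_
  }
  dims <- vapply(bands, function(b) dim(b), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension mismatch among bands")
  mx <- max(vapply(bands, max, numeric(1)), na.rm = TRUE)
  do_rescale <- if (identical(rescale, "auto")) mx > 1.5 else isTRUE(rescale)
  if (do_rescale) {
    message("read_scene: maximum value ", format(mx),
            " suggests scaled-integer reflectance; dividing by 10000")
    bands <- lapply(bands, function(b) b / 10000)
  }
  if (!is.null(nodata)) {
    nd <- Reduce(`&`, lapply(bands, function(b) b == nodata))
    mask <- if (is.null(mask)) nd else (mask | nd)
  }
  scene(bands, nodata_mask = mask, pixel_size = pixel_size,
        geotransform = gt, crs_id = crs)
}

#' Write an index map or binary map to TIFF
#'
#' Index maps are stored as a value page plus a validity page; values are
#' affinely mapped into \[0, 1\] for float TIFF storage with the scale and
#' offset recorded in the sidecar, so reading restores original units. Binary
#' maps are stored as a single 0/1 page and round-trip exactly.
#'
#' @param x a [index_map()] or [binary_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  if (inherits(x, "pki_index_map")) {
    v <- x$values
    rng <- range(v[x$valid_mask], finite = TRUE)
    if (!any(x$valid_mask) || !all(is.finite(rng))) rng <- c(0, 1)
    offset <- rng[1]
    scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    sv <- (v - offset) / scale
    sv[!x$valid_mask] <- 0
    tiff::writeTIFF(list(sv, x$valid_mask * 1), path,
                    bits.per.sample = 32L, reduce = FALSE)
    write_aux(path, list(
      type = "index", index_name = x$index_name, scale = scale,
      offset = offset, pixel_size = x$pixel_size,
      geotransform = unname(x$geotransform), crs_id = x$crs_id))
  } else if (inherits(x, "pki_binary_map")) {
    tiff::writeTIFF(x$presence * 1, path, bits.per.sample = 8L,
                    reduce = FALSE)
    write_aux(path, list(
      type = "binary", year = x$year, rule_descriptor = x$rule_descriptor,
      pixel_size = x$pixel_size, geotransform = unname(x$geotransform),
      crs_id = x$crs_id))
  } else stop("`x` must be a pki_index_map or pki_binary_map")
  invisible(path)
}

#' Read an index map or binary map written by [write_raster()]
#'
#' @param path TIFF file path (with its `.aux.json` sidecar).
#' @return a [index_map()] or [binary_map()] according to the sidecar type.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_aux(path)
  if (is.null(meta)) stop("missing sidecar metadata for ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  gt <- geotransform_from_meta(meta, nrow(pages[[1]]), meta$pixel_size)
  crs <- if (is.null(meta$crs_id) || is.na(meta$crs_id)) NA_character_ else meta$crs_id
  if (identical(meta$type, "index")) {
    valid <- pages[[2]] > 0.5
    v <- pages[[1]] * meta$scale + meta$offset
    v[!valid] <- NA_real_
    index_map(v, valid, index_name = meta$index_name,
              pixel_size = meta$pixel_size, geotransform = gt, crs_id = crs)
  } else if (identical(meta$type, "binary")) {
    binary_map(pages[[1]] > 0.5,
               year = if (is.null(meta$year)) NA_integer_ else meta$year,
               rule_descriptor = meta$rule_descriptor %||% "",
               pixel_size = meta$pixel_size, geotransform = gt, crs_id = crs)
  } else stop("unsupported raster type in sidecar: ", meta$type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read labelled reference sample points
#'
#' Accepts a CSV (columns `x`,`y` or `row`,`col`, plus `class` and `year`) or
#' a GeoJSON FeatureCollection of points with `class` and `year` properties.
#' Class labels are normalized to `PK`, `OV`, `NV` (case/whitespace tolerant;
#' long names such as "other vegetation" are recognized). Points outside the
#' scene extent are excluded and the exclusion count reported.
#'
#' @param path CSV or GeoJSON file.
#' @param scene a [scene()] used to resolve coordinates to pixels and to
#'   bound the extent.
#' @return a data frame of class `pki_reference_points` with columns `row`,
#'   `col`, `class`, `year`; the number of excluded points is available as
#'   `attr(x, "n_excluded")`.
#' @export
read_reference_points <- function(path, scene) {
  stopifnot_scene(scene)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    if (is.null(feats)) stop("GeoJSON file has no features")
    xy <- t(vapply(feats, function(f) unlist(f$geometry$coordinates)[1:2],
                   numeric(2)))
    cls <- vapply(feats, function(f) as.character(f$properties$class),
                  character(1))
    yr <- vapply(feats, function(f)
      as.integer(f$properties$year %||% NA_integer_), integer(1))
    df <- data.frame(x = xy[, 1], y = xy[, 2], class = cls, year = yr)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  names(df) <- tolower(names(df))
  if (!"class" %in% names(df)) stop("reference file lacks a `class` column")
  if (!"year" %in% names(df)) df$year <- NA_integer_
  if (all(c("row", "col") %in% names(df))) {
    rc <- cbind(row = as.numeric(df$row), col = as.numeric(df$col))
  } else if (all(c("x", "y") %in% names(df))) {
    x <- suppressWarnings(as.numeric(df$x))
    y <- suppressWarnings(as.numeric(df$y))
    if (anyNA(x) || anyNA(y)) stop("unparseable coordinates in reference file")
    rc <- xy_to_rowcol(x, y, scene$geotransform)
  } else stop("reference file needs `x`,`y` or `row`,`col` columns")
  cls <- normalize_class_label(df$class)
  d <- dim(scene)
  inside <- rc[, "row"] >= 1 & rc[, "row"] <= d[1] &
    rc[, "col"] >= 1 & rc[, "col"] <= d[2]
  n_excl <- sum(!inside)
  if (n_excl > 0)
    message("read_reference_points: excluded ", n_excl,
            " point(s) outside the scene extent")
  out <- data.frame(row = as.integer(rc[inside, "row"]),
                    col = as.integer(rc[inside, "col"]),
                    class = cls[inside],
                    year = as.integer(df$year[inside]))
  attr(out, "n_excluded") <- n_excl
  class(out) <- c("pki_reference_points", "data.frame")
  out
}

# Tolerant label normalization to the three validation classes.
normalize_class_label <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  out <- ifelse(key %in% c("pk", "pedicularis", "pediculariskansuensis",
                           "pkansuensis", "target"), "PK",
         ifelse(key %in% c("ov", "othervegetation", "vegetation", "grass",
                           "native"), "OV",
         ifelse(key %in% c("nv", "nonvegetation", "soil", "baresoil", "water",
                           "nonveg", "watershadow"), "NV", NA_character_)))
  if (anyNA(out))
    stop("unknown class label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected PK, OV or NV)")
  out
}
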