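# In situ hyperspectral curves and band-level contrast checks.
#
# Field spectra (350-2500 nm at 1 nm) are resampled to sensor bands with a
# boxcar (uniform) response over nominal band intervals, then compared between
# the target species and a background species. Three qualitative contrasts
# motivate the index design: higher blue (purple-red inflorescences), a weaker
# green peak (flowers masking leaves), and a higher red / red-edge response.

#' Nominal sensor band wavelength ranges
#'
#' Editable defaults for the SuperDove-style band set (nm). These are nominal
#' intervals for boxcar resampling, not measured response functions.
#'
#' @return named list of `c(lower, upper)` nm intervals.
#' @export
default_band_ranges <- function() {
  list(coastal_blue = c(431, 452), blue = c(465, 515), green_i = c(513, 549),
       green = c(547, 583), yellow = c(600, 620), red = c(650, 680),
       red_edge = c(697, 713), nir = c(845, 885))
}

#' Read hyperspectral reflectance curves from CSV
#'
#' Expected columns: `wavelength_nm`, `reflectance`, `species`.
#'
#' @param path CSV file.
#' @return named list of curves, one per species; each a list with
#'   `wavelengths` (strictly increasing) and `reflectance`.
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "reflectance", "species")
  if (!all(need %in% names(df)))
    stop("spectra CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$species), function(d) {
    d <- d[order(d$wavelength_nm), ]
    if (anyDuplicated(d$wavelength_nm))
      stop("duplicate wavelengths for species ", d$species[1])
    hyperspectral_curve(d$wavelength_nm, d$reflectance, d$species[1])
  })
}

#' Construct a hyperspectral reflectance curve
#'
#' @param wavelengths nm, strictly increasing.
#' @param reflectance unitless, finite, same length.
#' @param species label.
#' @return an object of class `pki_spectrum`.
#' @export
hyperspectral_curve <- function(wavelengths, reflectance,
                                species = NA_character_) {
  if (length(wavelengths) != length(reflectance))
    stop("wavelengths and reflectance lengths differ")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (!all(is.finite(reflectance))) stop("reflectance must be finite")
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 species = species),
            class = "pki_spectrum")
}

#' Boxcar band averages of a hyperspectral curve
#'
#' Per band, the mean reflectance over curve samples whose wavelength lies in
#' the closed band interval (uniform spectral response).
#'
#' @param curve a [hyperspectral_curve()].
#' @param ranges named list of `c(lower, upper)` nm intervals, default
#'   [default_band_ranges()].
#' @return named numeric vector of per-band reflectance.
#' @export
band_average <- function(curve, ranges = default_band_ranges()) {
  if (!inherits(curve, "pki_spectrum")) stop("`curve` must be a pki_spectrum")
  vapply(ranges, function(rg) {
    inb <- curve$wavelengths >= rg[1] & curve$wavelengths <= rg[2]
    if (!any(inb))
      stop("band interval [", rg[1], ", ", rg[2],
           "] nm contains no curve samples")
    mean(curve$reflectance[inb])
  }, numeric(1))
}

#' Band-level contrast between target and background spectra
#'
#' Signed per-band differences (target minus background) plus the three flags
#' that define the target's flowering signature: higher blue, lower green,
#' higher red AND red edge.
#'
#' @param target,background named per-band reflectance vectors sharing at
#'   least the blue, green, red and red_edge bands (e.g. from
#'   [band_average()] or a template row).
#' @return list with `delta` (named vector) and logical flags `blue_up`,
#'   `green_down`, `red_rededge_up`, plus `all_criteria`.
#' @export
class_contrast <- function(target, background) {
  common <- intersect(names(target), names(background))
  need <- c("blue", "green", "red", "red_edge")
  if (!all(need %in% common))
    stop("band mismatch: need ", paste(need, collapse = ", "),
         " in both vectors")
  delta <- target[common] - background[common]
  flags <- list(blue_up = unname(delta["blue"] > 0),
                green_down = unname(delta["green"] < 0),
                red_rededge_up = unname(delta["red"] > 0 &
                                          delta["red_edge"] > 0))
  c(list(delta = delta), flags,
    list(all_criteria = flags$blue_up && flags$green_down &&
           flags$red_rededge_up))
}
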