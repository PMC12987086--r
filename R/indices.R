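# Spectral index formulas.
#
# The target index contrasts the flowering signature of P. kansuensis
# (elevated blue from purple-red inflorescences, elevated red edge from intact
# canopy structure) against the stronger green peak of native pasture:
#
#   PKI_raw = (rho_RedEdge + rho_Blue) / (2.5 * rho_Green)
#
# The 2.5 scaling factor normalizes the decision threshold to 1. The seven
# benchmarks are the standard published definitions.

# Registry: required bands + pixel-wise formula on a named list of band values.
index_registry <- function() {
  list(
    PKI_raw = list(bands = c("blue", "green", "red_edge"),
                   fun = function(b, k = 2.5) (b$red_edge + b$blue) / (k * b$green),
                   denom = function(b, k = 2.5) k * b$green),
    RI    = list(bands = c("red", "green"),
                 fun = function(b, ...) b$red / b$green,
                 denom = function(b, ...) b$green),
    NDVI  = list(bands = c("nir", "red"),
                 fun = function(b, ...) (b$nir - b$red) / (b$nir + b$red),
                 denom = function(b, ...) b$nir + b$red),
    NDRE  = list(bands = c("nir", "red_edge"),
                 fun = function(b, ...) (b$nir - b$red_edge) / (b$nir + b$red_edge),
                 denom = function(b, ...) b$nir + b$red_edge),
    GNDVI = list(bands = c("nir", "green"),
                 fun = function(b, ...) (b$nir - b$green) / (b$nir + b$green),
                 denom = function(b, ...) b$nir + b$green),
    CIRE  = list(bands = c("nir", "red_edge"),
                 fun = function(b, ...) b$nir / b$red_edge - 1,
                 denom = function(b, ...) b$red_edge),
    CIG   = list(bands = c("nir", "green"),
                 fun = function(b, ...) b$nir / b$green - 1,
                 denom = function(b, ...) b$green),
    ARI   = list(bands = c("green", "red_edge"),
                 fun = function(b, ...) 1 / b$green - 1 / b$red_edge,
                 denom = function(b, ...) b$green * b$red_edge)
  )
}

#' Names of the implemented spectral indices
#'
#' @return character vector: `PKI_raw` plus the seven benchmark indices.
#' @export
index_names <- function() names(index_registry())

#' Compute the raw P. kansuensis Index
#'
#' Per valid pixel, `(red_edge + blue) / (scaling_factor * green)`. Pixels
#' with zero green reflectance or nodata in any used band are flagged invalid.
#' The raw index is scale-invariant (multiplying all bands by a positive
#' constant leaves it unchanged), which buffers multiplicative illumination
#' effects; grayscale opening ([grayscale_open()]) turns it into the final
#' refined index.
#'
#' @param scene a [scene()] with blue, green and red_edge bands.
#' @param scaling_factor positive denominator scaling, default 2.5 (places the
#'   decision boundary for flowering targets at 1).
#' @return a [index_map()] named `"PKI_raw"`.
#' @examples
#' b <- function(v) matrix(v, 2, 2)
#' sc <- scene(list(blue = b(0.25), green = b(0.20), red = b(0.1),
#'                  red_edge = b(0.25), nir = b(0.4)))
#' compute_pki_raw(sc)$values[1, 1]  # exactly 1
#' @export
compute_pki_raw <- function(scene, scaling_factor = 2.5) {
  stopifnot_scene(scene)
  if (!is.numeric(scaling_factor) || length(scaling_factor) != 1 ||
      scaling_factor <= 0)
    stop("`scaling_factor` must be a single positive number")
  compute_index(scene, "PKI_raw", scaling_factor = scaling_factor)
}

#' Compute a benchmark spectral index
#'
#' Standard definitions: `RI = red/green`; `NDVI = (nir-red)/(nir+red)`;
#' `NDRE = (nir-red_edge)/(nir+red_edge)`; `GNDVI = (nir-green)/(nir+green)`;
#' `CIRE = nir/red_edge - 1`; `CIG = nir/green - 1`;
#' `ARI = 1/green - 1/red_edge`. Zero denominators and nodata inputs give
#' invalid pixels, never infinities.
#'
#' @param scene a [scene()].
#' @param name one of `RI`, `NDVI`, `NDRE`, `GNDVI`, `CIRE`, `CIG`, `ARI`
#'   (case-insensitive); `PKI_raw` is also accepted for symmetry.
#' @return a [index_map()].
#' @export
compute_benchmark <- function(scene, name) compute_index(scene, name)

#' @rdname compute_benchmark
#' @param scaling_factor passed through to the `PKI_raw` formula.
#' @export
compute_index <- function(scene, name, scaling_factor = 2.5) {
  stopifnot_scene(scene)
  reg <- index_registry()
  key <- match(tolower(name), tolower(names(reg)))
  if (is.na(key)) stop("unknown index name: ", name, " (known: ",
                       paste(names(reg), collapse = ", "), ")")
  entry <- reg[[key]]
  require_bands(scene, entry$bands)
  b <- scene$bands[entry$bands]
  denom <- entry$denom(b, scaling_factor)
  valid <- !scene$nodata_mask & denom != 0
  for (g in b) valid <- valid & is.finite(g)
  v <- entry$fun(b, scaling_factor)
  v[!valid] <- NA_real_
  index_map(v, valid, index_name = names(reg)[key],
            pixel_size = scene$pixel_size, geotransform = scene$geotransform,
            crs_id = scene$crs_id)
}
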