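# Grayscale morphology with a flat square structuring element.
#
# The index surface is treated as topography: erosion replaces each pixel by
# the neighborhood minimum, dilation by the maximum, and opening (erosion then
# dilation) levels bright features smaller than the element while preserving
# coherent patches. Applied to the raw index this yields the refined PKI.
#
# Border policy: neighborhoods are clipped at the image edge (min/max over the
# in-image part of the window). Invalid pixels are excluded from every
# neighborhood and remain invalid in the output. Under this clipped/masked
# definition erosion and dilation form an adjunction on the valid domain, so
# the opening is exactly anti-extensive, increasing and idempotent.

#' Flat square structuring element
#'
#' @param size odd window side length in pixels (default 3, i.e. the 8-connected
#'   neighborhood plus center).
#' @return an object of class `pki_se`.
#' @export
structuring_element <- function(size = 3) {
  if (!is.numeric(size) || length(size) != 1 || size < 1 || size %% 2 != 1)
    stop("`size` must be an odd positive integer")
  structure(list(size = as.integer(size)), class = "pki_se")
}

#' @export
print.pki_se <- function(x, ...) {
  cat(sprintf("<pki_se> flat square %d x %d\n", x$size, x$size))
  invisible(x)
}

# Worker: windowed min or max of `values` over a size x size window, clipped
# at borders, ignoring pixels where `valid` is FALSE. Returns the filtered
# matrix; positions with no valid pixel in the window get NA.
morph_filter <- function(values, valid, size, op = c("min", "max")) {
  op <- match.arg(op)
  nr <- nrow(values); nc <- ncol(values)
  if (nr == 0 || nc == 0) stop("empty image")
  r <- (size - 1L) %/% 2L
  fill <- if (op == "min") Inf else -Inf
  v <- values
  v[!valid] <- fill
  v[is.na(v)] <- fill
  # pad with the identity element so out-of-image offsets never contribute
  pv <- matrix(fill, nr + 2 * r, nc + 2 * r)
  pv[(r + 1):(r + nr), (r + 1):(r + nc)] <- v
  acc <- matrix(fill, nr, nc)
  cmp <- if (op == "min") pmin else pmax
  for (dy in -r:r) for (dx in -r:r) {
    acc <- cmp(acc, pv[(r + 1 + dy):(r + nr + dy), (r + 1 + dx):(r + nc + dx)])
  }
  acc[!is.finite(acc)] <- NA_real_
  acc
}

as_morph_input <- function(image) {
  if (inherits(image, "pki_index_map")) {
    list(values = image$values, valid = image$valid_mask, map = image)
  } else if (is.matrix(image)) {
    list(values = image, valid = is.finite(image), map = NULL)
  } else stop("`image` must be a pki_index_map or a numeric matrix")
}

morph_output <- function(res, inp, suffix) {
  valid <- inp$valid & !is.na(res)
  res[!valid] <- NA_real_
  if (is.null(inp$map)) return(res)
  out <- inp$map
  out$values <- res
  out$valid_mask <- valid
  out$index_name <- paste0(inp$map$index_name, suffix)
  out
}

#' Grayscale erosion
#'
#' Each pixel is replaced by the minimum value within the structuring-element
#' neighborhood, clipped at image borders; invalid pixels are excluded from
#' neighborhoods and stay invalid.
#'
#' @param image a [index_map()] or numeric matrix (`NA` treated as invalid).
#' @param se a [structuring_element()].
#' @return same type as `image`.
#' @export
grayscale_erode <- function(image, se = structuring_element(3)) {
  if (!inherits(se, "pki_se")) stop("`se` must be a structuring_element()")
  inp <- as_morph_input(image)
  morph_output(morph_filter(inp$values, inp$valid, se$size, "min"), inp, "_ero")
}

#' Grayscale dilation
#'
#' Dual of [grayscale_erode()]: neighborhood maximum.
#'
#' @inheritParams grayscale_erode
#' @return same type as `image`.
#' @export
grayscale_dilate <- function(image, se = structuring_element(3)) {
  if (!inherits(se, "pki_se")) stop("`se` must be a structuring_element()")
  inp <- as_morph_input(image)
  morph_output(morph_filter(inp$values, inp$valid, se$size, "max"), inp, "_dil")
}

#' Grayscale opening
#'
#' Erosion followed by dilation with the same flat element. Removes bright
#' speckle narrower than the element while exactly preserving structures that
#' contain a full element-sized square; this is the refinement that turns the
#' raw index into the final PKI.
#'
#' @inheritParams grayscale_erode
#' @return same type as `image`; for an index map the name gains no suffix and
#'   `"PKI_raw"` becomes `"PKI"`.
#' @export
grayscale_open <- function(image, se = structuring_element(3)) {
  if (!inherits(se, "pki_se")) stop("`se` must be a structuring_element()")
  inp <- as_morph_input(image)
  ero <- morph_filter(inp$values, inp$valid, se$size, "min")
  valid2 <- inp$valid & !is.na(ero)
  opened <- morph_filter(ero, valid2, se$size, "max")
  out <- morph_output(opened, inp, "")
  if (inherits(out, "pki_index_map"))
    out$index_name <- if (identical(inp$map$index_name, "PKI_raw")) "PKI" else
      paste0(inp$map$index_name, "_opened")
  out
}

#' Compute the refined P. kansuensis Index from a scene
#'
#' Convenience wrapper: [compute_pki_raw()] followed by [grayscale_open()].
#'
#' @param scene a [scene()].
#' @param scaling_factor denominator scaling of the raw index (default 2.5).
#' @param se_size structuring-element side (odd, default 3).
#' @return a [index_map()] named `"PKI"`.
#' @export
compute_pki <- function(scene, scaling_factor = 2.5, se_size = 3) {
  grayscale_open(compute_pki_raw(scene, scaling_factor),
                 structuring_element(se_size))
}
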