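# Synthetic multispectral scene generator.
#
# Emulates the statistical structure the mapping method assumes: spatially
# clustered target patches whose band signature is high-blue / low-green /
# high-red-edge relative to a green-dominated grass background, plus soil,
# dark water/shadow surfaces, linear spectral mixing at patch edges, per-band
# Gaussian noise, and an optional additive radiometric offset in a
# sub-rectangle (the cross-scene normalization artifact that produces
# fixed-rule false positives). All templates are synthetic constants chosen to
# satisfy the qualitative contrasts; they are not measured reflectances.

#' Default synthetic class reflectance templates
#'
#' Five-band mean reflectance per class. The `target` template gives a raw
#' index of about 2.06 (> 1) and the backgrounds stay well below 1; the
#' `water_shadow` template is deliberately one of the dark surfaces whose raw
#' index exceeds 1 while red reflectance is at most 0.05, so the fixed rule's
#' red floor is exercised.
#'
#' @return named list of named numeric band vectors.
#' @export
default_templates <- function() {
  list(
    target       = c(blue = 0.080, green = 0.070, red = 0.100,
                     red_edge = 0.280, nir = 0.420),
    grass        = c(blue = 0.035, green = 0.120, red = 0.060,
                     red_edge = 0.160, nir = 0.480),
    soil         = c(blue = 0.090, green = 0.150, red = 0.200,
                     red_edge = 0.200, nir = 0.250),
    water_shadow = c(blue = 0.030, green = 0.012, red = 0.020,
                     red_edge = 0.015, nir = 0.010)
  )
}

#' Configuration of the synthetic scene generator
#'
#' @param height,width scene size in pixels.
#' @param templates named list of per-class band templates; must contain
#'   `target` and `grass` (the matrix background). Default
#'   [default_templates()].
#' @param noise_sd per-band Gaussian noise standard deviation (single value or
#'   named per class), default 0.01.
#' @param n_target_patches number of target ellipses, default 8.
#' @param radius_range min/max ellipse semi-axis in pixels, default `c(4, 9)`.
#' @param cluster_factor Neyman-Scott style clustering: patches are children
#'   of `ceiling(n/cluster_factor)` parent centers, scattered with
#'   `cluster_sd` pixels; `cluster_factor = 1` gives unclustered placement.
#' @param cluster_sd child scatter around parents, default 15 pixels.
#' @param n_soil_patches,n_water_patches background feature counts.
#' @param edge_mixing_width pixels of linear spectral mixing at target patch
#'   borders (0 disables mixing), default 1.
#' @param offset_region optional `c(row1, row2, col1, col2)` sub-rectangle.
#' @param offset_vector named per-band additive offset applied inside
#'   `offset_region`.
#' @param pixel_size meters per pixel, default 3.
#' @param seed integer seed making generation deterministic.
#' @return an object of class `pki_scene_config`.
#' @export
scene_config <- function(height = 160, width = 160,
                         templates = default_templates(), noise_sd = 0.01,
                         n_target_patches = 8, radius_range = c(4, 9),
                         cluster_factor = 3, cluster_sd = 15,
                         n_soil_patches = 3, n_water_patches = 2,
                         edge_mixing_width = 1, offset_region = NULL,
                         offset_vector = NULL, pixel_size = 3, seed = 1) {
  if (height < 8 || width < 8) stop("degenerate extent")
  if (!all(c("target", "grass") %in% names(templates)))
    stop("templates must include `target` and `grass`")
  bn <- names(templates[[1]])
  if (!all(vapply(templates, function(t) identical(names(t), bn), logical(1))))
    stop("template band-set mismatch across classes")
  if (any(unlist(templates) < 0)) stop("templates must be non-negative")
  if (any(noise_sd < 0)) stop("noise sd must be >= 0")
  if (!is.null(offset_region) && length(offset_region) != 4)
    stop("offset_region must be c(row1, row2, col1, col2)")
  structure(list(height = height, width = width, templates = templates,
                 noise_sd = noise_sd, n_target_patches = n_target_patches,
                 radius_range = radius_range, cluster_factor = cluster_factor,
                 cluster_sd = cluster_sd, n_soil_patches = n_soil_patches,
                 n_water_patches = n_water_patches,
                 edge_mixing_width = edge_mixing_width,
                 offset_region = offset_region, offset_vector = offset_vector,
                 pixel_size = pixel_size, seed = seed),
            class = "pki_scene_config")
}

# Rasterize a filled rotated ellipse into a logical mask.
ellipse_mask <- function(nr, nc, cy, cx, ry, rx, theta = 0) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

# Clustered ellipse placement (parent-child) for compact, coherent patches.
place_patches <- function(n, nr, nc, radius_range, cluster_factor, cluster_sd) {
  if (n == 0) return(matrix(FALSE, nr, nc))
  n_par <- max(1L, ceiling(n / max(1, cluster_factor)))
  pad <- radius_range[2] + 1
  py <- runif(n_par, pad, nr - pad)
  px <- runif(n_par, pad, nc - pad)
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(n)) {
    p <- ((i - 1) %% n_par) + 1
    cy <- min(max(py[p] + rnorm(1, 0, cluster_sd), pad), nr - pad)
    cx <- min(max(px[p] + rnorm(1, 0, cluster_sd), pad), nc - pad)
    ry <- runif(1, radius_range[1], radius_range[2])
    rx <- runif(1, radius_range[1], radius_range[2])
    mask <- mask | ellipse_mask(nr, nc, cy, cx, ry, rx, runif(1, 0, pi))
  }
  mask
}

# Box-blur a 0/1 matrix with a (2w+1)-sided window (clipped at borders);
# yields the local target cover fraction used for linear edge mixing.
box_fraction <- function(mask, w) {
  if (w <= 0) return(mask * 1)
  nr <- nrow(mask); nc <- ncol(mask)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  pm <- matrix(0, nr + 2 * w, nc + 2 * w)
  pm[(w + 1):(w + nr), (w + 1):(w + nc)] <- mask
  p1 <- matrix(0, nr + 2 * w, nc + 2 * w)
  p1[(w + 1):(w + nr), (w + 1):(w + nc)] <- 1
  for (dy in -w:w) for (dx in -w:w) {
    num <- num + pm[(w + 1 + dy):(w + nr + dy), (w + 1 + dx):(w + nc + dx)]
    den <- den + p1[(w + 1 + dy):(w + nr + dy), (w + 1 + dx):(w + nc + dx)]
  }
  num / den
}

#' Generate a synthetic scene and its label map
#'
#' Reflectance is the per-pixel class template, linearly mixed with the grass
#' background over `edge_mixing_width` pixels at target patch borders, plus
#' independent per-band Gaussian noise and the configured additive offset
#' inside `offset_region`. Deterministic under the config seed.
#'
#' @param config a [scene_config()].
#' @return list with `scene` (a [scene()]) and `labels`: `class` (character
#'   matrix: the dominant class per pixel), `target_fraction` (numeric matrix
#'   in \[0, 1\]; 1 = pure target, 0 = pure background, intermediate = mixed
#'   edge pixel), and `pure_target` / `pure_background` logical matrices.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "pki_scene_config")) stop("`config` must be a scene_config()")
  set.seed(config$seed)
  nr <- config$height; nc <- config$width
  tmpl <- config$templates
  bn <- names(tmpl[[1]])

  cls <- matrix("grass", nr, nc)
  if (!is.null(tmpl$soil) && config$n_soil_patches > 0) {
    m <- place_patches(config$n_soil_patches, nr, nc,
                       pmin(config$radius_range * 2, floor(min(nr, nc) / 4)),
                       1, 0)
    cls[m] <- "soil"
  }
  if (!is.null(tmpl$water_shadow) && config$n_water_patches > 0) {
    m <- place_patches(config$n_water_patches, nr, nc, config$radius_range,
                       1, 0)
    cls[m] <- "water_shadow"
  }
  target <- place_patches(config$n_target_patches, nr, nc,
                          config$radius_range, config$cluster_factor,
                          config$cluster_sd)
  cls[target] <- "target"
  frac <- box_fraction(target, config$edge_mixing_width)
  frac[target] <- pmax(frac[target], 0.5 + 1e-9)  # dominant class stays target

  bands <- setNames(vector("list", length(bn)), bn)
  for (b in bn) {
    base <- matrix(0, nr, nc)
    for (k in names(tmpl)) base[cls == k] <- tmpl[[k]][b]
    # linear mixing against grass in the edge zone around target patches
    mixzone <- frac > 0 & frac < 1
    base[mixzone] <- frac[mixzone] * tmpl$target[b] +
      (1 - frac[mixzone]) * tmpl$grass[b]
    sdv <- if (length(config$noise_sd) == 1) config$noise_sd else
      matrix(unname(config$noise_sd[cls]), nr, nc)
    if (any(sdv > 0)) base <- base + rnorm(nr * nc, 0, sdv)
    if (!is.null(config$offset_region) && !is.null(config$offset_vector) &&
        b %in% names(config$offset_vector)) {
      o <- config$offset_region
      base[o[1]:o[2], o[3]:o[4]] <- base[o[1]:o[2], o[3]:o[4]] +
        config$offset_vector[[b]]
    }
    bands[[b]] <- pmax(base, 0)
  }
  sc <- suppressWarnings(scene(bands, pixel_size = config$pixel_size))
  labels <- list(class = cls, target_fraction = frac,
                 pure_target = target & frac >= 1,
                 pure_background = !target & frac <= 0)
  list(scene = sc, labels = labels)
}

#' Draw labelled reference points from a synthetic label map
#'
#' PK points come from patch-interior pixels when `center_bias` is on
#' (interior = pixels whose full 3x3 neighborhood is pure target, mirroring
#' sampling from patch centers to avoid mixed pixels); OV points from pure
#' grass; NV points from pure soil or water pixels.
#'
#' @param labels the `labels` element of [generate_scene()].
#' @param n_per_class points per class (single number or named vector with
#'   entries PK, OV, NV).
#' @param center_bias restrict PK samples to patch interiors (default TRUE).
#' @param seed integer seed.
#' @param year year tag for the emitted points.
#' @return a `pki_reference_points` data frame (`row`, `col`, `class`, `year`).
#' @export
generate_reference_points <- function(labels, n_per_class = 50,
                                      center_bias = TRUE, seed = 1,
                                      year = NA_integer_) {
  set.seed(seed)
  if (length(n_per_class) == 1)
    n_per_class <- c(PK = n_per_class, OV = n_per_class, NV = n_per_class)
  pure_t <- labels$target_fraction >= 1
  pk_pool <- if (center_bias) {
    interior <- morph_filter(pure_t * 1, matrix(TRUE, nrow(pure_t),
                                                ncol(pure_t)), 3, "min") >= 1
    which(interior)
  } else which(pure_t)
  ov_pool <- which(labels$class == "grass" & labels$target_fraction <= 0)
  nv_pool <- which(labels$class %in% c("soil", "water_shadow") &
                     labels$target_fraction <= 0)
  pools <- list(PK = pk_pool, OV = ov_pool, NV = nv_pool)
  rows <- lapply(names(pools), function(k) {
    n <- if (k %in% names(n_per_class)) n_per_class[[k]] else 0
    if (n == 0) return(NULL)
    if (length(pools[[k]]) < n)
      stop("class ", k, " has only ", length(pools[[k]]),
           " eligible pixels (requested ", n, ")")
    i <- pools[[k]][sample.int(length(pools[[k]]), n)]
    data.frame(row = ((i - 1) %% nrow(labels$class)) + 1,
               col = ((i - 1) %/% nrow(labels$class)) + 1,
               class = k, year = as.integer(year))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pki_reference_points", "data.frame")
  out
}

#' Generate a scripted multi-year stack of scenes with known truth
#'
#' Patch geometry is generated once and each patch is switched on or off per
#' year by the script, so persistence classes (ephemeral, continuous,
#' recurrent) of the truth stack are known by construction. Scenes for all
#' years share extent, templates and noise model; each year gets an
#' independent noise draw.
#'
#' @param years integer vector (>= 3 years).
#' @param patch_years list, one integer vector per patch giving the years the
#'   patch is present; patch count = `length(patch_years)`.
#' @param config a [scene_config()]; its `n_target_patches` is overridden by
#'   the script length.
#' @return list with `scenes` (per-year [scene()]s), `truth` (a
#'   [annual_stack()] of pure-geometry presence maps), `labels` (per-year
#'   label maps) and `patch_masks` (per-patch logical matrices).
#' @export
generate_annual_stack <- function(years, patch_years, config = scene_config()) {
  if (length(years) < 3) stop("need >= 3 years")
  if (!all(unlist(patch_years) %in% years))
    stop("patch_years references years outside `years`")
  set.seed(config$seed)
  nr <- config$height; nc <- config$width
  n <- length(patch_years)
  n_par <- max(1L, ceiling(n / max(1, config$cluster_factor)))
  pad <- config$radius_range[2] + 1
  py <- runif(n_par, pad, nr - pad)
  px <- runif(n_par, pad, nc - pad)
  patch_masks <- lapply(seq_len(n), function(i) {
    p <- ((i - 1) %% n_par) + 1
    cy <- min(max(py[p] + rnorm(1, 0, config$cluster_sd), pad), nr - pad)
    cx <- min(max(px[p] + rnorm(1, 0, config$cluster_sd), pad), nc - pad)
    ellipse_mask(nr, nc, cy, cx,
                 runif(1, config$radius_range[1], config$radius_range[2]),
                 runif(1, config$radius_range[1], config$radius_range[2]),
                 runif(1, 0, pi))
  })
  # static background features (soil, water) shared by all years
  soil <- if (!is.null(config$templates$soil) && config$n_soil_patches > 0)
    place_patches(config$n_soil_patches, nr, nc,
                  pmin(config$radius_range * 2, floor(min(nr, nc) / 4)), 1, 0)
  else matrix(FALSE, nr, nc)
  water <- if (!is.null(config$templates$water_shadow) &&
               config$n_water_patches > 0)
    place_patches(config$n_water_patches, nr, nc, config$radius_range, 1, 0)
  else matrix(FALSE, nr, nc)
  scenes <- list(); labels <- list(); truth_maps <- list()
  for (k in seq_along(years)) {
    yr <- years[k]
    on <- vapply(patch_years, function(p) yr %in% p, logical(1))
    target <- Reduce(`|`, patch_masks[on], matrix(FALSE, nr, nc))
    cfg_y <- config
    cfg_y$seed <- config$seed + k  # independent noise per year
    gen <- generate_scene_from_mask(target, cfg_y, soil = soil, water = water)
    scenes[[k]] <- gen$scene
    labels[[k]] <- gen$labels
    truth_maps[[k]] <- binary_map(target, year = yr,
                                  rule_descriptor = "scripted truth",
                                  pixel_size = config$pixel_size)
  }
  list(scenes = setNames(scenes, years), truth = annual_stack(truth_maps),
       labels = setNames(labels, years), patch_masks = patch_masks)
}

# Scene synthesis for a fixed target mask (shared by generate_annual_stack).
generate_scene_from_mask <- function(target, config, soil = NULL,
                                     water = NULL) {
  set.seed(config$seed)
  nr <- config$height; nc <- config$width
  tmpl <- config$templates
  bn <- names(tmpl[[1]])
  cls <- matrix("grass", nr, nc)
  if (!is.null(soil)) cls[soil & !target] <- "soil"
  if (!is.null(water)) cls[water & !target] <- "water_shadow"
  cls[target] <- "target"
  frac <- box_fraction(target, config$edge_mixing_width)
  frac[target] <- pmax(frac[target], 0.5 + 1e-9)
  bands <- setNames(vector("list", length(bn)), bn)
  for (b in bn) {
    base <- matrix(tmpl$grass[b], nr, nc)
    for (k in c("soil", "water_shadow"))
      if (!is.null(tmpl[[k]])) base[cls == k] <- tmpl[[k]][b]
    mix <- frac > 0
    base[mix] <- frac[mix] * tmpl$target[b] + (1 - frac[mix]) * tmpl$grass[b]
    if (any(config$noise_sd > 0))
      base <- base + rnorm(nr * nc, 0, config$noise_sd[1])
    bands[[b]] <- pmax(base, 0)
  }
  list(scene = suppressWarnings(scene(bands, pixel_size = config$pixel_size)),
       labels = list(class = cls, target_fraction = frac,
                     pure_target = target & frac >= 1,
                     pure_background = !target & frac <= 0))
}
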