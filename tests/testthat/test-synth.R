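test_that("zero-noise scenes reproduce class templates exactly", {
  cfg <- scene_config(height = 80, width = 80, noise_sd = 0,
                      edge_mixing_width = 0, seed = 21)
  gen <- generate_scene(cfg)
  tmpl <- default_templates()
  for (k in names(tmpl)) {
    px <- gen$labels$class == k & gen$labels$target_fraction %in% c(0, 1)
    if (!any(px)) next
    for (b in names(tmpl[[k]]))
      expect_true(all(gen$scene$bands[[b]][px] == tmpl[[k]][b]),
                  label = paste(k, b))
  }
})

test_that("default templates put the raw index above 1 on target, below 1 on background", {
  tmpl <- default_templates()
  raw <- function(t) (t["red_edge"] + t["blue"]) / (2.5 * t["green"])
  expect_gt(raw(tmpl$target), 1)
  expect_lt(raw(tmpl$grass), 1)
  expect_lt(raw(tmpl$soil), 1)
  expect_gt(tmpl$target["red"], 0.05)
  # the dark-water template is the deliberate ratio-inflation case:
  # raw index above 1 but red at or below the 0.05 floor
  expect_gt(raw(tmpl$water_shadow), 1)
  expect_lte(tmpl$water_shadow["red"], 0.05)
  # and the same holds on a generated zero-noise scene
  cfg <- scene_config(height = 80, width = 80, noise_sd = 0,
                      edge_mixing_width = 0, seed = 22)
  gen <- generate_scene(cfg)
  pkir <- compute_pki_raw(gen$scene)
  tgt <- gen$labels$class == "target"
  grs <- gen$labels$class == "grass"
  expect_true(all(pkir$values[tgt] > 1))
  expect_true(all(pkir$values[grs] < 1))
})

test_that("scene generation is deterministic under a fixed seed", {
  cfg <- scene_config(seed = 33)
  g1 <- generate_scene(cfg)
  g2 <- generate_scene(cfg)
  expect_identical(g1$scene$bands, g2$scene$bands)
  expect_identical(g1$labels, g2$labels)
  g3 <- generate_scene(scene_config(seed = 34))
  expect_false(identical(g1$scene$bands, g3$scene$bands))
  p1 <- generate_reference_points(g1$labels, 20, seed = 5)
  p2 <- generate_reference_points(g1$labels, 20, seed = 5)
  expect_identical(p1, p2)
  p3 <- generate_reference_points(g1$labels, 20, seed = 6)
  expect_false(identical(p1$row, p3$row))
  expect_equal(table(p3$class), table(p1$class))  # same class counts
})

test_that("center bias restricts target points to patch interiors", {
  # hand-built label map with a single 3x3 target patch: only its center
  # pixel has a full 3x3 target neighborhood
  cls <- matrix("grass", 9, 9)
  cls[4:6, 4:6] <- "target"
  frac <- matrix(0, 9, 9); frac[4:6, 4:6] <- 1
  labels <- list(class = cls, target_fraction = frac)
  pts <- generate_reference_points(labels, c(PK = 1, OV = 5, NV = 0),
                                   center_bias = TRUE, seed = 1)
  pk <- pts[pts$class == "PK", ]
  expect_equal(c(pk$row, pk$col), c(5, 5))
  expect_error(generate_reference_points(labels, c(PK = 2, OV = 5, NV = 0),
                                         center_bias = TRUE, seed = 1),
               "eligible")
  # without center bias all 9 patch pixels are eligible
  pts2 <- generate_reference_points(labels, c(PK = 9, OV = 5, NV = 0),
                                    center_bias = FALSE, seed = 1)
  expect_equal(nrow(pts2[pts2$class == "PK", ]), 9)
})

test_that("cross-scene additive offsets create false positives inside the region only", {
  cfg <- scene_config(height = 100, width = 100, noise_sd = 0,
                      edge_mixing_width = 0, n_target_patches = 0,
                      n_soil_patches = 0, n_water_patches = 0,
                      offset_region = c(10, 40, 10, 40),
                      offset_vector = c(blue = 0.10, red = 0.10,
                                        red_edge = 0.15),
                      seed = 44)
  gen <- generate_scene(cfg)
  pki <- compute_pki(gen$scene)
  bm <- classify_fixed(pki, gen$scene)
  inside <- matrix(FALSE, 100, 100); inside[10:40, 10:40] <- TRUE
  expect_gt(sum(bm$presence[inside]), 0)     # offset-driven false positives
  expect_equal(sum(bm$presence[!inside]), 0) # none outside the region
})

test_that("scripted annual stacks encode patch persistence by construction", {
  cfg <- scene_config(height = 120, width = 120, seed = 13,
                      cluster_factor = 1, cluster_sd = 0)
  years <- 2021:2023
  script <- list(2022, 2021:2023, c(2021, 2023))
  sim <- generate_annual_stack(years, script, cfg)
  expect_equal(length(sim$scenes), 3)
  expect_equal(sim$truth$years, years)
  # truth maps are exactly the union of the scripted patch masks
  for (k in seq_along(years)) {
    on <- vapply(script, function(p) years[k] %in% p, logical(1))
    want <- Reduce(`|`, sim$patch_masks[on], matrix(FALSE, 120, 120))
    expect_identical(sim$truth$maps[[k]]$presence, want)
  }
  expect_error(generate_annual_stack(years, list(2020), cfg), "outside")
})

test_that("generator rejects invalid configurations", {
  expect_error(scene_config(height = 4), "degenerate")
  expect_error(scene_config(noise_sd = -1), "noise sd")
  tmpl <- default_templates()
  tmpl$target <- tmpl$target * -1
  expect_error(scene_config(templates = tmpl), "non-negative")
  tmpl2 <- default_templates()
  tmpl2$soil <- tmpl2$soil[-1]
  expect_error(scene_config(templates = tmpl2), "band-set mismatch")
})
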