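test_that("scene construction enforces aligned grids and band vocabulary", {
  b <- matrix(0.1, 4, 5)
  sc <- scene(list(blue = b, green = b, red = b, red_edge = b, nir = b))
  expect_equal(dim(sc), c(4, 5))
  expect_false(any(sc$nodata_mask))
  expect_error(scene(list(blue = b, green = matrix(0.1, 3, 5), red = b,
                          red_edge = b, nir = b)),
               "identical dimensions")
  expect_error(scene(list(blau = b)), "unknown band")
  expect_error(scene(list(blue = b), pixel_size = 0), "positive")
  expect_warning(scene(list(blue = b * 20, green = b, red = b,
                            red_edge = b, nir = b)),
                 "outside")
  # non-finite values are folded into the nodata mask
  b2 <- b; b2[2, 3] <- NA
  sc2 <- scene(list(blue = b2, green = b, red = b, red_edge = b, nir = b))
  expect_true(sc2$nodata_mask[2, 3])
  expect_equal(sum(sc2$nodata_mask), 1)
})

test_that("scene and raster round-trips preserve values, masks and georeferencing", {
  set.seed(42)
  bands <- lapply(setNames(nm = c("blue", "green", "red", "red_edge", "nir")),
                  function(b) matrix(runif(30, 0.01, 0.6), 5, 6))
  nd <- matrix(FALSE, 5, 6); nd[1, 1] <- TRUE; nd[4, 2] <- TRUE
  gt <- c(xmin = 500, ymax = 1000, xres = 3, yres = 3)
  sc <- scene(bands, nodata_mask = nd, geotransform = gt, crs_id = "EPSG:32645")
  f <- tempfile(fileext = ".tif")
  write_scene(sc, f)
  rt <- read_scene(f)
  for (b in names(bands))
    expect_lt(max(abs(rt$bands[[b]][!nd] - bands[[b]][!nd])), 1e-6)
  expect_equal(rt$nodata_mask, nd)
  expect_equal(unname(rt$geotransform), unname(gt))
  expect_equal(rt$crs_id, "EPSG:32645")

  # index map: wide value range restored through the sidecar scaling
  v <- matrix(rnorm(30, 0, 8), 5, 6)
  valid <- matrix(TRUE, 5, 6); valid[2, 2] <- FALSE
  im <- index_map(v, valid, "ARI", geotransform = gt)
  f2 <- tempfile(fileext = ".tif")
  write_raster(im, f2)
  rt2 <- read_raster(f2)
  expect_s3_class(rt2, "pki_index_map")
  expect_equal(rt2$valid_mask, im$valid_mask)
  rng <- diff(range(v[valid]))
  expect_lt(max(abs(rt2$values[valid] - v[valid])), rng * 2^-23)
  expect_true(is.na(rt2$values[2, 2]))

  # binary map: exact boolean round-trip
  bm <- binary_map(matrix(runif(30) > 0.5, 5, 6), year = 2022L,
                   rule_descriptor = "fixed", geotransform = gt)
  f3 <- tempfile(fileext = ".tif")
  write_raster(bm, f3)
  rt3 <- read_raster(f3)
  expect_identical(rt3$presence, bm$presence)
  expect_identical(rt3$year, 2022L)
})

test_that("read_scene applies band mapping, nodata flagging and integer rescale", {
  # sidecar-free multiband file read through an explicit band mapping
  pages <- lapply(1:8, function(i) matrix(i / 10, 4, 4))
  pages[[2]][1, 1] <- 0; pages[[4]][1, 1] <- 0; pages[[6]][1, 1] <- 0
  pages[[7]][1, 1] <- 0; pages[[8]][1, 1] <- 0
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 32L)
  mp <- c(blue = 2, green = 4, red = 6, red_edge = 7, nir = 8)
  sc <- read_scene(f, band_mapping = mp, nodata = 0)
  expect_equal(names(sc$bands), names(mp))
  expect_equal(sc$bands$red_edge[2, 2], 0.7, tolerance = 1e-6)
  # pixels equal to the nodata value in every band are masked (direct scan)
  direct <- Reduce(`&`, lapply(mp, function(i) pages[[i]] == 0))
  expect_equal(sc$nodata_mask, direct)
  expect_error(read_scene(f, band_mapping = mp[-4]), "required band absent")
  expect_error(read_scene(f, band_mapping = c(mp, coastal_blue = 99)),
               "exceeds page count")
  expect_error(read_scene(tempfile(), band_mapping = mp), "not found")
  # forced rescale divides by the scaled-integer convention (10000)
  sc2 <- read_scene(f, band_mapping = mp, rescale = TRUE)
  expect_equal(sc2$bands$blue[2, 2], 0.2 / 10000, tolerance = 1e-9)
})

test_that("reference points are parsed, normalized and bounded by the extent", {
  b <- matrix(0.1, 10, 10)
  sc <- scene(list(blue = b, green = b, red = b, red_edge = b, nir = b),
              pixel_size = 3)  # extent x [0,30], y [0,30]
  csv <- tempfile(fileext = ".csv")
  writeLines(c("x,y,class,year",
               "1.5,28.5,PK,2021",     # row 1, col 1
               "16.5,16.5,ov ,2021",   # row 5, col 6
               "28.5,1.5,Non-vegetation,2022",
               "99,99,PK,2022"),       # outside
             csv)
  expect_message(pts <- read_reference_points(csv, sc), "excluded 1")
  expect_equal(nrow(pts), 3)
  expect_equal(pts$class, c("PK", "OV", "NV"))
  expect_equal(attr(pts, "n_excluded"), 1)
  expect_equal(pts$row[1], 1L); expect_equal(pts$col[1], 1L)
  expect_equal(pts$row[2], 5L); expect_equal(pts$col[2], 6L)

  writeLines(c("x,y,class,year", "1.5,1.5,shrubbery,2021"), csv)
  expect_error(read_reference_points(csv, sc), "unknown class label")

  gj <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(4.5, 25.5)),
           properties = list(class = " pk", year = 2023)),
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(7.5, 7.5)),
           properties = list(class = "grass", year = 2023)))),
    gj, auto_unbox = TRUE)
  pts2 <- read_reference_points(gj, sc)
  expect_equal(pts2$class, c("PK", "OV"))
  expect_equal(pts2$row[1], 2L)
  expect_equal(pts2$col[1], 2L)
})
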