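# Small helper: a binary map from a logical matrix with a year tag.
bmap <- function(m, year) binary_map(m, year = year, pixel_size = 3)

test_that("invaded area follows the pixel-count arithmetic", {
  m <- matrix(FALSE, 100, 100)
  expect_equal(invaded_area(bmap(m, 2021L)), 0)
  m[] <- TRUE
  expect_equal(invaded_area(bmap(m, 2021L)), 9)        # 10^4 px * 9 m2 / 10^4
  m2 <- matrix(FALSE, 200, 100); m2[1:100, 1] <- TRUE
  expect_equal(invaded_area(bmap(m2, 2021L)), 100 * 9 / 1e4)
  expect_equal(invaded_area(bmap(m, 2021L), pixel_area_m2 = 25), 25)
  expect_error(invaded_area(bmap(m, 2021L), pixel_area_m2 = 0), "> 0")
})

test_that("linear trend reproduces the published five-year worked example", {
  tr <- linear_trend(2021:2025, c(250.00, 2168.16, 2042.48, 797.52, 159.73))
  expect_equal(round(tr$slope, 2), -155.12)
  expect_equal(round(tr$r2, 2), 0.06)
  expect_equal(round(tr$p_value, 2), 0.68)
  expect_equal(round(tr$mean_area, 2), 1083.58)
  # perfectly linear series (lm warns about the perfect fit)
  tr2 <- suppressWarnings(linear_trend(2021:2025, 100 + 7 * (0:4)))
  expect_equal(tr2$slope, 7)
  expect_equal(tr2$r2, 1)
  # constant series (again a degenerate fit, so lm warns)
  tr3 <- suppressWarnings(linear_trend(2021:2025, rep(5, 5)))
  expect_equal(tr3$slope, 0)
  expect_equal(tr3$r2, 0)
  expect_error(linear_trend(c(2021, 2021, 2022), c(1, 2, 3)), "distinct")
  expect_error(linear_trend(2021:2022, c(1, 2)), ">= 3")
})

test_that("series correlation is plain Pearson r", {
  a <- c(1, 2, 3)
  expect_equal(series_correlation(a, a), 1)
  expect_equal(series_correlation(a, -a), -1)
  expect_equal(series_correlation(a, c(2, 4, 5)),
               cov(a, c(2, 4, 5)) / (sd(a) * sd(c(2, 4, 5))))
  expect_equal(round(series_correlation(a, c(2, 4, 5)), 7), 0.9819805)
  expect_error(series_correlation(a, rep(1, 3)), "variance")
})

test_that("persistence typology matches the published category definitions", {
  m0 <- matrix(FALSE, 4, 4)
  put <- function(m, i, j) { m[i, j] <- TRUE; m }
  y1 <- m0; y2 <- m0; y3 <- m0
  y2 <- put(y2, 1, 1)                       # present 2022 only -> ephemeral
  for (y in 1:3) assign(paste0("y", y), put(get(paste0("y", y)), 2, 2))
  # (2,2) present all three years -> continuous
  y1 <- put(y1, 3, 3); y3 <- put(y3, 3, 3)  # gap year -> recurrent
  y1 <- put(y1, 4, 4); y2 <- put(y2, 4, 4)  # two consecutive years
  stk <- annual_stack(list(bmap(y1, 2021L), bmap(y2, 2022L), bmap(y3, 2023L)))
  p <- persistence_classify(stk)            # default merges two-year runs
  expect_equal(p$category[1, 1], "ephemeral")
  expect_equal(p$category[2, 2], "continuous")
  expect_equal(p$category[3, 3], "recurrent")
  expect_equal(p$category[4, 4], "continuous")
  expect_equal(p$category[1, 2], "never")
  p4 <- persistence_classify(stk, merge_short = FALSE)
  expect_equal(p4$category[4, 4], "short_continuous")
  # areas partition the footprint exactly and shares sum to 100
  expect_equal(sum(p$summary$area_ha), p$total_footprint_ha)
  expect_equal(sum(p$summary$share_pct), 100)
  expect_equal(p$total_footprint_ha, 4 * 9 / 1e4)
})

test_that("persistence classes match a per-pixel enumeration oracle", {
  set.seed(404)
  ny <- 5
  maps <- lapply(1:ny, function(k)
    bmap(matrix(runif(12 * 12) < 0.35, 12, 12), 2020L + k))
  stk <- annual_stack(maps)
  got <- persistence_classify(stk)$category
  arr <- sapply(maps, function(m) m$presence)   # 144 x 5
  for (px in seq_len(144))
    expect_equal(got[px], oracle_persistence(arr[px, ]),
                 label = paste("pixel", px))
  # partition property on the random stack
  s <- persistence_classify(stk)$summary
  expect_equal(sum(s$area_ha),
               sum(Reduce(`|`, lapply(maps, function(m) m$presence))) * 9 / 1e4)
})

test_that("published share arithmetic is reproduced", {
  shares <- persistence_shares(c(4824.7, 161.6, 125.4))
  expect_equal(round(shares, 1), c(94.4, 3.2, 2.5))
  expect_equal(sum(c(4824.7, 161.6, 125.4)), 5111.7)
})

test_that("recurrence statistics follow the re-appearance definition", {
  m0 <- matrix(FALSE, 5, 5)
  put <- function(m, i, j) { m[i, j] <- TRUE; m }
  # pixel (1,1): years 1 and 3 -> recurs in year 3
  # pixel (2,2): years 1,2,3  -> never recurs (no absence gap)
  y1 <- put(put(m0, 1, 1), 2, 2)
  y2 <- put(m0, 2, 2)
  y3 <- put(put(m0, 1, 1), 2, 2)
  stk <- annual_stack(list(bmap(y1, 1L), bmap(y2, 2L), bmap(y3, 3L)))
  rs <- recurrence_stats(stk)
  expect_equal(rs$year, 3L)
  expect_equal(rs$recurrence_area_ha, 9 / 1e4)
  expect_equal(rs$invaded_area_ha, 2 * 9 / 1e4)
  expect_equal(rs$recurrence_rate, 0.5)
  # no pixel ever re-appears -> all zero
  stk2 <- annual_stack(list(bmap(y1, 1L), bmap(y1, 2L), bmap(y1, 3L)))
  rs2 <- recurrence_stats(stk2)
  expect_true(all(rs2$recurrence_area_ha == 0))
  expect_true(all(rs2$recurrence_rate == 0))
  # recurrence area can never exceed the year's invaded area
  set.seed(55)
  maps <- lapply(1:6, function(k)
    bmap(matrix(runif(100) < 0.4, 10, 10), 2000L + k))
  rs3 <- recurrence_stats(annual_stack(maps))
  expect_true(all(rs3$recurrence_area_ha <= rs3$invaded_area_ha))
})

test_that("density grids aggregate presence fractions with marginal profiles", {
  # uniform full presence -> all densities 1, flat profiles
  full <- bmap(matrix(TRUE, 30, 30), 2021L)          # 90 m x 90 m at 3 m/px
  dg <- density_grid(full, cell_size_m = 30)          # 3 x 3 cells
  expect_equal(dim(dg$density), c(3, 3))
  expect_true(all(dg$density == 1))
  expect_equal(dg$col_profile, rep(1, 3))
  expect_equal(dg$row_profile, rep(1, 3))
  # empty map -> zeros
  dg0 <- density_grid(bmap(matrix(FALSE, 30, 30), 2021L), 30)
  expect_true(all(dg0$density == 0))
  # presence confined to the central cell
  m <- matrix(FALSE, 30, 30); m[11:20, 11:20] <- TRUE
  dgc <- density_grid(bmap(m, 2021L), 30)
  expect_equal(dgc$density[2, 2], 1)
  expect_equal(sum(dgc$density), 1)
  expect_equal(dgc$col_profile, c(0, 1 / 3, 0))
  expect_equal(dgc$row_profile, c(0, 1 / 3, 0))
  expect_error(density_grid(full, cell_size_m = 1), ">=")
  # mean density * valid area ~ invaded area (exact here: divisible grid)
  set.seed(66)
  mr <- matrix(runif(900) < 0.3, 30, 30)
  dgr <- density_grid(bmap(mr, 2021L), 30)
  expect_equal(mean(dgr$density) * 30 * 30 * 9 / 1e4,
               invaded_area(bmap(mr, 2021L)))
})

test_that("change grids are pixelwise differences and antisymmetric", {
  set.seed(8)
  m1 <- bmap(matrix(runif(900) < 0.3, 30, 30), 2021L)
  m2 <- bmap(matrix(runif(900) < 0.5, 30, 30), 2022L)
  d1 <- density_grid(m1, 30); d2 <- density_grid(m2, 30)
  cg <- change_grid(d1, d2)
  expect_equal(cg$delta, d2$density - d1$density)
  expect_equal(change_grid(d2, d1)$delta, -cg$delta)
  expect_true(all(change_grid(d1, d1)$delta == 0))
  # full turnover
  dfull <- density_grid(bmap(matrix(TRUE, 30, 30), 2022L), 30)
  dempty <- density_grid(bmap(matrix(FALSE, 30, 30), 2021L), 30)
  expect_true(all(change_grid(dempty, dfull)$delta == 1))
  expect_equal(change_grid(dempty, dfull)$col_profile, rep(1, 3))
  d_bad <- density_grid(m1, 15)
  expect_error(change_grid(d1, d_bad), "mismatch")
})

test_that("annual stacks enforce ordering and co-registration", {
  m <- matrix(FALSE, 4, 4)
  expect_error(annual_stack(list(bmap(m, 2021L), bmap(matrix(FALSE, 5, 4),
                                                      2022L))),
               "mixed extents")
  expect_error(annual_stack(list(bmap(m, 2021L), bmap(m, 2021L))),
               "strictly increasing")
  stk <- annual_stack(list(bmap(m, 2023L), bmap(m, 2021L), bmap(m, 2022L)))
  expect_equal(stk$years, 2021:2023)   # reordered by year
  expect_error(persistence_classify(annual_stack(list(bmap(m, 1L),
                                                      bmap(m, 2L)))),
               ">= 3 years")
})
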