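# Growing-season month rules, season means, area weighting and
# multi-season combination.

test_that("March planting / September harvest spans March..September", {
  m <- growing_season_months(61, 266)   # Mar 2, Sep 23
  expect_equal(m$month, 3:9)
  expect_equal(m$year_offset, rep(0L, 7))
  # day variants within the same months give the same result
  m2 <- growing_season_months(88, 248)  # Mar 29, Sep 5
  expect_equal(m2$month, 3:9)
})

test_that("wheat rule returns the four months ending at harvest", {
  m <- growing_season_months(288, 196, rule = "wheat")  # harvest mid-July
  expect_equal(m$month, 4:7)
  expect_equal(m$year_offset, rep(0L, 4))
  # harvest in February wraps into the previous year
  m2 <- growing_season_months(288, 51, rule = "wheat")
  expect_equal(m2$month, c(11, 12, 1, 2))
  expect_equal(m2$year_offset, c(-1L, -1L, 0L, 0L))
})

test_that("cross-year seasons span the year boundary", {
  m <- growing_season_months(314, 51)   # Nov 10 -> Feb 20
  expect_equal(m$month, c(11, 12, 1, 2))
  expect_equal(m$year_offset, c(-1L, -1L, 0L, 0L))
  # same-month season is a single month, not an error
  m1 <- growing_season_months(91, 110)
  expect_equal(nrow(m1), 1)
})

test_that("season_mean is the plain mean and propagates missing months", {
  expect_equal(season_mean(rep(7, 12), 3:9), 7)
  expect_equal(season_mean(c(1, 2, 3), 1:3), 2)
  expect_equal(season_mean(c(5, 10), 2), 10)
  expect_true(is.na(season_mean(c(1, NA, 3), 1:3)))
})

test_that("area-weighted mean handles weights and missing cells", {
  expect_equal(area_weighted_region_mean(c(1, 3), c(0.25, 0.75)), 2.5)
  expect_equal(area_weighted_region_mean(c(1, 2, 3), rep(1, 3)), 2)
  expect_equal(area_weighted_region_mean(5, 1), 5)
  # renormalization over available cells
  expect_equal(
    suppressWarnings(area_weighted_region_mean(c(1, NA), c(0.25, 0.75))), 1)
  expect_warning(area_weighted_region_mean(c(1, NA), c(0.25, 0.75)),
                 "renormalizing")
  expect_true(is.na(area_weighted_region_mean(c(NA, NA), c(1, 1))))
})

test_that("multi-season combination is the season-weighted average", {
  p1 <- data.frame(region = "A", year = 1:3, temp = c(20, 21, 22),
                   spei = c(0.1, 0.2, 0.3))
  p2 <- data.frame(region = "A", year = 1:3, temp = c(30, 31, 32),
                   spei = c(-0.1, -0.2, -0.3))
  c55 <- combine_multi_season(list(p1, p2), c(0.5, 0.5))
  expect_equal(c55$temp, c(25, 26, 27))
  expect_equal(c55$spei, rep(0, 3))
  c10 <- combine_multi_season(list(p1, p2), c(1, 0))
  expect_equal(c10$temp, p1$temp)
  expect_error(combine_multi_season(list(p1), c(0.5, 0.5)), "one weight")
})

test_that("aggregation matches a hand-computed weighted season mean", {
  # 1 region, 2 cells, 2 years of known monthly values
  grid <- expand.grid(month = 1:12, year = 2001:2002,
                      cell = c("A_c1", "A_c2"), KEEP.OUT.ATTRS = FALSE)
  grid$region <- "A"
  grid$temp <- ifelse(grid$cell == "A_c1", grid$month,
                      grid$month + 10) + (grid$year - 2001)
  grid$spei <- ifelse(grid$cell == "A_c1", 0.5, -0.5)
  cal <- data.frame(region = "A", crop = "maize", season = 1,
                    plant_doy = 61, harvest_doy = 266, weight = 1)
  w <- data.frame(cell = c("A_c1", "A_c2"), region = "A",
                  weight = c(0.25, 0.75))
  out <- aggregate_climate(grid, cal, w, crop = "maize")
  # cell means Mar-Sep: mean(3:9)=6 (c1, year 2001), 16 (c2)
  expect_equal(out$temp[out$year == 2001], 0.25 * 6 + 0.75 * 16)
  expect_equal(out$temp[out$year == 2002], 0.25 * 7 + 0.75 * 17)
  expect_equal(out$spei, c(-0.25, -0.25))
})

test_that("maize uses the main season only; rice weights both", {
  grid <- expand.grid(month = 1:12, year = 2001:2002, cell = "A_c1",
                      KEEP.OUT.ATTRS = FALSE)
  grid$region <- "A"
  grid$temp <- grid$month
  grid$spei <- ifelse(grid$month <= 6, 1, -1)
  cal <- data.frame(region = "A", crop = c("maize", "maize",
                                           "rice", "rice"),
                    season = c(1, 2, 1, 2),
                    plant_doy = c(61, 182, 61, 182),
                    harvest_doy = c(151, 266, 151, 266),
                    weight = c(0.8, 0.2, 0.7, 0.3))
  w <- data.frame(cell = "A_c1", region = "A", weight = 1)
  maize <- aggregate_climate(grid, cal, w, crop = "maize")
  # main season Mar-May only: mean(3:5) = 4
  expect_equal(maize$temp, c(4, 4))
  rice <- aggregate_climate(grid, cal, w, crop = "rice")
  expect_equal(rice$temp, 0.7 * 4 + 0.3 * mean(7:9) + c(0, 0))
})

test_that("cross-year aggregation pulls months from the prior year", {
  grid <- expand.grid(month = 1:12, year = 2001:2003, cell = "A_c1",
                      KEEP.OUT.ATTRS = FALSE)
  grid$region <- "A"
  grid$temp <- grid$year + grid$month / 100
  grid$spei <- 0
  cal <- data.frame(region = "A", crop = "soy", season = 1,
                    plant_doy = 314, harvest_doy = 51, weight = 1)
  w <- data.frame(cell = "A_c1", region = "A", weight = 1)
  out <- aggregate_climate(grid, cal, w, crop = "soy")
  # harvest year 2002 uses Nov, Dec 2001 and Jan, Feb 2002
  expect_equal(out$year, 2002:2003)  # 2001 lacks Nov/Dec 2000
  expect_equal(out$temp[1], mean(c(2001.11, 2001.12, 2002.01, 2002.02)))
})

test_that("aggregation is linear and invariant to weight rescaling", {
  set.seed(1)
  cfg <- syn_config(n_regions = 2, n_cells_per_region = 3,
                    years = 2005:2010, seed = 21)
  grid <- gen_climate_grid(cfg)
  cal <- gen_crop_calendar(cfg)
  w <- gen_area_weights(cfg)
  base <- aggregate_climate(grid, cal, w, crop = cfg$crop)
  g2 <- grid; g2$temp <- 3 * g2$temp; g2$spei <- 3 * g2$spei
  scaled <- aggregate_climate(g2, cal, w, crop = cfg$crop)
  expect_equal(scaled$temp, 3 * base$temp)
  expect_equal(scaled$spei, 3 * base$spei)
  # shuffle cells and rescale weights by a region constant
  perm <- sample(nrow(grid))
  w2 <- w; w2$weight <- w2$weight * ifelse(w2$region == w2$region[1], 7, 3)
  again <- aggregate_climate(grid[perm, ], cal, w2, crop = cfg$crop)
  expect_equal(again$temp, base$temp, tolerance = 1e-12)
})
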