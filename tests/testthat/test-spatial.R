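flat_raster <- function(v, nr, nc, cell = 0.05, xmin = -80, ymax = -10) {
  grid_raster(matrix(v, nr, nc), xmin = xmin, ymax = ymax, cell = cell)
}

test_that("range reconstruction intersects regions with the elevation band", {
  dem <- flat_raster(c(100, 500, 1200), 1, 3)
  reg <- flat_raster(1, 1, 3)
  tr <- taxon_range("t", 1, 400, 1000)
  expect_equal(as.vector(reconstruct_range(tr, reg, dem)$values),
               c(FALSE, TRUE, FALSE))
  # all-covering band reduces to region membership
  reg2 <- flat_raster(c(1, 2, 1), 1, 3)
  tr2 <- taxon_range("t", 1, -1e6, 1e6)
  expect_equal(as.vector(reconstruct_range(tr2, reg2, dem)$values),
               c(TRUE, FALSE, TRUE))
  # wrong region wins over elevation
  tr3 <- taxon_range("t", 9, 0, 2000)
  expect_false(any(reconstruct_range(tr3, reg, dem)$values))
  expect_error(reconstruct_range(tr, reg, flat_raster(0, 2, 3)),
               "co-registered")
})

test_that("occupancy conserves area and applies the strict 5% rule", {
  set.seed(61)
  mask <- flat_raster(runif(40 * 40) < 0.3, 40, 40, cell = 0.05)
  occ <- grid_occupancy(mask, 0.5)
  fine_area <- sum(endophylo:::cell_areas_km2(mask)[mask$values])
  expect_equal(sum(occ$area$values), fine_area, tolerance = 1e-9)

  # boundary behavior: 4% absent, 6% present
  m2 <- flat_raster(FALSE, 100, 100, cell = 0.05)
  m2$values[1:20, 1:20] <- FALSE
  m2$values[cbind(sample(1:10, 4), 1:4)] <- TRUE  # 4 of 100 fine cells
  o2 <- grid_occupancy(m2, 0.5)
  expect_false(o2$presence$values[1, 1])
  m2$values[1:10, 1:10] <- FALSE
  m2$values[1, 1:6] <- TRUE                       # 6 of 100 fine cells
  o3 <- grid_occupancy(m2, 0.5)
  expect_true(o3$presence$values[1, 1])
  expect_error(grid_occupancy(m2, 0.13), "integer multiple")
})

test_that("cell areas follow the cosine of latitude", {
  eq <- grid_raster(matrix(TRUE, 1, 1), 0, 0.025, 0.05)   # centred on 0
  hi <- grid_raster(matrix(TRUE, 1, 1), 0, 60.025, 0.05)  # centred on 60
  a_eq <- endophylo:::cell_areas_km2(eq)[1, 1]
  a_hi <- endophylo:::cell_areas_km2(hi)[1, 1]
  expect_equal(a_eq / a_hi, 1 / cos(60 * pi / 180), tolerance = 1e-4)
})

test_that("trait surfaces are area-weighted means bounded by the
           contributing extremes", {
  reg <- flat_raster(1, 10, 10, cell = 0.05)
  dem <- flat_raster(500, 10, 10, cell = 0.05)
  ranges <- list(taxon_range("A", 1, 0, 1000),
                 taxon_range("B", 1, 0, 1000))
  occ <- occupancy_set(ranges, reg, dem, coarse_cell = 0.5)
  # both taxa fill the single coarse cell equally
  surf <- weighted_trait_surface(occ, c(A = 1000, B = 2000))
  expect_equal(surf$values[1, 1], 1500)
  # a present taxon without a trait value is an error
  expect_error(weighted_trait_surface(occ, c(A = 1000, B = NA)), "B")
  # single-taxon surface returns the trait exactly
  occ1 <- occupancy_set(ranges[1], reg, dem, coarse_cell = 0.5)
  expect_equal(weighted_trait_surface(occ1, c(A = 1234))$values[1, 1], 1234)
})

test_that("weighted surface errors on missing traits and respects
           unequal weights", {
  # two taxa with unequal occupied areas in one coarse cell
  reg <- flat_raster(1, 10, 10, cell = 0.05)
  dem <- flat_raster(rep(c(100, 900), c(40, 60)), 10, 10, cell = 0.05)
  ranges <- list(taxon_range("A", 1, 0, 500),    # 40 cells
                 taxon_range("B", 1, 0, 1000))   # all 100 cells
  occ <- occupancy_set(ranges, reg, dem, coarse_cell = 0.5)
  expect_error(weighted_trait_surface(occ, c(A = 1)), "B")
  surf <- weighted_trait_surface(occ, c(A = 1000, B = 2000))
  v <- surf$values[1, 1]
  expect_gt(v, 1000)
  expect_lt(v, 2000)
  # exact area weighting (areas within one latitude band are equal here)
  wA <- sum(occ$area$A)
  wB <- sum(occ$area$B)
  expect_equal(v, (wA * 1000 + wB * 2000) / (wA + wB))
})

test_that("species density partitions into PE and CE with a guarded ratio", {
  reg <- flat_raster(1, 10, 10, cell = 0.05)
  dem <- flat_raster(500, 10, 10, cell = 0.05)
  ranges <- lapply(sprintf("t%d", 1:9), taxon_range,
                   region_ids = 1, elev_min = 0, elev_max = 1000)
  occ <- occupancy_set(ranges, reg, dem, coarse_cell = 0.5)
  endo <- stats::setNames(rep(c("PE", "CE"), c(3, 6)), sprintf("t%d", 1:9))
  d <- species_density(occ, endo)
  expect_equal(d$total$values[1, 1], 9)
  expect_equal(d$pe$values[1, 1] + d$ce$values[1, 1], d$total$values[1, 1])
  expect_equal(d$ratio$values[1, 1], 0.5)
  # PE-only situation: ratio is nodata
  d2 <- species_density(occ, stats::setNames(rep("PE", 9), names(endo)))
  expect_true(is.na(d2$ratio$values[1, 1]))
})

test_that("ecoregion summaries split surface values by region id", {
  surf <- flat_raster(rep(c(10, 20), each = 50), 10, 10)
  eco <- flat_raster(rep(c(1, 2), each = 50), 10, 10)
  es <- ecoregion_summary(surf, eco)
  expect_true(all(es[["1"]] == 10))
  expect_true(all(es[["2"]] == 20))
  # nodata excluded
  surf$values[1, 1] <- NA
  es2 <- ecoregion_summary(surf, eco)
  expect_length(es2[["1"]], 49)
})

test_that("environmental statistics use the standard percentile
           convention", {
  mask <- flat_raster(TRUE, 10, 10)
  env <- flat_raster(1:100, 10, 10)
  st <- taxon_env_stats(mask, env)
  expect_equal(unname(st$percentiles[["50%"]]), 50.5)
  expect_equal(unname(st$percentiles[["25%"]]), 25.75)
  expect_equal(st$mean, 50.5)
  expect_true(st$median_pm2.5[1] < 50.5 && st$median_pm2.5[2] > 50.5)
  expect_true(st$median_pm5[1] < st$median_pm2.5[1])
  cst <- taxon_env_stats(mask, flat_raster(7, 10, 10))
  expect_true(all(cst$percentiles == 7))
  expect_equal(cst$sd, 0)
  empty <- flat_raster(FALSE, 10, 10)
  expect_error(taxon_env_stats(empty, env), "no cells")
})

test_that("elevation-band shrinkage never increases occupied area", {
  set.seed(62)
  L <- simulate_landscape(c(-80, -78, -12, -10), cell = 0.05, seed = 3)
  wide <- taxon_range("t", 1:4, 0, 3500)
  narrow <- taxon_range("t", 1:4, 500, 3000)
  ow <- grid_occupancy(reconstruct_range(wide, L$regions, L$dem), 0.5)
  on_ <- grid_occupancy(reconstruct_range(narrow, L$regions, L$dem), 0.5)
  expect_true(all(on_$area$values <= ow$area$values + 1e-12))
})

test_that("ascii grid round trip preserves values and georeference", {
  r <- flat_raster(rnorm(12), 3, 4, cell = 0.25, xmin = -70, ymax = -5)
  r$values[2, 2] <- NA
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  r2 <- read_ascii_grid(f)
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  expect_equal(r2$cell, r$cell)
  expect_equal(r2$xmin, r$xmin)
  expect_equal(r2$ymax, r$ymax)
})
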