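test_that("adjacent pixels join or split on the date difference", {
  r <- mk_raster(matrix(c(10L, 0L, 12L, 0L), 2, 2))
  expect_equal(dplyr::n_distinct(flood_fill_patches(r, 3)$patch), 1L)
  r2 <- mk_raster(matrix(c(10L, 0L, 20L, 0L), 2, 2))
  expect_equal(dplyr::n_distinct(flood_fill_patches(r2, 3)$patch), 2L)
})

test_that("membership is transitive: a date chain joins ends beyond the cut-off", {
  m <- matrix(0L, 1, 4)
  m[1, ] <- c(1L, 4L, 7L, 10L)
  r <- mk_raster(m)
  ff <- flood_fill_patches(r, 3)
  expect_equal(dplyr::n_distinct(ff$patch), 1L)  # 1 and 10 differ by 9
  expect_same_partition(ff, brute_force_patches(r, 3))
  # cut-off 2 breaks every link
  expect_equal(dplyr::n_distinct(flood_fill_patches(r, 2)$patch), 4L)
})

test_that("diagonal-only contact connects (queen scheme)", {
  m <- matrix(0L, 3, 3)
  m[1, 1] <- 5L; m[2, 2] <- 5L; m[3, 3] <- 5L
  expect_equal(dplyr::n_distinct(flood_fill_patches(mk_raster(m), 1)$patch),
               1L)
})

test_that("unburned and unmapped pixels both break connectivity", {
  m <- matrix(c(5L, 0L, 5L), 1, 3)
  expect_equal(dplyr::n_distinct(flood_fill_patches(mk_raster(m), 14)$patch),
               2L)
  m2 <- matrix(c(5L, -1L, 5L), 1, 3)
  expect_equal(dplyr::n_distinct(flood_fill_patches(mk_raster(m2), 14)$patch),
               2L)
})

test_that("degenerate rasters are handled", {
  expect_equal(nrow(flood_fill_patches(mk_raster(matrix(0L, 3, 3)), 5)), 0)
  expect_equal(nrow(brute_force_patches(mk_raster(matrix(0L, 3, 3)), 5)), 0)
  one <- mk_raster(matrix(c(0L, 7L, 0L, 0L), 2, 2))
  expect_equal(dplyr::n_distinct(flood_fill_patches(one, 5)$patch), 1L)
  expect_error(flood_fill_patches(mk_raster(matrix(1L, 2, 2)), 0), "cutoff")
})

test_that("flood fill equals the brute-force graph oracle on random rasters", {
  for (seed in 1:40) {
    r <- random_burn_raster(nr = 25, nc = 25, p_burn = 0.4,
                            date_range = c(1L, 30L), seed = seed)
    co <- c(1L, 3L, 5L, 9L, 14L)[(seed %% 5) + 1]
    expect_same_partition(flood_fill_patches(r, co),
                          brute_force_patches(r, co))
  }
})

test_that("every burned pixel lands in exactly one patch", {
  r <- random_burn_raster(seed = 7)
  px <- flood_fill_patches(r, 5)
  expect_equal(nrow(px), n_burned(r))
  expect_false(any(duplicated(px[, c("row", "col")])))
  # pixel coordinates map back to the raster's burn dates
  expect_equal(px$burn_date, r$values[cbind(px$row, px$col)])
})

test_that("partitions at a smaller cut-off refine those at a larger one", {
  for (seed in c(2, 13)) {
    r <- random_burn_raster(nr = 30, nc = 30, seed = seed)
    prev <- NULL
    for (co in c(1L, 3L, 5L, 9L, 14L)) {
      cur <- flood_fill_patches(r, co)
      if (!is.null(prev)) {
        expect_true(refines(prev, cur))
        expect_lte(dplyr::n_distinct(cur$patch),
                   dplyr::n_distinct(prev$patch))
      }
      prev <- cur
    }
  }
})

test_that("patch serials are deterministic and ordered by first pixel", {
  r <- random_burn_raster(seed = 5)
  a <- flood_fill_patches(r, 5, survey = "SYN")
  b <- flood_fill_patches(r, 5, survey = "SYN")
  expect_identical(a, b)
  # patch 1 contains the row-major first burned pixel
  first_pixel <- which(t(r$values) > 0, arr.ind = TRUE)[1, ]
  expect_equal(a$patch[a$row == first_pixel[2] & a$col == first_pixel[1]],
               1L)
  expect_match(a$patch_id[1], "^SYN_co5_")
})

test_that("size filters keep patches by pixel count and by area", {
  # three patches of 3, 5 and 63 pixels, far apart
  m <- matrix(0L, 40, 40)
  m[2, 2:4] <- 10L
  m[10, 10:14] <- 10L
  m[25:31, 25:33] <- 10L
  px <- flood_fill_patches(mk_raster(m), 5)
  kept <- filter_patches(px, min_pixels = 5)
  sizes <- sort(as.integer(table(kept$patch)))
  expect_equal(sizes, c(5L, 63L))
  expect_equal(nrow(filter_patches(px, min_pixels = 1)), nrow(px))
})

test_that("the 107 ha area cut keeps a 5-pixel equatorial MODIS-like patch", {
  ps <- 463 / (6371000 * pi / 180)      # 463 m at the equator, in degrees
  m <- matrix(0L, 6, 8)
  m[3, 2:6] <- 100L                     # 5 pixels ~ 107.2 ha
  m[5, 1:4] <- 200L                     # 4 pixels ~ 85.8 ha
  r <- burn_raster(m, origin = c(0, 3 * ps), pixel_size = ps)
  px <- flood_fill_patches(r, 5)
  kept <- filter_patches(px, min_pixels = 1, min_area_ha = 107)
  expect_equal(dplyr::n_distinct(kept$patch), 1L)
  expect_equal(unique(kept$burn_date), 100L)
})

test_that("patches are assigned to the month of their mean burn date", {
  m <- matrix(0L, 3, 8)
  m[1, 1:2] <- 40L                      # 9 Feb
  m[3, 1:6] <- c(28L, 29L, 30L, 31L, 32L, 33L)   # Jan-Feb straddle
  px <- monthly_grouping(flood_fill_patches(mk_raster(m), 5))
  by_patch <- dplyr::distinct(px, patch, month)
  expect_equal(nrow(by_patch), 2)
  expect_equal(by_patch$month[by_patch$patch == 1], 2L)  # day 40 -> Feb
  expect_equal(by_patch$month[by_patch$patch == 2], 1L)  # mean 30.5 -> Jan
  # a re-burn months later stays a separate patch at any tested cut-off
  m2 <- matrix(0L, 1, 1); m2[1, 1] <- 70L
  r2 <- mk_raster(rbind(c(70L, 71L), c(280L, 281L)))
  expect_equal(dplyr::n_distinct(flood_fill_patches(r2, 14)$patch), 2L)
})
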