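# helper: single-patch morphology for a 0/1 mask matrix
morph_of <- function(mask) {
  r <- mk_raster(mask * 10L)
  patch_morphology(flood_fill_patches(r, 5))
}

test_that("perimeter counts exposed cell edges, including hole boundaries", {
  expect_equal(morph_of(matrix(1L, 1, 1))$perimeter, 4L)
  expect_equal(morph_of(matrix(1L, 2, 2))$perimeter, 8L)
  ring <- matrix(1L, 3, 3); ring[2, 2] <- 0L
  expect_equal(morph_of(ring)$perimeter, 16L)  # 12 outer + 4 around the hole
})

test_that("core pixels are those totally surrounded by the patch", {
  expect_equal(morph_of(matrix(1L, 3, 3))$n_core, 1L)
  expect_equal(morph_of(matrix(1L, 2, 7))$n_core, 0L)   # 2-wide strip
  expect_equal(morph_of(matrix(1L, 5, 5))$n_core, 9L)   # inner 3x3
  # 4-neighbor variant counts more pixels as core
  plus <- matrix(0L, 3, 3); plus[2, ] <- 1L; plus[, 2] <- 1L
  r <- mk_raster(plus * 10L)
  px <- flood_fill_patches(r, 5)
  expect_equal(patch_morphology(px, core_neighbors = 8)$n_core, 0L)
  expect_equal(patch_morphology(px, core_neighbors = 4)$n_core, 1L)
})

test_that("pixel areas follow the spherical model", {
  ps <- 463 / (6371000 * pi / 180)
  r <- burn_raster(matrix(10L, 1, 1), origin = c(0, ps), pixel_size = ps)
  expect_equal(pixel_area_ha(r), 21.44, tolerance = 2e-3)
  # area scales with cos(latitude)
  r60 <- burn_raster(matrix(10L, 1, 1), origin = c(0, 60 + ps / 2),
                     pixel_size = ps)
  expect_equal(pixel_area_ha(r60) / pixel_area_ha(r), 0.5, tolerance = 1e-3)
})

test_that("shape index follows both normalizations", {
  expect_equal(shape_index(42, 49), 1.5)                      # n = k^2
  expect_equal(shape_index(42, 49, "sqrt_formula"), 1.5)
  expect_equal(shape_index(52, 63), 1.625)                    # p_min = 32
  expect_equal(shape_index(52, 63, "sqrt_formula"), 0.25 * 52 / sqrt(63))
  expect_equal(shape_index(220, 295), 220 / 70)               # p_min = 4k+2
  expect_equal(round(shape_index(220, 295), 2), 3.14)
  # filled squares are maximally compact
  for (n in c(2, 5, 9)) {
    p <- morph_of(matrix(1L, n, n))$perimeter
    expect_equal(shape_index(p, n^2), 1)
  }
  expect_error(shape_index(10, 4, "nope"))
})

test_that("fractal dimension matches its closed form and bounds", {
  expect_equal(fractal_dimension(136, 171), 2 * log(34) / log(171))
  expect_equal(round(fractal_dimension(136, 171), 2), 1.37)
  expect_equal(fractal_dimension(8, 4), 1)          # 2x2 block
  expect_true(is.na(fractal_dimension(4, 1)))
  # stays in [1, 2] for real patches of >= 5 pixels
  for (seed in c(3, 8)) {
    r <- random_burn_raster(seed = seed)
    tr <- patch_traits(filter_patches(flood_fill_patches(r, 14)))
    expect_true(all(tr$D2 >= 1 - 1e-9 & tr$D2 <= 2 + 1e-9))
  }
})

test_that("the trait table reproduces hand-computed values on a block patch", {
  m <- matrix(0L, 7, 7); m[3:5, 3:5] <- 40L
  r <- mk_raster(m)
  tr <- patch_traits(flood_fill_patches(r, 5))
  expect_equal(tr$N_pixels, 9L)
  expect_equal(tr$N_core_pixels, 1L)
  expect_equal(tr$P, 12L)
  expect_equal(tr$PAR, 12 / 9)
  expect_equal(tr$SI, 1)
  expect_equal(tr$CA, tr$A_core / tr$A)
  expect_equal(tr$BD_min, 40L)
  expect_equal(tr$BD_max, 40L)
  expect_equal(tr$BD_mean, 40)
  expect_equal(tr$Year, 2001L)
  expect_equal(tr$X, mean(pixel_lon(r, 3:5)))
  expect_equal(tr$Y, mean(pixel_lat(r, 3:5)))
  # catalogue column order
  expect_equal(names(tr)[-1],
               c("patch_id", "N_pixels", "N_core_pixels", "A", "A_core",
                 "P", "PAR", "SI", "D2", "CA", "X", "Y", "sigma_X",
                 "sigma_Y", "theta", "sigma_X_km", "sigma_Y_km", "theta_km",
                 "R_SDE", "E_SDE", "BD_min", "BD_max", "BD_mean", "Year"))
})

test_that("shape traits are invariant to translation, rotation and mirroring", {
  set.seed(42)
  base <- matrix(0L, 12, 12)
  base[3:9, 4:8] <- 20L
  base[5, 6] <- 0L; base[4:6, 9] <- 20L     # irregular shape with a hole
  variants <- list(
    base,
    rbind(matrix(0L, 2, 12), base[1:10, ]),          # translated
    t(base)[, 12:1],                                  # rotated 90
    base[, 12:1]                                      # mirrored
  )
  trs <- lapply(variants, function(m)
    patch_traits(flood_fill_patches(mk_raster(m), 5)))
  for (i in 2:4) {
    for (col in c("N_pixels", "P", "PAR", "SI", "D2", "N_core_pixels"))
      expect_equal(trs[[i]][[col]], trs[[1]][[col]], label = col)
  }
  # translation changes only the center among the geometric fields
  expect_false(isTRUE(all.equal(trs[[2]]$Y, trs[[1]]$Y)))
})

test_that("square patches: PAR = 4/n decreases with size and CA grows toward 1", {
  par_seq <- ca_seq <- numeric(0)
  for (n in c(3, 5, 9, 15)) {
    tr <- patch_traits(flood_fill_patches(mk_raster(matrix(10L, n, n)), 5))
    expect_equal(tr$PAR, 4 / n)
    par_seq <- c(par_seq, tr$PAR)
    ca_seq <- c(ca_seq, tr$CA)
  }
  expect_true(all(diff(par_seq) < 0))
  expect_true(all(diff(ca_seq) > 0))
  expect_gt(tail(ca_seq, 1), 0.7)
})
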