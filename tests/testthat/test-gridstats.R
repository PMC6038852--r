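test_that("profile histogram conserves counts and carries Poisson errors", {
  h1 <- profile_histogram(rep(50, 100))
  expect_equal(sum(h1$count > 0), 1)
  expect_equal(h1$count[h1$count > 0], 100L)
  expect_equal(h1$err[h1$count > 0], 10)
  a <- sample_patch_sizes(1.5, 777, c(10, 1e3), seed = 5)
  h <- profile_histogram(a)
  expect_equal(sum(h$count), 777L)
  expect_equal(h$density, h$count / (h$hi - h$lo))
  expect_error(profile_histogram(numeric(0)), "empty")
  expect_error(profile_histogram(c(1, -2)), "positive")
})

test_that("log-density of a deterministic power-law sample is linear in log-size", {
  # inverse-CDF at equispaced quantiles: a noise-free power-law sample
  beta <- 1.8; m <- 10; M <- 1e4; n <- 20000
  u <- (seq_len(n) - 0.5) / n
  k <- 1 - beta
  areas <- (m^k + u * (M^k - m^k))^(1 / k)
  h <- profile_histogram(areas)
  occ <- h[h$count > 0, ]
  fit <- stats::lm(log10(density) ~ log10(mid), data = occ)
  expect_equal(-stats::coef(fit)[[2]], beta, tolerance = 0.05)
})

test_that("chi-square fit recovers a known exponent well within 3 sigma", {
  a <- sample_patch_sizes(2, 50000, c(10, 1e4), seed = 31)
  f <- fit_size_distribution(a)
  expect_true(f$converged)
  expect_lt(abs(f$beta - 2), 3 * f$sigma_beta)
  expect_gt(f$sigma_beta, 0)
  expect_equal(f$n_fires, 50000L)
  expect_equal(sum(f$bins$count), 50000L)
})

test_that("a flat linear density fits beta near zero", {
  set.seed(12)
  a <- runif(30000, 10, 1e3)
  f <- fit_size_distribution(a)
  expect_lt(abs(f$beta), 3 * f$sigma_beta + 0.05)
})

test_that("sigma_beta shrinks as 1/sqrt(counts)", {
  a <- sample_patch_sizes(2, 8000, c(10, 1e4), seed = 77)
  f1 <- fit_size_distribution(a)
  f2 <- fit_size_distribution(c(a, a))     # doubled counts, same bins
  expect_equal(f2$sigma_beta / f1$sigma_beta, 1 / sqrt(2), tolerance = 0.1)
  f4 <- fit_size_distribution(c(a, a, a, a))
  expect_equal(f4$sigma_beta / f1$sigma_beta, 0.5, tolerance = 0.1)
})

test_that("too few occupied bins yields a flagged non-fit", {
  f <- fit_power_law(profile_histogram(rep(c(10, 100), 5)))
  expect_false(f$converged)
  expect_true(is.na(f$beta))
})

test_that("tidy and glance expose the fit in broom style", {
  f <- fit_size_distribution(sample_patch_sizes(2, 5000, c(10, 1e4),
                                                seed = 2))
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "beta"))
  expect_equal(td$estimate[2], f$beta)
  expect_equal(td$std.error[2], f$sigma_beta)
  gl <- glance(f)
  expect_equal(gl$chi2, f$chi2)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("gridding assigns patches to half-open 1-degree cells", {
  cat <- tibble::tibble(
    X = c(0.2, 0.4, 1.0, -0.3), Y = c(10.5, 10.9, 10.2, 10.0),
    A = c(100, 200, 150, 120),
    PAR = c(0.4, 0.8, 0.5, 0.7), SI = 1.2, D2 = 1.3,
    R_SDE = 0.5, E_SDE = 0.8)
  g <- grid_traits(cat, min_fires_for_fit = 100)
  expect_equal(nrow(g), 3)
  c00 <- g[g$cell_lon == 0 & g$cell_lat == 10, ]
  expect_equal(c00$n_fires, 2L)
  expect_equal(c00$mean_PAR, 0.6)
  expect_equal(c00$sd_PAR, sd(c(0.4, 0.8)))
  # X = 1.0 is in the [1, 2) cell, X = -0.3 in [-1, 0)
  expect_equal(sort(g$cell_lon), c(-1, 0, 1))
  expect_true(all(is.na(g$beta)))   # below the fires-per-cell threshold
})

test_that("shifting all centers by one degree shifts the grid, values unchanged", {
  set.seed(8)
  cat <- tibble::tibble(
    X = runif(200, 0, 2), Y = runif(200, 40, 41),
    A = sample_patch_sizes(2, 200, c(10, 1e3), seed = 8),
    PAR = runif(200), SI = runif(200, 1, 3), D2 = runif(200, 1, 2),
    R_SDE = runif(200), E_SDE = runif(200))
  g1 <- grid_traits(cat, min_fires_for_fit = 20)
  g2 <- grid_traits(dplyr::mutate(cat, X = X + 1), min_fires_for_fit = 20)
  expect_equal(g2$cell_lon, g1$cell_lon + 1)
  expect_equal(g2$beta, g1$beta)
  expect_equal(g2$mean_SI, g1$mean_SI)
})

test_that("grid comparison reports differences in combined sigma units", {
  mk <- function(beta, sb) {
    g <- tibble::tibble(cell_lon = c(0, 1), cell_lat = 0,
                        beta = c(beta, NA), sigma_beta = c(sb, NA))
    attr(g, "cell_deg") <- 1
    g
  }
  same <- compare_grids(mk(2, 0.1), mk(2, 0.1))
  expect_equal(same$difference[1], 0)
  expect_equal(same$agreement_sigma[1], 0)
  ab <- compare_grids(mk(2, 0.1), mk(2.5, 0.1))
  expect_equal(ab$agreement_sigma[1], 0.5 / sqrt(0.02), tolerance = 1e-9)
  expect_true(is.na(ab$agreement_sigma[2]))  # missing stays missing
})
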