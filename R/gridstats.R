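#' Profile histogram of fire-patch sizes
#'
#' Counts fires in logarithmic size bins and normalizes each count by the
#' linear bin width, giving the density `N_f` per unit area against which
#' the power law `N_f = alpha * A_f^-beta` is fitted. Each bin carries a
#' Poisson error equal to the square root of its count.
#'
#' @param areas Patch areas (ha), all `> 0`.
#' @param bins_per_decade Number of bins per factor-10 of area (default 5).
#' @return A tibble, one row per bin: `lo`, `hi` (edges, ha), `mid`
#'   (geometric midpoint), `count`, `density` (count / linear width),
#'   `err` (`sqrt(count)`).
#' @export
profile_histogram <- function(areas, bins_per_decade = 5) {
  if (length(areas) == 0) stop("`areas` is empty")
  if (any(areas <= 0)) stop("areas must be positive")
  lo <- log10(min(areas)); hi <- log10(max(areas))
  if (hi - lo < 1e-12) {        # all areas equal: one bin centered on them
    lo <- lo - 0.5 / bins_per_decade
    hi <- hi + 0.5 / bins_per_decade
  }
  nb <- max(1L, ceiling((hi - lo) * bins_per_decade - 1e-9))
  edges <- 10^seq(lo, hi, length.out = nb + 1)
  # nudge the outer edges so min and max survive log/exp round-trip error
  edges[1] <- edges[1] * (1 - 1e-12)
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12)
  cnt <- as.integer(table(cut(areas, edges, right = FALSE,
                              include.lowest = TRUE)))
  tibble(lo = edges[-length(edges)], hi = edges[-1],
         mid = sqrt(edges[-length(edges)] * edges[-1]),
         count = cnt, density = cnt / (edges[-1] - edges[-length(edges)]),
         err = sqrt(cnt))
}

#' Fit the power-law size distribution with Poisson-weighted chi-square
#'
#' Fits `N_f = alpha * A_f^-beta` to a profile histogram by minimizing
#' `chi^2 = sum_i ((n_i - m_i(alpha, beta)) / sqrt(n_i))^2` over the
#' occupied bins, where the model count `m_i` is the power law integrated
#' across bin `i` (so the fit is exact with respect to within-bin
#' curvature). For fixed `beta` the optimal `alpha` is closed-form; `beta`
#' is found by 1-D minimization seeded by a weighted log-log least-squares
#' slope. The uncertainty `sigma_beta` is read off the chi-square profile:
#' the half-width of the interval where `chi^2(beta) <= chi2_min + 1`,
#' with `alpha` re-minimized at every `beta`.
#'
#' @param bins A [profile_histogram()] table.
#' @return An object of class `powerlaw_fit`: list with `alpha`, `beta`,
#'   `sigma_beta`, `chi2`, `n_fires`, `n_bins`, `converged` and the `bins`
#'   table. `NA` fit (with `converged = FALSE`) if fewer than 3 occupied
#'   bins.
#' @export
#' @examples
#' a <- sample_patch_sizes(2, 5000, c(10, 1e4), seed = 42)
#' fit <- fit_power_law(profile_histogram(a))
#' tidy(fit)
fit_power_law <- function(bins) {
  occ <- bins[bins$count >= 1, ]
  n_fires <- sum(bins$count)
  if (nrow(occ) < 3) {
    return(new_powerlaw_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                            n_fires, nrow(occ), FALSE, bins,
                            note = "fewer than 3 occupied bins"))
  }
  # model integral per bin for unit alpha
  gfun <- function(beta) {
    if (abs(beta - 1) < 1e-9) log(occ$hi / occ$lo)
    else (occ$hi^(1 - beta) - occ$lo^(1 - beta)) / (1 - beta)
  }
  chi2_profile <- function(beta) {
    g <- gfun(beta)
    alpha <- sum(g) / sum(g^2 / occ$count)
    list(chi2 = sum((occ$count - alpha * g)^2 / occ$count), alpha = alpha)
  }
  chi2_of <- function(beta) chi2_profile(beta)$chi2
  # seed: weighted least squares of log10(density) on log10(mid)
  wls <- stats::lm(log10(density) ~ log10(mid), data = occ,
                   weights = occ$count)
  beta0 <- -stats::coef(wls)[[2]]
  opt <- optimize(chi2_of, lower = beta0 - 2, upper = beta0 + 2)
  # widen if the minimum sits on the search edge
  tries <- 0
  while ((abs(opt$minimum - (beta0 - 2 - tries)) < 1e-6 ||
          abs(opt$minimum - (beta0 + 2 + tries)) < 1e-6) && tries < 8) {
    tries <- tries + 2
    opt <- optimize(chi2_of, lower = beta0 - 2 - tries,
                    upper = beta0 + 2 + tries)
  }
  beta_hat <- opt$minimum
  prof <- chi2_profile(beta_hat)
  target <- function(b) chi2_of(b) - (opt$objective + 1)
  hw <- function(dir) {
    step <- 0.05
    b <- beta_hat
    for (i in 1:200) {
      b <- b + dir * step
      if (target(b) > 0)
        return(abs(uniroot(target, sort(c(beta_hat, b)),
                           tol = 1e-6)$root - beta_hat))
    }
    NA_real_
  }
  sigma <- mean(c(hw(1), hw(-1)), na.rm = TRUE)
  new_powerlaw_fit(prof$alpha, beta_hat, sigma, opt$objective, n_fires,
                   nrow(occ), is.finite(sigma), bins)
}

new_powerlaw_fit <- function(alpha, beta, sigma_beta, chi2, n_fires, n_bins,
                             converged, bins, note = NULL) {
  structure(list(alpha = alpha, beta = beta, sigma_beta = sigma_beta,
                 chi2 = chi2, n_fires = n_fires, n_bins = n_bins,
                 converged = converged, bins = bins, note = note),
            class = "powerlaw_fit")
}

#' Fit the size distribution straight from patch areas
#'
#' Convenience wrapper: [profile_histogram()] then [fit_power_law()].
#'
#' @inheritParams profile_histogram
#' @return A `powerlaw_fit`.
#' @export
fit_size_distribution <- function(areas, bins_per_decade = 5) {
  fit_power_law(profile_histogram(areas, bins_per_decade))
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<powerlaw_fit> not converged:", x$note %||% "", "\n")
  } else {
    cat(sprintf(
      "<powerlaw_fit> beta = %.3f +/- %.3f (chi2 = %.2f, %d bins, %d fires)\n",
      x$beta, x$sigma_beta, x$chi2, x$n_bins, x$n_fires))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fit_power_law
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("alpha", "beta"),
         estimate = c(x$alpha, x$beta),
         std.error = c(NA_real_, x$sigma_beta))
}

#' @rdname fit_power_law
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(beta = x$beta, sigma_beta = x$sigma_beta, chi2 = x$chi2,
         n_bins = x$n_bins, n_fires = x$n_fires, converged = x$converged)
}

#' @rdname fit_power_law
#' @param object A `powerlaw_fit`.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  b <- object$bins[object$bins$count > 0, ]
  p <- ggplot2::ggplot(b, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$density - .data$err / (.data$hi - .data$lo), 1e-300),
      ymax = .data$density + .data$err / (.data$hi - .data$lo)),
      width = 0) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fire patch area (ha)", y = "fires per unit area")
  if (isTRUE(object$converged))
    p <- p + ggplot2::geom_function(
      fun = function(a) object$alpha * a^(-object$beta), color = "red")
  p
}

#' Aggregate a trait catalogue to a lon/lat grid
#'
#' Assigns each patch to the grid cell containing its center (cells are
#' half-open `[w, e) x [s, n)`, anchored at integer multiples of
#' `cell_deg`; centers on the antimeridian wrap to -180) and computes, per
#' cell, the mean and standard deviation of the perimeter-to-area ratio,
#' shape index, fractal dimension, ellipse ratio and eccentricity, the
#' fire count, and - for cells with at least `min_fires_for_fit` fires -
#' the power-law fit of the size distribution.
#'
#' @param catalogue Trait table from [patch_traits()].
#' @param cell_deg Cell width in degrees (default 1).
#' @param min_area_ha Minimum patch area retained before aggregation.
#' @param min_fires_for_fit Minimum fires per cell for a beta fit
#'   (default 20; sparser cells get `NA`).
#' @param bins_per_decade Binning of the per-cell size distribution.
#' @return A tibble, one row per occupied cell: `cell_lon`, `cell_lat`
#'   (west/south cell corners), `n_fires`, `mean_*` and `sd_*` for `PAR`,
#'   `SI`, `D2`, `R_SDE`, `E_SDE`, plus `beta`, `sigma_beta`, `chi2`.
#'   Cell size is attached as attribute `cell_deg`.
#' @export
grid_traits <- function(catalogue, cell_deg = 1.0, min_area_ha = 0,
                        min_fires_for_fit = 20, bins_per_decade = 5) {
  stopifnot(cell_deg > 0)
  cat2 <- dplyr::filter(catalogue, .data$A >= min_area_ha)
  if (nrow(cat2) == 0) stop("no patches to grid")
  lon <- cat2$X
  lon[lon >= 180] <- lon[lon >= 180] - 360
  cat2$cell_lon <- floor(lon / cell_deg) * cell_deg
  cat2$cell_lat <- floor(cat2$Y / cell_deg) * cell_deg
  msd <- function(x, f) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  out <- cat2 |>
    dplyr::summarise(
      n_fires = dplyr::n(),
      dplyr::across(c("PAR", "SI", "D2", "R_SDE", "E_SDE"),
                    list(mean = \(x) msd(x, mean), sd = \(x) msd(x, sd)),
                    .names = "{.fn}_{.col}"),
      fit = list(if (dplyr::n() >= min_fires_for_fit)
        fit_size_distribution(.data$A, bins_per_decade) else NULL),
      .by = c("cell_lon", "cell_lat")) |>
    dplyr::mutate(
      beta = purrr::map_dbl(.data$fit, \(f) if (is.null(f)) NA_real_ else f$beta),
      sigma_beta = purrr::map_dbl(.data$fit,
                                  \(f) if (is.null(f)) NA_real_ else f$sigma_beta),
      chi2 = purrr::map_dbl(.data$fit, \(f) if (is.null(f)) NA_real_ else f$chi2)
    ) |>
    dplyr::select(-"fit") |>
    dplyr::arrange(.data$cell_lat, .data$cell_lon)
  attr(out, "cell_deg") <- cell_deg
  out
}

#' Compare the beta maps of two gridded products
#'
#' Per-cell difference of the fitted power-law exponents and the degree of
#' agreement in units of the combined standard deviation:
#' `N = |beta_A - beta_B| / sqrt(sigma_A^2 + sigma_B^2)`; two products are
#' compatible within `N` sigma in that cell.
#'
#' @param grid_a,grid_b Grids from [grid_traits()] with identical
#'   `cell_deg`.
#' @return A tibble: `cell_lon`, `cell_lat`, `beta_a`, `beta_b`,
#'   `difference`, `agreement_sigma` (`NA` where either beta is missing).
#' @export
compare_grids <- function(grid_a, grid_b) {
  ca <- attr(grid_a, "cell_deg"); cb <- attr(grid_b, "cell_deg")
  if (!is.null(ca) && !is.null(cb) && abs(ca - cb) > 1e-12)
    stop("grid geometries differ (cell size)")
  dplyr::inner_join(
    dplyr::select(grid_a, "cell_lon", "cell_lat", beta_a = "beta",
                  sa = "sigma_beta"),
    dplyr::select(grid_b, "cell_lon", "cell_lat", beta_b = "beta",
                  sb = "sigma_beta"),
    by = c("cell_lon", "cell_lat")) |>
    dplyr::mutate(
      difference = .data$beta_a - .data$beta_b,
      agreement_sigma = abs(.data$difference) /
        sqrt(.data$sa^2 + .data$sb^2)) |>
    dplyr::select("cell_lon", "cell_lat", "beta_a", "beta_b", "difference",
                  "agreement_sigma")
}

#' Plot a gridded trait map
#'
#' @param grid A [grid_traits()] table.
#' @param variable Column to map (default `"beta"`).
#' @return A ggplot tile map.
#' @export
plot_trait_grid <- function(grid, variable = "beta") {
  cd <- attr(grid, "cell_deg") %||% 1
  ggplot2::ggplot(grid, ggplot2::aes(.data$cell_lon + cd / 2,
                                     .data$cell_lat + cd / 2,
                                     fill = .data[[variable]])) +
    ggplot2::geom_tile(width = cd, height = cd) +
    ggplot2::scale_fill_viridis_c(name = variable) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}
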