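#' Build a table of synthetic fire events
#'
#' Each event is an elliptical fire front that ignites at a pixel and grows
#' daily: on day offset `d` (0-based) the front covers every pixel whose
#' center lies within the ellipse of semi-minor axis `spread_rate * d`
#' pixels and semi-major axis `elongation * spread_rate * d`, oriented with
#' its major axis at `azimuth_deg` clockwise from north. A pixel burns on
#' the first day the growing ellipse covers its center, so burn dates
#' increase outward from the ignition.
#'
#' @param ignition_row,ignition_col Ignition pixel (1-based grid indices).
#' @param start_day Day of year the event ignites (integer, >= 1).
#' @param spread_rate Radial growth in pixels/day (> 0).
#' @param elongation Major/minor axis ratio of the front (>= 1).
#' @param azimuth_deg Major-axis azimuth, degrees clockwise from north.
#' @param duration_days Number of days of growth (>= 1).
#' @return A tibble, one row per event, usable as the `events` argument of
#'   [simulate_burn_raster()].
#' @export
fire_events <- function(ignition_row, ignition_col, start_day,
                        spread_rate = 1, elongation = 1, azimuth_deg = 0,
                        duration_days = 3) {
  ev <- tibble(
    ignition_row = as.integer(ignition_row),
    ignition_col = as.integer(ignition_col),
    start_day = as.integer(start_day),
    spread_rate = as.numeric(spread_rate),
    elongation = as.numeric(elongation),
    azimuth_deg = as.numeric(azimuth_deg),
    duration_days = as.integer(duration_days)
  )
  if (any(ev$spread_rate <= 0)) stop("`spread_rate` must be > 0")
  if (any(ev$elongation < 1)) stop("`elongation` must be >= 1")
  if (any(ev$duration_days < 1)) stop("`duration_days` must be >= 1")
  if (any(ev$start_day < 1)) stop("`start_day` must be >= 1")
  ev
}

#' Draw a random table of synthetic fire events
#'
#' Convenience generator for property tests and demonstrations: ignitions
#' uniform over the grid (keeping the final footprint inside it), start days
#' uniform over `day_range`, log-uniform spread rates, and uniform
#' elongation/azimuth.
#'
#' @param n Number of events.
#' @param grid_shape `c(rows, cols)` of the target grid.
#' @param day_range Integer range of possible start days.
#' @param spread_range Range of spread rates (pixels/day).
#' @param duration_range Integer range of durations (days).
#' @param max_elongation Upper bound of the elongation ratio.
#' @param size_beta Optional power-law exponent: when given, event footprint
#'   areas (pixels) are drawn from a truncated Pareto over `size_range_px`
#'   - the size structure observed for real fire regimes - and spread rates
#'   are derived from them; `spread_range` is then ignored.
#' @param size_range_px Footprint area range (pixels) for `size_beta`.
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A [fire_events()] tibble.
#' @export
random_fire_events <- function(n, grid_shape, day_range = c(1L, 300L),
                               spread_range = c(0.5, 2), duration_range = c(1L, 5L),
                               max_elongation = 3, size_beta = NULL,
                               size_range_px = c(7, 2500), seed = 1L) {
  withr_seed(seed)
  dur <- sample(seq(duration_range[1], duration_range[2]), n, replace = TRUE)
  if (is.null(size_beta)) {
    rate <- exp(stats::runif(n, log(spread_range[1]), log(spread_range[2])))
  } else {
    areas <- sample_patch_sizes(size_beta, n, size_range_px,
                                seed = seed + 1L)
    rate <- sqrt(areas / pi) / dur     # disc of the drawn area after `dur` days
  }
  elong <- stats::runif(n, 1, max_elongation)
  margin <- ceiling(rate * dur * elong) + 1L
  fire_events(
    ignition_row = vapply(margin, function(m)
      sample(seq(min(m + 1L, grid_shape[1]), max(1L, grid_shape[1] - m)), 1L), 1L),
    ignition_col = vapply(margin, function(m)
      sample(seq(min(m + 1L, grid_shape[2]), max(1L, grid_shape[2] - m)), 1L), 1L),
    start_day = sample(seq(day_range[1], day_range[2]), n, replace = TRUE),
    spread_rate = rate, elongation = elong,
    azimuth_deg = stats::runif(n, 0, 360), duration_days = dur
  )
}

# Restore-free local seed: deterministic draws without clobbering the
# caller's RNG stream.
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

#' Simulate a burn-date raster with known ground truth
#'
#' Paints the events of a [fire_events()] table onto a grid. When event
#' footprints overlap, first-burn wins: a pixel keeps its earliest burn
#' date (ties broken by event order), so the ground-truth labeling
#' partitions the burned pixels - each burned pixel belongs to exactly one
#' event.
#'
#' @param events A [fire_events()] tibble.
#' @param grid_shape `c(rows, cols)` in pixels.
#' @param pixel_size Degrees per pixel. The default 1/240 deg gives a
#'   463 m pixel at the equator (MODIS MCD64A1-like); use 1/370 deg for a
#'   300 m MERIS-like grid.
#' @param origin Upper-left corner `c(lon, lat)` in degrees.
#' @param year Calendar year of the date axis.
#' @param seed Integer seed (the geometry is deterministic; the seed is kept
#'   in the output for provenance and future stochastic extensions).
#' @return A list with `raster` (a [burn_raster()]) and `truth` (an integer
#'   matrix of event IDs, 0 where unburned).
#' @export
#' @examples
#' sim <- simulate_burn_raster(fire_events(10, 10, start_day = 100),
#'                             grid_shape = c(20, 20))
#' table(sim$truth[sim$truth > 0])
simulate_burn_raster <- function(events, grid_shape,
                                 pixel_size = 1 / 240,
                                 origin = c(0, grid_shape[1] * pixel_size),
                                 year = 2001L, seed = 1L) {
  stopifnot(is.data.frame(events), nrow(events) > 0, length(grid_shape) == 2)
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  date_mat <- matrix(Inf, nr, nc)
  label_mat <- matrix(0L, nr, nc)
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    fp <- event_footprint(ev, nr, nc, event_index = e)
    newer <- fp$date < date_mat[fp$cells]
    cells <- fp$cells[newer]
    date_mat[cells] <- fp$date[newer]
    label_mat[cells] <- e
  }
  vals <- date_mat
  vals[!is.finite(vals)] <- 0
  list(raster = burn_raster(vals, origin = origin, pixel_size = pixel_size,
                            year = year),
       truth = label_mat)
}

# First burn day (absolute) for every pixel an event covers; errors if the
# footprint escapes the grid.
event_footprint <- function(ev, nr, nc, event_index) {
  reach <- ceiling(ev$spread_rate * ev$duration_days * ev$elongation)
  r0 <- ev$ignition_row; c0 <- ev$ignition_col
  rows <- (r0 - reach):(r0 + reach)
  cols <- (c0 - reach):(c0 + reach)
  grid <- expand.grid(row = rows, col = cols)
  # offsets in (east, north) pixel units from the ignition center
  east <- grid$col - c0
  north <- -(grid$row - r0)
  az <- ev$azimuth_deg * pi / 180
  u <- east * sin(az) + north * cos(az)      # along major axis
  v <- east * cos(az) - north * sin(az)      # along minor axis
  rho <- sqrt((u / ev$elongation)^2 + v^2)   # minor-axis-equivalent radius
  day_off <- ceiling(rho / ev$spread_rate - 1e-9)
  covered <- day_off <= ev$duration_days
  if (any(covered & (grid$row < 1 | grid$row > nr |
                     grid$col < 1 | grid$col > nc)))
    stop(sprintf("event %d: footprint exceeds the grid", event_index))
  keep <- covered
  tibble_cells <- cbind(grid$row[keep], grid$col[keep])
  list(cells = tibble_cells[, 1] + (tibble_cells[, 2] - 1) * nr,
       date = ev$start_day + day_off[keep])
}

#' Sample fire-patch areas from a truncated power law
#'
#' Draws i.i.d. areas from the truncated Pareto density `p(A) ~ A^-beta` on
#' `[size_range[1], size_range[2]]` by inverse-CDF sampling, the
#' size-distribution model used for the gridded power-law fit. Used to
#' validate the fitter with known exponent.
#'
#' @param beta Power-law exponent (>= 0; `beta = 0` is a flat density).
#' @param n_patches Number of draws (0 gives an empty vector).
#' @param size_range `c(min, max)` areas, `min >= 5` pixels-equivalent and
#'   `min < max`.
#' @param seed Integer seed.
#' @return Numeric vector of `n_patches` areas.
#' @export
sample_patch_sizes <- function(beta, n_patches, size_range = c(10, 1e4),
                               seed = 1L) {
  if (beta < 0) stop("`beta` must be >= 0")
  if (length(size_range) != 2 || size_range[1] >= size_range[2])
    stop("`size_range` must be an increasing pair")
  if (size_range[1] < 5) stop("minimum size must be >= 5")
  if (n_patches == 0) return(numeric(0))
  withr_seed(seed)
  u <- stats::runif(n_patches)
  m <- size_range[1]; M <- size_range[2]
  if (abs(beta - 1) < 1e-12) {
    exp(log(m) + u * (log(M) - log(m)))
  } else {
    k <- 1 - beta
    (m^k + u * (M^k - m^k))^(1 / k)
  }
}

#' Closed-form CDF of the truncated Pareto size distribution
#'
#' @param q Quantiles (areas).
#' @inheritParams sample_patch_sizes
#' @return `P(A <= q)` under the truncated power law.
#' @export
ptruncpareto <- function(q, beta, size_range) {
  m <- size_range[1]; M <- size_range[2]
  q <- pmin(pmax(q, m), M)
  if (abs(beta - 1) < 1e-12) {
    (log(q) - log(m)) / (log(M) - log(m))
  } else {
    k <- 1 - beta
    (q^k - m^k) / (M^k - m^k)
  }
}
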