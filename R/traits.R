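#' Scalar morphology helpers
#'
#' Vectorized building blocks of the per-patch trait table. `P` is the
#' patch perimeter in pixel sides, `n_pixels` the number of burned pixels.
#'
#' `perimeter_area_ratio(P, n)` is `P / n` (pixel units).
#'
#' `shape_index(P, n, variant)` normalizes the perimeter by that of a
#' maximally compact patch of the same cell count. Two conventions exist:
#' * `"compact_min_perimeter"` (default, the landscape-ecology convention):
#'   `SI = P / p_min(n)` with `p_min = 4k` if `n = k^2`, `4k + 2` if
#'   `k^2 < n <= k(k+1)`, and `4k + 4` otherwise, where `k = floor(sqrt(n))`.
#'   A filled square scores exactly 1.
#' * `"sqrt_formula"`: `SI = 0.25 P / sqrt(n)`, the continuous
#'   approximation (equals the compact variant only on perfect squares).
#'
#' `fractal_dimension(P, n)` is the perimeter-area scaling exponent
#' `D2 = 2 ln(P/4) / ln(n)`, between 1 (smooth outline) and 2 (convoluted);
#' undefined (NA) for single-pixel patches.
#'
#' `core_area_index(a_core, a)` is the cored fraction `A_core / A`.
#'
#' @param P Perimeter(s) in pixel sides.
#' @param n_pixels Pixel count(s).
#' @param variant Shape-index convention, see above.
#' @param a,a_core Patch and core areas (same units).
#' @return Numeric vector of trait values.
#' @name scalar-traits
NULL

#' @rdname scalar-traits
#' @export
perimeter_area_ratio <- function(P, n_pixels) P / n_pixels

#' @rdname scalar-traits
#' @export
shape_index <- function(P, n_pixels,
                        variant = c("compact_min_perimeter", "sqrt_formula")) {
  variant <- match.arg(variant)
  if (variant == "sqrt_formula") return(0.25 * P / sqrt(n_pixels))
  P / min_perimeter(n_pixels)
}

# Minimum perimeter of a polyomino with n cells (spiral-packed square).
min_perimeter <- function(n_pixels) {
  k <- floor(sqrt(n_pixels))
  dplyr::case_when(
    n_pixels == k^2 ~ 4 * k,
    n_pixels <= k * (k + 1) ~ 4 * k + 2,
    .default = 4 * k + 4
  )
}

#' @rdname scalar-traits
#' @export
fractal_dimension <- function(P, n_pixels) {
  ifelse(n_pixels > 1, 2 * log(0.25 * P) / log(n_pixels), NA_real_)
}

#' @rdname scalar-traits
#' @export
core_area_index <- function(a_core, a) a_core / a

#' Perimeter and core-pixel counts per patch
#'
#' The perimeter of a patch is the number of unit cell edges adjacent to
#' exactly one of its pixels - outer boundary plus any interior hole
#' boundaries. A core pixel is a patch pixel all of whose neighbors
#' (8-neighborhood by default, matching "totally surrounded") also belong
#' to the patch.
#'
#' @param patches Pixel table from [flood_fill_patches()].
#' @param core_neighbors 8 (default) or 4, the neighborhood defining a core
#'   pixel.
#' @return A tibble: `patch`, `n_pixels`, `perimeter`, `n_core`.
#' @export
patch_morphology <- function(patches, core_neighbors = 8) {
  stopifnot(core_neighbors %in% c(4, 8))
  if (nrow(patches) == 0)
    return(tibble(patch = integer(), n_pixels = integer(),
                  perimeter = integer(), n_core = integer()))
  # local label matrix padded by one ring of background
  r0 <- min(patches$row) - 1L; c0 <- min(patches$col) - 1L
  nr <- max(patches$row) - r0 + 2L
  nc <- max(patches$col) - c0 + 2L
  lab <- matrix(0L, nr, nc)
  lab[cbind(patches$row - r0 + 1L, patches$col - c0 + 1L)] <- patches$patch

  shift <- function(dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- lab[rs - dr, cs - dc]
    out
  }
  rook <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  diag <- list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))

  inside <- lab > 0L
  perim_contrib <- matrix(0L, nr, nc)
  core_ok <- matrix(TRUE, nr, nc)
  for (d in rook) {
    nb <- shift(d[1], d[2])
    perim_contrib <- perim_contrib + (inside & nb != lab)
    core_ok <- core_ok & nb == lab
  }
  if (core_neighbors == 8)
    for (d in diag) core_ok <- core_ok & shift(d[1], d[2]) == lab

  tibble(patch = lab[inside],
         perim = perim_contrib[inside],
         core = (core_ok & inside)[inside]) |>
    dplyr::summarise(n_pixels = dplyr::n(),
                     perimeter = as.integer(sum(.data$perim)),
                     n_core = as.integer(sum(.data$core)),
                     .by = "patch") |>
    dplyr::arrange(.data$patch)
}

#' Per-patch functional trait table
#'
#' Computes, for every patch in a catalogue, the full trait record: pixel
#' and core-pixel counts, geodesic areas (ha, spherical Earth), perimeter,
#' perimeter-to-area ratio, shape index, fractal correlation dimension,
#' core-area index, patch center, standard deviation ellipse (degree and
#' local-km fits), burn-date summary and year. Columns follow the
#' catalogue field order: `patch_id`, `N_pixels`, `N_core_pixels`, `A`,
#' `A_core`, `P`, `PAR`, `SI`, `D2`, `CA`, `X`, `Y`, `sigma_X`, `sigma_Y`,
#' `theta`, `sigma_X_km`, `sigma_Y_km`, `theta_km`, `R_SDE`, `E_SDE`,
#' `BD_min`, `BD_max`, `BD_mean`, `Year`.
#'
#' @param patches Pixel table from [flood_fill_patches()] (ideally after
#'   [filter_patches()]; the SDE and complexity indices are unreliable
#'   below 5 pixels).
#' @param geometry Raster geometry; defaults to the attribute on `patches`.
#' @param si_variant Shape-index convention, see [shape_index()].
#' @param core_neighbors Core-pixel neighborhood (8 or 4).
#' @return A tibble, one row per patch, in the column order above.
#' @export
patch_traits <- function(patches, geometry = attr(patches, "geometry"),
                         si_variant = "compact_min_perimeter",
                         core_neighbors = 8) {
  if (is.null(geometry)) stop("raster `geometry` is required")
  morph <- patch_morphology(patches, core_neighbors = core_neighbors)
  if (nrow(morph) == 0) return(empty_trait_table())
  area_by_row <- row_areas(geometry)

  core_map <- core_pixel_flags(patches, core_neighbors)
  base <- patches |>
    dplyr::mutate(pix_area = area_by_row[.data$row], core = core_map) |>
    dplyr::summarise(
      patch_id = .data$patch_id[1],
      A = sum(.data$pix_area),
      A_core = sum(.data$pix_area[.data$core]),
      X = mean(.data$lon), Y = mean(.data$lat),
      BD_min = min(.data$burn_date), BD_max = max(.data$burn_date),
      BD_mean = round(mean(.data$burn_date), 2),
      .by = "patch")

  sde <- patches |>
    tidyr::nest(.by = "patch", .key = "px") |>
    dplyr::mutate(fit = purrr::map(.data$px, \(d) fit_sde(d$lon, d$lat))) |>
    dplyr::select("patch", "fit") |>
    tidyr::unnest("fit")

  year0 <- if (!is.null(geometry$year)) geometry$year else 2001L
  base |>
    dplyr::inner_join(morph, by = "patch") |>
    dplyr::inner_join(sde, by = "patch") |>
    dplyr::mutate(
      PAR = perimeter_area_ratio(.data$perimeter, .data$n_pixels),
      SI = shape_index(.data$perimeter, .data$n_pixels, si_variant),
      D2 = fractal_dimension(.data$perimeter, .data$n_pixels),
      CA = core_area_index(.data$A_core, .data$A),
      Year = as.integer(format(
        as.Date(paste0(year0, "-01-01")) + floor(.data$BD_mean) - 1, "%Y"))
    ) |>
    dplyr::transmute(
      patch = .data$patch, patch_id = .data$patch_id,
      N_pixels = .data$n_pixels, N_core_pixels = .data$n_core,
      A = .data$A, A_core = .data$A_core, P = .data$perimeter,
      PAR = .data$PAR, SI = .data$SI, D2 = .data$D2, CA = .data$CA,
      X = .data$X, Y = .data$Y,
      sigma_X = .data$sigma_X, sigma_Y = .data$sigma_Y, theta = .data$theta,
      sigma_X_km = .data$sigma_X_km, sigma_Y_km = .data$sigma_Y_km,
      theta_km = .data$theta_km, R_SDE = .data$R_SDE, E_SDE = .data$E_SDE,
      BD_min = .data$BD_min, BD_max = .data$BD_max, BD_mean = .data$BD_mean,
      Year = .data$Year)
}

empty_trait_table <- function() {
  tibble(patch = integer(), patch_id = character(), N_pixels = integer(),
         N_core_pixels = integer(), A = numeric(), A_core = numeric(),
         P = integer(), PAR = numeric(), SI = numeric(), D2 = numeric(),
         CA = numeric(), X = numeric(), Y = numeric(), sigma_X = numeric(),
         sigma_Y = numeric(), theta = numeric(), sigma_X_km = numeric(),
         sigma_Y_km = numeric(), theta_km = numeric(), R_SDE = numeric(),
         E_SDE = numeric(), BD_min = integer(), BD_max = integer(),
         BD_mean = numeric(), Year = integer())
}

# logical vector aligned with `patches` rows: is each pixel a core pixel?
core_pixel_flags <- function(patches, core_neighbors = 8) {
  if (nrow(patches) == 0) return(logical(0))
  r0 <- min(patches$row) - 1L; c0 <- min(patches$col) - 1L
  nr <- max(patches$row) - r0 + 2L
  nc <- max(patches$col) - c0 + 2L
  lab <- matrix(0L, nr, nc)
  rr <- patches$row - r0 + 1L; cc <- patches$col - c0 + 1L
  lab[cbind(rr, cc)] <- patches$patch
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (core_neighbors == 8)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  ok <- rep(TRUE, nrow(patches))
  for (d in offs)
    ok <- ok & lab[cbind(rr + d[1], cc + d[2])] == patches$patch
  ok
}
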