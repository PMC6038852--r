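#' Tiling scheme with overlapping borders
#'
#' Patch construction over large domains is parallelized by cutting the
#' domain into square tiles whose cores partition it and whose full extents
#' overlap their neighbors, so that fires straddling a core boundary are
#' still reconstructed whole in at least one tile. The published runs used
#' 3.5 deg tiles with 0.5 deg borders around 2.5 deg cores.
#'
#' @param tile_size_deg Full tile width (degrees).
#' @param border_deg Overlap border width (degrees).
#' @param core_size_deg Core width; must satisfy
#'   `core_size_deg + 2 * border_deg == tile_size_deg`.
#' @return A `tile_scheme` list.
#' @export
tile_scheme <- function(tile_size_deg = 3.5, border_deg = 0.5,
                        core_size_deg = 2.5) {
  if (abs(core_size_deg + 2 * border_deg - tile_size_deg) > 1e-9)
    stop("invalid scheme: core + 2*border must equal the tile size")
  structure(list(tile_size_deg = tile_size_deg, border_deg = border_deg,
                 core_size_deg = core_size_deg), class = "tile_scheme")
}

#' Lay out tiles over a domain
#'
#' Cores step by `core_size_deg` from the west/south domain corner and
#' partition the domain exactly once (the last core in each direction is
#' clipped at the domain edge); each full extent is its core dilated by
#' `border_deg`, clipped at the domain edge. Core extents are half-open
#' `[west, east) x [south, north)`, so a patch center on a shared core
#' boundary belongs to exactly one tile.
#'
#' @param domain_bounds `c(west, south, east, north)` in degrees.
#' @param scheme A [tile_scheme()].
#' @return A tibble, one row per tile: `tile_id`, `full_w`, `full_s`,
#'   `full_e`, `full_n`, `core_w`, `core_s`, `core_e`, `core_n`.
#' @export
make_tiles <- function(domain_bounds, scheme = tile_scheme()) {
  stopifnot(length(domain_bounds) == 4)
  w <- domain_bounds[1]; s <- domain_bounds[2]
  e <- domain_bounds[3]; n <- domain_bounds[4]
  if (e - w < scheme$core_size_deg - 1e-9 ||
      n - s < scheme$core_size_deg - 1e-9)
    stop("domain must span at least one tile core")
  edges <- function(lo, hi) {
    starts <- seq(lo, hi - 1e-9, by = scheme$core_size_deg)
    tibble(lo = starts, hi = pmin(starts + scheme$core_size_deg, hi))
  }
  ew <- edges(w, e); sn <- edges(s, n)
  grid <- tidyr::expand_grid(ix = seq_len(nrow(ew)), iy = seq_len(nrow(sn)))
  b <- scheme$border_deg
  tibble(
    tile_id = sprintf("tile_%02d_%02d", grid$ix, grid$iy),
    core_w = ew$lo[grid$ix], core_e = ew$hi[grid$ix],
    core_s = sn$lo[grid$iy], core_n = sn$hi[grid$iy]
  ) |>
    dplyr::mutate(
      full_w = pmax(.data$core_w - b, w), full_e = pmin(.data$core_e + b, e),
      full_s = pmax(.data$core_s - b, s), full_n = pmin(.data$core_n + b, n)
    ) |>
    dplyr::select("tile_id", "full_w", "full_s", "full_e", "full_n",
                  "core_w", "core_s", "core_e", "core_n")
}

#' Assign a patch center to the tile owning it
#'
#' A patch reconstructed in several overlapping tiles is kept exactly once:
#' the tile whose half-open core `[west, east) x [south, north)` contains
#' its center.
#'
#' @param lon,lat Patch center coordinates (degrees), vectorized.
#' @param tiles Tile table from [make_tiles()].
#' @return Character vector of tile IDs (`NA` when the center lies outside
#'   every core).
#' @export
assign_patch_to_tile <- function(lon, lat, tiles) {
  vapply(seq_along(lon), function(i) {
    hit <- which(lon[i] >= tiles$core_w & lon[i] < tiles$core_e &
                 lat[i] >= tiles$core_s & lat[i] < tiles$core_n)
    if (length(hit) == 1) tiles$tile_id[hit] else NA_character_
  }, character(1))
}

#' Build the patch catalogue tile by tile
#'
#' Reference-equivalent tiled execution: crops the raster to each tile's
#' full extent, reconstructs patches per tile, and keeps each patch in the
#' unique tile whose core contains its center (deduplicating the overlap).
#' Patches are renumbered globally in the same deterministic order as the
#' single-raster path, so for fires smaller than the border width the
#' result is identical to [flood_fill_patches()] on the whole raster.
#' Patches wider than the border can still be split at tile seams - a
#' known limitation of the overlap scheme; the single-raster path is the
#' reference.
#'
#' @inheritParams flood_fill_patches
#' @param scheme A [tile_scheme()].
#' @return Same layout as [flood_fill_patches()].
#' @export
tiled_patches <- function(raster, cutoff_days, scheme = tile_scheme(),
                          survey = "SYN") {
  ps <- raster$pixel_size
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  domain <- c(raster$origin[1], raster$origin[2] - nr * ps,
              raster$origin[1] + nc * ps, raster$origin[2])
  tiles <- make_tiles(domain, scheme)
  pieces <- purrr::pmap(tiles, function(tile_id, full_w, full_s, full_e,
                                        full_n, core_w, core_s, core_e,
                                        core_n) {
    sub <- crop_burn_raster(raster, c(full_w, full_s, full_e, full_n))
    px <- flood_fill_patches(sub, cutoff_days, survey = survey)
    if (nrow(px) == 0) return(px)
    centers <- px |>
      dplyr::summarise(X = mean(.data$lon), Y = mean(.data$lat),
                       .by = "patch") |>
      dplyr::filter(.data$X >= core_w, .data$X < core_e,
                    .data$Y >= core_s, .data$Y < core_n)
    kept <- dplyr::semi_join(px, centers, by = "patch")
    # back to whole-raster pixel indices
    dr <- round((raster$origin[2] - sub$origin[2]) / ps)
    dc <- round((sub$origin[1] - raster$origin[1]) / ps)
    # global pixel indices; recompute lon/lat from the global geotransform
    # so coordinates are bit-identical to the single-raster path
    dplyr::mutate(kept, row = .data$row + as.integer(dr),
                  col = .data$col + as.integer(dc),
                  lon = pixel_lon(raster, .data$col),
                  lat = pixel_lat(raster, .data$row),
                  .tile = tile_id)
  })
  all_px <- dplyr::bind_rows(pieces)
  if (nrow(all_px) == 0) return(empty_patch_table(raster, cutoff_days))
  # renumber globally: row-major first pixel, as in the single-raster path
  firsts <- all_px |>
    dplyr::mutate(.tile_patch = paste(.data$.tile, .data$patch)) |>
    dplyr::group_by(.data$.tile_patch) |>
    dplyr::summarise(ord = min((.data$row - 1) * 1e9 + .data$col),
                     .groups = "drop") |>
    dplyr::arrange(.data$ord) |>
    dplyr::mutate(serial = dplyr::row_number())
  out <- all_px |>
    dplyr::mutate(.tile_patch = paste(.data$.tile, .data$patch)) |>
    dplyr::inner_join(dplyr::select(firsts, ".tile_patch", "serial"),
                      by = ".tile_patch") |>
    dplyr::mutate(patch = .data$serial,
                  patch_id = sprintf("%s_co%d_%06d", survey,
                                     as.integer(cutoff_days), .data$serial)) |>
    dplyr::select("patch", "patch_id", "row", "col", "lon", "lat",
                  "burn_date") |>
    dplyr::arrange(.data$patch, .data$row, .data$col)
  attr(out, "geometry") <- raster_geometry(raster)
  attr(out, "cutoff_days") <- as.integer(cutoff_days)
  out
}
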