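#' Reconstruct fire patches from a burn-date raster
#'
#' Aggregates burned pixels into fire patches: two pixels belong to the same
#' patch when they are connected by a chain of queen-adjacent (8-neighbor)
#' burned pixels whose pairwise burn-date differences are each at most
#' `cutoff_days`. This is the connected-component partition of the graph
#' whose vertices are burned pixels and whose edges join adjacent pixels
#' with `|date difference| <= cutoff_days`; the transitive closure means a
#' patch may span a date range much wider than the cut-off. Unburned and
#' unmapped pixels break connectivity.
#'
#' Implemented as a vectorized scan over the four forward neighbor offsets
#' feeding a union-find structure, which is equivalent to (and checked in
#' the test-suite against) an explicit graph-component oracle,
#' [brute_force_patches()].
#'
#' Patch serials are deterministic: patches are numbered by the row-major
#' position of their first pixel (earliest burn date breaking ties), so
#' identical rasters always yield identical catalogues.
#'
#' @param raster A [burn_raster()].
#' @param cutoff_days Temporal cut-off in days (integer >= 1). The published
#'   catalogues use 3, 5, 9 and 14.
#' @param survey Label embedded in patch IDs (e.g. `"SYN"`, `"MODIS_6"`).
#' @return A tibble with one row per burned pixel: `patch` (integer serial),
#'   `patch_id` (string embedding survey and cut-off), `row`, `col`, `lon`,
#'   `lat`, `burn_date`. The raster geometry and cut-off are attached as
#'   attributes `geometry` and `cutoff_days`.
#' @export
#' @examples
#' r <- burn_raster(matrix(c(10, 0, 12, 0), 2, 2), origin = c(0, 1),
#'                  pixel_size = 0.01)
#' flood_fill_patches(r, cutoff_days = 3)
flood_fill_patches <- function(raster, cutoff_days, survey = "SYN") {
  check_cutoff(cutoff_days)
  v <- raster$values
  if (any(abs(v - round(v)) > 1e-9)) stop("burn dates must be integers")
  nr <- nrow(v); nc <- ncol(v)
  burned <- v > 0L
  n <- sum(burned)
  if (n == 0L) return(empty_patch_table(raster, cutoff_days))

  id <- matrix(0L, nr, nc)
  id[burned] <- seq_len(n)               # vertex ids in column-major order
  parent <- seq_len(n)

  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  # forward queen offsets: E, SW, S, SE (each undirected edge visited once)
  offsets <- list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    if (nr - dr < 1 || nc - abs(dc) < 1) next
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- v[r1, c1, drop = FALSE]
    b <- v[r1 + dr, c1 + dc, drop = FALSE]
    ok <- which(a > 0L & b > 0L & abs(a - b) <= cutoff_days)
    if (!length(ok)) next
    ia <- id[r1, c1, drop = FALSE][ok]
    ib <- id[r1 + dr, c1 + dc, drop = FALSE][ok]
    for (k in seq_along(ia)) {
      ra <- find_root(ia[k]); rb <- find_root(ib[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }

  roots <- vapply(seq_len(n), find_root, integer(1))
  finalize_patch_table(raster, cutoff_days, survey, burned, roots)
}

#' Brute-force patch reconstruction (reference oracle)
#'
#' Builds the pixel adjacency graph explicitly - every queen-adjacent pair
#' of burned pixels with burn-date difference at most `cutoff_days` becomes
#' an edge - and takes connected components with [igraph::components()].
#' Intended for small rasters as an independent check of
#' [flood_fill_patches()]; the two must produce identical partitions.
#'
#' @inheritParams flood_fill_patches
#' @return Same layout as [flood_fill_patches()].
#' @export
brute_force_patches <- function(raster, cutoff_days, survey = "SYN") {
  check_cutoff(cutoff_days)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  burned <- v > 0L
  n <- sum(burned)
  if (n == 0L) return(empty_patch_table(raster, cutoff_days))
  id <- matrix(0L, nr, nc)
  id[burned] <- seq_len(n)
  cells <- which(burned, arr.ind = TRUE)
  edges <- list()
  for (k in seq_len(n)) {
    r <- cells[k, 1]; c <- cells[k, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!burned[rr, cc]) next
      j <- id[rr, cc]
      if (j > id[r, c] && abs(v[r, c] - v[rr, cc]) <= cutoff_days)
        edges[[length(edges) + 1]] <- c(id[r, c], j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  roots <- igraph::components(g)$membership
  finalize_patch_table(raster, cutoff_days, survey, burned, roots)
}

check_cutoff <- function(cutoff_days) {
  if (!is.numeric(cutoff_days) || length(cutoff_days) != 1 ||
      cutoff_days < 1 || cutoff_days != round(cutoff_days))
    stop("`cutoff_days` must be a single integer >= 1")
}

empty_patch_table <- function(raster, cutoff_days) {
  out <- tibble(patch = integer(), patch_id = character(), row = integer(),
                col = integer(), lon = numeric(), lat = numeric(),
                burn_date = integer())
  attr(out, "geometry") <- raster_geometry(raster)
  attr(out, "cutoff_days") <- as.integer(cutoff_days)
  out
}

raster_geometry <- function(raster) {
  list(origin = raster$origin, pixel_size = raster$pixel_size,
       year = raster$year, nrow = nrow(raster$values),
       ncol = ncol(raster$values))
}

# Shared tail of both builders: renumber components deterministically
# (row-major first pixel, earliest date tie-break) and lay out the pixel
# table.
finalize_patch_table <- function(raster, cutoff_days, survey, burned, roots) {
  v <- raster$values
  nr <- nrow(v)
  cells <- which(burned, arr.ind = TRUE)    # column-major order
  px <- tibble(row = as.integer(cells[, 1]), col = as.integer(cells[, 2]),
               burn_date = as.integer(v[burned]), comp = as.integer(roots))
  # row-major position of each component's first pixel; earliest date tie-break
  ord <- order(px$row, px$col)
  first_seen <- ord[!duplicated(px$comp[ord])]
  firsts <- px[first_seen, ]
  firsts <- firsts[order(firsts$row, firsts$col, firsts$burn_date), ]
  serial <- setNames(seq_len(nrow(firsts)), firsts$comp)
  px$patch <- as.integer(serial[as.character(px$comp)])
  px <- px[order(px$patch, px$row, px$col), ]
  out <- tibble(
    patch = px$patch,
    patch_id = sprintf("%s_co%d_%06d", survey, as.integer(cutoff_days),
                       px$patch),
    row = px$row, col = px$col,
    lon = pixel_lon(raster, px$col),
    lat = pixel_lat(raster, px$row),
    burn_date = px$burn_date
  )
  attr(out, "geometry") <- raster_geometry(raster)
  attr(out, "cutoff_days") <- as.integer(cutoff_days)
  out
}

#' Filter a patch catalogue by size
#'
#' Keeps patches with at least `min_pixels` pixels and a total area of at
#' least `min_area_ha` hectares. The published trait catalogues drop
#' patches below 5 pixels; cross-product comparisons additionally drop
#' patches below 107 ha (the area of a 5-pixel fire at the equator at
#' 463 m resolution).
#'
#' @param patches Pixel table from [flood_fill_patches()].
#' @param min_pixels Minimum pixel count (>= 1).
#' @param min_area_ha Minimum patch area in hectares.
#' @param geometry Raster geometry; defaults to the attribute carried by
#'   `patches` (needed only when `min_area_ha > 0`).
#' @return The filtered pixel table, patch order preserved.
#' @export
filter_patches <- function(patches, min_pixels = 5L, min_area_ha = 0,
                           geometry = attr(patches, "geometry")) {
  stopifnot(min_pixels >= 1)
  if (nrow(patches) == 0) return(patches)
  keep <- patches |>
    dplyr::count(.data$patch, name = "n_pixels") |>
    dplyr::filter(.data$n_pixels >= min_pixels)
  if (min_area_ha > 0) {
    if (is.null(geometry)) stop("`geometry` needed to apply an area filter")
    area_by_row <- row_areas(geometry)
    ar <- patches |>
      dplyr::mutate(a = area_by_row[.data$row]) |>
      dplyr::summarise(area_ha = sum(.data$a), .by = "patch") |>
      dplyr::filter(.data$area_ha >= min_area_ha)
    keep <- dplyr::semi_join(keep, ar, by = "patch")
  }
  out <- dplyr::semi_join(patches, keep, by = "patch")
  attr(out, "geometry") <- attr(patches, "geometry")
  attr(out, "cutoff_days") <- attr(patches, "cutoff_days")
  out
}

# per-row pixel areas (ha) from a geometry list
row_areas <- function(geometry) {
  fake <- list(values = matrix(0L, geometry$nrow, 1), origin = geometry$origin,
               pixel_size = geometry$pixel_size)
  class(fake) <- "burn_raster"
  pixel_area_ha(fake)
}

#' Annotate patches with their output month
#'
#' Fire records are organized on a monthly time step (a pixel can burn more
#' than once a year, so yearly files would collide). Patches are built on
#' the full date axis first and then assigned to the calendar month that
#' contains their mean burn date; patches are never truncated at month
#' boundaries.
#'
#' @param patches Pixel table from [flood_fill_patches()].
#' @param year Calendar year anchoring day 1; defaults to the year of the
#'   source raster.
#' @return `patches` with an added `month` column (integer 1-12, constant
#'   within each patch).
#' @export
monthly_grouping <- function(patches, year = NULL) {
  if (is.null(year)) {
    geom <- attr(patches, "geometry")
    year <- if (!is.null(geom)) geom$year else 2001L
  }
  if (nrow(patches) == 0) return(dplyr::mutate(patches, month = integer()))
  out <- patches |>
    dplyr::mutate(
      month = as.integer(format(
        as.Date(paste0(year, "-01-01")) + floor(mean(.data$burn_date)) - 1,
        "%m")),
      .by = "patch")
  attr(out, "geometry") <- attr(patches, "geometry")
  attr(out, "cutoff_days") <- attr(patches, "cutoff_days")
  out
}

#' Plot a patch catalogue
#'
#' @param patches Pixel table from [flood_fill_patches()].
#' @return A ggplot of pixels colored by patch.
#' @export
plot_patches <- function(patches) {
  ggplot2::ggplot(patches,
                  ggplot2::aes(.data$lon, .data$lat,
                               fill = factor(.data$patch))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}
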