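#' Fit a Standard Deviation Ellipse to pixel coordinates
#'
#' Centrographic summary of a point set: the ellipse centered on the
#' coordinate mean whose axes are the directional standard deviations along
#' the principal directions of the centered coordinates. Half-axis lengths
#' are `sqrt(2) * sqrt(eigenvalues)` of the 2x2 covariance matrix computed
#' with `n - 2` in the denominator (the convention of the classical
#' centrographic implementations; with these factors the ellipse covers
#' roughly two thirds of a compact point cloud). The azimuth `theta` is the
#' direction of the major axis measured clockwise from north, folded to
#' `[0, 180)` since an ellipse axis has no preferred sense.
#'
#' Two fits are reported: one in raw lon/lat degrees, and one after
#' projecting the points to a local flat (equirectangular) frame
#' `x_km = (lon - lon0) * 111.320 * cos(lat0)`,
#' `y_km = (lat - lat0) * 110.574` about the patch center, which yields the
#' km half-axes used for the ellipse ratio `R = sigma_min / sigma_maj`
#' (in `(0, 1]`) and eccentricity `E = sqrt(1 - R^2)`; `R^2 + E^2 = 1` by
#' construction.
#'
#' Degenerate inputs: with fewer than 3 points every field is `NA`; with
#' collinear points the minor axis is 0, `R = 0`, `E = 1` and `degenerate`
#' is set.
#'
#' @param lon,lat Coordinates of the pixel centers (degrees).
#' @param scale_factor Axis scale multiplier (default `sqrt(2)`).
#' @param ddof Denominator offset of the covariance (default 2).
#' @return A one-row tibble: `sigma_X`, `sigma_Y` (degree half-axes,
#'   minor <= major), `theta`, `sigma_X_km`, `sigma_Y_km`, `theta_km`,
#'   `R_SDE`, `E_SDE`, `degenerate`.
#' @export
#' @examples
#' pts <- expand.grid(lon = seq(0, 0.03, 0.01), lat = seq(0, 0.03, 0.01))
#' fit_sde(pts$lon, pts$lat)  # 4-fold symmetry: R_SDE = 1, E_SDE = 0
fit_sde <- function(lon, lat, scale_factor = sqrt(2), ddof = 2) {
  n <- length(lon)
  stopifnot(length(lat) == n)
  if (n < 3) {
    return(tibble(sigma_X = NA_real_, sigma_Y = NA_real_, theta = NA_real_,
                  sigma_X_km = NA_real_, sigma_Y_km = NA_real_,
                  theta_km = NA_real_, R_SDE = NA_real_, E_SDE = NA_real_,
                  degenerate = TRUE))
  }
  lon0 <- mean(lon); lat0 <- mean(lat)
  deg <- sde_axes(lon - lon0, lat - lat0, scale_factor, ddof)
  km <- sde_axes((lon - lon0) * KM_PER_DEG_LON_EQ * cos(lat0 * pi / 180),
                 (lat - lat0) * KM_PER_DEG_LAT, scale_factor, ddof)
  degenerate <- km$minor <= km$major * 1e-12
  R <- if (degenerate) 0 else km$minor / km$major
  tibble(sigma_X = deg$minor, sigma_Y = deg$major, theta = deg$theta,
         sigma_X_km = km$minor, sigma_Y_km = km$major, theta_km = km$theta,
         R_SDE = R, E_SDE = sqrt(pmax(0, 1 - R^2)), degenerate = degenerate)
}

# principal axes of a centered 2D point set; x = east, y = north
sde_axes <- function(x, y, scale_factor, ddof) {
  n <- length(x)
  cmat <- crossprod(cbind(x, y)) / max(n - ddof, 1)
  e <- eigen(cmat, symmetric = TRUE)
  major_v <- e$vectors[, 1]
  theta <- atan2(major_v[1], major_v[2]) * 180 / pi   # clockwise from north
  theta <- theta %% 180
  if (theta >= 180 - 1e-9) theta <- 0    # fold boundary: 180 == 0
  list(major = scale_factor * sqrt(max(e$values[1], 0)),
       minor = scale_factor * sqrt(max(e$values[2], 0)),
       theta = theta)
}

#' Fraction of points inside a fitted standard deviation ellipse
#'
#' Diagnostic companion to [fit_sde()]: the share of the input points whose
#' Mahalanobis-style elliptical radius is at most 1 under the fitted km
#' ellipse. For compact convex patches this is around 2/3.
#'
#' @inheritParams fit_sde
#' @param fit Optional precomputed [fit_sde()] row.
#' @return A single fraction in `[0, 1]` (NA for degenerate fits).
#' @export
sde_coverage <- function(lon, lat, fit = fit_sde(lon, lat)) {
  if (isTRUE(fit$degenerate) || is.na(fit$sigma_X_km)) return(NA_real_)
  lon0 <- mean(lon); lat0 <- mean(lat)
  x <- (lon - lon0) * KM_PER_DEG_LON_EQ * cos(lat0 * pi / 180)
  y <- (lat - lat0) * KM_PER_DEG_LAT
  th <- fit$theta_km * pi / 180
  u <- x * sin(th) + y * cos(th)   # along major axis
  v <- x * cos(th) - y * sin(th)
  mean((u / fit$sigma_Y_km)^2 + (v / fit$sigma_X_km)^2 <= 1)
}
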