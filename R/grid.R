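#' Define a regular longitude-latitude grid
#'
#' Cells are half-open `[edge, edge + resolution)` in both axes and enumerated
#' row-major from the south-west corner: cell 1 covers
#' `[lon_min, lon_min + res) x [lat_min, lat_min + res)`, ids then increase
#' eastward along each latitude row before moving north.
#'
#' @param lon_min,lon_max,lat_min,lat_max grid extents in degrees.
#' @param resolution cell size in degrees (default 1).
#' @return An object of class `bg_grid` with the extents, `n_lon`, `n_lat`
#'   and `n_cells`.
#' @examples
#' g <- make_grid(-180, 180, -75, -30)
#' g$n_cells  # 360 x 45 = 16200
#' @export
make_grid <- function(lon_min, lon_max, lat_min, lat_max, resolution = 1) {
  stopifnot(is.numeric(resolution), resolution > 0)
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("grid extents must be increasing")
  spans <- c((lon_max - lon_min) / resolution, (lat_max - lat_min) / resolution)
  if (any(abs(spans - round(spans)) > 1e-8))
    stop("grid extents must be integer multiples of the resolution")
  n_lon <- as.integer(round(spans[1]))
  n_lat <- as.integer(round(spans[2]))
  if (n_lon < 2 || n_lat < 2)
    stop("grid must span at least 2 cells per axis")
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         resolution = resolution,
         n_lon = n_lon, n_lat = n_lat,
         n_cells = n_lon * n_lat),
    class = "bg_grid")
}

#' @export
print.bg_grid <- function(x, ...) {
  cat(sprintf("<bg_grid> %g deg, lon [%g, %g), lat [%g, %g): %d x %d = %d cells\n",
              x$resolution, x$lon_min, x$lon_max, x$lat_min, x$lat_max,
              x$n_lon, x$n_lat, x$n_cells))
  invisible(x)
}

#' Wrap longitudes into [-180, 180)
#' @param lon numeric vector of longitudes in degrees.
#' @return wrapped longitudes.
#' @export
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Map points to grid cells
#'
#' Applies the half-open cell convention: a point lying exactly on an interior
#' edge belongs to the cell whose lower edge it is. Points outside the grid
#' extent map to `NA`.
#'
#' @param grid a `bg_grid`.
#' @param lon,lat coordinates in degrees; longitudes are wrapped into
#'   `[-180, 180)` first.
#' @return integer cell ids (NA outside the extent).
#' @export
cell_of <- function(grid, lon, lat) {
  lon <- wrap_lon(lon)
  col <- floor((lon - grid$lon_min) / grid$resolution)
  row <- floor((lat - grid$lat_min) / grid$resolution)
  ok <- !is.na(lon) & !is.na(lat) &
    col >= 0 & col < grid$n_lon & row >= 0 & row < grid$n_lat
  out <- rep(NA_integer_, length(lon))
  out[ok] <- as.integer(row[ok] * grid$n_lon + col[ok] + 1)
  out
}

#' Cell centre coordinates
#' @param grid a `bg_grid`.
#' @return data.frame with `cell`, `lon`, `lat` (centres), one row per cell.
#' @export
cell_centers <- function(grid) {
  half <- grid$resolution / 2
  lon <- grid$lon_min + (seq_len(grid$n_lon) - 1) * grid$resolution + half
  lat <- grid$lat_min + (seq_len(grid$n_lat) - 1) * grid$resolution + half
  data.frame(cell = seq_len(grid$n_cells),
             lon = rep(lon, times = grid$n_lat),
             lat = rep(lat, each = grid$n_lon))
}

#' Spherical cell areas
#'
#' Analytic area of each cell on the sphere,
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_{top} - \sin\phi_{bottom})}, which gives
#' the same band and global sums as an equal-area map projection without any
#' projection machinery. Summed over a full sphere of 1-degree cells the areas
#' add to \eqn{4\pi R^2}.
#'
#' @param grid a `bg_grid`.
#' @param R sphere radius in km (default 6371, the Earth mean radius).
#' @return numeric vector of areas in km^2, one per cell.
#' @export
cell_areas <- function(grid, R = 6371) {
  dlam <- grid$resolution * pi / 180
  lat_bot <- (grid$lat_min + (seq_len(grid$n_lat) - 1) * grid$resolution) * pi / 180
  lat_top <- lat_bot + grid$resolution * pi / 180
  band <- R^2 * dlam * (sin(lat_top) - sin(lat_bot))
  rep(band, each = grid$n_lon)
}

# Run code with a temporary RNG state seeded from `seed`; restores the caller's
# stream so generators are reproducible without clobbering user RNG.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}
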