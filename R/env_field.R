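#' Construct a gridded environmental field
#'
#' One value per ocean cell; land (masked) cells carry `NA`.
#'
#' @param grid a `bg_grid`.
#' @param values numeric vector, length `grid$n_cells`.
#' @param mask logical vector, `TRUE` = ocean. Defaults to all ocean.
#' @param variable variable name (e.g. `"temperature"`).
#' @param depth depth in metres (0, 100, 200 or 500 in the default setup).
#' @return object of class `bg_env_field`.
#' @export
env_field <- function(grid, values, mask = NULL, variable = "temperature",
                      depth = 200) {
  stopifnot(inherits(grid, "bg_grid"), length(values) == grid$n_cells)
  if (is.null(mask)) mask <- rep(TRUE, grid$n_cells)
  stopifnot(length(mask) == grid$n_cells, is.logical(mask))
  values[!mask] <- NA_real_
  structure(list(grid = grid, values = values, mask = mask,
                 variable = variable, depth = depth),
            class = "bg_env_field")
}

#' @export
print.bg_env_field <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<bg_env_field> %s @ %g m: %d ocean cells, range [%.2f, %.2f]\n",
              x$variable, x$depth, sum(x$mask), min(v), max(v)))
  invisible(x)
}

#' Default land mask for the synthetic scene
#'
#' Mostly ocean, with a few fixed rectangular land blocks standing in for
#' continental margins and island groups so that the on-land cleaning rule and
#' masked-cell handling are exercised.
#'
#' @param grid a `bg_grid`.
#' @return logical vector, `TRUE` = ocean.
#' @export
make_land_mask <- function(grid) {
  cc <- cell_centers(grid)
  land <- (cc$lon >= -75 & cc$lon < -62 & cc$lat >= -56 & cc$lat < -30) | # SW coast
    (cc$lon >= 165 & cc$lon < 175 & cc$lat >= -46 & cc$lat < -34) |       # islands
    (cc$lat < -72)                                                        # ice shelf
  !land
}

#' Synthetic baseline temperature field
#'
#' Temperature increases monotonically with latitude from `T_south` at the
#' southern edge to `T_north` at the northern edge (poleward-cold), plus a
#' smooth zonal sinusoidal perturbation and white noise. The latitudinal
#' profile blends a linear trend with a logistic steepening centred at
#' `front_frac` of the latitude span: with `front_weight = 0` the profile is
#' purely linear; with the defaults it concentrates much of the meridional
#' temperature change in a narrow frontal zone, mimicking the sharp
#' oceanographic fronts that separate water masses. The latitude of any
#' isotherm of the noise-free, zonally averaged profile is given by
#' [isotherm_latitude()].
#'
#' @param grid a `bg_grid`.
#' @param mask logical ocean mask (default [make_land_mask()]).
#' @param T_south,T_north temperatures (degC) at the southern / northern edge;
#'   `T_south < T_north` required.
#' @param noise_sd white-noise s.d. in degC (default 0.3).
#' @param zonal_amp amplitude (degC) of the zonal perturbation (default 1).
#' @param zonal_wavenumber integer number of wave cycles around the globe
#'   (default 3; 0 gives a zonally constant field).
#' @param front_weight fraction of the meridional change carried by the
#'   frontal (logistic) component, in `[0, 1)` (default 0.8; 0 = linear).
#' @param front_sharpness steepness of the logistic component on the unit
#'   latitude span (default 40).
#' @param front_frac position of the front as a fraction of the latitude span
#'   (default: where the linear profile crosses 8 degC).
#' @param depth nominal depth label in metres (default 200).
#' @param seed integer seed; the field is reproducible from it.
#' @return a `bg_env_field`.
#' @export
make_temperature_field <- function(grid, mask = make_land_mask(grid),
                                   T_south = -1, T_north = 17,
                                   noise_sd = 0.3, zonal_amp = 1,
                                   zonal_wavenumber = 3,
                                   front_weight = 0.8, front_sharpness = 40,
                                   front_frac = (8 - T_south) / (T_north - T_south),
                                   depth = 200, seed = 1) {
  stopifnot(T_south < T_north, front_weight >= 0, front_weight < 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cc <- cell_centers(grid)
  u <- (cc$lat - grid$lat_min) / (grid$lat_max - grid$lat_min)
  vals <- T_south + (T_north - T_south) *
    lat_profile(u, front_weight, front_sharpness, front_frac) +
    zonal_amp * sin(zonal_wavenumber * cc$lon * pi / 180)
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, stats::rnorm(grid$n_cells, 0, noise_sd))
  f <- env_field(grid, vals, mask, "temperature", depth)
  f$profile <- list(T_south = T_south, T_north = T_north,
                    front_weight = front_weight,
                    front_sharpness = front_sharpness,
                    front_frac = front_frac)
  f
}

# Monotone unit profile: linear / logistic blend, g(0) = 0, g(1) = 1.
lat_profile <- function(u, w, s, u0) {
  if (w == 0 || s == 0) return(u)
  sig <- function(x) 1 / (1 + exp(-s * (x - u0)))
  (1 - w) * u + w * (sig(u) - sig(0)) / (sig(1) - sig(0))
}

#' Isotherm latitude of the latitudinal temperature profile
#'
#' Inverts the (strictly monotone) noise-free, zonally averaged latitudinal
#' profile of [make_temperature_field()]: the latitude at which it equals
#' `temp`. Closed-form for the linear profile, numeric root otherwise.
#'
#' @param grid a `bg_grid`.
#' @param temp isotherm temperature (degC).
#' @param T_south,T_north,front_weight,front_sharpness,front_frac profile
#'   parameters as in [make_temperature_field()].
#' @return latitude in degrees.
#' @export
isotherm_latitude <- function(grid, temp, T_south = -1, T_north = 17,
                              front_weight = 0.8, front_sharpness = 40,
                              front_frac = (8 - T_south) / (T_north - T_south)) {
  target <- (temp - T_south) / (T_north - T_south)
  if (front_weight == 0)
    return(grid$lat_min + target * (grid$lat_max - grid$lat_min))
  u <- stats::uniroot(function(x)
    lat_profile(x, front_weight, front_sharpness, front_frac) - target,
    c(0, 1), tol = 1e-10)$root
  grid$lat_min + u * (grid$lat_max - grid$lat_min)
}

#' Spatially heterogeneous sampling-effort field
#'
#' Uniform background effort plus Gaussian hotspots at seeded random centres,
#' capped at 1, mimicking survey effort concentrated near accessible areas.
#'
#' @param grid a `bg_grid`.
#' @param mask ocean mask.
#' @param background baseline effort in `[0, 1]` (default 0.3).
#' @param n_hotspots number of hotspots (default 25).
#' @param hotspot_sd hotspot radius parameter in degrees (default 5).
#' @param hotspot_amp peak added effort per hotspot (default 0.8).
#' @param seed integer seed.
#' @return numeric vector of per-cell effort in `[0, 1]` (NA on land).
#' @export
make_effort_field <- function(grid, mask = make_land_mask(grid),
                              background = 0.3, n_hotspots = 40,
                              hotspot_sd = 5, hotspot_amp = 0.7, seed = 1) {
  stopifnot(background >= 0, background <= 1)
  cc <- cell_centers(grid)
  eff <- rep(background, grid$n_cells)
  if (n_hotspots > 0) {
    centers <- with_seed(seed, data.frame(
      lon = stats::runif(n_hotspots, grid$lon_min, grid$lon_max),
      lat = stats::runif(n_hotspots, grid$lat_min, grid$lat_max)))
    for (i in seq_len(n_hotspots)) {
      dlon <- abs(cc$lon - centers$lon[i])
      dlon <- pmin(dlon, 360 - dlon)          # zonal wrap-around
      d2 <- dlon^2 + (cc$lat - centers$lat[i])^2
      eff <- eff + hotspot_amp * exp(-d2 / (2 * hotspot_sd^2))
    }
  }
  eff <- pmin(eff, 1)
  eff[!mask] <- NA_real_
  eff
}

#' Per-GCM historical/future field pairs with additive warming anomalies
#'
#' Each pseudo-GCM gets a scalar warming anomaly drawn from
#' `Normal(mean_warming, gcm_sd)`, optionally plus a latitudinal gradient term,
#' added uniformly to its historical field. Historical fields differ from the
#' observed baseline by a fixed offset (`hist_offset`) so that downstream delta
#' bias correction is actually exercised rather than trivially inert.
#'
#' @param grid a `bg_grid`.
#' @param baseline a `bg_env_field`, the observed baseline.
#' @param n_gcms number of pseudo-GCMs (default 10).
#' @param mean_warming mean anomaly in degC (default 2).
#' @param gcm_sd inter-model s.d. of the anomaly in degC (default 0.5).
#' @param lat_gradient optional anomaly gradient in degC per degree latitude
#'   about the grid mid-latitude (default 0).
#' @param hist_offset constant offset (degC) between each GCM's historical
#'   field and the baseline (default 0.5).
#' @param seed integer seed.
#' @return list of length `n_gcms`; each element has `hist` and `future`
#'   (`bg_env_field`s) and the scalar `anomaly` drawn for that GCM.
#' @export
make_future_anomalies <- function(grid, baseline, n_gcms = 10,
                                  mean_warming = 2, gcm_sd = 0.5,
                                  lat_gradient = 0, hist_offset = 0.5,
                                  seed = 1) {
  stopifnot(inherits(baseline, "bg_env_field"), n_gcms >= 1, gcm_sd >= 0)
  anomalies <- with_seed(seed, stats::rnorm(n_gcms, mean_warming, gcm_sd))
  cc <- cell_centers(grid)
  lat_term <- lat_gradient * (cc$lat - mean(c(grid$lat_min, grid$lat_max)))
  lapply(seq_len(n_gcms), function(g) {
    hist_vals <- baseline$values + hist_offset
    fut_vals <- hist_vals + anomalies[g] + lat_term
    list(
      gcm = sprintf("gcm%02d", g),
      anomaly = anomalies[g],
      hist = env_field(grid, hist_vals, baseline$mask, baseline$variable,
                       baseline$depth),
      future = env_field(grid, fut_vals, baseline$mask, baseline$variable,
                         baseline$depth))
  })
}

#' Write an environmental field as long-format CSV
#'
#' Columns `lon`, `lat`, `depth`, `variable`, `value`; masked cells omitted.
#' A sidecar `<path>.meta.json`-style text file records provenance parameters.
#'
#' @param field a `bg_env_field`.
#' @param path output CSV path.
#' @param meta optional named list recorded in the sidecar file.
#' @return `path`, invisibly.
#' @export
write_env_csv <- function(field, path, meta = list()) {
  cc <- cell_centers(field$grid)
  keep <- field$mask
  df <- data.frame(lon = cc$lon[keep], lat = cc$lat[keep],
                   depth = field$depth, variable = field$variable,
                   value = field$values[keep])
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, c(list(variable = field$variable, depth = field$depth),
                        meta))
  invisible(path)
}

#' Read a long-format environmental CSV back onto a grid
#' @param path CSV written by [write_env_csv()].
#' @param grid the `bg_grid` the field lives on.
#' @return a `bg_env_field`.
#' @export
read_env_csv <- function(path, grid) {
  df <- utils::read.csv(path)
  vals <- rep(NA_real_, grid$n_cells)
  vals[cell_of(grid, df$lon, df$lat)] <- df$value
  env_field(grid, vals, !is.na(vals), df$variable[1], df$depth[1])
}

# Sidecar metadata: plain key=value lines next to a data file.
write_sidecar <- function(path, meta) {
  if (!length(meta)) return(invisible(NULL))
  lines <- vapply(names(meta), function(k)
    paste0(k, "=", paste(format(meta[[k]]), collapse = ",")), character(1))
  writeLines(lines, paste0(path, ".meta"))
  invisible(NULL)
}
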