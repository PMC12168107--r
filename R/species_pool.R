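#' Synthetic species pool with Gaussian thermal niches
#'
#' Plants the community structure the regionalisation analysis assumes: two
#' thermal guilds whose optima sit on either side of a climatic barrier, a
#' handful of widespread species whose broad niches straddle the barrier, and
#' small localised groups confined to narrow longitude windows near the
#' barrier temperature (the seed of minor clusters).
#'
#' @param n_south,n_subtrop numbers of cold-guild and warm-guild species
#'   (defaults 30 each).
#' @param n_widespread number of broad-niche transition species (default 5).
#' @param n_local number of localised species (default 5), split across two
#'   longitude windows.
#' @param barrier_temp barrier temperature in degC (default 8).
#' @param margin minimum distance (degC) of guild optima from the barrier
#'   (default 2.5).
#' @param seed integer seed; pools are deterministic per seed.
#' @return data.frame with one row per species: `species_id`, `guild`,
#'   `thermal_optimum` (degC), `niche_breadth` (degC, Gaussian s.d.),
#'   `max_occupancy`, `lon_min`/`lon_max` (local species only, NA otherwise).
#' @export
make_species_pool <- function(n_south = 30, n_subtrop = 30, n_widespread = 5,
                              n_local = 5, barrier_temp = 8, margin = 2.5,
                              seed = 1) {
  stopifnot(n_south >= 0, n_subtrop >= 0, n_widespread >= 0, n_local >= 0)
  if (n_south + n_subtrop < 2) stop("need at least 2 guild species")
  with_seed(seed, {
    # guild optima are evenly spaced with jitter (limiting-similarity niche
    # packing), so species richness has no gaps along the thermal gradient
    strat <- function(n, lo, hi) {
      step <- (hi - lo) / n
      sort(lo + (seq_len(n) - 0.5) * step + stats::runif(n, -step / 2, step / 2))
    }
    rows <- list()
    if (n_south > 0)
      rows$south <- data.frame(
        species_id = sprintf("south_%02d", seq_len(n_south)), guild = "south",
        thermal_optimum = strat(n_south, barrier_temp - 8.5, barrier_temp - margin),
        niche_breadth = stats::runif(n_south, 1.6, 2.25),
        max_occupancy = stats::runif(n_south, 0.75, 1),
        lon_min = NA_real_, lon_max = NA_real_)
    if (n_subtrop > 0)
      rows$subtrop <- data.frame(
        species_id = sprintf("subtrop_%02d", seq_len(n_subtrop)), guild = "subtrop",
        thermal_optimum = strat(n_subtrop, barrier_temp + margin, barrier_temp + 7.5),
        niche_breadth = stats::runif(n_subtrop, 1.6, 2.25),
        max_occupancy = stats::runif(n_subtrop, 0.75, 1),
        lon_min = NA_real_, lon_max = NA_real_)
    if (n_widespread > 0)
      rows$widespread <- data.frame(
        species_id = sprintf("wide_%02d", seq_len(n_widespread)), guild = "widespread",
        thermal_optimum = barrier_temp + stats::runif(n_widespread, -1, 1),
        niche_breadth = stats::runif(n_widespread, 4, 6),
        max_occupancy = 0.004,
        lon_min = NA_real_, lon_max = NA_real_)
    if (n_local > 0) {
      base <- stats::runif(2, -160, 120)  # two community windows, 8 deg wide
      w <- base[(seq_len(n_local) - 1) %% 2 + 1]
      rows$local <- data.frame(
        species_id = sprintf("local_%02d", seq_len(n_local)), guild = "local",
        thermal_optimum = barrier_temp + stats::runif(n_local, -0.5, 0.5),
        niche_breadth = 0.75,
        max_occupancy = 1,
        lon_min = w, lon_max = w + 8)
    }
    pool <- do.call(rbind, rows)
    rownames(pool) <- NULL
    attr(pool, "barrier_temp") <- barrier_temp
    pool
  })
}

#' Gaussian occupancy probability of a species at a temperature
#'
#' \eqn{p = p_{max} \exp(-(T - \mu)^2 / (2\sigma^2))} with optimum \eqn{\mu}
#' and niche breadth \eqn{\sigma}.
#'
#' @param species one row of a species pool (list or 1-row data.frame).
#' @param temp temperature(s) in degC.
#' @return occupancy probabilities in `[0, 1]`.
#' @export
occupancy_probability <- function(species, temp) {
  species$max_occupancy *
    exp(-(temp - species$thermal_optimum)^2 / (2 * species$niche_breadth^2))
}

#' Simulate occurrence records from a species pool
#'
#' Detection in a cell is Bernoulli with probability
#' `occupancy * effort`; each detected (species, cell) pair yields one or more
#' records (duplication mimics protocol-driven resampling), dated uniformly
#' within 1950-2019 and the austral spring/summer months (Oct-Mar).
#' A truth table of guilds and barrier-side cell regions is emitted alongside.
#'
#' @param pool species pool from [make_species_pool()].
#' @param env a `bg_env_field` (temperature at the reference depth).
#' @param effort per-cell sampling effort in `[0, 1]` (NA on land), e.g. from
#'   [make_effort_field()].
#' @param seed integer seed.
#' @param barrier_temp barrier used for the truth regions; defaults to the
#'   pool's planted barrier.
#' @return list with `records` (data.frame: `species`, `decimalLongitude`,
#'   `decimalLatitude`, `year`, `month`) and `truth` (list: `species` guild
#'   table, `cells` with `true_region` per ocean cell, `barrier_temp`).
#' @export
simulate_occurrences <- function(pool, env, effort, seed = 1,
                                 barrier_temp = attr(pool, "barrier_temp")) {
  if (is.null(pool) || nrow(pool) == 0) stop("species pool is empty")
  stopifnot(inherits(env, "bg_env_field"))
  eff <- effort
  eff[is.na(eff)] <- 0
  if (any(eff < 0 | eff > 1)) stop("effort must lie in [0, 1]")
  grid <- env$grid
  cc <- cell_centers(grid)
  temp <- env$values
  ocean <- which(env$mask & !is.na(temp))
  months <- c(10, 11, 12, 1, 2, 3)
  with_seed(seed, {
    recs <- vector("list", nrow(pool))
    for (i in seq_len(nrow(pool))) {
      sp <- pool[i, ]
      p <- occupancy_probability(sp, temp[ocean])
      if (!is.na(sp$lon_min)) {
        inwin <- cc$lon[ocean] >= sp$lon_min & cc$lon[ocean] < sp$lon_max
        p[!inwin] <- 0
      }
      hit <- ocean[stats::runif(length(ocean)) < p * eff[ocean]]
      if (!length(hit)) next
      nrec <- 1 + stats::rpois(length(hit), 0.7)
      cell <- rep(hit, nrec)
      recs[[i]] <- data.frame(
        species = sp$species_id,
        decimalLongitude = cc$lon[cell],
        decimalLatitude = cc$lat[cell],
        year = sample(1950:2019, length(cell), replace = TRUE),
        month = sample(months, length(cell), replace = TRUE))
    }
    records <- do.call(rbind, recs)
    if (is.null(records))
      records <- data.frame(species = character(), decimalLongitude = numeric(),
                            decimalLatitude = numeric(), year = integer(),
                            month = integer())
    truth <- list(
      species = data.frame(species_id = pool$species_id, guild = pool$guild),
      cells = data.frame(
        cell = ocean,
        true_region = ifelse(temp[ocean] < barrier_temp, "south", "subtrop")),
      barrier_temp = barrier_temp)
    list(records = records, truth = truth)
  })
}

#' Expected occurrence field of a species (no sampling noise)
#'
#' The per-cell expected detection probability `occupancy * effort`; useful
#' for asserting planted structure on expectations rather than realisations.
#'
#' @inheritParams simulate_occurrences
#' @param species one row of the pool.
#' @return numeric vector over cells (0 on land).
#' @export
expected_occurrence_field <- function(species, env, effort) {
  p <- occupancy_probability(species, env$values)
  if (!is.na(species$lon_min)) {
    cc <- cell_centers(env$grid)
    p[cc$lon < species$lon_min | cc$lon >= species$lon_max] <- 0
  }
  p <- p * effort
  p[is.na(p)] <- 0
  p
}

#' Assemble the default synthetic study scene
#'
#' One call building the complete set of study conditions used throughout the
#' package's experiments: a 1-degree Southern Ocean grid (360 x 45 cells), a
#' baseline temperature field with an 8 degC barrier isotherm, a five-variable
#' environmental stack (temperature at three depths, two non-informative
#' variables), a 70-species pool (30 + 30 guild species, 5 widespread,
#' 5 localised), heterogeneous sampling effort, simulated occurrence records
#' with ground truth, and 10 pseudo-GCM warming anomaly pairs.
#'
#' @param seed master integer seed; all component seeds derive from it.
#' @param n_gcms number of pseudo-GCMs (default 10).
#' @param mean_warming mean warming in degC for the future scenario (default 2).
#' @param gcm_sd inter-model anomaly spread in degC (default 0.5).
#' @return list with `grid`, `mask`, `temp` (baseline field), `env_stack`
#'   (data.frame of per-cell predictor columns), `effort`, `pool`, `records`,
#'   `truth`, `gcms` and `barrier_temp`.
#' @export
make_default_scene <- function(seed = 42, n_gcms = 10, mean_warming = 2,
                               gcm_sd = 0.5) {
  seed <- as.integer(seed) %% 100000L
  grid <- make_grid(-180, 180, -75, -30, 1)
  mask <- make_land_mask(grid)
  temp <- make_temperature_field(grid, mask, seed = seed + 1L)
  effort <- make_effort_field(grid, mask, seed = seed + 2L)
  pool <- make_species_pool(seed = seed + 3L)
  occ <- simulate_occurrences(pool, temp, effort, seed = seed + 4L)
  env_stack <- with_seed(seed + 5L, {
    n <- grid$n_cells
    t200 <- temp$values
    data.frame(
      cell = seq_len(n),
      temp_200m = t200,
      temp_100m = 1.5 + 0.95 * t200 + stats::rnorm(n, 0, 0.8),
      temp_0m = 4 + 0.9 * t200 + stats::rnorm(n, 0, 1.6),
      sal_0m = 34 + 0.5 * sin(2 * cell_centers(grid)$lon * pi / 180) +
        stats::rnorm(n, 0, 0.3),
      oxy_200m = stats::rnorm(n, 250, 20))
  })
  env_stack[!mask, -1] <- NA
  gcms <- make_future_anomalies(grid, temp, n_gcms = n_gcms,
                                mean_warming = mean_warming, gcm_sd = gcm_sd,
                                seed = seed + 6L)
  list(grid = grid, mask = mask, temp = temp, env_stack = env_stack,
       effort = effort, pool = pool, records = occ$records, truth = occ$truth,
       gcms = gcms, barrier_temp = attr(pool, "barrier_temp"))
}

#' Write occurrence records as CSV with a metadata sidecar
#' @param records data.frame as returned by [simulate_occurrences()].
#' @param path output CSV path.
#' @param meta named list recorded in the sidecar (seed, parameters).
#' @return `path`, invisibly.
#' @export
write_occurrences_csv <- function(records, path, meta = list()) {
  utils::write.csv(records, path, row.names = FALSE)
  write_sidecar(path, meta)
  invisible(path)
}
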