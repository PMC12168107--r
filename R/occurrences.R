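#' Coordinate cleaning of occurrence records
#'
#' Applies the standard automated coordinate checks: exact duplicates, equal
#' longitude and latitude, (0, 0) coordinates, records outside the grid
#' extent, and records falling on land cells. Each record is charged to the
#' first rule it violates, in that order, so the report's removed counts plus
#' the retained count always equal the input count.
#'
#' @param records data.frame with `species`, `decimalLongitude`,
#'   `decimalLatitude` (and any other columns, preserved).
#' @param grid a `bg_grid`.
#' @param mask logical ocean mask over the grid (`TRUE` = ocean).
#' @return list with `records` (cleaned, plus a `cell` column) and `report`
#'   (data.frame of per-rule removed counts and the retained count).
#' @export
clean_coordinates <- function(records, grid, mask) {
  n <- nrow(records)
  lon <- records$decimalLongitude
  lat <- records$decimalLatitude
  dup <- duplicated(records)
  eq <- !dup & !is.na(lon) & !is.na(lat) & lon == lat & lon != 0
  zero <- !dup & !is.na(lon) & !is.na(lat) & lon == 0 & lat == 0
  cell <- cell_of(grid, lon, lat)
  out_ext <- !dup & !eq & !zero & is.na(cell)
  on_land <- !dup & !eq & !zero & !out_ext & !mask[cell]
  drop <- dup | eq | zero | out_ext | on_land
  kept <- records[!drop, , drop = FALSE]
  kept$cell <- cell[!drop]
  report <- data.frame(
    rule = c("duplicate", "equal_lon_lat", "zero_zero", "out_of_extent",
             "on_land", "retained"),
    n = c(sum(dup), sum(eq), sum(zero), sum(out_ext), sum(on_land),
          sum(!drop)))
  list(records = kept, report = report)
}

#' Temporal filtering of occurrence records
#'
#' Keeps records inside both the year window and the month set; records with
#' missing year or month are removed and counted separately.
#'
#' @param records data.frame with `year` and `month` columns.
#' @param years inclusive year window (default `c(1950, 2019)`).
#' @param months retained months (default October-March:
#'   `c(10, 11, 12, 1, 2, 3)`).
#' @return list with `records` and `report` (removed-by-rule counts).
#' @export
filter_temporal <- function(records, years = c(1950, 2019),
                            months = c(10, 11, 12, 1, 2, 3)) {
  missing <- is.na(records$year) | is.na(records$month)
  in_year <- !missing & records$year >= years[1] & records$year <= years[2]
  in_month <- !missing & records$month %in% months
  keep <- in_year & in_month
  report <- data.frame(
    rule = c("missing_date", "out_of_window", "retained"),
    n = c(sum(missing), sum(!missing & !keep), sum(keep)))
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Species retention rules
#'
#' A species is retained if it has at least `min_occ` in-area occurrences
#' (vagrant cut-off) OR if more than `endemic_frac` of its occurrences fall
#' inside the study area (endemism rule, protecting rare but endemic species
#' from the first rule). Occurrences are counted on cell-aggregated presences
#' (unique 1-degree cells), not raw records, removing protocol-driven record
#' duplication. Records north of `study_area_lat_max` count as out-of-area.
#'
#' @param records cleaned records (must carry `species`, coordinates).
#' @param study_area_lat_max northern limit of the study area in degrees
#'   (default -30; the area is everything south of it).
#' @param min_occ minimum in-area presence cells (default 10).
#' @param endemic_frac in-area fraction above which a species is kept
#'   regardless of `min_occ` (default 0.5, strict inequality).
#' @return data.frame per species: `species`, `n_in`, `n_total`, `retained`,
#'   `rule` (`"cutoff"`, `"endemic"` or `"dropped"`).
#' @export
select_species <- function(records, study_area_lat_max = -30, min_occ = 10,
                           endemic_frac = 0.5) {
  # aggregate to 1-degree bins globally so in- and out-of-area counts are
  # comparable presence-cell counts
  bin <- paste(floor(records$decimalLongitude), floor(records$decimalLatitude))
  in_area <- records$decimalLatitude < study_area_lat_max
  u <- !duplicated(data.frame(records$species, bin))
  sp <- records$species[u]
  ia <- in_area[u]
  n_in <- tapply(ia, sp, sum)
  n_tot <- tapply(ia, sp, length)
  species <- names(n_in)
  n_in <- as.integer(n_in)
  n_tot <- as.integer(n_tot)
  cutoff <- n_in >= min_occ
  endemic <- n_in / n_tot > endemic_frac
  data.frame(
    species = species, n_in = n_in, n_total = n_tot,
    retained = cutoff | endemic,
    rule = ifelse(cutoff, "cutoff", ifelse(endemic, "endemic", "dropped")))
}

#' Rasterise records into a binary species x cell presence matrix
#'
#' Multiple records of a species within one grid cell collapse to a single
#' presence. Only species in `keep_species` (e.g. those retained by
#' [select_species()]) and records inside the grid are used.
#'
#' @param records cleaned occurrence records.
#' @param grid a `bg_grid`.
#' @param keep_species character vector of species to keep (default: all).
#' @return a `bg_presence` object: sparse binary `Matrix` (species x cell,
#'   column names are cell ids of occupied cells only) with attribute
#'   `global_counts`, the per-species raw record count.
#' @export
rasterize_records <- function(records, grid, keep_species = NULL) {
  if (!is.null(keep_species))
    records <- records[records$species %in% keep_species, , drop = FALSE]
  cell <- if ("cell" %in% names(records)) records$cell else
    cell_of(grid, records$decimalLongitude, records$decimalLatitude)
  ok <- !is.na(cell)
  records <- records[ok, , drop = FALSE]
  cell <- cell[ok]
  if (!nrow(records)) stop("no records to rasterise")
  sp <- factor(records$species)
  cells_used <- sort(unique(cell))
  ci <- match(cell, cells_used)
  pm <- Matrix::sparseMatrix(
    i = as.integer(sp), j = ci, x = 1,
    dims = c(nlevels(sp), length(cells_used)),
    dimnames = list(levels(sp), as.character(cells_used)))
  pm <- Matrix::drop0(pm)
  pm@x[] <- 1  # duplicate records within a cell collapse to a single presence
  attr(pm, "grid") <- grid
  attr(pm, "global_counts") <- table(records$species)
  pm
}

#' Cell ids of a presence matrix
#' @param pm presence matrix from [rasterize_records()].
#' @return integer cell ids corresponding to the matrix columns.
#' @export
presence_cells <- function(pm) as.integer(colnames(pm))
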