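#' Delta (anomaly) bias correction of a climate field
#'
#' Adds each model's projected change to the observed baseline instead of
#' using its absolute outputs: `corrected = baseline + (future - hist)` per
#' cell. The corrected field therefore keeps the baseline's spatial anomalies
#' exactly; a zero-anomaly model returns the baseline unchanged.
#'
#' @param baseline,gcm_hist,gcm_future `bg_env_field`s on the same grid.
#' @return a `bg_env_field` with corrected values.
#' @export
delta_correct <- function(baseline, gcm_hist, gcm_future) {
  g <- baseline$grid
  if (!identical(unclass(g), unclass(gcm_hist$grid)) ||
      !identical(unclass(g), unclass(gcm_future$grid)))
    stop("all three fields must share the grid")
  env_field(g, baseline$values + (gcm_future$values - gcm_hist$values),
            baseline$mask, baseline$variable, baseline$depth)
}

#' Project an ensemble over one or more climate fields
#'
#' Every accepted member is projected onto each supplied environmental stack
#' (one stack for the baseline; one per pseudo-GCM for a future scenario).
#' The per-cell mean and standard deviation are taken over all member x GCM
#' predictions pooled together, and the full run-level matrix is retained for
#' run-wise area statistics.
#'
#' @param members list of accepted `bg_member`s (e.g. the accepted subset of
#'   an ensemble).
#' @param env_stacks a single data.frame of per-cell predictors (with `cell`)
#'   or a list of such data.frames, one per GCM.
#' @return a `bg_prediction`: `cell`, `mean`, `sd` (vectors over the stack's
#'   cells), `runs` (matrix cells x runs), `run_meta` (data.frame `member`,
#'   `gcm`), `n_runs`.
#' @export
project_ensemble <- function(members, env_stacks) {
  if (!length(members)) stop("no accepted members to project")
  if (is.data.frame(env_stacks)) env_stacks <- list(env_stacks)
  cells <- env_stacks[[1]]$cell
  vars <- members[[1]]$vars
  runs <- list()
  meta <- list()
  for (g in seq_along(env_stacks)) {
    nd <- env_stacks[[g]]
    ok <- stats::complete.cases(nd[, vars, drop = FALSE])
    for (i in seq_along(members)) {
      p <- rep(NA_real_, length(cells))
      p[ok] <- members[[i]]$predict(nd[ok, , drop = FALSE])
      runs[[length(runs) + 1]] <- p
      meta[[length(meta) + 1]] <- data.frame(member = i, gcm = g)
    }
  }
  runs <- do.call(cbind, runs)
  structure(list(cell = cells,
                 mean = rowMeans(runs),
                 sd = apply(runs, 1, stats::sd),
                 runs = runs,
                 run_meta = do.call(rbind, meta),
                 n_runs = ncol(runs)),
            class = "bg_prediction")
}

#' @export
print.bg_prediction <- function(x, ...) {
  cat(sprintf("<bg_prediction> %d cells x %d runs, mean prob %.3f\n",
              length(x$cell), x$n_runs, mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' Hard classification of cells to regions
#'
#' Each cell is assigned to the region with the highest ensemble-mean
#' probability, with a confidence equal to that winning probability. Exact
#' ties are flagged as transition cells and left unassigned.
#'
#' @param predictions named list of `bg_prediction`s (one per region, on the
#'   same cells).
#' @return data.frame: `cell`, `region` (name, NA on ties/undefined),
#'   `confidence`, `tie`.
#' @export
classify_cells <- function(predictions) {
  if (length(predictions) < 2)
    stop("need predictions for at least 2 regions")
  cells <- predictions[[1]]$cell
  pm <- vapply(predictions, function(p) p$mean, numeric(length(cells)))
  top <- apply(pm, 1, function(r) {
    if (all(is.na(r))) return(c(NA, NA, NA))
    w <- which(r == max(r, na.rm = TRUE))
    c(if (length(w) > 1) NA else w[1], max(r, na.rm = TRUE),
      as.integer(length(w) > 1))
  })
  data.frame(cell = cells,
             region = names(predictions)[top[1, ]],
             confidence = top[2, ],
             tie = !is.na(top[3, ]) & top[3, ] == 1)
}

#' Normalised transition (entropy) index
#'
#' For per-region occurrence probabilities \eqn{p_i} with \eqn{P = \sum p_i},
#' \eqn{TI = -\sum_i (p_i/P) \log(p_i/P)} (natural log, with
#' \eqn{0 \log 0 = 0}), normalised by its simplex maximum \eqn{\log N} so the
#' index lies in `[0, 1]`: 1 where all regions are equally probable, 0 where a
#' single region dominates. Cells with \eqn{P = 0} are undefined (`NA`).
#' Scaling all probabilities by a positive constant leaves the index
#' unchanged, since only the shares \eqn{p_i/P} enter.
#'
#' @param p numeric vector of length N (one cell) or matrix cells x N.
#' @return normalised index in `[0, 1]` (vector over cells).
#' @export
transition_index <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (any(p < 0, na.rm = TRUE)) stop("probabilities must be non-negative")
  N <- ncol(p)
  if (N < 2) stop("need at least 2 regions")
  P <- rowSums(p)
  sh <- p / P
  ti <- -rowSums(ifelse(sh > 0, sh * log(sh), 0)) / log(N)
  ti[!is.finite(P) | P == 0] <- NA_real_
  ti
}

#' Transition-zone map from region predictions
#'
#' @param predictions named list of `bg_prediction`s (one per region).
#' @return data.frame `cell`, `ti` (normalised transition index, NA where all
#'   region probabilities are zero or undefined).
#' @export
transition_map <- function(predictions) {
  cells <- predictions[[1]]$cell
  pm <- vapply(predictions, function(p) p$mean, numeric(length(cells)))
  ti <- rep(NA_real_, length(cells))
  ok <- stats::complete.cases(pm)
  ti[ok] <- transition_index(pm[ok, , drop = FALSE])
  data.frame(cell = cells, ti = ti)
}

#' Equal-area gains and losses across occurrence-probability classes
#'
#' For each probability class (default: very low `[0, 0.2]` to very high
#' `(0.8, 1]`), the change in area between the future and present
#' distributions. Areas are computed per run (per member for the present, per
#' member x GCM for the future) from the spherical cell areas; each future
#' run is paired with its member's present run and the paired per-run area
#' differences are tested: Shapiro-Wilk at `alpha` decides between a paired
#' t-test (normality not rejected) and a sign test on the medians.
#'
#' @param present,future `bg_prediction`s for the same region and cells.
#' @param areas per-cell areas in km^2 over the full grid (see
#'   [cell_areas()]).
#' @param breaks class boundaries (default `c(0, 0.2, 0.4, 0.6, 0.8, 1)`);
#'   classes are `(lo, hi]` with the first including 0.
#' @param alpha significance level (default 0.05).
#' @return data.frame per class: `class`, `lo`, `hi`, `area_present`,
#'   `area_future`, `delta`, `sd_present`, `sd_future`, `test`, `p_value`,
#'   `significant`.
#' @export
area_change <- function(present, future, areas,
                        breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1), alpha = 0.05) {
  stopifnot(identical(present$cell, future$cell))
  a <- areas[present$cell]
  class_area <- function(runs) {
    # rows: classes, cols: runs
    out <- vapply(seq_len(ncol(runs)), function(j) {
      cl <- cut(runs[, j], breaks, include.lowest = TRUE)
      as.numeric(tapply(a, cl, sum, default = 0))
    }, numeric(length(breaks) - 1))
    matrix(out, nrow = length(breaks) - 1)
  }
  ap <- class_area(present$runs)
  af <- class_area(future$runs)
  member_of_future <- future$run_meta$member
  rows <- lapply(seq_len(length(breaks) - 1), function(c_i) {
    p_runs <- ap[c_i, ]
    f_runs <- af[c_i, ]
    d <- f_runs - p_runs[member_of_future]
    test <- NA_character_
    pv <- NA_real_
    if (length(d) >= 3 && stats::sd(d) > 0) {
      sw <- stats::shapiro.test(if (length(d) > 5000) d[seq_len(5000)] else d)
      if (sw$p.value > alpha) {
        test <- "paired t"
        pv <- stats::t.test(d)$p.value
      } else {
        test <- "sign"
        nz <- d[d != 0]
        pv <- if (length(nz)) stats::binom.test(sum(nz > 0), length(nz))$p.value
          else 1
      }
    }
    data.frame(
      class = sprintf("(%.1f, %.1f]", breaks[c_i], breaks[c_i + 1]),
      lo = breaks[c_i], hi = breaks[c_i + 1],
      area_present = mean(p_runs), area_future = mean(f_runs),
      delta = mean(f_runs) - mean(p_runs),
      sd_present = stats::sd(p_runs), sd_future = stats::sd(f_runs),
      test = test, p_value = pv,
      significant = !is.na(pv) & pv < alpha)
  })
  do.call(rbind, rows)
}

#' Transition-zone area change by longitude sector
#'
#' The transition zone is the set of cells whose normalised transition index
#' is at least `ti_threshold`. Reports the present and future zone area and
#' their difference per longitude sector, plus the area-weighted mean
#' latitude of the zone in each period (a poleward shift shows up as a more
#' negative future mean latitude in a southern-hemisphere domain).
#'
#' @param ti_present,ti_future transition maps from [transition_map()] on the
#'   same cells.
#' @param areas per-cell areas (full grid).
#' @param grid the `bg_grid`.
#' @param ti_threshold zone membership threshold (default 0.9).
#' @param sector_breaks longitude sector boundaries (default 90-degree
#'   sectors).
#' @return data.frame per sector: `lon_min`, `lon_max`, `area_present`,
#'   `area_future`, `delta`; attributes `mean_lat_present`,
#'   `mean_lat_future`.
#' @export
transition_zone_change <- function(ti_present, ti_future, areas, grid,
                                   ti_threshold = 0.9,
                                   sector_breaks = seq(-180, 180, by = 90)) {
  stopifnot(identical(ti_present$cell, ti_future$cell))
  cc <- cell_centers(grid)
  cells <- ti_present$cell
  lon <- cc$lon[cells]
  lat <- cc$lat[cells]
  a <- areas[cells]
  in_p <- !is.na(ti_present$ti) & ti_present$ti >= ti_threshold
  in_f <- !is.na(ti_future$ti) & ti_future$ti >= ti_threshold
  sec <- cut(lon, sector_breaks, include.lowest = TRUE)
  ap <- tapply(a * in_p, sec, sum, default = 0)
  af <- tapply(a * in_f, sec, sum, default = 0)
  out <- data.frame(
    lon_min = utils::head(sector_breaks, -1),
    lon_max = utils::tail(sector_breaks, -1),
    area_present = as.numeric(ap), area_future = as.numeric(af),
    delta = as.numeric(af - ap))
  attr(out, "mean_lat_present") <-
    if (any(in_p)) sum(lat[in_p] * a[in_p]) / sum(a[in_p]) else NA_real_
  attr(out, "mean_lat_future") <-
    if (any(in_f)) sum(lat[in_f] * a[in_f]) / sum(a[in_f]) else NA_real_
  out
}
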