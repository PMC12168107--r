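#' Build a presence-absence dataset for one region
#'
#' Presences are the cells assigned to the target region; absences are the
#' cells assigned to any other retained region (their species composition is
#' assumed sufficiently distinct). Unassigned cells never enter the dataset.
#' Regions with fewer than `min_presences` presences are flagged unmodellable.
#'
#' @param regions a `bg_regions` assignment.
#' @param region_id target region id.
#' @param env_stack data.frame of per-cell predictors with a `cell` column.
#' @param min_presences minimum presences required to model (default 30).
#' @return a `bg_pa` object: data.frame with `cell`, `response` (1/0),
#'   predictor columns, plus attributes `region_id` and `modellable`.
#' @export
build_pa <- function(regions, region_id, env_stack, min_presences = 30) {
  ra <- regions$cells
  assigned <- !is.na(ra$region)
  if (!any(assigned & ra$region == region_id))
    stop("region ", region_id, " has no assigned cells")
  keep <- assigned
  df <- data.frame(cell = ra$cell[keep],
                   response = as.integer(ra$region[keep] == region_id))
  df <- merge(df, env_stack, by = "cell", sort = TRUE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  attr(df, "region_id") <- region_id
  attr(df, "modellable") <- sum(df$response) >= min_presences
  class(df) <- c("bg_pa", "data.frame")
  df
}

#' Group collinear predictors and pick one representative per group
#'
#' Groups are the connected components of the graph joining variable pairs
#' with |Spearman rho| above the threshold. Constant variables (rho
#' undefined) are excluded with a warning. The representative of each group
#' is the variable with the highest univariate median importance across the
#' modelling techniques, from a preliminary single-variable fit round.
#'
#' @param pa a `bg_pa` dataset.
#' @param rho Spearman threshold (default 0.7, strict inequality).
#' @param techniques techniques used for the preliminary round (default all).
#' @param n_perm permutations for the importance estimate (default 10).
#' @param seed integer seed.
#' @return list with `groups` (list of character vectors), `representatives`
#'   (character vector, one per group) and `univariate_importance`
#'   (data.frame).
#' @export
collinearity_groups <- function(pa, rho = 0.7,
                                techniques = bg_techniques(), n_perm = 10,
                                seed = 1) {
  vars <- setdiff(names(pa), c("cell", "response"))
  if (length(vars) < 2) stop("need at least 2 candidate variables")
  x <- as.matrix(pa[vars])
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("excluding constant variables: ",
            paste(vars[const], collapse = ", "))
    vars <- vars[!const]
    x <- x[, vars, drop = FALSE]
  }
  cm <- stats::cor(x, method = "spearman")
  adj <- abs(cm) > rho
  # connected components by label propagation over the small variable graph
  comp <- seq_along(vars)
  repeat {
    old <- comp
    for (i in seq_along(vars)) comp[adj[i, ]] <- min(comp[adj[i, ] | seq_along(vars) == i])
    if (identical(old, comp)) break
  }
  groups <- split(vars, comp)
  names(groups) <- NULL
  imp <- univariate_importance(pa, vars, techniques, n_perm, seed)
  reps <- vapply(groups, function(g) {
    gi <- imp[match(g, imp$variable), ]
    # highest median importance; near-ties (within 0.01) broken by AUC
    top <- gi$median_importance >= max(gi$median_importance) - 0.01
    g[top][which.max(gi$median_auc[top])]
  }, character(1))
  list(groups = groups, representatives = reps, univariate_importance = imp)
}

# Preliminary round: per variable, fit each technique on that variable alone
# (on a row subsample for speed) and measure its permutation importance and
# discrimination (AUC). Importance saturates near 1 for any strong predictor,
# so ties in median importance are broken by AUC when picking representatives.
univariate_importance <- function(pa, vars, techniques, n_perm, seed,
                                  n_sub = 3000) {
  sub <- if (nrow(pa) > n_sub)
    pa[with_seed(seed, sample.int(nrow(pa), n_sub)), , drop = FALSE] else pa
  out <- lapply(seq_along(vars), function(i) {
    v <- vars[i]
    fits <- lapply(techniques, function(tech)
      tryCatch(fit_technique(tech, sub, v, seed = seed + i),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    imps <- vapply(fits, function(fit)
      permutation_importance(fit, sub, v, n_perm = n_perm,
                             seed = seed + i)$importance, numeric(1))
    aucs <- vapply(fits, function(fit)
      auc_rank(fit$predict(sub), sub$response), numeric(1))
    data.frame(variable = v,
               median_importance = stats::median(imps, na.rm = TRUE),
               median_auc = stats::median(aucs, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Permutation importance of a variable for a fitted model
#'
#' The variable's column is shuffled `n_perm` times; `r` is the mean Pearson
#' correlation between the model's original predictions and its predictions
#' on the shuffled data, and importance is `Imp = 1 - r`. A variable the
#' model ignores leaves predictions unchanged (r = 1, Imp = 0); shuffling a
#' strong predictor decorrelates them (Imp near 1 or above).
#'
#' @param member a fitted model member (from [fit_technique()]).
#' @param data dataset the model was fitted on.
#' @param variable variable name to shuffle.
#' @param n_perm number of permutations (default 10).
#' @param seed integer seed.
#' @return list with `variable`, `r` and `importance`.
#' @export
permutation_importance <- function(member, data, variable, n_perm = 10,
                                   seed = 1) {
  orig <- member$predict(data)
  if (stats::sd(orig) == 0) {
    warning("zero-variance predictions; importance defined as 0")
    return(list(variable = variable, r = 1, importance = 0))
  }
  rs <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    shuf <- data
    shuf[[variable]] <- sample(shuf[[variable]])
    pred <- member$predict(shuf)
    if (stats::sd(pred) == 0) return(1)
    stats::cor(orig, pred)
  }, numeric(1)))
  r <- mean(rs)
  list(variable = variable, r = r, importance = 1 - r)
}

#' Select predictors by median permutation importance
#'
#' After collinearity grouping, all techniques are fitted on the group
#' representatives jointly; variables whose median importance across
#' techniques exceeds `importance_min` are kept. As a mutual-exclusivity
#' check, the Pearson correlation between the kept variables' importance
#' vectors (across techniques) must never fall below `imp_anticorr`; if it
#' does, selection fails with a diagnostic.
#'
#' @param pa a `bg_pa` dataset.
#' @param rho collinearity threshold passed to [collinearity_groups()].
#' @param importance_min minimum median importance (default 0.10, strict).
#' @param imp_anticorr anti-correlation failure threshold (default -0.3).
#' @param techniques modelling techniques (default all five).
#' @param n_perm permutations per importance estimate (default 10).
#' @param seed integer seed.
#' @return list with `selected` (character vector), `importance` (data.frame
#'   variable x technique importances + medians) and `groups`.
#' @export
select_variables <- function(pa, rho = 0.7, importance_min = 0.10,
                             imp_anticorr = -0.3,
                             techniques = bg_techniques(), n_perm = 10,
                             seed = 1) {
  cg <- collinearity_groups(pa, rho, techniques, n_perm, seed)
  reps <- cg$representatives
  # importance round on a subsample; final models are fitted elsewhere
  sub <- if (nrow(pa) > 4000)
    pa[with_seed(seed, sample.int(nrow(pa), 4000)), , drop = FALSE] else pa
  fits <- lapply(techniques, function(tech)
    tryCatch(fit_technique(tech, sub, reps, seed = seed),
             error = function(e) NULL))
  names(fits) <- techniques
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no technique could be fitted for variable selection")
  imp <- sapply(reps, function(v)
    vapply(fits, function(f)
      permutation_importance(f, sub, v, n_perm, seed)$importance,
      numeric(1)))
  imp <- matrix(imp, nrow = length(fits),
                dimnames = list(names(fits), reps))
  med <- apply(imp, 2, stats::median)
  selected <- reps[med > importance_min]
  if (!length(selected))
    stop("no variable passes the median importance threshold (",
         importance_min, "); the region cannot be modelled. Medians: ",
         paste(sprintf("%s=%.3f", reps, med), collapse = ", "))
  if (length(selected) > 1) {
    ic <- stats::cor(imp[, selected, drop = FALSE])
    bad <- which(ic < imp_anticorr, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad))
      stop("importance vectors are negatively correlated (< ", imp_anticorr,
           ") for: ",
           paste(apply(bad, 1, function(b)
             paste(selected[b], collapse = " vs ")), collapse = "; "))
  }
  list(selected = unname(selected),
       importance = data.frame(variable = reps, t(imp),
                               median_importance = med, row.names = NULL),
       groups = cg)
}

#' Tile the grid into square spatial blocks
#'
#' Blocks are contiguous square latitude-longitude tiles of side `block_deg`.
#' With `block_deg = "auto"` the side is chosen as the lag distance at which
#' the Moran's I correlogram of the leading predictor first drops below 0.1,
#' i.e. the scale beyond which residual spatial autocorrelation is weak.
#'
#' @param grid a `bg_grid`.
#' @param block_deg block side in degrees, or `"auto"`.
#' @param env_values per-cell values of the leading predictor (required for
#'   `"auto"`).
#' @param max_lag largest lag examined for `"auto"` (default 30 degrees).
#' @param n_sample cells subsampled for the correlogram (default 1200).
#' @param seed integer seed for the subsample.
#' @return list with `block` (integer block id per grid cell) and
#'   `block_deg` (the side used).
#' @export
spatial_blocks <- function(grid, block_deg = "auto", env_values = NULL,
                           max_lag = 30, n_sample = 1200, seed = 1) {
  if (identical(block_deg, "auto")) {
    if (is.null(env_values))
      stop("env_values needed to choose the block size automatically")
    block_deg <- moran_block_size(grid, env_values, max_lag, n_sample, seed)
  }
  if (block_deg < grid$resolution)
    stop("block_deg must be at least the grid resolution")
  cc <- cell_centers(grid)
  bx <- floor((cc$lon - grid$lon_min) / block_deg)
  by <- floor((cc$lat - grid$lat_min) / block_deg)
  nbx <- max(bx) + 1
  list(block = as.integer(by * nbx + bx + 1), block_deg = block_deg)
}

# Moran's I correlogram on a seeded subsample of cells; returns the first lag
# (bin midpoint, degrees) at which I drops below 0.1, rounded up to a whole
# number of grid cells.
moran_block_size <- function(grid, env_values, max_lag = 30,
                             n_sample = 1200, seed = 1) {
  cc <- cell_centers(grid)
  ok <- which(!is.na(env_values))
  idx <- if (length(ok) > n_sample)
    with_seed(seed, sample(ok, n_sample)) else ok
  x <- env_values[idx] - mean(env_values[idx])
  lon <- cc$lon[idx]; lat <- cc$lat[idx]
  d <- sqrt(outer(lon, lon, "-")^2 + outer(lat, lat, "-")^2)
  binw <- 2
  mids <- seq(binw / 2, max_lag, by = binw)
  v <- mean(x^2)
  for (m in mids) {
    w <- d > m - binw / 2 & d <= m + binw / 2
    diag(w) <- FALSE
    if (!any(w)) next
    I <- sum(w * outer(x, x)) / sum(w) / v
    if (I < 0.1) return(max(grid$resolution, ceiling(m)))
  }
  max_lag
}

#' Assign spatial blocks to cross-validation folds with class balance
#'
#' Blocks are assigned to `k` folds at random, retrying until every fold's
#' presence and absence counts are within `tol` (relative) of `n/k`. If the
#' balance is unattainable in `max_tries` draws the best attempt is returned
#' with a warning.
#'
#' @param pa a `bg_pa` dataset.
#' @param blocks result of [spatial_blocks()] (or an integer block id per
#'   grid cell).
#' @param k number of folds (default 4).
#' @param tol relative tolerance on per-fold class counts (default 0.1).
#' @param max_tries maximum retry count (default 1000).
#' @param seed integer seed; folds are deterministic per seed.
#' @return a `bg_folds` data.frame: `cell`, `block`, `fold`.
#' @export
assign_folds <- function(pa, blocks, k = 4, tol = 0.1, max_tries = 1000,
                         seed = 1) {
  block <- if (is.list(blocks)) blocks$block else blocks
  b <- block[pa$cell]
  ub <- sort(unique(b))
  n_pres <- sum(pa$response == 1)
  n_abs <- sum(pa$response == 0)
  target_p <- n_pres / k
  target_a <- n_abs / k
  with_seed(seed, {
    best <- NULL
    best_dev <- Inf
    for (try in seq_len(max_tries)) {
      fb <- sample(rep_len(seq_len(k), length(ub)))
      fold <- fb[match(b, ub)]
      pc <- tabulate(fold[pa$response == 1], k)
      ac <- tabulate(fold[pa$response == 0], k)
      dev <- max(abs(pc - target_p) / target_p, abs(ac - target_a) / target_a)
      if (dev < best_dev) { best_dev <- dev; best <- fold }
      if (dev <= tol) break
    }
    if (best_dev > tol)
      warning(sprintf(
        "fold balance unattained in %d tries (worst relative deviation %.2f)",
        max_tries, best_dev))
    structure(data.frame(cell = pa$cell, block = b, fold = best),
              class = c("bg_folds", "data.frame"),
              balance_dev = best_dev, k = k)
  })
}

#' The five distribution-modelling technique families
#'
#' Family contracts rather than specific packages: a linear-logistic model
#' (GLM with quadratic terms), a smooth additive model (GAM), a feed-forward
#' neural network, a discriminant analysis, and adaptive regression splines
#' (hinge-basis logistic regression with stepwise pruning). Each returns
#' calibrated occurrence probabilities.
#'
#' @return character vector of technique names.
#' @export
bg_techniques <- function() c("glm", "gam", "ann", "fda", "mars")

#' Fit one modelling technique
#'
#' @param technique one of [bg_techniques()].
#' @param data training data with a `response` column (0/1).
#' @param vars predictor variable names.
#' @param seed integer seed (used by the stochastic techniques).
#' @return a `bg_member`: list with `technique`, `vars` and
#'   `predict(newdata)` returning probabilities in `[0, 1]`.
#' @export
fit_technique <- function(technique, data, vars, seed = 1) {
  y <- data$response
  if (length(unique(y)) < 2)
    stop("training response has a single class; cannot calibrate")
  x <- data[, vars, drop = FALSE]
  member <- switch(
    technique,
    glm = {
      form <- stats::as.formula(paste(
        "y ~", paste(sprintf("%s + I(%s^2)", vars, vars), collapse = " + ")))
      fit <- stats::glm(form, data = cbind(y = y, x), family = stats::binomial())
      list(predict = function(nd)
        as.numeric(stats::predict(fit, newdata = nd, type = "response")))
    },
    gam = {
      ks <- vapply(vars, function(v) min(5, length(unique(x[[v]])) - 1),
                   numeric(1))
      form <- stats::as.formula(paste(
        "y ~", paste(sprintf("s(%s, k = %d)", vars, ks), collapse = " + ")))
      fit <- mgcv::gam(form, data = cbind(y = y, x),
                       family = stats::binomial(), method = "REML")
      list(predict = function(nd)
        as.numeric(stats::predict(fit, newdata = nd, type = "response")))
    },
    ann = {
      ctr <- vapply(x, mean, numeric(1))
      scl <- vapply(x, stats::sd, numeric(1))
      scl[scl == 0] <- 1
      xs <- scale(as.matrix(x), ctr, scl)
      fit <- with_seed(seed,
                       nnet::nnet(xs, y, size = 4, decay = 0.01, maxit = 300,
                                  entropy = TRUE, trace = FALSE))
      list(predict = function(nd) {
        nds <- scale(as.matrix(nd[, vars, drop = FALSE]), ctr, scl)
        as.numeric(stats::predict(fit, nds))
      })
    },
    fda = {
      fit <- tryCatch(MASS::qda(x, grouping = factor(y)),
                      error = function(e) MASS::lda(x, grouping = factor(y)))
      list(predict = function(nd)
        as.numeric(stats::predict(fit, nd[, vars, drop = FALSE])$posterior[, "1"]))
    },
    mars = fit_hinge_splines(y, x, vars),
    stop("unknown technique: ", technique))
  structure(c(list(technique = technique, vars = vars), member),
            class = "bg_member")
}

# Adaptive regression splines: logistic regression on a hinge basis
# max(0, x - k) / max(0, k - x) with knots at deciles of each predictor,
# backward-pruned by AIC. Piecewise-linear, data-adaptive response shapes.
fit_hinge_splines <- function(y, x, vars) {
  basis_spec <- lapply(vars, function(v) {
    kn <- unique(stats::quantile(x[[v]], seq(0.1, 0.9, 0.2), names = FALSE))
    kn
  })
  names(basis_spec) <- vars
  mk_basis <- function(df) {
    cols <- list()
    for (v in vars) {
      cols[[paste0(v, "_lin")]] <- df[[v]]
      for (j in seq_along(basis_spec[[v]])) {
        k <- basis_spec[[v]][j]
        cols[[sprintf("%s_h%d", v, j)]] <- pmax(0, df[[v]] - k)
      }
    }
    as.data.frame(cols)
  }
  bx <- mk_basis(x)
  dat <- cbind(y = y, bx)
  full <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  pruned <- tryCatch(
    suppressWarnings(stats::step(full, direction = "backward", trace = 0)),
    error = function(e) full)
  list(predict = function(nd) {
    p <- as.numeric(stats::predict(pruned, newdata = mk_basis(nd),
                                   type = "response"))
    pmin(pmax(p, 0), 1)
  })
}

#' Fit the cross-validated technique ensemble for one region
#'
#' For each fold, each technique is fitted on the remaining folds, yielding
#' `length(techniques) * k` members (20 under the defaults). Members whose
#' fit fails are recorded and excluded.
#'
#' @param pa a `bg_pa` dataset (must be modellable).
#' @param folds a `bg_folds` assignment.
#' @param vars predictor names (e.g. from [select_variables()]).
#' @param techniques technique names (default all five).
#' @param seed integer seed.
#' @return a `bg_ensemble`: `members` (list of fitted `bg_member`s with
#'   `fold` set), `failed` (data.frame of failures), `k`, `techniques`,
#'   `region_id`.
#' @export
fit_region_models <- function(pa, folds, vars,
                              techniques = bg_techniques(), seed = 1) {
  if (!attr(pa, "modellable"))
    stop("region has fewer presences than the modelling minimum")
  k <- attr(folds, "k")
  members <- list()
  failed <- list()
  for (f in seq_len(k)) {
    train <- pa[folds$fold != f, , drop = FALSE]
    for (tech in techniques) {
      m <- tryCatch(
        fit_technique(tech, train, vars, seed = seed + 13L * f),
        error = function(e) e)
      if (inherits(m, "error")) {
        failed[[length(failed) + 1]] <- data.frame(
          technique = tech, fold = f, error = conditionMessage(m))
      } else {
        m$fold <- f
        members[[length(members) + 1]] <- m
      }
    }
  }
  structure(list(
    members = members,
    failed = if (length(failed)) do.call(rbind, failed) else
      data.frame(technique = character(), fold = integer(),
                 error = character()),
    k = k, techniques = techniques,
    region_id = attr(pa, "region_id")),
    class = "bg_ensemble")
}

#' @export
print.bg_ensemble <- function(x, ...) {
  cat(sprintf("<bg_ensemble> region %s: %d members (%d failed)\n",
              x$region_id, length(x$members), nrow(x$failed)))
  invisible(x)
}

#' Jaccard similarity of a confusion table
#'
#' `J = TP / (TP + FP + FN)`: agreement between predicted and observed
#' presences, independent of true negatives and hence of prevalence.
#'
#' @param tp,fp,fn confusion counts.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(tp, fp, fn) tp / (tp + fp + fn)

# Rank (Mann-Whitney) AUC.
auc_rank <- function(pred, obs) {
  n1 <- sum(obs == 1)
  n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(pred)
  (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate ensemble members on their held-out folds
#'
#' For each member, predictions on its calibration folds choose the
#' binarisation threshold maximising the Jaccard index there; the member is
#' then scored on its held-out fold (confusion counts, Jaccard, AUC) and
#' accepted iff `J >= jaccard_min`. Members whose held-out fold has no
#' presences are unevaluable and rejected with a reason.
#'
#' @param ensemble a `bg_ensemble`.
#' @param pa the `bg_pa` dataset.
#' @param folds the `bg_folds` used for fitting.
#' @param jaccard_min acceptance threshold (default 0.5; `J = 0.5` is
#'   accepted).
#' @param thresholds candidate binarisation thresholds.
#' @return data.frame, one row per member: `technique`, `fold`, `threshold`,
#'   `TP`, `FP`, `FN`, `TN`, `jaccard`, `auc`, `accepted`, `reason`.
#' @export
evaluate_models <- function(ensemble, pa, folds, jaccard_min = 0.5,
                            thresholds = seq(0.01, 0.99, by = 0.01)) {
  rows <- lapply(ensemble$members, function(m) {
    hold <- folds$fold == m$fold
    if (!any(pa$response[hold] == 1))
      return(data.frame(technique = m$technique, fold = m$fold,
                        threshold = NA, TP = NA, FP = NA, FN = NA, TN = NA,
                        jaccard = NA, auc = NA, accepted = FALSE,
                        reason = "no presences in held-out fold"))
    calib_pred <- m$predict(pa[!hold, , drop = FALSE])
    calib_obs <- pa$response[!hold]
    js <- vapply(thresholds, function(t) {
      p <- calib_pred >= t
      jaccard_index(sum(p & calib_obs == 1), sum(p & calib_obs == 0),
                    sum(!p & calib_obs == 1))
    }, numeric(1))
    thr <- thresholds[which.max(js)]
    pred <- m$predict(pa[hold, , drop = FALSE])
    obs <- pa$response[hold]
    p <- pred >= thr
    tp <- sum(p & obs == 1); fp <- sum(p & obs == 0)
    fn <- sum(!p & obs == 1); tn <- sum(!p & obs == 0)
    j <- jaccard_index(tp, fp, fn)
    data.frame(technique = m$technique, fold = m$fold, threshold = thr,
               TP = tp, FP = fp, FN = fn, TN = tn, jaccard = j,
               auc = auc_rank(pred, obs), accepted = j >= jaccard_min,
               reason = NA_character_)
  })
  do.call(rbind, rows)
}

#' Evaluation-strip response curves
#'
#' For each member and variable, predicted probability over a grid spanning
#' the observed range with all other variables held at their medians. A
#' response is ecologically plausible if, after a 5-point moving average, its
#' first differences change sign at most once (monotone or unimodal).
#'
#' @param ensemble a `bg_ensemble`.
#' @param pa the `bg_pa` dataset (defines observed ranges and medians).
#' @param n_points grid points per variable (default 100).
#' @return data.frame: `technique`, `fold`, `variable`, `value`,
#'   `probability`, `plausible`.
#' @export
response_curves <- function(ensemble, pa, n_points = 100) {
  vars <- ensemble$members[[1]]$vars
  meds <- vapply(pa[vars], stats::median, numeric(1))
  rows <- list()
  for (m in ensemble$members) {
    for (v in vars) {
      grid_v <- seq(min(pa[[v]]), max(pa[[v]]), length.out = n_points)
      nd <- as.data.frame(as.list(meds))[rep(1, n_points), , drop = FALSE]
      nd[[v]] <- grid_v
      p <- m$predict(nd)
      rows[[length(rows) + 1]] <- data.frame(
        technique = m$technique, fold = m$fold, variable = v,
        value = grid_v, probability = p,
        plausible = curve_plausible(p))
    }
  }
  do.call(rbind, rows)
}

# Plausibility rule: <= 1 sign change of the first difference after a 5-point
# moving average; tiny wiggles below 1e-6 are treated as flat.
curve_plausible <- function(p, tol = 1e-6) {
  sm <- stats::filter(p, rep(1 / 5, 5), sides = 2)
  sm <- sm[!is.na(sm)]
  d <- diff(sm)
  s <- sign(d)
  s[abs(d) < tol] <- 0
  s <- s[s != 0]
  if (length(s) < 2) return(TRUE)
  sum(diff(s) != 0) <= 1
}
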