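# Small planted presence-absence dataset: response driven by a logistic in
# x1, with a collinear copy and noise variables.
toy_pa <- function(n = 600, seed = 4) {
  set.seed(seed)
  x1 <- runif(n, -3, 3)
  df <- data.frame(
    cell = seq_len(n),
    response = rbinom(n, 1, plogis(3 * x1)),
    x1 = x1,
    x1_copy = x1 + rnorm(n, 0, 0.2),
    noise_a = rnorm(n),
    noise_b = rnorm(n))
  attr(df, "region_id") <- 1L
  attr(df, "modellable") <- TRUE
  class(df) <- c("bg_pa", "data.frame")
  df
}

toy_regions2 <- function(n1, n2, n_unassigned = 0) {
  n <- n1 + n2 + n_unassigned
  structure(list(
    cells = data.frame(cell = seq_len(n),
                       region = c(rep(1L, n1), rep(2L, n2),
                                  rep(NA_integer_, n_unassigned)),
                       reason = NA_character_),
    species = data.frame(species = character(), region = integer(),
                         reason = character()),
    region_sizes = c(`1` = n1, `2` = n2),
    module_of_region = 1:2, min_nodes = 20), class = "bg_regions")
}

test_that("presence-absence framing uses other regions as absences", {
  reg <- toy_regions2(200, 150, 30)
  env <- data.frame(cell = seq_len(380), temp = rnorm(380))
  pa1 <- build_pa(reg, 1, env)
  expect_equal(sum(pa1$response), 200)
  expect_equal(sum(pa1$response == 0), 150)
  expect_true(attr(pa1, "modellable"))
  # unassigned cells never appear at all
  expect_false(any(pa1$cell > 350))
  # fewer than 30 presences -> unmodellable flag
  reg_small <- toy_regions2(12, 300)
  pa_small <- build_pa(reg_small, 1, data.frame(cell = 1:312,
                                                temp = rnorm(312)))
  expect_false(attr(pa_small, "modellable"))
  expect_error(fit_region_models(pa_small, NULL, "temp"), "fewer presences")
  expect_error(build_pa(reg, 99, env), "no assigned cells")
})

test_that("collinearity groups are Spearman components with one representative", {
  pa <- toy_pa()
  cg <- collinearity_groups(pa, techniques = c("glm", "fda"), seed = 1)
  grp_sizes <- sort(vapply(cg$groups, length, integer(1)))
  expect_equal(grp_sizes, c(1L, 1L, 2L))
  both <- cg$groups[[which(vapply(cg$groups, length, integer(1)) == 2)]]
  expect_setequal(both, c("x1", "x1_copy"))
  expect_equal(length(cg$representatives), 3)
  # the informative pair is represented by one of its members
  expect_true(any(cg$representatives %in% c("x1", "x1_copy")))
  # transitive chains merge into one component
  set.seed(2)
  n2 <- 800
  a <- rnorm(n2); b <- a + rnorm(n2, 0, 0.85); c2 <- b + rnorm(n2, 0, 0.85)
  pa2 <- toy_pa(n2)
  pa2$x1 <- a; pa2$x1_copy <- b; pa2$noise_a <- c2
  pa2$response <- rbinom(n2, 1, plogis(2 * a))
  stopifnot(cor(a, b, method = "spearman") > 0.7,
            cor(b, c2, method = "spearman") > 0.7)
  stopifnot(cor(a, c2, method = "spearman") < 0.7)  # only chained links
  cg2 <- collinearity_groups(pa2, techniques = "glm", seed = 1)
  chain <- cg2$groups[[which.max(vapply(cg2$groups, length, integer(1)))]]
  expect_setequal(chain, c("x1", "x1_copy", "noise_a"))
  # constant variables are excluded with a warning
  pa3 <- toy_pa()
  pa3$noise_a <- 1
  expect_warning(collinearity_groups(pa3, techniques = "glm", seed = 1),
                 "constant")
})

test_that("permutation importance separates used from ignored variables", {
  pa <- toy_pa()
  fit <- fit_technique("glm", pa, c("x1", "noise_a"), seed = 1)
  # ignored variable: shuffling noise_a barely changes a model dominated by x1
  imp_noise <- permutation_importance(fit, pa, "noise_a", seed = 2)
  imp_x1 <- permutation_importance(fit, pa, "x1", seed = 2)
  expect_lt(imp_noise$importance, 0.05)
  expect_gt(imp_x1$importance, 0.5)
  # a single-variable strong monotone fit: importance near or above 1
  fit1 <- fit_technique("glm", pa, "x1", seed = 1)
  expect_gt(permutation_importance(fit1, pa, "x1", seed = 3)$importance, 0.8)
  # determinism per seed
  expect_identical(permutation_importance(fit, pa, "x1", seed = 7),
                   permutation_importance(fit, pa, "x1", seed = 7))
})

test_that("variable selection keeps the driver and drops noise", {
  pa <- toy_pa(800)
  vs <- select_variables(pa, techniques = c("glm", "gam", "fda"), seed = 5)
  expect_equal(length(vs$selected), 1)
  expect_true(vs$selected %in% c("x1", "x1_copy"))
  med <- vs$importance$median_importance
  names(med) <- vs$importance$variable
  expect_gt(med[[vs$selected]], 0.10)
  expect_true(all(med[c("noise_a", "noise_b")] < 0.10))
  # Imp = 1 - r is a relative measure: when nothing clears the threshold the
  # selection fails loudly rather than returning an empty set
  expect_error(
    suppressWarnings(select_variables(pa, techniques = c("glm", "fda"),
                                      importance_min = 2, seed = 5)),
    "no variable passes")
})

test_that("spatial blocks tile the grid and folds balance classes", {
  g <- make_grid(0, 40, -60, -40, 1)
  blocks <- spatial_blocks(g, block_deg = 10)
  expect_equal(length(unique(blocks$block)), 8)
  # contiguity: cells of one block span at most block_deg degrees
  cc <- cell_centers(g)
  for (b in unique(blocks$block)) {
    sel <- blocks$block == b
    expect_lte(diff(range(cc$lon[sel])), 10)
    expect_lte(diff(range(cc$lat[sel])), 10)
  }
  expect_error(spatial_blocks(g, block_deg = 0.5), "at least")
  # folds: 8 blocks over k = 4 -> 2 blocks per fold; class balance within tol
  set.seed(3)
  pa <- data.frame(cell = sample(g$n_cells, 500),
                   response = rbinom(500, 1, 0.5))
  attr(pa, "region_id") <- 1L; attr(pa, "modellable") <- TRUE
  folds <- assign_folds(pa, blocks, k = 4, seed = 9)
  expect_equal(as.integer(table(folds$fold[!duplicated(folds$block)])),
               rep(2L, 4))
  pres <- table(folds$fold[pa$response == 1])
  expect_true(all(abs(pres - sum(pa$response) / 4) <=
                    0.1 * sum(pa$response) / 4 + 1e-9))
  expect_identical(assign_folds(pa, blocks, seed = 5)$fold,
                   assign_folds(pa, blocks, seed = 5)$fold)
  # degenerate: all presences in one block cannot balance -> warning
  pa_deg <- data.frame(cell = c(1:40, 600:659),
                       response = rep(c(1, 0), c(40, 60)))
  expect_warning(assign_folds(pa_deg, blocks, k = 4, max_tries = 25,
                              seed = 1), "balance")
})

test_that("the ensemble has technique x fold members and logs failures", {
  pa <- toy_pa(400)
  blocks <- list(block = rep(1:8, length.out = 10000), block_deg = 1)
  folds <- suppressWarnings(assign_folds(pa, blocks, seed = 1))
  ens <- fit_region_models(pa, folds, "x1", techniques = c("glm", "fda"),
                           seed = 2)
  expect_equal(length(ens$members), 8)
  expect_equal(nrow(ens$failed), 0)
  preds <- ens$members[[1]]$predict(pa)
  expect_true(all(preds >= 0 & preds <= 1))
  # a training set with a single class breaks the discriminant member; the
  # failure is recorded and the rest of the ensemble survives
  pa_one <- toy_pa(200)
  pa_one$response[folds$fold[1:200] != 1] <- 0  # fold 1 holds all presences
  folds200 <- folds[1:200, ]
  ens2 <- fit_region_models(pa_one, folds200, "x1",
                            techniques = c("glm", "fda"), seed = 2)
  expect_lt(length(ens2$members), 8)
  expect_gt(nrow(ens2$failed), 0)
  expect_true("fda" %in% ens2$failed$technique)
})

test_that("all five technique families return calibrated probabilities", {
  pa <- toy_pa(500)
  for (tech in bg_techniques()) {
    fit <- fit_technique(tech, pa, c("x1", "noise_a"), seed = 3)
    p <- fit$predict(pa)
    expect_equal(length(p), nrow(pa))
    expect_true(all(p >= 0 & p <= 1), label = tech)
    # every family must track the planted monotone signal
    expect_gt(suppressWarnings(cor(p, plogis(3 * pa$x1))), 0.8)
  }
})

test_that("evaluation computes Jaccard on held-out folds and rejects weak models", {
  expect_equal(jaccard_index(3, 1, 2), 0.5)
  pa <- toy_pa(600)
  blocks <- list(block = rep(1:12, length.out = 10000), block_deg = 1)
  folds <- suppressWarnings(assign_folds(pa, blocks, seed = 2))
  ens <- fit_region_models(pa, folds, "x1", techniques = c("glm", "gam"),
                           seed = 1)
  ev <- evaluate_models(ens, pa, folds)
  expect_equal(nrow(ev), 8)
  expect_true(all(ev$jaccard >= 0 & ev$jaccard <= 1))
  expect_true(all(ev$auc > 0.8))
  expect_equal(ev$accepted, ev$jaccard >= 0.5)
  expect_equal(ev$TP + ev$FP + ev$FN + ev$TN,
               as.integer(table(folds$fold)[as.character(ev$fold)]),
               ignore_attr = TRUE)
  # members predicting coin flips hover near the J = 1/3 expectation and are
  # rejected
  coin <- ens
  coin$members <- lapply(coin$members, function(m) {
    m$predict <- function(nd) {
      set.seed(1)
      runif(nrow(nd))
    }
    m
  })
  evc <- evaluate_models(coin, pa, folds, thresholds = 0.5)
  expect_true(all(!evc$accepted))
  expect_lt(abs(median(evc$jaccard) - 1 / 3), 0.1)
})

test_that("response curves flag implausible wiggly members", {
  pa <- toy_pa(500)
  blocks <- list(block = rep(1:8, length.out = 10000), block_deg = 1)
  folds <- suppressWarnings(assign_folds(pa, blocks, seed = 1))
  ens <- fit_region_models(pa, folds, "x1", techniques = "glm", seed = 1)
  rc <- response_curves(ens, pa)
  expect_true(all(rc$plausible))  # monotone logistic responses
  expect_true(all(rc$probability >= 0 & rc$probability <= 1))
  # an oscillating response is implausible
  osc <- ens
  osc$members <- lapply(osc$members, function(m) {
    m$predict <- function(nd) (sin(3 * nd$x1) + 1) / 2
    m
  })
  rco <- response_curves(osc, pa)
  expect_true(all(!rco$plausible))
})
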