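# Shared fixtures: small graphs, a brute-force partition oracle, and a
# lazily built full-size default scene reused by the heavier tests.

# Minimal network container for arbitrary (not necessarily bipartite) graphs;
# matches the fields map_equation_length() and infomap_cluster() use.
mknet <- function(edges, n) {
  structure(list(edges = edges, n_nodes = n, n_edges = nrow(edges),
                 node_names = as.character(seq_len(n)),
                 node_type = rep("site", n), site_cells = seq_len(n)),
            class = "bg_bipartite")
}

fixture_graphs <- function() {
  list(
    cycle4 = mknet(cbind(1:4, c(2, 3, 4, 1)), 4),
    path5 = mknet(cbind(1:4, 2:5), 5),
    star6 = mknet(cbind(rep(1, 5), 2:6), 6),
    two_triangles = mknet(rbind(cbind(c(1, 2, 3), c(2, 3, 1)),
                                cbind(c(4, 5, 6), c(5, 6, 4)),
                                c(3, 4)), 6),
    k23 = mknet(as.matrix(expand.grid(1:2, 3:5)), 5),
    two_bicliques = mknet(rbind(as.matrix(expand.grid(1:2, 3:4)),
                                as.matrix(expand.grid(5:6, 7:8))), 8),
    bipartite_blocks = mknet(rbind(as.matrix(expand.grid(1:2, 3:4)),
                                   as.matrix(expand.grid(5:6, 7:8)),
                                   c(2, 7)), 8))
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  res <- list()
  rec <- function(i, assign, k) {
    if (i > n) {
      res[[length(res) + 1]] <<- assign
      return()
    }
    for (m in seq_len(k + 1)) rec(i + 1, c(assign, m), max(k, m))
  }
  rec(1, integer(0), 0)
  res
}

# Exhaustive minimum description length over all partitions (n <= 8).
brute_force_min_L <- function(net) {
  stopifnot(net$n_nodes <= 8)
  min(vapply(all_partitions(net$n_nodes),
             function(m) map_equation_length(net, m), numeric(1)))
}

# Adjusted Rand index between two labelled partitions (independent of the
# package's clustering code; used as the recovery oracle).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Full default scene pipeline at the package's default conditions, built once
# per test run and cached. Covers occurrence processing, clustering, region
# models and projections.
scene_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (!is.null(scene_cache$pipe)) return(scene_cache$pipe)
  sc <- make_default_scene(42)
  cl <- clean_coordinates(sc$records, sc$grid, sc$mask)
  tf <- filter_temporal(cl$records)
  sel <- select_species(tf$records)
  pm <- rasterize_records(tf$records, sc$grid, sel$species[sel$retained])
  net <- build_network(pm)
  part <- infomap_cluster(net, n_runs = 100, seed = 42)
  reg <- filter_minor_clusters(part, net)
  fid <- species_fidelity(part, net, pm)
  t_calib <- Sys.time()
  models <- lapply(1:2, function(r) {
    pa <- build_pa(reg, r, sc$env_stack)
    vs <- select_variables(pa, seed = 100 + r)
    blocks <- spatial_blocks(sc$grid, "auto",
                             env_values = sc$env_stack$temp_200m, seed = 1)
    folds <- suppressWarnings(assign_folds(pa, blocks, seed = 200 + r))
    ens <- fit_region_models(pa, folds, vs$selected, seed = 300 + r)
    ev <- evaluate_models(ens, pa, folds)
    list(pa = pa, vs = vs, folds = folds, ens = ens, ev = ev)
  })
  calib_seconds <- as.numeric(Sys.time() - t_calib, units = "secs")
  fut_stacks <- lapply(sc$gcms, function(g) {
    corr <- delta_correct(sc$temp, g$hist, g$future)
    df <- sc$env_stack
    df$temp_200m <- corr$values
    df
  })
  preds <- lapply(models, function(m)
    project_ensemble(m$ens$members[m$ev$accepted], sc$env_stack))
  futs <- lapply(models, function(m)
    project_ensemble(m$ens$members[m$ev$accepted], fut_stacks))
  names(preds) <- names(futs) <- paste0("region", 1:2)
  scene_cache$pipe <- list(sc = sc, clean = cl, temporal = tf, sel = sel,
                           pm = pm, net = net, part = part, reg = reg,
                           fid = fid, models = models,
                           fut_stacks = fut_stacks,
                           preds = preds, futs = futs,
                           calib_seconds = calib_seconds)
  scene_cache$pipe
}
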