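test_that("bipartite network mirrors the presence matrix", {
  records <- data.frame(
    species = c("a", "a", "a", "b", "b", "c", "c"),
    decimalLongitude = c(0.5, 1.5, 2.5, 0.5, 1.5, 2.5, 3.5),
    decimalLatitude = rep(-45.5, 7), year = 2000, month = 1)
  g <- make_grid(0, 10, -50, -40, 1)
  pm <- rasterize_records(records, g)
  net <- build_network(pm)
  expect_equal(net$n_edges, 7)
  deg <- node_degrees(net)
  expect_equal(deg[match("a", net$node_names)], 3)
  # edges connect species to sites only
  n_sp <- sum(net$node_type == "species")
  expect_true(all(net$edges[, 1] <= n_sp & net$edges[, 2] > n_sp))
  expect_error(build_network(pm[0, , drop = FALSE]), "empty")
})

test_that("map-equation length matches hand-derived codelengths", {
  gs <- fixture_graphs()
  # single-module 4-cycle: L is the entropy of uniform visit rates, 2 bits
  expect_equal(map_equation_length(gs$cycle4, rep(1, 4)), 2, tolerance = 1e-9)
  # split into adjacent pairs: evaluate q H(Q) + sum (q_i + p_i) H(P_i) by
  # hand for q_i = 1/4, p_i = 1/2 per module
  q_i <- 1 / 4; p_i <- 1 / 2; q <- 1 / 2
  HQ <- 1  # two equal exit rates
  HP <- -(q_i / (q_i + p_i)) * log2(q_i / (q_i + p_i)) -
    2 * ((1 / 4) / (q_i + p_i)) * log2((1 / 4) / (q_i + p_i))
  L_pairs <- q * HQ + 2 * (q_i + p_i) * HP
  expect_equal(map_equation_length(gs$cycle4, c(1, 1, 2, 2)), L_pairs,
               tolerance = 1e-9)
  # disconnected bicliques: the component split beats one module
  expect_lt(map_equation_length(gs$two_bicliques, rep(c(1, 2), each = 4)),
            map_equation_length(gs$two_bicliques, rep(1, 8)))
  # partitions with unassigned or empty modules are rejected
  expect_error(map_equation_length(gs$cycle4, c(1, 1, 2, NA)), "assigned")
})

test_that("greedy optimiser attains the exhaustive optimum on all fixtures", {
  for (nm in names(fixture_graphs())) {
    net <- fixture_graphs()[[nm]]
    part <- infomap_cluster(net, n_runs = 100, seed = 17)
    expect_equal(part$codelength, brute_force_min_L(net), tolerance = 1e-9,
                 label = paste("codelength on", nm))
    expect_equal(part$codelength, map_equation_length(net, part$modules),
                 tolerance = 1e-9)
  }
})

test_that("clustering separates planted blocks and is deterministic per seed", {
  net <- fixture_graphs()$bipartite_blocks  # 2 bicliques + 1 cross edge
  part <- infomap_cluster(net, n_runs = 100, seed = 5)
  expect_equal(part$n_modules, 2)
  expect_equal(length(unique(part$modules[c(1, 2, 3, 4)])), 1)
  expect_equal(length(unique(part$modules[c(5, 6, 7, 8)])), 1)
  # disconnected components never share a module
  disc <- fixture_graphs()$two_bicliques
  pd <- infomap_cluster(disc, n_runs = 20, seed = 2)
  expect_gte(pd$n_modules, 2)
  expect_equal(length(intersect(pd$modules[1:4], pd$modules[5:8])), 0)
  # determinism contract
  expect_identical(infomap_cluster(net, n_runs = 30, seed = 11)$modules,
                   infomap_cluster(net, n_runs = 30, seed = 11)$modules)
})

test_that("clustering agrees with an independent Infomap implementation", {
  # planted 2-block bipartite graph: 2 x K_{5,15} plus two cross edges
  b1 <- as.matrix(expand.grid(1:5, 6:20))
  b2 <- as.matrix(expand.grid(21:25, 26:40))
  net <- mknet(rbind(b1, b2, c(3, 26), c(23, 6)), 40)
  ours <- infomap_cluster(net, n_runs = 50, seed = 4)
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  ref <- igraph::membership(igraph::cluster_infomap(g, nb.trials = 10))
  # same codelength under the package's own objective, same partition
  expect_equal(ours$codelength, map_equation_length(net, as.integer(ref)),
               tolerance = 1e-9)
  expect_equal(adjusted_rand(ours$modules, as.integer(ref)), 1)
})

test_that("edge-free nodes do not change the description length", {
  gs <- fixture_graphs()
  net <- gs$cycle4
  aug <- mknet(net$edges, 5)  # node 5 isolated
  expect_equal(map_equation_length(aug, c(1, 1, 1, 1, 2)),
               map_equation_length(net, rep(1, 4)), tolerance = 1e-12)
})

test_that("minor-cluster filter applies the fewer-than-20 rule and renumbers", {
  sizes <- c(210, 180, 12, 20, 5)
  mods <- rep(seq_along(sizes), sizes)
  n <- length(mods)
  net <- mknet(cbind(seq_len(n - 1), seq_len(n - 1) + 1L), n)  # shape only
  part <- structure(list(modules = mods, codelength = 1,
                         n_modules = 5), class = "bg_partition")
  reg <- filter_minor_clusters(part, net, min_nodes = 20)
  # three modules survive (>= 20 nodes, size exactly 20 retained)
  expect_equal(length(reg$region_sizes), 3)
  expect_equal(unname(reg$region_sizes), c(210, 180, 20))
  # renumbered by decreasing size: region 1 is the largest
  expect_equal(reg$module_of_region, c(1L, 2L, 4L))
  # unassigned nodes carry the reason
  unass <- is.na(reg$cells$region)
  expect_equal(sum(unass), 12 + 5)
  expect_true(all(reg$cells$reason[unass] == "minor_cluster"))
  # min_nodes = 1 retains everything
  expect_equal(length(filter_minor_clusters(part, net, 1)$region_sizes), 5)
  expect_warning(filter_minor_clusters(part, net, 1000), "no regions")
})

test_that("species fidelity is the share of presence cells per cluster", {
  records <- data.frame(
    species = rep(c("a", "b", "c"), c(10, 6, 10)),
    decimalLongitude = c(seq(0.5, 9.5, 1),            # a: 8 west, 2 east
                         seq(10.5, 15.5, 1),          # b: all east
                         seq(0.5, 4.5, 1), seq(10.5, 14.5, 1)),  # c: 5/5
    decimalLatitude = -45.5, year = 2000, month = 1)
  records$decimalLongitude[records$species == "a"][9:10] <- c(10.5, 11.5)
  records$decimalLongitude[records$species == "a"][1:8] <- seq(0.5, 7.5, 1)
  g <- make_grid(0, 16, -50, -40, 1)
  pm <- rasterize_records(records, g)
  net <- build_network(pm)
  # partition sites by west (< 10) / east; species with their majority side
  is_site <- net$node_type == "site"
  cc <- cell_centers(g)
  mods <- integer(net$n_nodes)
  mods[is_site] <- ifelse(cc$lon[net$site_cells] < 10, 1L, 2L)
  mods[!is_site] <- c(1L, 2L, 1L)
  part <- structure(list(modules = mods, codelength = 1, n_modules = 2),
                    class = "bg_partition")
  fid <- species_fidelity(part, net, pm)
  expect_equal(unname(fid["a", ]), c(0.8, 0.2))
  expect_equal(unname(fid["b", ]), c(0, 1))
  expect_equal(unname(fid["c", ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(fid)), rep(1, 3), tolerance = 1e-12)
})

test_that("network export round-trips through Pajek with attributes", {
  net <- fixture_graphs()$bipartite_blocks
  part <- infomap_cluster(net, n_runs = 10, seed = 1)
  path <- tempfile(fileext = ".net")
  export_network(net, path, part)
  back <- read_pajek(path)
  expect_equal(back$edges, unname(net$edges))
  expect_equal(back$node_names, net$node_names)
  expect_equal(back$modules, part$modules)
  expect_equal(length(back$node_type), net$n_nodes)
  # without a partition no .clu sidecar is written
  p2 <- tempfile(fileext = ".net")
  export_network(net, p2)
  expect_false(file.exists(paste0(p2, ".clu")))
})
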