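#' Build the bipartite species-site network
#'
#' One node per species and per occupied site (grid cell), one undirected,
#' unweighted edge per presence. Species-species and site-site links do not
#' exist by construction; there are no isolated nodes because only occupied
#' cells and present species enter the matrix.
#'
#' @param pm presence matrix from [rasterize_records()].
#' @return a `bg_bipartite` object: `edges` (2-column integer matrix of node
#'   indices), `node_names`, `node_type` (`"species"`/`"site"`), `n_nodes`,
#'   `n_edges`, `site_cells` (grid cell id per site node).
#' @export
build_network <- function(pm) {
  if (is.null(dim(pm)) || nrow(pm) == 0 || ncol(pm) == 0 ||
      length(pm@x) == 0)
    stop("presence matrix is empty")
  tm <- Matrix::which(pm > 0, arr.ind = TRUE)
  n_sp <- nrow(pm)
  edges <- cbind(tm[, 1], n_sp + tm[, 2])
  structure(list(
    edges = edges,
    node_names = c(rownames(pm), paste0("cell_", colnames(pm))),
    node_type = rep(c("species", "site"), c(n_sp, ncol(pm))),
    n_nodes = n_sp + ncol(pm),
    n_edges = nrow(edges),
    site_cells = as.integer(colnames(pm))),
    class = "bg_bipartite")
}

#' @export
print.bg_bipartite <- function(x, ...) {
  cat(sprintf("<bg_bipartite> %d species + %d sites, %d edges\n",
              sum(x$node_type == "species"), sum(x$node_type == "site"),
              x$n_edges))
  invisible(x)
}

#' Node degrees of a bipartite network
#' @param net a `bg_bipartite`.
#' @return integer vector of degrees, one per node.
#' @export
node_degrees <- function(net) {
  tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = net$n_nodes)
}

#' Two-level map-equation description length
#'
#' Description length (bits per step) of a random walk on the undirected,
#' unweighted network under a two-level coding with the given partition.
#' With node visit rates \eqn{p_\alpha = deg(\alpha)/2E}, module exit rates
#' \eqn{q_i} = (boundary edges of module i)/2E, \eqn{q = \sum_i q_i} and
#' module totals \eqn{p_{i\circ} = \sum_{\alpha \in i} p_\alpha}:
#' \deqn{L = q H(Q) + \sum_i (q_i + p_{i\circ}) H(P_i)}
#' with base-2 entropies over the normalised rate vectors. For the
#' single-module partition this reduces to the entropy of the visit rates.
#'
#' @param net a `bg_bipartite` (any undirected edge list network works).
#' @param modules integer module id per node (every node assigned once).
#' @return description length in bits.
#' @export
map_equation_length <- function(net, modules) {
  stopifnot(length(modules) == net$n_nodes)
  if (anyNA(modules)) stop("every node must be assigned to a module")
  modules <- as.integer(factor(modules))
  deg <- node_degrees(net)
  twoE <- 2 * net$n_edges
  p <- deg / twoE
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  m1 <- modules[net$edges[, 1]]
  m2 <- modules[net$edges[, 2]]
  n_mod <- max(modules)
  if (any(tabulate(modules, n_mod) == 0)) stop("empty module in partition")
  internal <- tabulate(m1[m1 == m2], nbins = n_mod)
  mod_deg <- as.numeric(tapply(deg, modules, sum))
  w <- mod_deg / twoE                      # p_i-circle
  q_i <- (mod_deg - 2 * internal) / twoE   # exit rates
  q <- sum(q_i)
  sum(plogp(q)) - 2 * sum(plogp(q_i)) + sum(plogp(q_i + w)) - sum(plogp(p))
}

#' Cluster a network by greedy map-equation minimisation with restarts
#'
#' Each node starts in its own module; seeded-random-order local node moves
#' and module aggregation passes repeat until no move lowers the description
#' length (a Louvain-style search on the two-level map equation). Because the
#' search is stochastic, `n_runs` independent restarts with distinct sub-seeds
#' are performed and the partition with the shortest description length is
#' returned. Ties between equal-length partitions resolve to the first found
#' under the seeded order, so results are reproducible per seed.
#'
#' @param net a `bg_bipartite`.
#' @param n_runs number of restarts (default 100).
#' @param seed integer seed.
#' @return a `bg_partition`: `modules` (integer per node, relabelled 1..k in
#'   order of first appearance), `codelength` (bits), `n_modules`, `seed`,
#'   `best_run`.
#' @export
infomap_cluster <- function(net, n_runs = 100, seed = 1) {
  stopifnot(net$n_edges >= 1, n_runs >= 1)
  res <- infomap_greedy_cpp(net$edges[, 1] - 1L, net$edges[, 2] - 1L,
                            net$n_nodes, as.integer(n_runs),
                            as.integer(seed))
  mods <- res$membership + 1L
  mods <- match(mods, unique(mods))  # relabel in order of first appearance
  structure(list(
    modules = mods,
    codelength = res$codelength,
    n_modules = max(mods),
    seed = seed, n_runs = n_runs, best_run = res$best_run),
    class = "bg_partition")
}

#' @export
print.bg_partition <- function(x, ...) {
  cat(sprintf("<bg_partition> %d modules, L = %.4f bits (best of %d runs)\n",
              x$n_modules, x$codelength, x$n_runs))
  invisible(x)
}

#' Discard minor clusters and renumber regions by size
#'
#' Modules with fewer than `min_nodes` nodes (species + sites) are discarded:
#' their nodes become unassigned, with the reason recorded. Remaining modules
#' are renumbered by decreasing node count, so region 1 is always the largest.
#'
#' @param partition a `bg_partition`.
#' @param net the `bg_bipartite` the partition was computed on.
#' @param min_nodes minimum node count for a module to become a region
#'   (default 20; a module of exactly 20 nodes is retained).
#' @return a `bg_regions` object: `cells` (data.frame `cell`, `region`,
#'   `reason`), `species` (data.frame `species`, `region`, `reason`),
#'   `region_sizes` (named node counts), `module_of_region` (original module
#'   ids), `min_nodes`.
#' @export
filter_minor_clusters <- function(partition, net, min_nodes = 20) {
  sizes <- table(partition$modules)
  keep <- as.integer(names(sizes)[sizes >= min_nodes])
  if (!length(keep)) {
    warning("all modules have fewer than ", min_nodes, " nodes; ",
            "no regions retained")
  }
  keep <- keep[order(-sizes[as.character(keep)], keep)]
  region_of_module <- rep(NA_integer_, max(partition$modules))
  region_of_module[keep] <- seq_along(keep)
  region <- region_of_module[partition$modules]
  reason <- ifelse(is.na(region), "minor_cluster", NA_character_)
  is_site <- net$node_type == "site"
  structure(list(
    cells = data.frame(cell = net$site_cells,
                       region = region[is_site],
                       reason = reason[is_site]),
    species = data.frame(species = net$node_names[!is_site],
                         region = region[!is_site],
                         reason = reason[!is_site]),
    region_sizes = stats::setNames(as.integer(sizes[as.character(keep)]),
                                   seq_along(keep)),
    module_of_region = keep,
    min_nodes = min_nodes),
    class = "bg_regions")
}

#' @export
print.bg_regions <- function(x, ...) {
  cat(sprintf("<bg_regions> %d regions (node counts: %s); %d unassigned nodes\n",
              length(x$region_sizes),
              paste(x$region_sizes, collapse = ", "),
              sum(is.na(x$cells$region)) + sum(is.na(x$species$region))))
  invisible(x)
}

#' Species fidelity to clusters
#'
#' For each species, the share of its presence cells falling in each cluster
#' of the partition (before any minor-cluster discard):
#' F_i = occurrences of species i in the cluster / total occurrences of i.
#' Rows sum to 1 because every presence cell belongs to exactly one cluster.
#'
#' @param partition a `bg_partition`.
#' @param net the network the partition was computed on.
#' @param pm the presence matrix the network was built from.
#' @return matrix species x cluster of fidelities in `[0, 1]`.
#' @export
species_fidelity <- function(partition, net, pm) {
  if (any(Matrix::rowSums(pm) == 0))
    stop("species with zero occurrences violate the presence-matrix invariant")
  is_site <- net$node_type == "site"
  site_mod <- partition$modules[is_site]
  n_mod <- max(partition$modules)
  idx <- Matrix::which(pm > 0, arr.ind = TRUE)
  counts <- matrix(0, nrow(pm), n_mod,
                   dimnames = list(rownames(pm), seq_len(n_mod)))
  tab <- table(factor(idx[, 1], levels = seq_len(nrow(pm))),
               factor(site_mod[idx[, 2]], levels = seq_len(n_mod)))
  counts[] <- as.numeric(tab)
  counts / Matrix::rowSums(pm)
}

#' Export a network and partition in Pajek format
#'
#' Writes a Pajek `.net` file (vertex names then edge list) plus two sidecar
#' partition files: `<path>.clu` with the module id per node and `<path>.typ`
#' with the node type (1 = species, 2 = site). The export round-trips through
#' [read_pajek()] with an identical edge set.
#'
#' @param net a `bg_bipartite`.
#' @param path output path for the `.net` file.
#' @param partition optional `bg_partition`; omit to skip the `.clu` file.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, partition = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d", net$n_nodes), con)
  writeLines(sprintf('%d "%s"', seq_len(net$n_nodes), net$node_names), con)
  writeLines("*Edges", con)
  writeLines(sprintf("%d %d", net$edges[, 1], net$edges[, 2]), con)
  writeLines(as.character(ifelse(net$node_type == "species", 1L, 2L)),
             paste0(path, ".typ"))
  if (!is.null(partition))
    writeLines(as.character(partition$modules), paste0(path, ".clu"))
  invisible(path)
}

#' Read a Pajek network written by [export_network()]
#' @param path the `.net` file path.
#' @return list with `edges`, `node_names`, `node_type` (if the `.typ`
#'   sidecar exists) and `modules` (if the `.clu` sidecar exists).
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("\\*Vertices ", "", lines[1], ignore.case = TRUE))
  vlines <- lines[2:(n + 1)]
  names <- sub('^\\d+ "(.*)"$', "\\1", vlines)
  estart <- which(tolower(lines) == "*edges")[1]
  el <- lines[(estart + 1):length(lines)]
  parts <- do.call(rbind, strsplit(el, " "))
  out <- list(edges = cbind(as.integer(parts[, 1]), as.integer(parts[, 2])),
              node_names = names)
  typ <- paste0(path, ".typ")
  if (file.exists(typ))
    out$node_type <- c("species", "site")[as.integer(readLines(typ))]
  clu <- paste0(path, ".clu")
  if (file.exists(clu)) out$modules <- as.integer(readLines(clu))
  out
}
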