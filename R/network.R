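#' Build a PPI network from a scored interaction table
#'
#' Reconstructs an undirected simple protein-protein interaction network
#' over a given node set from a STRING-style edge list carrying per-channel
#' confidence scores. An edge is retained when its curated-database score
#' reaches `db_min` OR its experimental score reaches `exp_min` (inclusive
#' thresholds). Self-loops are dropped; duplicate pairs are merged keeping
#' the maximum score per channel. Nodes without any retained edge stay in
#' the network as isolates.
#'
#' @param nodes character vector of protein IDs to keep (e.g. the DAPs from
#'   [dap_fit()]).
#' @param interactions data frame with columns `protein1`, `protein2`,
#'   `databases_score`, `experiments_score` (scores in `[0, 1]`).
#' @param db_min,exp_min per-channel retention thresholds (defaults 0.3 and
#'   0.15).
#' @return An object of class `ppi_network`: list with `graph` (an
#'   \pkg{igraph} graph), `edges` (retained edges with scores) and `nodes`.
#' @examples
#' inter <- data.frame(protein1 = c("A", "A"), protein2 = c("B", "C"),
#'                     databases_score = c(0.4, 0.1),
#'                     experiments_score = c(0, 0.1))
#' ppi_network(c("A", "B", "C"), inter)   # keeps only A-B
#' @export
ppi_network <- function(nodes, interactions, db_min = 0.3, exp_min = 0.15) {
  stopifnot(db_min >= 0, db_min <= 1, exp_min >= 0, exp_min <= 1)
  df <- validate_interactions(interactions)
  nodes <- unique(as.character(nodes))
  df <- df[df$protein1 %in% nodes & df$protein2 %in% nodes, , drop = FALSE]
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  if (nrow(df)) {
    a <- pmin(df$protein1, df$protein2)
    b <- pmax(df$protein1, df$protein2)
    key <- paste(a, b, sep = "\r")
    df <- data.frame(protein1 = a, protein2 = b,
                     databases_score = df$databases_score,
                     experiments_score = df$experiments_score,
                     stringsAsFactors = FALSE)
    df <- do.call(rbind, lapply(split(df, key), function(d)
      data.frame(protein1 = d$protein1[1], protein2 = d$protein2[1],
                 databases_score = max(d$databases_score),
                 experiments_score = max(d$experiments_score),
                 stringsAsFactors = FALSE)))
    rownames(df) <- NULL
    df <- df[df$databases_score >= db_min | df$experiments_score >= exp_min,
             , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, edges = df, nodes = nodes,
                 db_min = db_min, exp_min = exp_min),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  comp <- igraph::components(x$graph)
  cat(sprintf(paste0("ppi_network: %d nodes, %d edges, %d components ",
                     "(largest %d)\n"),
              length(x$nodes), nrow(x$edges), comp$no, max(comp$csize)))
  cat(sprintf("  edge filter: databases >= %g OR experiments >= %g\n",
              x$db_min, x$exp_min))
  invisible(x)
}

#' Per-group PPI network from detection frequencies
#'
#' Builds the network of one clinical group: the node set comprises the
#' proteins detected (PSM value positive) in at least half of the group's
#' subjects -- a majority threshold of `ceiling(n / 2)`, which gives 3 of 5,
#' 2 of 4 and 4 of 7 for the default cohort sizes. Edges are then filtered
#' as in [ppi_network()]. Optionally the node set is intersected with a DAP
#' list.
#'
#' @inheritParams group_mean_profiles
#' @param group group label.
#' @param interactions scored interaction table (see [ppi_network()]).
#' @param daps optional character vector; if given, nodes are restricted to
#'   these proteins after the membership rule.
#' @param min_subjects membership threshold override; default
#'   `ceiling(n/2)` for a group of size n.
#' @inheritParams ppi_network
#' @return A `ppi_network`.
#' @export
group_network <- function(x, design, group, interactions, daps = NULL,
                          min_subjects = NULL, db_min = 0.3, exp_min = 0.15) {
  check_design(x, design)
  gs <- group_subjects(design)
  if (!group %in% names(gs)) stop("unknown group: ", group)
  subj <- gs[[group]]
  thr <- if (is.null(min_subjects)) ceiling(length(subj) / 2) else min_subjects
  det <- rowSums(psm_values(x)[, subj, drop = FALSE] > 0)
  nodes <- rownames(x)[det >= thr]
  if (!is.null(daps)) nodes <- intersect(nodes, daps)
  ppi_network(nodes, interactions, db_min = db_min, exp_min = exp_min)
}

#' Topological centrality profile of a PPI network
#'
#' Computes the node, edge and network-level centralities used to rank
#' regulatory proteins, following the Centiscape conventions:
#'
#' * `degree`: incident edge count;
#' * `betweenness`: number of shortest s-t paths through the node, each
#'   unordered pair weighted by its path-count fraction (unnormalized);
#' * `stress`: raw count of shortest s-t paths through the node;
#' * `closeness`: reciprocal of the summed distances to all nodes of the
#'   component;
#' * `eccentricity`: reciprocal of the maximum distance within the
#'   component;
#' * `radiality`: sum over other nodes of (component diameter + 1 -
#'   distance), divided by (component size - 1);
#' * `centroid`: min over other nodes w of `gamma_v(w) - gamma_w(v)`, where
#'   `gamma_v(w)` counts nodes strictly closer to v than to w;
#' * `eigenvector`: principal eigenvector of the component adjacency,
#'   scaled to maximum 1;
#' * `bridging`: betweenness times the bridging coefficient
#'   `(1/deg(v)) / sum over neighbours i of 1/deg(i)`;
#' * per edge, `edge_betweenness`; per network, diameter, average distance
#'   and average degree of the largest component.
#'
#' Distance-based measures are computed per connected component; isolated
#' nodes get degree 0 and `NA` for the distance-based columns.
#'
#' @param net a [ppi_network()] (or an \pkg{igraph} graph).
#' @return An object of class `centrality_table`: list with `nodes` (data
#'   frame of per-node centralities and component membership), `edges`
#'   (edge betweenness) and `network` (diameter, average distance, average
#'   degree, sizes).
#' @export
centrality_table <- function(net) {
  g <- as_network_graph(net)
  n <- igraph::vcount(g)
  if (n < 1) stop("network has no nodes")
  ids <- igraph::V(g)$name
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  nd <- data.frame(node = ids, component = comp$membership,
                   degree = as.integer(deg), betweenness = btw,
                   centroid = NA_real_, stress = 0,
                   eigenvector = NA_real_, bridging = NA_real_,
                   eccentricity = NA_real_, closeness = NA_real_,
                   radiality = NA_real_,
                   stringsAsFactors = FALSE, row.names = NULL)

  for (ci in which(comp$csize >= 2)) {
    vi <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vi)
    d <- igraph::distances(sub)
    nc <- nrow(d)
    diam <- max(d)
    nd$closeness[vi] <- 1 / rowSums(d)
    nd$eccentricity[vi] <- 1 / apply(d, 1, max)
    nd$radiality[vi] <- ((diam + 1) * (nc - 1) - rowSums(d)) / (nc - 1)
    # gamma[v, w] = #nodes strictly closer to v than to w
    gam <- matrix(0L, nc, nc)
    for (v in seq_len(nc)) gam[v, ] <- colSums(d[, v] < d)
    fmat <- gam - t(gam)
    diag(fmat) <- NA
    nd$centroid[vi] <- apply(fmat, 1, min, na.rm = TRUE)
    nd$stress[vi] <- stress_centrality(sub, d)
    ev <- igraph::eigen_centrality(sub)$vector   # scaled to max 1
    nd$eigenvector[vi] <- ev
  }
  # bridging coefficient from the full graph's degrees
  adj <- igraph::as_adj_list(g)
  bc <- vapply(seq_len(n), function(v) {
    nb <- as.integer(adj[[v]])
    if (!length(nb)) return(NA_real_)
    (1 / deg[v]) / sum(1 / deg[nb])
  }, numeric(1))
  nd$bridging <- nd$betweenness * bc

  edges <- igraph::as_data_frame(g, what = "edges")[, c("from", "to")]
  edges$edge_betweenness <- igraph::edge_betweenness(g, directed = FALSE)

  big <- which.max(comp$csize)
  network <- list(n_nodes = n, n_edges = igraph::ecount(g),
                  n_components = comp$no,
                  largest_component_size = max(comp$csize),
                  diameter = NA_integer_, average_distance = NA_real_,
                  average_degree = NA_real_)
  if (max(comp$csize) >= 2) {
    vi <- which(comp$membership == big)
    sub <- igraph::induced_subgraph(g, vi)
    d <- igraph::distances(sub)
    network$diameter <- as.integer(max(d))
    network$average_distance <- mean(d[upper.tri(d)])
    network$average_degree <- 2 * igraph::ecount(sub) / igraph::vcount(sub)
  }
  structure(list(nodes = nd, edges = edges, network = network),
            class = "centrality_table")
}

as_network_graph <- function(net) {
  if (inherits(net, "ppi_network")) return(net$graph)
  if (inherits(net, "igraph")) {
    if (is.null(igraph::V(net)$name))
      igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
    return(net)
  }
  stop("'net' must be a ppi_network or igraph graph")
}

# raw shortest-path counts through each node, per component.
# sigma[s, t] = number of shortest s-t paths (BFS path counting); a path
# passes through v iff d[s,v] + d[v,t] == d[s,t], contributing
# sigma[s,v] * sigma[v,t].
stress_centrality <- function(g, d = igraph::distances(g)) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    for (dist in seq_len(max(d[s, ]))) {
      for (v in which(d[s, ] == dist)) {
        nb <- as.integer(adj[[v]])
        sig[s, v] <- sum(sig[s, nb[d[s, nb] == dist - 1]])
      }
    }
  }
  out <- numeric(n)
  for (v in seq_len(n)) {
    ind <- outer(d[, v], d[v, ], `+`) == d
    paths <- outer(sig[, v], sig[v, ], `*`) * ind
    paths[v, ] <- 0; paths[, v] <- 0
    out[v] <- sum(paths[upper.tri(paths)])
  }
  out
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("centrality_table: %d nodes, %d edges, %d component(s)\n",
              x$network$n_nodes, x$network$n_edges, x$network$n_components))
  cat(sprintf("  largest component: %d nodes, diameter %s, avg distance %s, avg degree %s\n",
              x$network$largest_component_size,
              format(x$network$diameter),
              format(round(x$network$average_distance, 3)),
              format(round(x$network$average_degree, 3))))
  invisible(x)
}

#' Hub and bottleneck selection
#'
#' Flags key regulatory nodes by pairing betweenness with a second
#' centrality: a *hub* has betweenness and centroid both strictly above
#' their network averages; a *bottleneck* has betweenness and bridging both
#' strictly above their averages. Averages are taken over all non-isolated
#' nodes of the analyzed network.
#'
#' @param ct a [centrality_table()].
#' @return An object of class `hub_selection`: data frame with columns
#'   `node`, `is_hub`, `is_bottleneck` plus the relevant centralities;
#'   attribute `means` records the network averages used.
#' @export
hub_selection <- function(ct) {
  nd <- ct$nodes
  keep <- nd$degree > 0
  means <- c(betweenness = mean(nd$betweenness[keep]),
             centroid = mean(nd$centroid[keep]),
             bridging = mean(nd$bridging[keep]))
  out <- data.frame(node = nd$node,
                    betweenness = nd$betweenness,
                    centroid = nd$centroid,
                    bridging = nd$bridging,
                    is_hub = keep & nd$betweenness > means["betweenness"] &
                      !is.na(nd$centroid) & nd$centroid > means["centroid"],
                    is_bottleneck = keep &
                      nd$betweenness > means["betweenness"] &
                      !is.na(nd$bridging) & nd$bridging > means["bridging"],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, means = means, class = c("hub_selection", "data.frame"))
}

#' @export
print.hub_selection <- function(x, ...) {
  m <- attr(x, "means")
  cat(sprintf("hub_selection: %d hubs, %d bottlenecks of %d nodes\n",
              sum(x$is_hub), sum(x$is_bottleneck), nrow(x)))
  cat(sprintf("  means: betweenness %.3f, centroid %.3f, bridging %.3f\n",
              m["betweenness"], m["centroid"], m["bridging"]))
  sel <- x[x$is_hub | x$is_bottleneck, , drop = FALSE]
  if (nrow(sel)) print.data.frame(utils::head(sel, 20), digits = 3)
  invisible(x)
}

#' Degree-preserving random network ensemble
#'
#' Generates `n` randomized replicas of a network by double-edge-swap
#' rewiring, which preserves every node's degree exactly while destroying
#' all higher-order structure; each replica uses at least `10 * |E|` swap
#' attempts. The ensemble provides the null distribution against which the
#' observed centrality structure is validated.
#'
#' @param net a [ppi_network()] or \pkg{igraph} graph with at least 2 edges.
#' @param n number of replicas (default 1000).
#' @param seed integer seed; the whole ensemble is reproducible from it.
#' @param swap_factor swap attempts per edge per replica (default 10).
#' @param keep_graphs if `TRUE`, the replica graphs are returned too.
#' @return An object of class `random_ensemble`: list with `summary` (data
#'   frame per replica: mean betweenness, degree-sequence check, simplicity
#'   check, and whether the replica is unchanged from the input -- the
#'   degenerate no-valid-swap case), `real_mean_betweenness`, `quantile`
#'   (fraction of replicas with mean betweenness at or below the observed),
#'   `n`, `seed`, and optionally `graphs`.
#' @export
random_ensemble <- function(net, n = 1000, seed = 1, swap_factor = 10,
                            keep_graphs = FALSE) {
  g <- as_network_graph(net)
  ne <- igraph::ecount(g)
  if (ne < 2) stop("need at least 2 edges to rewire")
  deg0 <- sort(igraph::degree(g))
  key0 <- edge_key(g)
  real_mean <- mean(igraph::betweenness(g, directed = FALSE))
  set.seed(seed)
  means <- numeric(n); degok <- simple <- unchanged <- logical(n)
  graphs <- if (keep_graphs) vector("list", n)
  for (i in seq_len(n)) {
    r <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                  niter = swap_factor * ne))
    means[i] <- mean(igraph::betweenness(r, directed = FALSE))
    degok[i] <- identical(sort(igraph::degree(r)), deg0)
    simple[i] <- igraph::is_simple(r)
    unchanged[i] <- identical(edge_key(r), key0)
    if (keep_graphs) graphs[[i]] <- r
  }
  structure(list(summary = data.frame(replicate = seq_len(n),
                                      mean_betweenness = means,
                                      degseq_preserved = degok,
                                      simple = simple,
                                      unchanged = unchanged),
                 real_mean_betweenness = real_mean,
                 quantile = sum(means <= real_mean) / n,
                 n = n, seed = seed, swap_factor = swap_factor,
                 graphs = graphs),
            class = "random_ensemble")
}

edge_key <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
}

#' @export
print.random_ensemble <- function(x, ...) {
  cat(sprintf("random_ensemble: %d degree-preserving replicas (seed %d)\n",
              x$n, x$seed))
  cat(sprintf("  mean betweenness: real %.3f; null %.3f [%.3f, %.3f]\n",
              x$real_mean_betweenness, mean(x$summary$mean_betweenness),
              stats::quantile(x$summary$mean_betweenness, 0.025),
              stats::quantile(x$summary$mean_betweenness, 0.975)))
  cat(sprintf("  empirical quantile of the real value: %.3f\n", x$quantile))
  invisible(x)
}

#' Null-distribution plot for a random ensemble
#'
#' Density of the per-replica mean betweenness with the observed network's
#' value marked, the standard visual check that the real topology departs
#' from the degree-preserving null.
#'
#' @param x a [random_ensemble()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.random_ensemble <- function(x, ...) {
  dens <- stats::density(x$summary$mean_betweenness)
  graphics::plot(dens, main = "Mean betweenness: real vs degree-preserving null",
                 xlab = "mean betweenness",
                 xlim = range(c(dens$x, x$real_mean_betweenness)), ...)
  graphics::abline(v = x$real_mean_betweenness, col = 2, lwd = 2)
  graphics::legend("topright", legend = c("null density", "observed"),
                   col = c(1, 2), lwd = c(1, 2), cex = 0.8)
  invisible(x)
}

#' Compare an observed network with its random ensemble
#'
#' Records the per-replica mean betweenness, the observed network's mean
#' betweenness, and the empirical quantile of the observed value within the
#' ensemble, under the convention
#' `quantile = #\{replicas with mean <= observed\} / n`.
#'
#' @param net the observed network ([ppi_network()] or \pkg{igraph} graph).
#' @param ensemble a [random_ensemble()] built from the same network.
#' @return List with `replicate_means`, `real_mean_betweenness`, `quantile`,
#'   `n`, `seed`.
#' @export
compare_real_vs_random <- function(net, ensemble) {
  if (!inherits(ensemble, "random_ensemble")) stop("not a random_ensemble")
  g <- as_network_graph(net)
  real <- mean(igraph::betweenness(g, directed = FALSE))
  means <- ensemble$summary$mean_betweenness
  list(replicate_means = means, real_mean_betweenness = real,
       quantile = sum(means <= real) / length(means),
       n = length(means), seed = ensemble$seed)
}

#' Export a network
#'
#' Writes the retained edge list (with per-channel scores) as TSV, and the
#' graph itself in GraphML.
#'
#' @param net a [ppi_network()].
#' @param path output path (TSV); for `write_network_graphml`, the GraphML
#'   path.
#' @return The path, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_network_graph(net), path, format = "graphml")
  invisible(path)
}
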