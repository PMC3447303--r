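#' Ensemble specification for artificial network architectures
#'
#' Describes one of the four architecture families compared in the analysis:
#' `regular` (ring lattice, rewiring probability P = 0), `small-world`
#' (Watts-Strogatz rewiring, P = 0.25 by convention), `random` (P = 1) and
#' `scale-free` (Barabasi-Albert preferential attachment). All families are
#' post-matched to exactly `edges` edges so that architectures differ only in
#' topology, not density.
#'
#' @param topology one of "regular", "small-world", "random", "scale-free".
#' @param n node count.
#' @param edges exact undirected edge count; must satisfy
#'   n - 1 <= edges <= n(n-1)/2 when connectivity is required.
#' @param rewire_p Watts-Strogatz rewiring probability; forced to 0 for
#'   regular and 1 for random, default 0.25 for small-world.
#' @param instances ensemble size (the reference configuration uses 100).
#' @param seed integer master seed; per-instance seeds are derived from it.
#' @param connected require connected graphs (default TRUE).
#' @return a list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(topology = c("regular", "small-world", "random",
                                       "scale-free"),
                          n, edges, rewire_p = NULL, instances = 1L,
                          seed = 1L, connected = TRUE) {
  topology <- match.arg(topology)
  n <- as.integer(n)
  edges <- as.integer(edges)
  if (edges > n * (n - 1) / 2)
    stop(sprintf("edges = %d exceeds the maximum %d for n = %d",
                 edges, n * (n - 1) %/% 2, n))
  if (connected && edges < n - 1)
    stop(sprintf("edges = %d cannot connect %d nodes (need >= %d)",
                 edges, n, n - 1))
  rewire_p <- switch(topology,
    regular = 0, random = 1,
    `small-world` = if (is.null(rewire_p)) 0.25 else rewire_p,
    `scale-free` = NA_real_)
  if (!is.na(rewire_p) && (rewire_p < 0 || rewire_p > 1))
    stop("rewire_p must be in [0, 1]")
  structure(list(topology = topology, n = n, edges = edges,
                 rewire_p = rewire_p, instances = as.integer(instances),
                 seed = as.integer(seed), connected = connected),
            class = "ensemble_spec")
}

# Deterministic per-instance seed from the master seed; stays below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                as.double(index) * 104729) %% 2147483647)
}

as_igraph <- function(c) {
  igraph::graph_from_adjacency_matrix(c$weights, mode = "undirected",
                                      weighted = if (all(c$weights %in% c(0, 1))) NULL else TRUE)
}

graph_to_connectome <- function(g, labels = NULL) {
  m <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  m[m > 0] <- 1
  connectome(m, labels = labels)
}

#' Generate one artificial network
#'
#' Small-world family: a ring lattice whose even degree is nearest the
#' target mean degree 2*edges/n, rewired with probability `rewire_p`;
#' scale-free: preferential attachment with m = 2. The result is then
#' repaired to exactly `spec$edges` edges by [match_edge_count()], and
#' regenerated (bounded retries) if connectivity is required but lost.
#'
#' @param spec an [ensemble_spec()].
#' @param instance_seed integer seed for this instance.
#' @return a binary `connectome` with exactly `spec$edges` edges.
#' @export
generate_network <- function(spec, instance_seed = spec$seed) {
  for (attempt in 0:49) {
    s <- derive_seed(instance_seed, attempt)
    set.seed(s)
    g <- if (spec$topology == "scale-free") {
      igraph::sample_pa(spec$n, m = 2, directed = FALSE)
    } else {
      nei <- max(1L, round(spec$edges / spec$n))
      igraph::sample_smallworld(1, spec$n, nei, spec$rewire_p)
    }
    g <- igraph::simplify(g)
    g <- try(match_edge_count_graph(g, spec$edges, seed = derive_seed(s, 1L),
                                    connected = spec$connected),
             silent = TRUE)
    if (inherits(g, "try-error")) next
    if (!spec$connected || igraph::is_connected(g))
      return(graph_to_connectome(g))
  }
  stop(sprintf("failed to generate a %s network with n = %d, edges = %d",
               spec$topology, spec$n, spec$edges))
}

match_edge_count_graph <- function(g, target, seed, connected = TRUE) {
  n <- igraph::vcount(g)
  if (target > n * (n - 1) / 2 || (connected && target < n - 1))
    stop("infeasible target edge count")
  set.seed(seed)
  tries <- 0L
  while (igraph::ecount(g) != target) {
    tries <- tries + 1L
    if (tries > 200L * n) stop("edge-count repair exceeded retry budget")
    m <- igraph::ecount(g)
    if (m < target) {
      comp <- igraph::complementer(g)
      ce <- igraph::as_edgelist(comp, names = FALSE)
      pick <- ce[sample.int(nrow(ce), 1L), ]
      g <- igraph::add_edges(g, pick)
    } else {
      eid <- sample.int(m, 1L)
      g2 <- igraph::delete_edges(g, eid)
      if (connected && !igraph::is_connected(g2)) next
      g <- g2
    }
  }
  g
}

#' Adjust a binary graph to an exact edge count
#'
#' Uniformly random single-edge additions/deletions until the target is
#' reached; deletions that would disconnect the graph are rejected and
#' resampled (bounded retries). Needed because the standard generators
#' cannot hit an arbitrary edge count (e.g., 38 edges at 20 nodes) exactly.
#'
#' @param g a binary `connectome`.
#' @param target desired edge count.
#' @param seed integer seed.
#' @param connected reject disconnecting deletions (default TRUE).
#' @return a binary `connectome` with exactly `target` edges.
#' @export
match_edge_count <- function(g, target, seed = 1L, connected = TRUE) {
  ig <- match_edge_count_graph(as_igraph(g), target, seed, connected)
  graph_to_connectome(ig, labels = g$labels)
}

#' Generate a reproducible ensemble of networks
#'
#' @param spec an [ensemble_spec()].
#' @return list of `spec$instances` binary connectomes; instance i uses the
#'   seed derived deterministically from `spec$seed` and i, so the same spec
#'   always yields the same ensemble.
#' @export
generate_ensemble <- function(spec) {
  lapply(seq_len(spec$instances), function(i)
    generate_network(spec, derive_seed(spec$seed, i)))
}

#' Normalized shortest-path betweenness centrality
#'
#' Betweenness on the unweighted graph, normalized by (N-1)(N-2)/2 so that
#' the centre of a path graph scores 1. Disconnected graphs are allowed;
#' unreachable pairs contribute nothing.
#'
#' @param g a binary (or binarized) `connectome`.
#' @return numeric vector of length N with values in [0, 1].
#' @export
betweenness_centrality <- function(g) {
  ig <- as_igraph(binarize(g))
  b <- igraph::betweenness(ig, directed = FALSE, normalized = TRUE)
  unname(b)
}
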