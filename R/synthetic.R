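#' Specification for a synthetic structural connectome
#'
#' Describes a weighted, modular, hemispherically mirrored, hub-containing
#' connectome emulating the qualitative features of an averaged human DSI
#' matrix: clusters of nodes more densely connected inside than outside,
#' homotopic mirror symmetry between hemispheres with weaker
#' inter-hemispheric links, a few high-degree hub nodes, and log-normally
#' distributed positive fiber-density weights. It is a stand-in with known
#' ground truth, not a quantitative reproduction of any empirical matrix.
#'
#' The default configuration (N = 16, 4 modules, mirrored, 2 hubs) is small
#' enough for exact enumeration in tests while keeping every qualitative
#' feature.
#'
#' @param n even node count (default 16).
#' @param n_modules total module count, even when mirrored (default 4).
#' @param p_intra within-module connection probability (default 0.9); must
#'   exceed `p_inter`.
#' @param p_inter between-module connection probability (default 0.15).
#' @param n_hubs number of hub nodes, even when mirrored (default 2).
#' @param hub_boost extra probability of connecting a hub to each
#'   non-neighbor (default 0.3).
#' @param weight_meanlog,weight_sdlog log-normal weight parameters
#'   (defaults -0.5, 0.5).
#' @param mirror homotopic two-hemisphere symmetry (default TRUE).
#' @param inter_scale weight scale of inter-hemispheric links relative to
#'   intra-hemispheric ones (default 0.5).
#' @param seed integer seed.
#' @return list of class `synth_connectome_spec`.
#' @export
synth_connectome_spec <- function(n = 16L, n_modules = 4L, p_intra = 0.9,
                                  p_inter = 0.15, n_hubs = 2L,
                                  hub_boost = 0.3, weight_meanlog = -0.5,
                                  weight_sdlog = 0.5, mirror = TRUE,
                                  inter_scale = 0.5, seed = 1L) {
  if (p_intra <= p_inter)
    stop("modularity requires p_intra > p_inter")
  if (n %% 2 != 0) stop("n must be even")
  if (mirror && (n_modules %% 2 != 0 || n_hubs %% 2 != 0))
    stop("mirrored connectomes need even module and hub counts")
  structure(list(n = as.integer(n), n_modules = as.integer(n_modules),
                 p_intra = p_intra, p_inter = p_inter,
                 n_hubs = as.integer(n_hubs), hub_boost = hub_boost,
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog, mirror = mirror,
                 inter_scale = inter_scale, seed = as.integer(seed)),
            class = "synth_connectome_spec")
}

# one hemisphere (or the whole brain when mirror = FALSE): modular blocks
# with hub nodes of elevated degree; returns a weighted adjacency matrix
synth_hemisphere <- function(nh, n_modules, p_intra, p_inter, n_hubs,
                             hub_boost, mlog, slog) {
  modules <- rep(seq_len(n_modules), length.out = nh)
  modules <- sort(modules)
  adj <- matrix(0, nh, nh)
  hubs <- if (n_hubs > 0)
    round(seq(1, nh, length.out = n_hubs + 2))[2:(n_hubs + 1)]
  else integer(0)
  for (i in seq_len(nh - 1)) {
    for (j in seq(i + 1, nh)) {
      p <- if (modules[i] == modules[j]) p_intra else p_inter
      if (i %in% hubs || j %in% hubs) p <- min(1, p + hub_boost)
      if (stats::runif(1) < p)
        adj[i, j] <- adj[j, i] <- stats::rlnorm(1, mlog, slog)
    }
  }
  list(adj = adj, modules = modules, hubs = hubs)
}

#' Generate a synthetic structural connectome
#'
#' @param spec a [synth_connectome_spec()].
#' @return a weighted `connectome` with hemisphere tags (when mirrored) and
#'   attributes `modules` and `hubs`; connectivity is repaired by linking
#'   disconnected components with median-weight edges if needed.
#' @export
synth_connectome <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n
  if (spec$mirror) {
    nh <- n %/% 2L
    hemi <- synth_hemisphere(nh, spec$n_modules %/% 2L, spec$p_intra,
                             spec$p_inter, spec$n_hubs %/% 2L,
                             spec$hub_boost, spec$weight_meanlog,
                             spec$weight_sdlog)
    w <- matrix(0, n, n)
    w[1:nh, 1:nh] <- hemi$adj
    w[(nh + 1):n, (nh + 1):n] <- hemi$adj  # homotopic mirror copy
    # homotopic callosal links plus sparse random cross links, both weaker
    med <- stats::median(hemi$adj[hemi$adj > 0])
    for (i in seq_len(nh))
      w[i, i + nh] <- w[i + nh, i] <- spec$inter_scale * med
    for (i in seq_len(nh)) {
      for (j in seq_len(nh)) {
        if (j != i && stats::runif(1) < spec$p_inter / 2) {
          v <- spec$inter_scale * stats::rlnorm(1, spec$weight_meanlog,
                                                spec$weight_sdlog)
          w[i, j + nh] <- w[j + nh, i] <- v
        }
      }
    }
    hemisphere <- rep(c("left", "right"), each = nh)
    modules <- c(hemi$modules, hemi$modules + max(hemi$modules))
    hubs <- c(hemi$hubs, hemi$hubs + nh)
  } else {
    hemi <- synth_hemisphere(n, spec$n_modules, spec$p_intra, spec$p_inter,
                             spec$n_hubs, spec$hub_boost,
                             spec$weight_meanlog, spec$weight_sdlog)
    w <- hemi$adj
    hemisphere <- NULL
    modules <- hemi$modules
    hubs <- hemi$hubs
  }
  # connectivity repair: bridge components with median-weight edges
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    med <- stats::median(w[w > 0])
    for (k in seq(2, comp$no)) {
      i <- which(comp$membership == 1)[1]
      j <- which(comp$membership == k)[1]
      w[i, j] <- w[j, i] <- med
    }
  }
  out <- connectome(w, hemisphere = hemisphere)
  attr(out, "modules") <- modules
  attr(out, "hubs") <- hubs
  out
}

#' Synthetic "empirical" functional connectivity with known ground truth
#'
#' Computes the model FC of `true_sc` at its edge of bifurcation, then
#' perturbs every upper-triangle entry with Gaussian noise on the Fisher-z
#' scale (so perturbed correlations stay inside (-1, 1) without hard
#' truncation artifacts), back-transforms, symmetrizes, clips to
#' [-0.999, 0.999] and sets the diagonal to 1.
#'
#' @param true_sc the ground-truth structural `connectome`.
#' @param p_base an [ising_params()].
#' @param noise_sd Gaussian noise s.d. on the Fisher-z scale (>= 0).
#' @param seed integer seed for the noise.
#' @param W_grid coupling grid for the underlying sweep.
#' @return list: `fc` (noisy FC matrix), `w_star` (ground-truth coupling),
#'   `noise_sd`, `seed`.
#' @export
synth_empirical_fc <- function(true_sc, p_base = ising_params(),
                               noise_sd = 0.2, seed = 1L,
                               W_grid = default_w_grid()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mf <- model_fc(true_sc, p_base, W_grid)
  fc <- mf$fc
  if (noise_sd > 0) {
    set.seed(seed)
    ut <- upper.tri(fc)
    z <- atanh(pmin(pmax(fc[ut], -0.999), 0.999))
    z <- z + stats::rnorm(sum(ut), sd = noise_sd)
    fc[ut] <- tanh(z)
    fc[lower.tri(fc)] <- t(fc)[lower.tri(fc)]
    fc <- pmin(pmax(fc, -0.999), 0.999)
  }
  diag(fc) <- 1
  list(fc = fc, w_star = mf$w_star, noise_sd = noise_sd,
       seed = as.integer(seed))
}

#' Default coupling grid for sweeps on weighted synthetic connectomes
#'
#' Spans from the independent-spin regime to well past the coupling at
#' which the fully active state dominates, scaled by connectome strength:
#' the grid top is ~3x the coupling that balances the threshold term
#' against the mean total input.
#'
#' @param c optional `connectome` used to scale the grid; without it a
#'   generic 0-24 range is used (theta = 12 reference point).
#' @param theta threshold (default 12).
#' @param points grid length (default 41).
#' @return strictly increasing numeric vector starting at 0.
#' @export
default_w_grid <- function(c = NULL, theta = 12, points = 41L) {
  top <- if (is.null(c)) 2 * theta else {
    str <- mean(rowSums(c$weights))
    3 * theta / max(str, .Machine$double.eps)
  }
  seq(0, top, length.out = points)
}

#' Degree-preserving rewiring of a connectome
#'
#' Null model for ground-truth recovery tests: the binary support is
#' rewired by double-edge swaps (10x the edge count), preserving every
#' node's degree, and the original multiset of edge weights is reassigned
#' to the new edges in random order.
#'
#' @param c a `connectome`.
#' @param seed integer seed.
#' @return a rewired `connectome` with the same degree sequence and weight
#'   multiset.
#' @export
rewire_degree_preserving <- function(c, seed = 1L) {
  set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(c$weights > 0, mode = "undirected")
  g <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
  m <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  wvals <- c$weights[upper.tri(c$weights)]
  wvals <- sample(wvals[wvals > 0])
  out <- matrix(0, n_nodes(c), n_nodes(c))
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    out[idx[k, 1], idx[k, 2]] <- wvals[k]
    out[idx[k, 2], idx[k, 1]] <- wvals[k]
  }
  connectome(out, labels = c$labels, hemisphere = c$hemisphere)
}
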