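#' Exact pairwise mutual information and correlation
#'
#' Because the Boltzmann distribution is known exactly, the 2x2 joint law of
#' every spin pair follows from the enumerated marginals and pairwise
#' joints: p11 directly, p10/p01/p00 by marginal subtraction. Mutual
#' information is sum p(a,b) log[p(a,b)/(p(a)p(b))] in nats with
#' 0 log 0 := 0; the correlation is the Pearson correlation of the two
#' binary spins, (p11 - p_i p_j)/sqrt(p_i(1-p_i) p_j(1-p_j)), defined as 0
#' when either spin has zero variance (which happens at extreme couplings).
#' The MI diagonal stores each node's marginal entropy (a convenient
#' normalizer); it is excluded from pooled distributions.
#'
#' @param c a `connectome`.
#' @param p an [ising_params()].
#' @param summary optionally, a precomputed [boltzmann_summary()] for (c, p).
#' @param chunk_size,max_n passed to [boltzmann_summary()].
#' @return list of class `pair_stats`: `mi` (N x N, nats), `corr` (N x N),
#'   `marginals`, `W_at`, `params`.
#' @export
pair_stats <- function(c, p, summary = NULL, chunk_size = 65536L,
                       max_n = enumeration_cap()) {
  if (is.null(summary))
    summary <- boltzmann_summary(c, p, chunk_size = chunk_size, max_n = max_n)
  m <- summary$marginals
  n <- summary$n
  p11 <- summary$joint11
  pi_ <- matrix(m, n, n)  # pi_[i,j] = p_i
  pj_ <- t(pi_)           # pj_[i,j] = p_j
  p10 <- pi_ - p11
  p01 <- pj_ - p11
  p00 <- 1 - pi_ - pj_ + p11
  # 0 log 0 := 0; a (numerically) non-positive cell probability or marginal
  # product carries no contribution -- the limit is 0 in either case
  xlx <- function(num, den) {
    ok <- num > 0 & den > 0
    out <- array(0, dim(num))
    out[ok] <- num[ok] * log(num[ok] / den[ok])
    out
  }
  mi <- xlx(p11, pi_ * pj_) + xlx(p10, pi_ * (1 - pj_)) +
    xlx(p01, (1 - pi_) * pj_) + xlx(p00, (1 - pi_) * (1 - pj_))
  mi[mi < 0] <- pmax(mi[mi < 0], -1e-12)  # clip enumeration round-off
  mi <- (mi + t(mi)) / 2                  # exact symmetry despite fp ordering
  hbin <- -ifelse(m > 0, m * log(m), 0) - ifelse(m < 1, (1 - m) * log(1 - m), 0)
  diag(mi) <- hbin
  v <- m * (1 - m)
  denom <- sqrt(outer(v, v))
  corr <- ifelse(denom > 0, (p11 - pi_ * pj_) / denom, 0)
  diag(corr) <- ifelse(v > 0, 1, 0)
  corr <- pmin(pmax(corr, -1), 1)
  structure(list(mi = mi, corr = corr, marginals = m, W_at = p$W,
                 params = p),
            class = "pair_stats")
}

#' Pooled distribution of pairwise association values
#'
#' Pools the strictly-upper-triangle values of a measure over a list of
#' `pair_stats` (e.g., one per ensemble instance) and summarizes them with a
#' logarithmically binned histogram and the empirical survival function —
#' the form in which a power-law tail is visible.
#'
#' @param stats_list nonempty list of `pair_stats`.
#' @param measure "mi" (default) or "corr".
#' @param bins number of logarithmic bins over the positive values.
#' @return list: `values` (pooled vector), `hist` (data.frame bin_lo,
#'   bin_hi, count, density over positive values), `survival` (data.frame
#'   x, s with s = P(X >= x), nonincreasing).
#' @export
pair_value_distribution <- function(stats_list, measure = c("mi", "corr"),
                                    bins = 24L) {
  measure <- match.arg(measure)
  if (length(stats_list) == 0) stop("empty stats list")
  values <- unlist(lapply(stats_list, function(ps) {
    m <- ps[[measure]]
    m[upper.tri(m)]
  }), use.names = FALSE)
  pos <- values[values > 0]
  hist <- NULL
  if (length(pos) > 0) {
    lo <- min(pos)
    hi <- max(pos)
    brk <- if (hi > lo) exp(seq(log(lo), log(hi), length.out = bins + 1L))
           else c(lo * 0.999, hi * 1.001)
    brk[1] <- brk[1] * (1 - 1e-12)
    cnt <- tabulate(findInterval(pos, brk, rightmost.closed = TRUE),
                    nbins = length(brk) - 1L)
    hist <- data.frame(bin_lo = brk[-length(brk)], bin_hi = brk[-1],
                       count = cnt,
                       density = cnt / (diff(brk) * length(pos)))
  }
  xs <- sort(unique(values))
  # P(X >= x) at each unique x; counts strictly below x via cumulative sums
  below <- c(0, cumsum(tabulate(match(sort(values), xs), length(xs))))
  s <- 1 - below[seq_along(xs)] / length(values)
  list(values = values, hist = hist,
       survival = data.frame(x = xs, s = s))
}

#' Ensemble entropy-versus-coupling curves
#'
#' Runs [entropy_sweep()] on every instance of an ensemble and reports the
#' per-coupling mean and standard deviation of entropy across instances,
#' plus each instance's maximal entropy over the grid.
#'
#' @param ensemble list of `connectome`s, all with the same node count.
#' @param p_base an [ising_params()] (theta, epsilon, convention).
#' @param W_grid strictly increasing coupling grid.
#' @param topology optional tag carried into the output.
#' @param chunk_size passed to [entropy_sweep()].
#' @return list of class `ensemble_entropy_curve`: `topology`, `W`, `mean`,
#'   `sd`, `max_per_instance`, `entropy` (instances x grid matrix).
#' @export
ensemble_entropy_curves <- function(ensemble, p_base, W_grid,
                                    topology = NA_character_,
                                    chunk_size = 65536L) {
  stopifnot(length(ensemble) > 0)
  ns <- vapply(ensemble, n_nodes, integer(1))
  if (length(unique(ns)) != 1) stop("all instances must have the same N")
  E <- t(vapply(ensemble, function(g)
    entropy_sweep(g, p_base, W_grid, chunk_size = chunk_size)$entropy,
    numeric(length(W_grid))))
  structure(list(topology = topology, W = W_grid,
                 mean = colMeans(E),
                 sd = apply(E, 2, stats::sd),
                 max_per_instance = apply(E, 1, max),
                 entropy = E),
            class = "ensemble_entropy_curve")
}

#' Mean maximal entropy as a function of network size
#'
#' For each architecture and size, generates an ensemble at fixed mean
#' degree (edges = round(mean_degree * N / 2), so the number of connections
#' per node is held constant as N grows), sweeps the coupling grid, and
#' reports the ensemble mean of the per-instance maximal entropy.
#'
#' @param topologies character vector of architecture names.
#' @param N_list integer vector of network sizes (within the enumeration cap).
#' @param mean_degree target mean degree (default 3.8, the 20-node/38-edge
#'   reference density).
#' @param p_base an [ising_params()].
#' @param W_grid coupling grid.
#' @param instances instances per (topology, N).
#' @param seed master seed.
#' @return data.frame (topology, N, edges, mean_max_entropy), sorted by N
#'   within topology.
#' @export
max_entropy_vs_size <- function(topologies, N_list, mean_degree = 3.8,
                                p_base = ising_params(), W_grid,
                                instances = 20L, seed = 1L) {
  rows <- list()
  for (topo in topologies) {
    for (n in sort(as.integer(N_list))) {
      edges <- as.integer(round(mean_degree * n / 2))
      spec <- ensemble_spec(topo, n = n, edges = edges,
                            instances = instances,
                            seed = derive_seed(seed, n + 1000L *
                                                 match(topo, topologies)))
      ens <- generate_ensemble(spec)
      cur <- ensemble_entropy_curves(ens, p_base, W_grid, topology = topo)
      rows[[length(rows) + 1L]] <-
        data.frame(topology = topo, N = n, edges = edges,
                   mean_max_entropy = mean(cur$max_per_instance))
    }
  }
  do.call(rbind, rows)
}
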