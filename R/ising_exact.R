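#' Ising model parameters
#'
#' Global parameters of the stochastic spin network: every node carries a
#' binary state S in {0,1}, units are coupled through the connectivity
#' matrix C scaled by the global coupling W, activation is opposed by the
#' threshold theta, and epsilon is an inverse temperature setting the noise
#' level. Defaults theta = 12, W = 1 are the reference operating point.
#'
#' The energy of a configuration S is
#'   H = (theta/2) * sum_i S_i - (W/2) * sum_{i,j} C_ij S_i S_j
#' (full double sum over ordered pairs). `energy_convention = "full_theta"`
#' replaces theta/2 by theta in the first term; it exists for sensitivity
#' checks because the Glauber field and the energy function are stated with
#' inconsistent theta scalings, and the analytics here follow the energy as
#' written (`half_theta`).
#'
#' @param W global coupling strength (dimensionless), default 1.
#' @param theta activation threshold, default 12.
#' @param epsilon inverse temperature, must be > 0; default 1 (no value is
#'   canonical; it is always reported explicitly).
#' @param energy_convention "half_theta" (default) or "full_theta".
#' @return list of class `ising_params`.
#' @export
ising_params <- function(W = 1, theta = 12, epsilon = 1,
                         energy_convention = c("half_theta", "full_theta")) {
  energy_convention <- match.arg(energy_convention)
  if (epsilon <= 0) stop("epsilon (inverse temperature) must be > 0")
  structure(list(W = W, theta = theta, epsilon = epsilon,
                 energy_convention = energy_convention),
            class = "ising_params")
}

theta_factor <- function(p) if (p$energy_convention == "half_theta") 0.5 else 1

#' Energy of one spin configuration
#'
#' @param state binary vector in {0,1}^N, or a single bitmask integer
#'   (bit i-1 set = node i active).
#' @param c a `connectome`.
#' @param p an [ising_params()].
#' @return the scalar energy H of the configuration.
#' @export
energy <- function(state, c, p) {
  n <- n_nodes(c)
  if (length(state) == 1 && state >= 2 && n > 1)
    state <- bitmask_to_state(state, n)
  if (length(state) == 1 && n == 1) state <- as.numeric(state)
  if (length(state) != n)
    stop(sprintf("state has length %d, connectome has %d nodes",
                 length(state), n))
  s <- as.numeric(state)
  theta_factor(p) * p$theta * sum(s) -
    0.5 * p$W * drop(s %*% c$weights %*% s)
}

bitmask_to_state <- function(mask, n) {
  as.numeric(bitwAnd(rep(as.integer(mask), n),
                     bitwShiftL(1L, seq_len(n) - 1L)) != 0)
}

# chunk x n binary state matrix for bitmasks `masks` (integers < 2^n)
state_matrix <- function(masks, n) {
  out <- vapply(seq_len(n) - 1L,
                function(b) as.numeric(bitwAnd(masks, bitwShiftL(1L, b)) != 0),
                numeric(length(masks)))
  matrix(out, nrow = length(masks), ncol = n)
}

enumeration_cap <- function() 28L

# iterate chunks of bitmasks 0 .. 2^n - 1, calling f(masks) per chunk
for_each_chunk <- function(n, chunk_size, f) {
  total <- 2^n
  start <- 0
  while (start < total) {
    len <- min(chunk_size, total - start)
    f(as.integer(seq(start, length.out = len)))
    start <- start + len
  }
  invisible(NULL)
}

#' Exact Boltzmann-Gibbs summary of a spin network
#'
#' Enumerates all 2^N configurations in chunks of bitmasks, accumulating the
#' log partition function by streaming log-sum-exp (running maximum), and in
#' the same pass the mean energy, single-spin marginals P(S_i = 1) and the
#' pairwise joints P(S_i = 1, S_j = 1). The attractor-landscape entropy is
#' the Shannon entropy of the Boltzmann distribution, computed through the
#' identity  entropy = epsilon * <H> + log Z  (nats).
#'
#' @param c a `connectome`.
#' @param p an [ising_params()].
#' @param chunk_size states per chunk (default 2^16).
#' @param max_n enumeration cap (default 28); larger systems must be
#'   subsampled by the caller.
#' @param moments if FALSE, skip marginals/joints (entropy and logZ only).
#' @return list of class `boltzmann_summary`: `logZ`, `entropy` (nats),
#'   `meanH`, `marginals` (length N), `joint11` (N x N), `n`, `params`.
#' @export
boltzmann_summary <- function(c, p, chunk_size = 65536L,
                              max_n = enumeration_cap(), moments = TRUE) {
  n <- n_nodes(c)
  if (n > max_n)
    stop(sprintf(paste0("N = %d exceeds the enumeration cap %d; subsample ",
                        "nodes or raise max_n explicitly"), n, max_n))
  if (chunk_size < 1) stop("chunk_size must be >= 1")
  tfac <- theta_factor(p)
  C <- c$weights
  eps <- p$epsilon

  m_run <- -Inf      # running max of -eps * H
  z_run <- 0         # sum of exp(-eps*H - m_run)
  h_run <- 0         # sum of H * exp(-eps*H - m_run)
  marg_run <- numeric(n)
  joint_run <- matrix(0, n, n)

  for_each_chunk(n, chunk_size, function(masks) {
    S <- state_matrix(masks, n)
    a <- rowSums(S)
    q <- rowSums((S %*% C) * S)
    H <- tfac * p$theta * a - 0.5 * p$W * q
    if (any(!is.finite(H))) stop("non-finite energy encountered")
    le <- -eps * H
    m_new <- max(m_run, max(le))
    scale <- exp(m_run - m_new)
    w <- exp(le - m_new)
    z_run <<- z_run * scale + sum(w)
    h_run <<- h_run * scale + sum(H * w)
    if (moments) {
      marg_run <<- marg_run * scale + colSums(S * w)
      joint_run <<- joint_run * scale + crossprod(S * sqrt(w))
    }
    m_run <<- m_new
  })

  logZ <- m_run + log(z_run)
  meanH <- h_run / z_run
  marginals <- if (moments) marg_run / z_run else NULL
  joint11 <- if (moments) joint_run / z_run else NULL
  if (moments) diag(joint11) <- marginals
  structure(list(logZ = logZ, entropy = eps * meanH + logZ, meanH = meanH,
                 marginals = marginals, joint11 = joint11, n = n,
                 params = p),
            class = "boltzmann_summary")
}

#' @export
print.boltzmann_summary <- function(x, ...) {
  cat(sprintf(paste0("boltzmann_summary: N = %d, W = %g, theta = %g, ",
                     "epsilon = %g\n  logZ = %.6f, entropy = %.6f nats, ",
                     "<H> = %.6f\n"),
              x$n, x$params$W, x$params$theta, x$params$epsilon,
              x$logZ, x$entropy, x$meanH))
  invisible(x)
}

#' Entropy as a function of global coupling strength
#'
#' Sweeps W over a grid, reusing the per-configuration activation counts and
#' coupling quadratic forms across the grid (both are independent of W and
#' theta), so the cost of the whole sweep is one enumeration pass plus one
#' cheap reduction per grid point.
#'
#' @param c a `connectome`.
#' @param p_base [ising_params()] providing theta, epsilon, convention.
#' @param W_grid strictly increasing numeric vector of couplings.
#' @param chunk_size states per chunk.
#' @param max_n enumeration cap.
#' @return data.frame with columns `W`, `entropy` (nats), `logZ`, `meanH`.
#' @export
entropy_sweep <- function(c, p_base, W_grid, chunk_size = 65536L,
                          max_n = enumeration_cap()) {
  if (length(W_grid) == 0) stop("W_grid must be nonempty")
  if (length(W_grid) > 1 && any(diff(W_grid) <= 0))
    stop("W_grid must be strictly increasing")
  n <- n_nodes(c)
  if (n > max_n)
    stop(sprintf("N = %d exceeds the enumeration cap %d", n, max_n))
  tfac <- theta_factor(p_base)
  eps <- p_base$epsilon
  C <- c$weights
  G <- length(W_grid)

  m_run <- rep(-Inf, G)
  z_run <- numeric(G)
  h_run <- numeric(G)

  for_each_chunk(n, chunk_size, function(masks) {
    S <- state_matrix(masks, n)
    a <- tfac * p_base$theta * rowSums(S)
    q <- 0.5 * rowSums((S %*% C) * S)
    for (g in seq_len(G)) {
      H <- a - W_grid[g] * q
      le <- -eps * H
      m_new <- max(m_run[g], max(le))
      scale <- exp(m_run[g] - m_new)
      w <- exp(le - m_new)
      z_run[g] <<- z_run[g] * scale + sum(w)
      h_run[g] <<- h_run[g] * scale + sum(H * w)
      m_run[g] <<- m_new
    }
  })

  logZ <- m_run + log(z_run)
  meanH <- h_run / z_run
  data.frame(W = W_grid, entropy = eps * meanH + logZ, logZ = logZ,
             meanH = meanH)
}

#' Locate the edge of bifurcation on an entropy sweep
#'
#' The relevant bifurcation separating the trivial all-inactive regime from
#' the multi-attractor regime shows up as the region where entropy starts
#' its rapid rise. This locator returns the grid coupling with the largest
#' forward difference in entropy on the rising flank (all grid points at or
#' below the entropy argmax), ties broken toward smaller W.
#'
#' @param sweep data.frame with columns `W` and `entropy` (from
#'   [entropy_sweep()]).
#' @return the coupling W* at the steepest rise.
#' @export
find_edge_of_bifurcation <- function(sweep) {
  if (nrow(sweep) < 3) stop("need at least 3 grid points")
  e <- sweep$entropy
  W <- sweep$W
  imax <- which.max(e)
  if (imax == 1L || imax == length(e) || diff(range(e)) == 0)
    stop("entropy sweep has no interior maximum (flat or monotone)")
  d <- diff(e[seq_len(imax)]) / diff(W[seq_len(imax)])
  W[which.max(d)]
}
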