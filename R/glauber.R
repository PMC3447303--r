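#' Probability that a site resamples to the active state
#'
#' The stochastic update rule sets S_i = 1 with probability
#' g(W * sum_j C_ij S_j - theta_eff), g(x) = 1/(1 + exp(-epsilon x)).
#' `paper_literal` mode uses theta_eff = theta (the update rule as usually
#' written); `energy_consistent` mode uses theta_eff = theta/2, the
#' heat-bath probability whose stationary distribution is the Boltzmann law
#' of the half-theta energy used by the exact analytics. The two coincide
#' when theta = 0.
#'
#' @param state binary vector, current configuration.
#' @param i site index (1-based).
#' @param c a `connectome`.
#' @param p an [ising_params()].
#' @param mode "energy_consistent" (default) or "paper_literal".
#' @return probability in [0, 1].
#' @export
flip_probability <- function(state, i, c, p,
                             mode = c("energy_consistent", "paper_literal")) {
  mode <- match.arg(mode)
  n <- n_nodes(c)
  if (i < 1 || i > n) stop("site index out of range")
  theta_eff <- if (mode == "paper_literal") p$theta else p$theta / 2
  x <- p$W * sum(c$weights[i, ] * state) - theta_eff
  1 / (1 + exp(-p$epsilon * x))
}

#' Run an asynchronous Glauber chain
#'
#' Heat-bath dynamics: each step picks one uniformly random site and
#' resamples it via [flip_probability()] regardless of its current value;
#' one sweep is N steps. The state bitmask is recorded after every step, so
#' consecutive recorded states differ in at most one bit. The chain is
#' reproducible from `seed` (a single RNG stream; site choice and the
#' Bernoulli draw consume it in fixed order).
#'
#' @param c a `connectome` (at most 31 nodes).
#' @param p an [ising_params()].
#' @param sweeps total sweeps, must exceed `burn_in`.
#' @param burn_in sweeps discarded from the front.
#' @param seed integer RNG seed.
#' @param mode see [flip_probability()].
#' @param init optional initial binary state (default all zeros).
#' @return list of class `glauber_trajectory`: `states` (integer bitmasks,
#'   post burn-in, one per step), `n`, `sweep_count`, `burn_in`, `seed`,
#'   `mode`.
#' @export
run_chain <- function(c, p, sweeps, burn_in = 0L, seed = 1L,
                      mode = c("energy_consistent", "paper_literal"),
                      init = NULL) {
  mode <- match.arg(mode)
  if (burn_in < 0 || sweeps <= burn_in)
    stop("need sweeps > burn_in >= 0")
  n <- n_nodes(c)
  if (is.null(init)) init <- integer(n)
  if (length(init) != n || !all(init %in% c(0, 1)))
    stop("init must be a binary vector of length N")
  theta_eff <- if (mode == "paper_literal") p$theta else p$theta / 2
  set.seed(seed)
  states <- glauber_chain_cpp(c$weights, p$W, theta_eff, p$epsilon,
                              as.integer(sweeps), as.integer(init))
  states <- states[seq.int(burn_in * n + 1L, length(states))]
  structure(list(states = states, n = n, sweep_count = as.integer(sweeps),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 mode = mode),
            class = "glauber_trajectory")
}

#' Empirical per-node activation frequencies of a trajectory
#'
#' @param traj a `glauber_trajectory`.
#' @return numeric vector of length N: fraction of recorded steps in which
#'   each node is active.
#' @export
trajectory_marginals <- function(traj) {
  vapply(seq_len(traj$n) - 1L, function(b)
    mean(bitwAnd(traj$states, bitwShiftL(1L, b)) != 0), numeric(1))
}

#' Empirical distribution over global states
#'
#' @param traj a `glauber_trajectory`.
#' @param thin keep every `thin`-th recorded step (default 1).
#' @return named numeric vector: frequency of each visited state bitmask
#'   (names are the bitmask integers); sums to 1.
#' @export
empirical_state_distribution <- function(traj, thin = 1L) {
  s <- traj$states[seq.int(1L, length(traj$states), by = thin)]
  if (length(s) == 0) stop("empty trajectory")
  tab <- table(s)
  freq <- as.numeric(tab) / length(s)
  names(freq) <- names(tab)
  freq
}
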