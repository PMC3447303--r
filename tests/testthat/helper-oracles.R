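# Independent brute-force oracles, deliberately written without reusing the
# package's enumeration code paths: plain loops over explicit state vectors.

# all 2^n binary states as an (2^n x n) matrix, row order = bitmask order
all_states <- function(n) {
  S <- as.matrix(rev(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE])
  dimnames(S) <- NULL
  S
}

oracle_energy <- function(s, C, W, theta, half_theta = TRUE) {
  tf <- if (half_theta) 0.5 else 1
  tf * theta * sum(s) - 0.5 * W * sum(C * outer(s, s))
}

# full Boltzmann law by direct summation (no log-sum-exp, no chunking)
oracle_boltzmann <- function(C, W, theta, eps = 1, half_theta = TRUE) {
  n <- nrow(C)
  S <- all_states(n)
  H <- apply(S, 1, oracle_energy, C = C, W = W, theta = theta,
             half_theta = half_theta)
  u <- exp(-eps * (H - min(H)))
  P <- u / sum(u)
  logZ <- log(sum(u)) - eps * min(H)
  entropy <- -sum(ifelse(P > 0, P * log(P), 0))
  marginals <- colSums(S * P)
  joint11 <- t(S * P) %*% S
  diag(joint11) <- marginals
  list(P = P, H = H, logZ = logZ, entropy = entropy,
       marginals = marginals, joint11 = joint11,
       meanH = sum(P * H), states = S)
}

oracle_mi_pair <- function(P, S, i, j) {
  mi <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- sum(P[S[, i] == a & S[, j] == b])
    pa <- sum(P[S[, i] == a])
    pb <- sum(P[S[, j] == b])
    if (pab > 0) mi <- mi + pab * log(pab / (pa * pb))
  }
  mi
}

random_connectome <- function(n, p_edge = 0.4, weighted = FALSE, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (runif(1) < p_edge) {
      v <- if (weighted) runif(1, 0.2, 2) else 1
      w[i, j] <- w[j, i] <- v
    }
  }
  connectome(w)
}

binary_entropy <- function(p) {
  -ifelse(p > 0, p * log(p), 0) - ifelse(p < 1, (1 - p) * log(1 - p), 0)
}

default_theta12 <- function(W = 1) ising_params(W = W, theta = 12, epsilon = 1)
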