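test_that("energy matches hand evaluation and the oracle", {
  c2 <- connectome(matrix(c(0, 1, 1, 0), 2))
  p <- ising_params(W = 1, theta = 1, epsilon = 1)
  expect_equal(energy(c(0, 0), c2, p), 0)
  expect_equal(energy(c(1, 1), c2, p), 0)    # 0.5*1*2 - 0.5*1*2
  expect_equal(energy(c(1, 0), c2, p), 0.5)
  expect_equal(energy(c(0, 1), c2, p), 0.5)
  # full_theta convention doubles the threshold term
  pf <- ising_params(W = 1, theta = 1, epsilon = 1,
                     energy_convention = "full_theta")
  expect_equal(energy(c(1, 0), c2, pf), 1)
  expect_error(energy(c(1, 0, 1), c2, p), "length")
  # random weighted system vs oracle over all states
  g <- random_connectome(6, weighted = TRUE, seed = 3)
  pw <- ising_params(W = 1.7, theta = 2.3, epsilon = 1)
  S <- all_states(6)
  for (k in sample(nrow(S), 10)) {
    expect_equal(energy(S[k, ], g, pw),
                 oracle_energy(S[k, ], g$weights, 1.7, 2.3))
  }
})

test_that("single unbiased spin has logZ = entropy = ln 2", {
  c1 <- connectome(matrix(0, 1, 1))
  s <- boltzmann_summary(c1, ising_params(W = 0, theta = 0))
  expect_equal(s$logZ, log(2))
  expect_equal(s$entropy, log(2))
  expect_equal(s$marginals, 0.5)
})

test_that("chunked streaming equals naive enumeration on random graphs", {
  for (k in 1:20) {
    n <- sample(3:12, 1)
    g <- random_connectome(n, p_edge = 0.45, weighted = (k %% 2 == 0),
                           seed = 100 + k)
    W <- runif(1, 0, 4)
    theta <- runif(1, 0, 14)
    p <- ising_params(W = W, theta = theta, epsilon = 1)
    # deliberately small chunk size to exercise the streaming accumulator
    s <- boltzmann_summary(g, p, chunk_size = 17L)
    o <- oracle_boltzmann(g$weights, W, theta)
    expect_lt(abs(s$logZ - o$logZ), 1e-10)
    expect_lt(abs(s$entropy - o$entropy), 1e-10)
    expect_lt(abs(s$meanH - o$meanH), 1e-10)
    expect_lt(max(abs(s$marginals - o$marginals)), 1e-10)
    expect_lt(max(abs(s$joint11 - o$joint11)), 1e-10)
  }
})

test_that("Boltzmann probabilities normalize and joints obey bounds", {
  g <- random_connectome(9, seed = 8)
  p <- default_theta12(W = 2.5)
  s <- boltzmann_summary(g, p)
  o <- oracle_boltzmann(g$weights, 2.5, 12)
  expect_lt(abs(sum(o$P) - 1), 1e-10)
  expect_true(all(s$marginals >= 0 & s$marginals <= 1))
  expect_identical(s$joint11, t(s$joint11))
  expect_true(all(s$joint11 <= outer(s$marginals, s$marginals, pmin) + 1e-12))
  expect_equal(diag(s$joint11), s$marginals)
  expect_true(s$entropy >= 0 && s$entropy <= 9 * log(2))
  # entropy identity: entropy = eps*<H> + logZ by construction; cross-check
  # against the direct -sum P log P of the oracle
  expect_lt(abs(s$entropy - o$entropy), 1e-10)
})

test_that("W = 0 entropy equals the independent-spin closed form", {
  for (n in c(5, 20)) {
    g <- generate_network(ensemble_spec("small-world", n,
                                        round(1.9 * n), seed = n), 1)
    s <- boltzmann_summary(g, ising_params(W = 0, theta = 12, epsilon = 1),
                           moments = FALSE)
    p0 <- 1 / (1 + exp(12 / 2))
    expect_lt(abs(s$entropy - n * binary_entropy(p0)), 1e-9)
  }
})

test_that("node relabeling permutes marginals, preserves logZ and entropy", {
  g <- random_connectome(8, weighted = TRUE, seed = 21)
  p <- default_theta12(W = 1.5)
  s <- boltzmann_summary(g, p)
  set.seed(1)
  perm <- sample(8)
  gp <- connectome(g$weights[perm, perm])
  sp <- boltzmann_summary(gp, p)
  expect_equal(sp$logZ, s$logZ, tolerance = 1e-10)
  expect_equal(sp$entropy, s$entropy, tolerance = 1e-10)
  expect_equal(sp$marginals, s$marginals[perm], tolerance = 1e-10)
  expect_equal(sp$joint11, s$joint11[perm, perm], tolerance = 1e-10)
})

test_that("the enumeration cap refuses oversized systems with guidance", {
  g <- connectome(matrix(0, 30, 30))
  expect_error(boltzmann_summary(g, default_theta12()), "subsample")
  expect_error(entropy_sweep(g, default_theta12(), c(0, 1, 2)), "cap")
})

test_that("entropy sweeps reuse enumeration correctly and deterministically", {
  g <- random_connectome(10, seed = 31)
  p <- default_theta12()
  grid <- seq(0, 10, length.out = 11)
  sw <- entropy_sweep(g, p, grid, chunk_size = 101L)
  expect_equal(nrow(sw), 11)
  # each row equals an independent boltzmann_summary at that W
  for (k in c(1, 4, 8, 11)) {
    s <- boltzmann_summary(g, ising_params(W = grid[k], theta = 12),
                           moments = FALSE)
    expect_equal(sw$entropy[k], s$entropy, tolerance = 1e-10)
    expect_equal(sw$logZ[k], s$logZ, tolerance = 1e-10)
  }
  # identity entropy = eps*<H> + logZ at every grid point
  expect_lt(max(abs(sw$entropy - (1 * sw$meanH + sw$logZ))), 1e-9)
  # determinism
  expect_identical(sw, entropy_sweep(g, p, grid, chunk_size = 101L))
  expect_error(entropy_sweep(g, p, c(1, 1, 2)), "increasing")
  expect_error(entropy_sweep(g, p, numeric(0)), "nonempty")
  # single-point grid equals boltzmann_summary
  one <- entropy_sweep(g, p, 2.5)
  expect_equal(one$entropy,
               boltzmann_summary(g, ising_params(W = 2.5, theta = 12),
                                 moments = FALSE)$entropy)
})

test_that("entropy vanishes at strong coupling on connected binary graphs", {
  g <- generate_network(ensemble_spec("small-world", 14, 27, seed = 2), 3)
  grid <- seq(0, 30, length.out = 31)
  sw <- entropy_sweep(g, default_theta12(), grid)
  expect_lt(sw$entropy[31], 0.05 * max(sw$entropy))
})

test_that("the bifurcation locator finds the steepest rise on the flank", {
  sweep <- data.frame(W = 1:6, entropy = c(0, 0, 5, 9, 10, 2))
  expect_equal(find_edge_of_bifurcation(sweep), 2)
  expect_error(find_edge_of_bifurcation(
    data.frame(W = 1:5, entropy = rep(1, 5))), "flat|monotone")
  expect_error(find_edge_of_bifurcation(
    data.frame(W = 1:5, entropy = 1:5)), "flat|monotone")
  expect_error(find_edge_of_bifurcation(
    data.frame(W = 1:2, entropy = c(0, 1))), "3 grid")
  # ties break toward smaller W
  expect_equal(find_edge_of_bifurcation(
    data.frame(W = 1:5, entropy = c(0, 2, 4, 5, 1))), 1)
  # on a synthetic modular connectome the located W* precedes the argmax
  syn <- synth_connectome(synth_connectome_spec(seed = 5))
  sw <- entropy_sweep(syn, default_theta12(), default_w_grid(syn))
  ws <- find_edge_of_bifurcation(sw)
  expect_lt(ws, sw$W[which.max(sw$entropy)])
})
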