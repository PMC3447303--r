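test_that("pair statistics match the brute-force oracle", {
  c2 <- connectome(matrix(c(0, 1, 1, 0), 2))
  p <- ising_params(W = 1, theta = 1, epsilon = 1)
  ps <- pair_stats(c2, p)
  o <- oracle_boltzmann(c2$weights, 1, 1)
  expect_equal(ps$marginals, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(ps$mi[1, 2], oracle_mi_pair(o$P, o$states, 1, 2),
               tolerance = 1e-12)
  expect_equal(ps$mi[1, 2], 0.0303, tolerance = 1e-3)
  # larger random weighted system, all pairs
  g <- random_connectome(7, weighted = TRUE, seed = 19)
  pw <- default_theta12(W = 2)
  psw <- pair_stats(g, pw)
  ow <- oracle_boltzmann(g$weights, 2, 12)
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(psw$mi[i, j], oracle_mi_pair(ow$P, ow$states, i, j),
                 tolerance = 1e-10)
    pi_ <- ow$marginals[i]; pj_ <- ow$marginals[j]
    expect_equal(psw$corr[i, j],
                 (ow$joint11[i, j] - pi_ * pj_) /
                   sqrt(pi_ * (1 - pi_) * pj_ * (1 - pj_)),
                 tolerance = 1e-10)
  }
})

test_that("pair_stats invariants: symmetry, bounds, diagonal conventions", {
  g <- random_connectome(8, seed = 23)
  ps <- pair_stats(g, default_theta12(W = 2.8))
  expect_identical(ps$mi, t(ps$mi))
  expect_true(all(ps$mi >= -1e-12))
  expect_true(all(abs(ps$corr) <= 1))
  expect_equal(diag(ps$mi), binary_entropy(ps$marginals))
  expect_true(all(diag(ps$corr) %in% c(0, 1)))
  # MI bounded by the marginal entropies
  off <- upper.tri(ps$mi)
  cap <- outer(diag(ps$mi), diag(ps$mi), pmin)
  expect_true(all(ps$mi[off] <= cap[off] + 1e-9))
})

test_that("independent and cross-component pairs carry no information", {
  iso <- connectome(matrix(0, 2, 2))
  ps <- pair_stats(iso, ising_params(W = 1, theta = 1))
  expect_equal(ps$mi[1, 2], 0, tolerance = 1e-14)
  expect_equal(ps$corr[1, 2], 0)
  # two components joined only within themselves: the Boltzmann law factorizes
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  w[4:6, 4:6] <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  ps2 <- pair_stats(connectome(w), ising_params(W = 1.5, theta = 2))
  for (i in 1:3) for (j in 4:6)
    expect_lt(abs(ps2$mi[i, j]), 1e-12)
})

test_that("degenerate marginals at extreme W give zero correlation, not NaN", {
  g <- generate_network(ensemble_spec("small-world", 10, 19, seed = 3), 1)
  ps <- pair_stats(g, default_theta12(W = 40))
  expect_false(anyNA(ps$corr))
  expect_false(anyNA(ps$mi))
})

test_that("MI is invariant under relabeling a node's 0/1 convention", {
  # flipping spin i maps the system to one with the same joint law relabeled;
  # MI computed from the flipped 2x2 table must be unchanged
  g <- random_connectome(5, seed = 29)
  ps <- pair_stats(g, default_theta12(W = 2.5))
  s <- boltzmann_summary(g, default_theta12(W = 2.5))
  i <- 2; j <- 4
  p11 <- s$joint11[i, j]; pi_ <- s$marginals[i]; pj_ <- s$marginals[j]
  # relabel node i: p'ab table swaps rows
  tab <- matrix(c(1 - pi_ - pj_ + p11, pj_ - p11, pi_ - p11, p11), 2)
  tabf <- tab[2:1, ]
  mi_of <- function(tb) {
    pa <- rowSums(tb); pb <- colSums(tb)
    sum(ifelse(tb > 0, tb * log(tb / outer(pa, pb)), 0))
  }
  expect_equal(mi_of(tabf), mi_of(tab), tolerance = 1e-12)
  expect_equal(ps$mi[i, j], mi_of(tab), tolerance = 1e-10)
})

test_that("pooled pair-value distributions count, bin, and decay correctly", {
  g3 <- random_connectome(3, p_edge = 1, seed = 1)
  ps <- pair_stats(g3, ising_params(W = 1, theta = 1))
  d <- pair_value_distribution(list(ps))
  expect_length(d$values, 3)
  # many instances pool n*(n-1)/2 values each
  specs <- lapply(1:4, function(s) pair_stats(
    random_connectome(6, seed = s), default_theta12(W = 3)))
  d4 <- pair_value_distribution(specs, "mi")
  expect_length(d4$values, 4 * 15)
  expect_true(all(diff(d4$survival$s) <= 1e-12))
  expect_equal(d4$survival$s[1], 1)
  expect_equal(sum(d4$hist$count), sum(d4$values > 0))
  # all-identical values: single occupied bin, step survival
  fake <- list(list(mi = matrix(0.3, 4, 4), corr = matrix(0.3, 4, 4)))
  class(fake[[1]]) <- "pair_stats"
  df <- pair_value_distribution(fake, "mi")
  expect_equal(nrow(df$survival), 1)
  expect_equal(df$survival$s, 1)
  expect_error(pair_value_distribution(list()), "empty")
})

test_that("ensemble curves aggregate instance sweeps", {
  p <- default_theta12()
  grid <- seq(0, 12, length.out = 13)
  g1 <- generate_network(ensemble_spec("scale-free", 10, 19, seed = 2), 1)
  # single instance: mean equals its own sweep, sd 0
  cur1 <- ensemble_entropy_curves(list(g1), p, grid)
  sw1 <- entropy_sweep(g1, p, grid)
  expect_equal(cur1$mean, sw1$entropy)
  expect_equal(cur1$max_per_instance, max(sw1$entropy))
  # duplicated instances: sd identically 0
  cur2 <- ensemble_entropy_curves(list(g1, g1, g1), p, grid)
  expect_true(all(cur2$sd == 0))
  g2 <- generate_network(ensemble_spec("regular", 8, 16, seed = 2), 1)
  expect_error(ensemble_entropy_curves(list(g1, g2), p, grid), "same N")
})

test_that("size sweep holds mean degree fixed and is reproducible", {
  p <- default_theta12()
  grid <- seq(0, 16, length.out = 17)
  tab <- max_entropy_vs_size("scale-free", c(8, 10), mean_degree = 3.8,
                             p_base = p, W_grid = grid, instances = 2,
                             seed = 5)
  expect_equal(tab$edges, as.integer(round(3.8 * c(8, 10) / 2)))
  expect_equal(tab$N, c(8, 10))
  tab2 <- max_entropy_vs_size("scale-free", c(8, 10), mean_degree = 3.8,
                              p_base = p, W_grid = grid, instances = 2,
                              seed = 5)
  expect_identical(tab, tab2)
  # single (topology, N) row equals the ensemble maxima mean directly
  spec <- ensemble_spec("scale-free", 8,
                        as.integer(round(3.8 * 8 / 2)), instances = 2,
                        seed = isingnet:::derive_seed(5L, 8L + 1000L))
  cur <- ensemble_entropy_curves(generate_ensemble(spec), p, grid)
  expect_equal(tab$mean_max_entropy[1], mean(cur$max_per_instance))
})
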