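test_that("spec validation enforces modularity and mirror parity", {
  expect_error(synth_connectome_spec(p_intra = 0.1, p_inter = 0.5),
               "p_intra > p_inter")
  expect_error(synth_connectome_spec(n = 15), "even")
  expect_error(synth_connectome_spec(n_hubs = 1, mirror = TRUE), "even")
})

test_that("limiting case: full intra, zero inter gives exact blocks", {
  spec <- synth_connectome_spec(n = 8, n_modules = 2, p_intra = 1,
                                p_inter = 1e-9, n_hubs = 0, mirror = FALSE,
                                seed = 3)
  # p_inter ~ 0: cross-module edges almost surely absent before repair
  syn <- synth_connectome(spec)
  mods <- attr(syn, "modules")
  same <- outer(mods, mods, "==")
  expect_true(all((syn$weights > 0)[same & upper.tri(same)]))
  cross <- syn$weights[!same]
  # at most the connectivity-repair bridge exists across modules
  expect_lte(sum(cross > 0), 2)
})

test_that("mirrored connectomes are homotopically symmetric and valid", {
  syn <- synth_connectome(synth_connectome_spec(seed = 17))
  n <- n_nodes(syn)
  nh <- n / 2
  expect_identical(syn$weights, t(syn$weights))
  expect_true(all(diag(syn$weights) == 0))
  expect_true(all(syn$weights >= 0))
  expect_equal(syn$weights[1:nh, 1:nh],
               syn$weights[(nh + 1):n, (nh + 1):n])
  expect_equal(syn$hemisphere, rep(c("left", "right"), each = nh))
  # inter-hemispheric links are weaker on average than intra ones
  intra <- syn$weights[1:nh, 1:nh]
  inter <- syn$weights[1:nh, (nh + 1):n]
  expect_lt(mean(inter[inter > 0]), mean(intra[intra > 0]))
  # reproducible from the seed
  syn2 <- synth_connectome(synth_connectome_spec(seed = 17))
  expect_identical(syn$weights, syn2$weights)
})

test_that("hub nodes have elevated degree across seeds", {
  diffs <- vapply(1:50, function(s) {
    syn <- synth_connectome(synth_connectome_spec(n = 20, n_modules = 4,
                                                  n_hubs = 2, hub_boost = 0.4,
                                                  seed = s))
    deg <- rowSums(syn$weights > 0)
    hubs <- attr(syn, "hubs")
    mean(deg[hubs]) - mean(deg[-hubs])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("noiseless synthetic FC is exactly the model FC", {
  syn <- synth_connectome(synth_connectome_spec(seed = 23))
  grid <- default_w_grid(syn)
  fc0 <- synth_empirical_fc(syn, ising_params(), noise_sd = 0, seed = 1,
                            W_grid = grid)
  mf <- model_fc(syn, ising_params(), grid)
  ref <- mf$fc
  diag(ref) <- 1
  expect_equal(fc0$fc, ref, tolerance = 1e-12)
  expect_equal(fc0$w_star, mf$w_star)
  expect_error(synth_empirical_fc(syn, ising_params(), noise_sd = -0.1),
               "noise_sd")
})

test_that("noisy synthetic FC keeps FC invariants and is reproducible", {
  syn <- synth_connectome(synth_connectome_spec(seed = 29))
  grid <- default_w_grid(syn)
  fc <- synth_empirical_fc(syn, ising_params(), noise_sd = 0.2, seed = 4,
                           W_grid = grid)
  expect_identical(fc$fc, t(fc$fc))
  expect_true(all(fc$fc >= -1 & fc$fc <= 1))
  expect_equal(diag(fc$fc), rep(1, 16))
  fc2 <- synth_empirical_fc(syn, ising_params(), noise_sd = 0.2, seed = 4,
                            W_grid = grid)
  expect_identical(fc$fc, fc2$fc)
  # the noiseless FC (nonnegative under ferromagnetic coupling) round-trips
  # through the matrix reader after zeroing the diagonal
  mf <- model_fc(syn, ising_params(), grid)
  m <- mf$fc
  diag(m) <- 0
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, f, "matrix-csv")
  expect_lt(max(abs(read_connectome(f)$weights - m)), 1e-12)
})

test_that("recovery degrades monotonically in expectation with noise", {
  syn <- synth_connectome(synth_connectome_spec(seed = 37))
  grid <- default_w_grid(syn)
  mf <- model_fc(syn, ising_params(), grid)
  mean_r <- vapply(c(0, 0.2, 0.5), function(sd_) {
    mean(vapply(1:20, function(s) {
      fc <- synth_empirical_fc(syn, ising_params(), noise_sd = sd_,
                               seed = 1000 + s, W_grid = grid)
      fc_pattern_correlation(mf$fc, fc$fc)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
  expect_equal(mean_r[1], 1, tolerance = 1e-12)
})

test_that("degree-preserving rewiring keeps degrees and weight multiset", {
  syn <- synth_connectome(synth_connectome_spec(seed = 41))
  rw <- rewire_degree_preserving(syn, seed = 5)
  expect_equal(rowSums(rw$weights > 0), rowSums(syn$weights > 0))
  expect_equal(sort(rw$weights[upper.tri(rw$weights) & rw$weights > 0]),
               sort(syn$weights[upper.tri(syn$weights) & syn$weights > 0]))
  expect_false(identical(rw$weights, syn$weights))
})
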