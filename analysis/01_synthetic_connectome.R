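#!/usr/bin/env Rscript

# Stage 1: build the synthetic "human-like" structural connectome (modular,
# hemispherically mirrored, hub-containing, log-normal weights) and a noisy
# synthetic functional-connectivity matrix derived from it with known ground
# truth. Writes both matrices and a ground-truth manifest under results/.

suppressPackageStartupMessages({ library(isingnet); library(jsonlite) })

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

spec <- synth_connectome_spec(seed = seed)   # N = 16, 4 modules, 2 hubs
syn <- synth_connectome(spec)
message(sprintf("synthetic SC: N = %d, %d edges, %d hubs, mirrored = %s",
                n_nodes(syn), n_edges(syn), spec$n_hubs, spec$mirror))

p <- ising_params(theta = 12, epsilon = 1)
grid <- default_w_grid(syn)
fc <- synth_empirical_fc(syn, p, noise_sd = 0.2, seed = seed + 1L,
                         W_grid = grid)
message(sprintf("synthetic FC generated at ground-truth W* = %.3f ",
                fc$w_star))

write_matrix(syn$weights, "results/synthetic_sc.csv", "matrix-csv")
write_matrix(fc$fc, "results/synthetic_fc.csv", "matrix-csv")
write_json(list(stage = "synthetic_connectome", seed = seed,
                spec = unclass(spec), w_star = fc$w_star,
                noise_sd = fc$noise_sd, theta = p$theta,
                epsilon = p$epsilon,
                energy_convention = p$energy_convention,
                hubs = attr(syn, "hubs"), modules = attr(syn, "modules")),
           "results/synthetic_manifest.json", auto_unbox = TRUE, digits = NA)
message("wrote results/synthetic_sc.csv, results/synthetic_fc.csv")
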