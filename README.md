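# isingnet

Exact attractor-landscape statistics of Ising spin networks on connectomes.

## The problem

Resting-state brain activity is organized into reproducible spatial
patterns, and a long-standing hypothesis is that these patterns are shaped
by the anatomical wiring itself. `isingnet` studies the simplest model in
which this question can be answered *exactly*: each brain area is a binary
stochastic unit ("spin") S_i ∈ {0, 1}, coupled through a symmetric
structural connectivity matrix C with global coupling strength W, opposed
by an activation threshold θ, at inverse temperature ε. Under asynchronous
Glauber dynamics the stationary distribution over the 2^N global states is
the Boltzmann–Gibbs law

    P(S) = exp(−ε H(S)) / Z,
    H(S) = (θ/2) Σ_i S_i − (W/2) Σ_{i,j} C_ij S_i S_j,
    Z    = Σ_S exp(−ε H(S)).

Because Z can be computed by explicit enumeration at desk scale (N ≤ 28),
every quantity of interest is exact, with no sampling error:

- the **attractor-landscape entropy** E = −Σ P log P = ε⟨H⟩ + log Z (nats),
  a measure of the richness of the network's repertoire of states;
- its dependence on W, which has a low–high–low shape: a unique all-inactive
  state at weak coupling, a multi-attractor regime at intermediate coupling,
  a unique fully active state at strong coupling. The **edge of
  bifurcation** W\* — where the entropy starts its rapid rise — is located
  on the sweep;
- exact pairwise **mutual information** and **spin correlations**; the
  correlation matrix at W\* is the model's functional connectivity (FC),
  compared with an empirical or synthetic FC by the Pearson correlation of
  the strictly-upper-triangle entries;
- comparisons across network architectures — regular, small-world, random
  (Watts–Strogatz at rewiring probability P = 0, 0.25, 1) and scale-free
  (Barabási–Albert) — at exactly matched node and edge counts;
- **power-law tail fits** (maximum-likelihood exponent, KS-minimizing
  threshold, semiparametric bootstrap goodness-of-fit) for heavy-tailed
  quantities such as betweenness centrality and pooled pair-MI.

A synthetic-connectome generator (modular, hemispherically mirrored,
hub-containing, log-normal weights) and a matching noisy-FC generator
provide ground truth so the whole pipeline is testable without any
external data.

## Who it is for

Computational neuroscientists and network scientists who want exact (not
Monte-Carlo) Boltzmann statistics on small weighted graphs, reproducible
matched-density graph ensembles, and a tested Clauset-type power-law
fitter in R.

## Worked example

```r
library(isingnet)

syn  <- synth_connectome(synth_connectome_spec(seed = 1))  # N = 16, mirrored
p    <- ising_params(theta = 12, epsilon = 1)
grid <- default_w_grid(syn)

sweep <- entropy_sweep(syn, p, grid)
max(sweep$entropy)                  # 1.524 nats, at W = 3.678
(w_star <- find_edge_of_bifurcation(sweep))
# [1] 3.395

mf <- model_fc(syn, p, grid)        # exact spin correlations at W*
fc <- synth_empirical_fc(syn, p, noise_sd = 0.2, seed = 2, W_grid = grid)
fc_pattern_correlation(mf$fc, fc$fc)
# [1] 0.533
```

The entropy sweep on this 16-node synthetic connectome rises steeply near
W ≈ 3.4 (the edge of bifurcation), peaks at W ≈ 3.7, and collapses again
at strong coupling. The model FC computed at W\* recovers the pattern of a
noisy FC generated from the same anatomy with correlation 0.53 — and beats
a degree-preserving rewired null anatomy (r ≈ −0.04), demonstrating that
the anatomical wiring, not the degree sequence, carries the pattern.

The analysis workflow lives in `analysis/01_…R` through `analysis/06_…R`
(synthetic data → entropy sweep → topology ensembles → pair-MI
distributions → betweenness power law → FC comparison), each a thin driver
over the package functions writing its tables to `results/`. For example,
stage 3 prints, for matched 16-node / 30-edge ensembles (20 instances):

    regular      mean maximal entropy 1.589 (sd 0.229) nats
    small-world  mean maximal entropy 2.641 (sd 0.831) nats
    random       mean maximal entropy 2.942 (sd 0.738) nats
    scale-free   mean maximal entropy 5.277 (sd 0.543) nats

— the hub-containing scale-free architecture sustains by far the richest
attractor repertoire at matched density.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— synthetic connectome, exact entropy sweep, bifurcation point, model FC,
recovery statistic, and a small matched-edge topology comparison — and
writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Empirical structural/functional matrices (e.g., a 66-area DSI matrix) are
accepted as plain CSV/TSV by `read_connectome()` and by the `--sc`/`--fc`
flags of stages 5–6; they are optional and not distributed here.
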