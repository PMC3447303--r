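---
title: "Attractor landscapes of Ising spin networks on connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor landscapes of Ising spin networks on connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingnet)
```

## The model

Each node of a structural network carries a binary stochastic unit
S_i ∈ {0, 1}. Units are coupled symmetrically through the connectivity
matrix C (non-negative weights, zero diagonal), scaled by a global coupling
W and opposed by an activation threshold θ. The energy of a global
configuration S is

$$H(S) = \frac{\theta}{2}\sum_i S_i \;-\; \frac{W}{2}\sum_{i,j} C_{ij} S_i S_j ,$$

with the full double sum over ordered pairs, and the stationary law of the
single-site heat-bath (Glauber) dynamics is the Boltzmann–Gibbs
distribution $P(S) = e^{-\varepsilon H(S)}/Z$ at inverse temperature
ε. Everything downstream is computed from exact enumeration of the $2^N$
configurations: the log partition function, the mean energy, single-spin
marginals, pairwise joints, and the attractor-landscape entropy

$$E \;=\; -\sum_S P(S)\log P(S) \;=\; \varepsilon\langle H\rangle + \log Z
\quad\text{(nats)} .$$

The entropy identity above is used as the computational definition; it is
also asserted in the tests against the direct $-\sum P\log P$ of a naive
enumeration oracle. Note the identity only produces the *positive* Shannon
entropy; the package never reports the sign-flipped variant.

### The θ vs θ/2 conventions

The stochastic update rule is conventionally written with a field
$W\sum_j C_{ij}S_j - \theta$, while the energy above carries $\theta/2$.
These are mutually inconsistent: the heat-bath probability whose
stationary law matches the half-θ energy is
$g(W\sum_j C_{ij}S_j - \theta/2)$. The package resolves this explicitly:

- the exact analytics always use the energy as written
  (`energy_convention = "half_theta"`; `"full_theta"` exists for
  sensitivity checks);
- the simulator (`run_chain()`) defaults to `mode = "energy_consistent"`
  (θ/2), which makes simulation and analytics agree and is what the
  cross-validation tests assert; `mode = "paper_literal"` (full θ)
  reproduces the update rule as usually printed. The two modes coincide at
  θ = 0.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| θ | activation threshold (dimensionless) | 12 | reference operating point of the model family |
| W | global coupling (dimensionless) | 1, swept over a grid | the control parameter of the bifurcation |
| ε | inverse temperature | 1 | no canonical value exists; 1 makes energies and log-probabilities commensurate, and it is always echoed in outputs and manifests |
| chunk_size | states per enumeration chunk | 2^16 | keeps peak memory at a few MB regardless of N |
| enumeration cap | maximum N for exact sums | 28 | 2^28 states ≈ minutes at desk scale; larger systems must be explicitly subsampled by the caller |

Entropy sweeps exploit the decomposition
$H = \frac{\theta}{2}a(S) - \frac{W}{2}q(S)$ with $a(S)=\sum_i S_i$ and
$q(S)=\sum_{ij}C_{ij}S_iS_j$ both independent of W, so a whole W-grid
costs one enumeration pass plus a cheap log-sum-exp reduction per grid
point. All accumulations use a streaming running-maximum log-sum-exp,
because εH spans hundreds of nats across a sweep.

## The edge of bifurcation

Along a sweep the entropy is low at weak coupling (a unique all-inactive
state), rises rapidly where non-trivial attractors appear, peaks in the
multi-attractor regime, and collapses at strong coupling (a unique fully
active state). `find_edge_of_bifurcation()` returns the grid coupling with
the largest forward entropy difference on the rising flank (at or below
the argmax), ties broken toward smaller W. This is a deliberate,
reproducible discretization of "where the entropy starts to increase";
`model_fc()` exposes an integer `offset` so the FC can be evaluated one or
more grid points away from the located W*. Flat or monotone sweeps have no
interior structure and raise an error rather than returning a boundary
point.

## Architectures at matched density

Regular, small-world and random graphs are one Watts–Strogatz family
(ring lattice of even degree nearest the target mean degree, rewired with
probability P = 0, 0.25, 1); scale-free graphs are Barabási–Albert
preferential attachment with m = 2. No standard generator hits an
arbitrary edge count exactly (e.g., 38 edges at 20 nodes), so every graph
is post-repaired by uniformly random single-edge additions/deletions with
a connectivity guard (`match_edge_count()`); this makes architecture the
only variable at fixed N and edge count. Ensembles derive one seed per
instance from the master seed, so a spec is a complete description of its
ensemble.

## Synthetic world

`synth_connectome()` emulates the qualitative structure of an averaged
human DSI matrix: contiguous modules with denser within-module
connectivity (p_intra = 0.9 vs p_inter = 0.15), a homotopic mirror copy as
the second hemisphere with weaker inter-hemispheric links (homotopic
bridges at half the median intra weight plus sparse random cross links),
hub nodes with boosted attachment (hub_boost = 0.3), and log-normal
weights (meanlog −0.5, sdlog 0.5, a right-skewed positive weight law).
The default N = 16 with 4 modules and 2 hubs keeps exact enumeration
instantaneous in tests while retaining modularity, mirror symmetry and
hubs. It does **not** reproduce the quantitative weight distribution,
spatial embedding, or size of a real connectome — so a green recovery
test establishes that the pipeline recovers *this kind* of ground truth
under *this* noise model, not performance on empirical data.

`synth_empirical_fc()` perturbs the exact model FC on the Fisher-z scale
(noise_sd = 0.2 by default), which keeps perturbed correlations inside
(−1, 1) without truncation artifacts. The recovery experiments use a
degree-preserving rewired SC (double-edge swaps, 10× edge count) as the
null, so recovery cannot be explained by the degree sequence alone.

## Power-law fitting

`fit_powerlaw()` implements the maximum-likelihood tail fit with
KS-minimizing threshold: for every distinct candidate xmin with at least
`min_tail` (default 10) tail points, the continuous MLE
$\hat\gamma = 1 + n/\sum\log(x_i/x_{\min})$ (discrete variant: the
standard xmin − ½ shift), and the KS distance between the empirical and
fitted tail CDFs; the threshold minimizing KS wins, ties toward smaller
xmin. `bootstrap_pvalue()` is the semiparametric bootstrap: body values
resampled empirically, tail values drawn from the fitted law, each
replicate refit with the full scan. Zeros (e.g., leaf-node betweenness)
must be excluded by the caller; the continuous variant is the default for
betweenness and pooled MI, the discrete one for degree sequences.

## Numerical choices

- Natural logarithms everywhere; nats make the ε⟨H⟩ + log Z identity
  exact.
- Symmetry tolerance 1e−9 on input matrices, with automatic
  symmetrization (A + Aᵀ)/2 inside the tolerance and a hard error beyond
  (the Boltzmann form requires symmetric couplings).
- MI cells with numerically non-positive probabilities contribute 0
  (the 0·log 0 limit); the MI matrix is symmetrized after assembly to
  remove last-bit floating-point asymmetry; tiny negative MI round-off is
  clipped at −1e−12.
- Correlations involving a zero-variance spin (marginal 0 or 1 at extreme
  W) are defined as 0, not NaN, so pooled distributions never propagate
  NaNs.
- Hemisphere splitting without tags requires even N (first half = left);
  odd N without tags is an error rather than a silent convention.
- Weighted empirical matrices are used as-is by default; `binarize()` is
  opt-in, matching the treatment of artificial (binary) vs empirical
  (density-weighted) matrices.

## Known limitations

- Exactness is the point: there is no approximate free-energy path, so
  N > 28 is out of reach without subsampling.
- The entropy at W = 0 is the exact independent-spin value
  $N\,h\!\big(1/(1+e^{\varepsilon\theta/2})\big)$ — about 0.277 nats at
  N = 16, θ = 12, ε = 1. This floor is not small relative to the curve
  maxima of sparse 16-node binary graphs (≈0.4–5 nats); "entropy is
  negligible at both sweep extremes" therefore holds only in a relative
  sense at the strong-coupling end, and the low-coupling end should be
  compared against the analytic floor instead. For larger (e.g., 33-node
  weighted hemisphere) systems the floor shrinks relative to the maximum.
- The Glauber simulator caps N at 31 (integer bitmask states).
- The bifurcation locator returns a grid point; its resolution is the
  grid's, and no sub-grid interpolation is attempted.
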