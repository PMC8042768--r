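---
title: "SelON: modeling spatially varying stabilizing selection in ultraconserved elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SelON: modeling spatially varying stabilizing selection in ultraconserved elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Ultraconserved elements (UCEs) have a strongly conserved core flanked by
increasingly variable sequence. Standard substitution models (GTR with a
discrete Gamma rate distribution) describe this heterogeneity with a single
spatially unstructured rate distribution. SelON ("selection on nucleotides")
instead models it mechanistically, as a Wright–Fisher process of mutation,
drift, and position-dependent stabilizing selection toward an optimal
nucleotide sequence.

The ingredients, per UCE of length $l$:

* A global 4x4 mutation matrix $M$ with rates $\mu_{ij}$, shared by all UCEs
  of a dataset. The default flavor is the unrestricted 12-rate model
  (UNREST) with the G$\to$T rate pinned at 1, so 11 free relative rates; JC,
  HKY and GTR parameterizations are also available
  (`mutation_matrix()`).
* A Gaussian *sensitivity profile*
  $f(x) = N_e s_{\max}\, e^{-(x-\bar x)^2 / 2\sigma^2}$
  (`selection_profile()`): `nes_max` is the composite $N_e s_{\max}$ at the
  most conserved point $\bar x$ (1-based, continuous), and `width` $\sigma$
  is measured in sites. Because $\bar x$ is free, the conserved region need
  not be centered.
* An optimal base per site, $n^*_k$, fixed across the tree. Sequence fitness
  is $W = \exp(-\sum_k d_k f(k))$ with the binary distance $d_k = 0$ when
  the observed base matches $n^*_k$ and 1 otherwise, so fitness factorizes
  over sites (`sequence_fitness()`).
* The Moran/Sella–Hirsch fixation probability
  $u = (1-r^b)/(1-r^{2N_e})$ for a mutant with resident/mutant fitness
  ratio $r$, ploidy exponent $b$ (1 diploid, 2 haploid)
  (`fixation_probability()`).

Each site then gets its own substitution rate matrix
$q_{ij} = 2 b \mu_{ij} N_e u_{ij}$ and equilibrium frequencies $\pi$ solving
$\pi Q = 0$ (`site_rate_matrix()`, `equilibrium_frequencies()`). One
convention deserves emphasis: $f(k)$ is the *scaled* selection differential
$N_e s$. The per-copy fitness ratio entering $u_{ij}$ is therefore
$\exp(\Delta d \, f(k)/N_e)$, and the drift exponent $2N_e$ reconstitutes
$2f(k)$ — so $N_e$ cancels from the substitution rates in the large-$N_e$
limit. This is why `population_config()` treats $N_e$ (default $10^6$) as a
fixed constant rather than an estimated parameter: the data only identify
the composite $N_e s$. Composing the equations with the composite in *both*
exponents instead would freeze every selected site at its optimum (the
deleterious fixation probability would be $e^{-2 N_e f}$), collapse the
equilibrium substitution rate of selected sites to zero, and make `nes_max`
unidentifiable above $\approx 10^{-2}$ — inconsistent with the smooth,
recoverable profiles the model is meant to estimate.

With $f(k) = 0$ and $b = 1$ the site matrix reduces exactly to $M$: the
neutral limit is the bare mutation model.

### Rate scaling

Branch lengths should mean expected substitutions per site at equilibrium.
Each site's equilibrium rate is $-\sum_i \pi_i q_{ii}$; `scale_sites()`
divides every site's $Q$ by the scale factor $C$, defined as the **mean of
the per-site equilibrium rates across all sites of the dataset being fit
jointly**. Scaling each site by its own rate would erase among-site rate
variation — the phenomenon the model exists to describe — so the mean-rate
convention preserves relative site rates while giving the dataset mean rate
1. Because $Q/C$ shares eigenvectors with $Q$, the engine implements $C$ as
a rate multiplier on branch lengths and never re-decomposes matrices when
$C$ is refreshed.

### Likelihood

Site likelihoods come from Felsenstein pruning on a fixed rooted binary
topology, with root frequencies equal to the site's own $\pi$ (the process
is assumed to start at equilibrium; the simulator draws root states the same
way, keeping inference and simulation consistent). The process is
**non-reversible**, so the root location matters and no pulley-principle
rerooting is applied anywhere; an outgroup is recommended to absorb
root-adjacent identifiability problems, and root placement invariance is
only expected (and tested) for the reversible GTR+Gamma comparison model.
Missing data (gaps and IUPAC ambiguity codes) contribute a partial
likelihood of 1 in every state; an all-missing column contributes exactly 0
to the log-likelihood.

The comparison model is GTR+Gamma, partitioned by UCE (each locus gets its
own exchangeabilities, maximum-likelihood base frequencies, and shape
$\alpha$), with branch lengths shared across loci by default
(`fit_gtr_gamma(shared_branches = FALSE)` fits each locus separately). The
Gamma distribution is discretized by generalized Gauss–Laguerre quadrature
(`laguerre_gamma_rates()`, 4 or 8 categories), computed by the Golub–Welsch
tridiagonal method so shapes $\alpha < 1$ are handled exactly; weights sum
to 1 and the mean rate is 1 to machine precision. Model comparison uses
AICc with sample size $n = \text{taxa} \times \text{sites}$ (`aicc()`). In
the SelON parameter count, each estimated optimal nucleotide counts as one
parameter by default (`optimizer_config(count_optima = FALSE)` switches
this off), alongside 11 mutation rates, 3 profile parameters per UCE, and
one parameter per branch.

## Optimization

`fit_selon()` runs a four-stage hill climb, cycling until the
cycle-to-cycle improvement is below 1% of the log-likelihood or 12 cycles
have run:

1. **Branch lengths** — bounded Brent searches per branch in "generation"
   order: pendant branches first, then the branches subtending them, up to
   the root; full sweeps repeat until < 1% improvement or 10 sweeps.
   Bounds are $[10^{-9}, 10]$, tolerance $10^{-7}$.
2. **Profiles** — per UCE, a bounded derivative-free simplex search
   (Nelder–Mead on a logistic transform of the box; tolerance $10^{-6}$,
   5,000-evaluation cap) over (`nes_max`, `center`, `width`), with bounds
   `nes_max` $\in [0, 50]$, `center` $\in [1, l]$, `width`
   $\in [0.1, 10\,l]$.
3. **Mutation rates** — the same bounded simplex over the 11 free UNREST
   rates (log scale); the G$\to$T rate stays pinned at 1. Because the
   magnitude of $M$ is meaningful relative to $C$, the scale factor is
   refreshed inside this objective. The 11-dimensional search is
   warm-started every cycle, so its per-cycle budget is capped at 500
   evaluations.
4. **Optimal sequence** — per site, the log-likelihood of each of the four
   candidate optima (evaluated in four whole-dataset engine passes, since
   sites are independent given $C$); the argmax wins and ties keep the
   incumbent.

$C$ is held fixed within a stage and refreshed between stages under an
accept-guard: if the refreshed total log-likelihood is lower than before
the stage, the stage is reverted (stage 4 first re-runs its sweep once at
the refreshed scale). The guard makes the monotonicity contract exact — the
total log-likelihood never decreases across any stage or cycle.

Starting values: random seeded profiles, a Jukes–Cantor mutation start,
majority-rule optima (ties to the alphabetically first tied base), and
branch lengths from an F81 fit to the concatenated data via phangorn
(phangorn unroots the tree during optimization; the optimized lengths are
carried back onto the user's rooted topology by bipartition, with the
unrooted root-edge length split evenly between the two root-adjacent
branches).

## The synthetic-data generator

`generate_scenario_fixture()` emulates the simulation design used to probe
the model: two 10-taxon scenario trees (9 ingroup taxa plus the outgroup
`out`) whose branches are all either long (0.10 expected substitutions per
site) or short (0.025), differing in where the long branches sit; 22 UCEs
whose lengths sum to a target total (10,000 sites by default); and per-UCE
Gaussian profiles drawn once per fixture with centers uniform in
$[0.3l, 0.7l]$, widths uniform in $[l/10, l/4]$, and `nes_max` log-uniform
in $[0.5, 8]$. The exact scenario branch placements and the empirical
parameter estimates behind the original simulation design are not published,
so the trees and profile distributions here are documented stand-ins.
Optimal bases are uniform random; the generating mutation matrix is a fixed
UNREST matrix with a 2:1 transition:transversion bias, a typical vertebrate
nuclear value. Root states are drawn from each site's equilibrium
frequencies and evolved tip-ward by sampling from exact transition matrices
(no event-level simulation is needed). All randomness flows from the seed
argument; replicate $r$ of a fixture uses `seed + 1000 r + locus`.

What the generator does *not* emulate: indels and alignment error,
lineage-specific shifts of the optimal sequence, non-Gaussian spatial
profiles, and base-compositional heterogeneity across the tree. Passing
recovery tests on these fixtures therefore says nothing about robustness to
alignment artifacts or optimum shifts in real data.

## Numerical choices

* Site rate matrices are built in compiled code; fixation probabilities use
  `expm1` throughout, evaluate the neutral limit analytically when
  $|\ln r| < 10^{-8}$ (more precisely when $|\Delta d\, f| < 10^{-10}$ in
  the site-matrix kernel), and switch to a log-space form when the drift
  exponential would overflow.
* Equilibrium frequencies are left null vectors obtained from the same
  eigendecomposition that powers the matrix exponentials; entries more
  negative than $-10^{-12}$ signal failure, smaller negatives are clamped
  to zero before renormalization, and a second near-zero eigenvalue raises
  a degeneracy error instead of returning an arbitrary stationary vector.
* Transition matrices use the spectral form
  $P(t) = \sum_m e^{\lambda_m t} V_{\cdot m} V^{-1}_{m \cdot}$ with the
  rank-one modes precomputed; slices whose eigendecomposition fails a
  reconstruction check (tolerance $10^{-8}$ relative) fall back to
  scaling-and-squaring. Rows are clamped to $[0,1]$ and renormalized to
  absorb rounding noise.
* Pruning rescales partial likelihoods per node with accumulated log
  scalers (trigger $10^{-120}$), and a site likelihood of exactly zero is
  floored at $e^{-700}$ so degenerate proposals are penalized rather than
  fatal.
* Sites with sensitivity below $10^{-14}$ are treated as exactly neutral
  and share a single rate matrix (their optimum is then irrelevant), which
  also makes purely neutral datasets cheap.

## Problem sizes

The package's own test and acceptance analyses run the scenario fixtures at
22 UCEs totalling about 2,600 sites with 3–5 replicates per scenario, and
the full 10,000-site emulation remains available through the generator's
arguments. Fixation-probability checks use $10^5$ introductions per
condition; pruning and parsimony oracles use exhaustive enumeration on
trees of up to 5–6 taxa.

## Known limitations

The joint maximum-likelihood estimator of the per-site optimal sequence and
the Gaussian profile is biased on shallow trees with few taxa. On the
10-taxon scenario trees roughly 88% of tip bases match their site's
consensus, so after the optimal-sequence stage assigns each site's optimum
to (essentially) the consensus base, claiming weak selection across the
flanks moves root-frequency mass onto the observed base at every site and
is rewarded by the likelihood even on purely neutral data — a
Neyman–Scott-type effect of estimating one incidental parameter per site
from ten observations. Profile-likelihood scans show the likelihood peaks
at the generating parameters when the true optima are held fixed, but once
optima are free the maximum shifts to wider profiles. Consequences at the
fixture conditions, reproduced by `scripts/acceptance.R`: the fitted width
$\sigma$ is strongly upward-biased (median ratio near 3–4, far beyond its
nominal +50% band, although the center $\bar x$ and `nes_max` recover
well); the fitted scale factor drops correspondingly; and every branch
length stretches by roughly the ratio of generating to fitted scale factor
(tree lengths 1.3–2x the truth). The bias grows *milder*, not sharper,
with more sites; it is governed by the taxon count. Under the same fixture
conditions the GTR+Gamma comparison model recovers tree lengths well
(ratios near 1.0–1.3): with `nes_max` drawn log-uniform in $[0.5, 8]$
(median 2) the fixtures are only weakly conserved, and a free-shape
four-category Laguerre Gamma captures the resulting rate spread, so the
severe GTR tree-length underestimation reported for strongly conserved
empirical UCEs does not reproduce in this regime — we verified it also does
not appear with `nes_max` in $[5, 30]$. Both behaviors are faithfully
reported by the acceptance analyses rather than tuned away; analyses of
real UCEs should treat fitted widths and absolute tree lengths under SelON
with caution when taxon sampling is sparse, while relative branch ranking
(long versus short) remains reliable.

Other limitations: only fixed rooted topologies are analyzed (no topology
search); the optimal sequence is constant across the tree; the spatial
profile is Gaussian; the distance function is binary; and codon-level
selection is out of scope.
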