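---
title: "Modeling tumor clone migrations with ancestral-range models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor clone migrations with ancestral-range models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorgeo)
```

## The model

`tumorgeo` maps metastatic spread onto phylogenetic biogeography. A
patient's tumors are the *areas*; a clone lineage's *range* is the set of
areas it occupies, restricted to non-empty sets of at most two sites. The
null (empty) range is removed from the state space — a sampled clone is by
construction present at least at its sampling site — so for $n$ sites the
state space has $\binom{n}{1} + \binom{n}{2}$ ranges, indexed canonically
(singletons in ascending site order, then pairs lexicographically). The
two-site cap keeps ancestral reconstructions interpretable: larger
ancestral ranges mostly signal vicariance-style artifacts rather than
biology, because there is no physical barrier subdividing an anatomical
site.

**Anagenesis.** Along a branch the range evolves by a continuous-time
Markov chain: dispersal at rate $d$ adds any one absent site, extinction
at rate $e$ removes any one occupied site. Both rates are per unit branch
length; clone trees use mutations per site as the time proxy
("ultrametric-like" trees), so $d$ and $e$ are per unit of molecular
divergence, not per year. Singleton ranges cannot contract (null-range
removal), which makes every row of the generator sum to zero and every
$P(t) = e^{Qt}$ exactly stochastic — probability is conserved rather than
leaking into an absorbing empty state.

**Cladogenesis.** At a node the parent range is partitioned between the
two daughters. BAYAREALIKE copies the range unchanged; DEC allows subset
sympatry (one daughter inherits one parental site, the other the full
range) and vicariance (the two sites split between daughters); DIVALIKE
allows vicariance only. Each allowed ordered event carries weight 1. The
founder-event (+J) variants add jump events in which one daughter
colonizes a single site outside the parental range, each with weight $j$;
weights are normalized to probabilities per parent. This equal-weight
convention is the simplest one consistent with a fixed cladogenetic model
that assigns equal probability to its allowed events. Other
implementations reweight non-jump events as $j$ grows, which changes
absolute log-likelihoods by a model-specific reparameterization of $j$;
model rankings and ancestral annotations are the comparable quantities,
absolute likelihood values are not.

**Likelihood and fitting.** Tip conditionals are indicators of the
observed singleton range, pruning proceeds postorder with the
cladogenetic mixture at each node, and the root sums over a uniform prior
on all ranges. The uniform prior is a deliberate choice: it is the common
default, requires no extra parameters, and keeps the $j = 0$ nesting of
base and +J models exact, so likelihood-ratio tests are clean.
`fit_biogeo()` maximizes the likelihood over $d, e \in [10^{-9}, 5]$ and
$j \in [10^{-6}, 10]$ (log-scale L-BFGS-B, a fixed four-point start grid,
convergence tolerance about $10^{-8}$ on the log-likelihood), which makes
fits deterministic. AICc and BIC use the number of clones (tips) as the
sample size, the usual convention for these models; a different choice of
$n$ shifts AICc by the same amount for nested pairs and does not affect
the LRT. The LRT for $j$ sits on a boundary ($j \ge 0$); the plain
chi-square df-1 reference is the default, and the conservative 50:50
point-mass/chi-square mixture is available via `boundary = "mixture"`.

## From fits to migration graphs

Each internal node is annotated with its highest-probability range
(marginal probabilities from an inside–outside pass at the MLE). Exact
ties are broken deterministically by canonical state order and flagged in
the `tie` column so downstream scores are reproducible. Tips always keep
their observed site with probability 1. A migration path is emitted for
every edge whose child annotation contains a site absent from the parent
annotation — one path per gained site, with the full parent range as the
source. The path-derivation rule is stated for single-site annotations;
when a parent annotation spans two sites we report both as candidate
sources and, during evaluation, give credit if either candidate matches a
true path. This is the most permissive reading consistent with the rule,
and it is visible in output (comma-separated `source`).

Paths are classified by the primary flag: recipient primary → M→P, else
source containing the primary → P→M, else M→M. Scoring against a true
migration graph counts unique directed site pairs by default (mode
`"unique"`); mode `"multiset"` demands each repeated seeding of the same
pair be recovered separately and is kept for sensitivity analyses. The
two modes coincide whenever neither graph repeats a pair, which the test
suite checks by property.

## What the simulator emulates — and what it does not

`simulate_seeding()` generates benchmark datasets with the structure of
the standard simulated tumor cohorts: 5–7 sites (group m5) or 8–11 (m8),
7–28 clones, 9–99 SNVs, and four seeding scenarios. mS seeds every
metastasis with exactly one clone from the primary; pS uses 2–3 clones
per metastasis, still from the primary; pM draws sources from any
already-colonized site with at least two distinct sources; pR adds
reseeding of already-colonized sites and always includes one
metastasis-to-primary edge (the stricter of the two plausible readings of
"reseeding", chosen so every pR dataset exercises the M→P class). Trees
grow by random binary splitting; a migration is a founder split whose
second daughter starts the recipient site's population, so every
colonized site keeps at least one clone and the truth graph is the exact
list of realized migration events. SNVs drop uniformly on edges under
infinite sites (the implied outgroup carries no mutations), giving
homoplasy-free genotypes whose per-edge counts, divided by the SNV total,
are the branch lengths. Where the benchmark design leaves a count free,
the generator samples it uniformly from the stated range (e.g. 1–3
migrating clones per event), once, at generation time.

The generator reproduces scenario structure, not tumor growth dynamics:
there is no selection, no driver model, no sequencing noise, and clone
phylogenies are taken as known. Passing benchmarks here therefore says
the *inference machinery* is correct and well-calibrated on clean,
correctly specified trees — not that any model recovers migration
histories from noisy real sequencing data. Low-SNV datasets naturally
contain zero-length branches (sampled ancestral clones), which real clone
trees also have; see the degenerate cases below.

`simulate_under_model()` is the generative counterpart of the likelihood
(uniform root, cladogenetic draws, CTMC along branches) used for
parameter recovery, with one caveat spelled out under Limitations.

## Numerical choices

* Matrix exponentials use a dense Ward-style `expm` (state spaces are at
  most 66 states). Inside the optimizer, one eigendecomposition per
  $(d, e)$ with a reconstruction check (fallback to `expm` when the
  generator is numerically defective) plus caching of $P(t)$ per branch
  length makes fits fast without changing results beyond $10^{-9}$.
* Pruning rescales each node's conditional vector by its maximum,
  accumulating logs, so likelihoods of 28-clone, 11-site datasets do not
  underflow.
* Zero-length branches are legitimate input ($P(0) = I$); degree-2 nodes
  are collapsed by branch-length addition; clones observed in several
  sites are pre-split into zero-length tips named `clone@site`.
* Degenerate data: zero-length sibling tips at different sites have
  probability zero under copy-only cladogenesis (BAYAREALIKE without J)
  for every parameter value, and nested zero-length chains spanning three
  or more sites are impossible under any model with ranges capped at two.
  Such fits return `converged = FALSE` with `logLik = -Inf` and uniform
  node probabilities instead of raising, so multi-model pipelines keep
  running; the LRT treats a `-Inf` null against a finite +J alternative
  as overwhelming evidence for founder events.
* Model-table ties break by fewer parameters, then model name.

## Problem sizes used by the tests

The test suite verifies the pruning likelihood against exhaustive
enumeration over all ancestral state assignments (200 random trees of up
to 6 tips and 3 areas, agreement to $10^{-10}$), checks probability
conservation up to 11 sites, recovers $d$ on 50 simulated 20-clone
datasets under DEC($d = 0.2, e = 0.05$), measures LRT power on 20
datasets simulated with $j = 1$, validates 200 generator draws against
the scenario postconditions, and runs a one-dataset-per-cell benchmark
end to end. `scripts/acceptance.R` uses two datasets per cell; these
sizes are the package's own choice of a thorough-but-quick default, and
`make_benchmark(n_per_cell = 10)` scales to the full 80-dataset design.

## Known limitations

* **Extinction is weakly identified from single-site observations.** The
  observation process records one site per clone, so a lineage whose true
  range is two sites looks as if it contracted just before sampling. When
  data are generated under the model and then reduced to sampled
  singleton sites, the extinction-rate estimate absorbs that reduction
  and is biased upward — in our recovery experiments $\hat d$ is accurate
  while $\hat e$ runs to its upper bound. Treat fitted extinction rates
  as nuisance parameters, not biology.
* Absolute log-likelihoods are comparable only within this package's
  event-weight convention (see Cladogenesis above).
* Ranges are capped at two sites; datasets whose true ancestral clones
  occupied three or more sites are outside the model family as
  configured (the combinatorics support larger caps, but they are
  untested against any benchmark).
* No distance-dependent dispersal, time-stratification, Bayesian fitting,
  or confidence intervals on $(d, e, j)$; the phylogeny is taken as
  correct and clone-tree inference error is out of scope.
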