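---
title: "chronosim: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chronosim: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chronosim)
```

## Purpose

`chronosim` simulates phylogenies in which lineage-specific speciation
rates and molecular substitution rates evolve jointly, so that the
accuracy of molecular dating methods can be measured when their rate
priors are misspecified in a biologically structured way. This vignette
is the package's own account of the science: the simulation model and
its assumptions, the tunable parameters with units and defaults, what
the generator does and does not emulate, the numerical choices, and the
places where the design was genuinely open and a decision had to be
made.

## The simulation model

### Event-driven birth–death with evolving rates

The process starts from two crown lineages at time 0, both carrying the
initial rates (λ₀, r₀); the root node of every simulated tree is
therefore a crown divergence, which is what root calibrations and crown
age summaries refer to. Time advances by Gillespie steps: the waiting
time to the next event is exponential with rate Σ_l [λ(l,t) + μ + q],
the event type is chosen proportionally to its rate, and the affected
lineage proportionally to its own contribution (uniformly for
extinctions and rate jumps, proportionally to λ for speciations).

Rate evolution is a compound-Poisson discretisation of Brownian motion:
each lineage updates its rate pair at rate q, adding a bivariate normal
increment with covariance Σ·Δt, where Δt is the time since *that
lineage's* last update (inherited across speciation, so no evolution
time is lost or double-counted at nodes). For q large this converges to
correlated Brownian motion; q = 50/lineage/My is the default, and
summary statistics are insensitive to q above ~10 (a property test, not
a contract).

**Log versus natural scale.** The increments are applied to
(log λ, log r) by default. This was an open point: an additive reading
("an increment is added to the current speciation rate") suggests the
natural scale, but additive Brownian motion crosses zero, and the
empirical summaries this simulator is calibrated against are reported
as ranges of *log* speciation rates. Log-scale evolution keeps rates
strictly positive with no boundary hacks and makes the within-tree
range statistic natural. `sim_params(rate_scale = "natural")` restores
the literal additive reading, with reflection at a small positive floor
(`rate_floor`, default 1e-8) to preserve positivity.

### Conditioning on tip number (GSA)

To obtain correctly distributed trees with exactly n = 75 extant tips,
the run continues until the live-lineage count first reaches
⌈1.5 n⌉ (or a guard time of 500 My), and the Generalised Sampling
Approach then picks one of the maximal time intervals during which
exactly n lineages are alive, with probability proportional to the
interval's duration, and a present time uniformly inside it. The
history is truncated there. Runs that die out or never hold n lineages
are discarded and redrawn with fresh draws; the retry count is
reported. The outer first-passage stopping rule (1.5 n) bounds run time
while leaving, in practice, one or a few candidate intervals; intervals
the process would have re-entered after first passage are ignored,
a standard truncation in this family of samplers.

### Pruning and hidden speciation events

Extinct lineages are pruned, and chains of branches separated by
speciation events whose other daughter left no extant descendant are
merged. Each merged branch keeps (a) the summed expected substitutions
of its segments (the integral of r over each piecewise-constant
segment) and (b) the number of *hidden* speciation events absorbed into
it. Hidden events matter because speciation-associated bursts happen
whether or not the second daughter survives to be observed.

The pruned tree's root is the most recent common ancestor of the extant
tips, which is younger than the process origin whenever one of the two
initial lineages leaves no survivors. All reported root ages are crown
ages of the extant tree. (An early calibration prototype measured the
process origin instead; the resulting ~2 My bias is exactly the kind of
error this distinction prevents.)

### Punctuated bursts

The Punctuated model adds, at every speciation event — the crown
divergence included — an independent raw burst magnitude to *each*
daughter lineage (exponential by default; the family is configurable
and immaterial after rescaling). Granting a burst to each daughter
makes every node on a root-to-tip path contribute exactly one burst to
that path, which is what produces the node-count/path-length
correlation the model is meant to emulate. Per tree, a target burst
fraction of total tree length is drawn from Normal(0.16, 0.054)
truncated to (0, 1), and all bursts are rescaled by the common factor
that makes the burst share of the *pruned* tree equal the drawn
fraction exactly: bursts landing on surviving branches sum to
f/(1−f) × (gradual total). Bursts at events whose daughters all went
extinct are drawn but lost with the pruned lineages. Rescaling against
the pruned tree (rather than the full tree with extinct branches) is
deliberate: the 16 ± 5.4 % figure describes the trees one observes, and
the emitted phylogram's realized share equals the drawn fraction to
machine precision, so the between-tree distribution of realized shares
is exactly the truncated normal.

## Parameters, units, defaults

| parameter | unit | default | meaning |
|---|---|---|---|
| `lambda0` | events/lineage/My | 0.224 | initial speciation rate |
| `mu` | events/lineage/My | `lambda0/2` | extinction rate, constant |
| `r0` | subs/site/My | 0.01 | initial substitution rate |
| `q` | events/lineage/My | 50 | rate-update event rate |
| `sigma2_lambda` | (log-rate)²/My | 4.9e-4 | speed of λ evolution |
| `sigma2_r` | (log-rate)²/My | 0.04 | speed of r evolution |
| `rho` (or `cov_lr`) | – | 0 (Continuous: Cov = 0.0044) | increment correlation |
| `n_tips` | – | 75 | conditioning target |
| burst mean, SD | fraction of tree length | 0.16, 0.054 | punctuated target |
| alignment length | nt | 2000 | sequence simulation |
| gamma shape, categories | – | 0.30, 4 | among-site rate variation |
| calibration bounds | – | true age ± 15 % | hard uniform, 2 per tree |

### How the defaults were calibrated (and then frozen)

The supplementary material that carries the original bird-derived base
parameters is not part of this package's inputs; only the *validation
targets* those parameters produce are: a mean crown age of ≈ 28.4 My
and a mean within-tree range of log speciation rates at the tips of
≈ 0.44, for 75-tip trees. The defaults were therefore calibrated once,
before any acceptance test was written, by simulating with the package
itself:

1. The turnover μ/λ₀ = 0.5 was fixed a priori as a moderate,
   bird-plausible extinction fraction (it is not identified by the two
   targets alone).
2. λ₀ was tuned on a coarse grid to the 28.4 My crown-age target.
3. σ²_λ was tuned to the 0.44 log-rate-range target (the two
   interact only weakly).
4. A confirmation run of 200 replicates at the frozen values gave a
   crown age of 28.6 ± 0.55 My and a range of 0.432 ± 0.007; the
   defaults were not revisited afterwards.

σ²_r cannot be inferred from those targets. It was set to 0.04 — the
smallest round value for which the Continuous model's increment
covariance of 0.0044 is representable, since
ρ = 0.0044/√(σ²_λ σ²_r) must not exceed 1 (at the defaults ρ = 0.994).
A consequence worth knowing: substitution rates then vary substantially
within a tree (within-tree ranges of log r around 3), which dilutes the
punctuated burst signal in sister-pair analyses; see below.

`r0` = 0.01 subs/site/My is a typical avian mitochondrial value
(~2 %/My pairwise). The substitution model defaults (GTR with strong
transition bias, mtDNA-like base frequencies, gamma shape 0.30 over 4
categories, no invariant class) are a *synthetic* bird-like stand-in
for an unavailable empirical table, clearly labelled as such; every
value is overridable through `subst_model()`.

## Calibrations

Each tree receives exactly two calibrations: the root, plus one
internal node chosen by first drawing a *level* uniformly between 1 and
the largest number of internal nodes on any root-to-tip path (the root
is level 1), then drawing uniformly among the internal nodes at that
level; draws that return the root are rejected and redrawn. Levels
count internal nodes only — tips are never calibratable — and the
two-stage draw is kept literal (redraw-on-invalid rather than
renormalising). Bounds are hard uniform at the true age ± 15 %.

## Evaluation metrics

All clade comparisons use the rooted-clade convention (a clade is an
internal node's tip set), so the denominator for a 75-tip binary tree
is 74 clades including the root. MAPE is the *median* absolute
percentage error of node ages over shared clades — robust to the
occasional wild relative error at shallow nodes — with tips excluded
and calibrated nodes included by default (an `exclude` argument drops
any clade set). Topological error is the one-sided count of true clades
missing from the estimate; the Robinson–Foulds distance is the
symmetric count (twice the former for binary trees); both are provided
because published summaries use both conventions. The branch score sums
squared branch-length differences over the union of clades, a clade
missing from one tree contributing its length in the other. HPD width
is averaged over annotated internal nodes as (upper − lower)/point age.
The gamma statistic follows the standard internode-interval formula; a
negative estimate-minus-truth difference means reconstructed nodes sit
rootward (older) of the truth. Ultrametricity is enforced within a
relative tolerance of 1e-6, and externally produced estimates are
symmetrized to tip age 0 before gamma is computed.

## Sister-pair contrasts

Each tree yields one pair: the two clades splitting at the root. Both
clades are subsampled to the smaller clade's size (the even-sampling
device against the node-density effect), and contrasts in log clade
size (full sizes) are regressed through the origin on contrasts in the
log of the per-clade branch-length summary, with a two-sided t test on
the slope. Regression through the origin is the standard choice for
sign-arbitrary sister contrasts.

**The branch-length summary was an open design point, and the obvious
choice is wrong.** A median over the branches of the subsampled clade
subtree — even with the stem excluded — correlates with clade size
under the *Unlinked* model (observed p ≈ 1e-5), for purely tree-shape
reasons: subsampling a large clade merges branches into longer
segments, and a larger clade's crown is older, so any summary computed
below the root split inherits a size signal. The package therefore
summarises each clade by the median over sampled tips of the
*root-to-tip path length measured from the root split* (stem included):
both clades then span exactly the same time depth, the Unlinked model
is null as it must be, and genuine rate–size coupling — continuous
covariance, or bursts carried partly by hidden events that subsampling
cannot remove — still lengthens the larger clade's paths. The
tree-shape-confounded variant is retained for comparison as
`build_pairs(summary = "branch_median")`.

At the calibrated defaults the Continuous signal is strong (and the
Continuous replicate-set *selection filter* — accept the first
candidate set whose true-length regression is significantly positive —
mirrors how such a set is chosen in practice). The Punctuated signal is
real but modest at 50 pairs: the large σ²_r forced by the covariance
constraint adds gradual-rate noise to every path, so a single set is
significant only about half the time; the acceptance suite aggregates
three independent sets with a one-sided Stouffer combination rather
than pretending one set decides.

## What the generator does and does not emulate

It emulates: clade-scale birth–death dynamics with realistic crown ages
and within-tree speciation-rate spreads; gradual and punctuated
molecular rate variation with exact burst-share bookkeeping, hidden
events included; finite-alignment stochasticity under GTR+Γ; and
calibration regimes with known truth. It does **not** emulate:
population-genetic processes (coalescence, gene-tree discordance,
incomplete lineage sorting), multiple loci, indels or alignment error,
fossilized/through-time sampling, extinction-rate evolution, or
misplaced calibrations. A green test here therefore establishes
correctness of the simulation-and-measurement machinery under the
stated models — not that any empirical dataset evolved under them.

## Numerical choices

- Waiting times and event choices use R's global RNG; every pipeline
  replicate runs under a seed derived from (master seed, model,
  replicate index) via a small Lehmer mix, so any replicate is
  reproducible in isolation and streams never overlap in practice.
- The Σ Cholesky factor is computed once per run and tolerates
  singular Σ (ρ = ±1 or a zero variance).
- Ultrametricity of simulated trees is exact by construction (tip ages
  are set to 0, not accumulated); the 1e-6 relative tolerance applies
  to externally supplied trees.
- Failed runs (total extinction; tip target never held) are flagged
  and redrawn by `simulate_time_tree()`, up to `max_tries` (default
  100); retries are counted and surfaced in manifests.
- All file writers are deterministic; NEXUS output uses the package's
  own timestamp-free writer because the stock one embeds wall-clock
  time.
- Newick branch lengths are written with 15 significant digits so node
  ages survive a parse/write round trip to ~1e-12 relative error.

## Known limitations

- The bird-anchored defaults reproduce two printed validation summaries,
  not the original (unavailable) parameter table; other parameter
  combinations could match the same two targets.
- σ²_r is only bounded below by the covariance constraint; its default
  implies stronger within-tree substitution-rate variation than most
  empirical bird datasets show.
- The GSA outer rule truncates at first passage of 1.5 n lineages;
  n-tip intervals the process would have re-entered later are not
  sampled.
- `exec/chronosim evaluate` consumes summary trees (Newick or annotated
  NEXUS); raw posterior samples are out of scope.
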