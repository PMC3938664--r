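---
title: "Models and methods: PCR pooling, sequencing depth and platform effects on ecological inference"
author: "ampliconrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconrep)
```

## The scientific problem

Amplicon surveys of microbial communities pass a soil (or other
environmental) sample through a long chain of stochastic steps before any
ecology is inferred: a few DNA template molecules are drawn into a PCR,
amplified with taxon-specific efficiencies over ~30 cycles, often pooled
across several replicate reactions, and finally down-sampled again by the
sequencer to a platform-dependent read depth. Common lab lore holds that
pooling multiple PCR replicates protects diversity estimates from PCR
stochasticity. `ampliconrep` provides the machinery to test that claim:
α- and β-diversity estimators with seeded rarefaction, replicate-level
reproducibility statistics, permutation inference, and a generative
simulator of the whole library-preparation chain.

The central diagnostic is **pseudo-β-diversity**: the dissimilarity between
independently sequenced technical replicates of the *same* sample. Any
nonzero value is apparent turnover of purely technical origin, and its
dependence on sequencing depth separates sampling noise (which dies away as
depth grows) from persistent artefacts such as spurious OTUs (which do
not).

## Estimators

All α-diversity estimators operate on a single sample's count vector,
usually after rarefaction (sampling without replacement, i.e.
multivariate hypergeometric — the convention in community ecology for
"rarefied to even depth"):

* observed richness $S$;
* Chao1 in its classic form $S + F_1^2 / (2 F_2)$, with the bias-corrected
  fallback $S + F_1 (F_1 - 1) / 2$ when no doubletons exist;
* Fisher's α, the unique positive root of $S = \alpha \ln(1 + N/\alpha)$,
  found by bracketed root-finding to $10^{-9}$ (the left side is strictly
  increasing in α, so the root is unique whenever $N > S$);
* Simpson diversity in the complement form $1 - \sum p_i^2$ (values near
  0.8 on diverse soils are only consistent with this form, not with the
  dominance or inverse forms);
* Simpson's evenness $(1/\sum p_i^2)/S$, which lies in $(0, 1]$ by
  Cauchy–Schwarz.

The Simpson variant and the evenness normalization are conventions, kept
in their own exported functions so that a different convention can be
substituted without touching the pipeline.

Dissimilarities: Bray–Curtis $\sum|x_i - y_i| / \sum(x_i + y_i)$, binary
Jaccard $1 - |A \cap B| / |A \cup B|$, and β-sim
$\min(b, c) / (\min(b, c) + a)$ in the Lennon/Koleff presence-based form,
where $a$ counts shared taxa and $b, c$ the taxa unique to each sample.
β-sim discounts richness differences — a community nested in a richer one
scores 0 — which is exactly why platform effects shrink under it. Note
that β-sim is a *semimetric*: in a one-way perMANOVA partition its
between-group sum of squares ($SS_{total} - SS_{within}$) can be negative
when within-group turnover exceeds between-group turnover, and the package
reports such values as they are (negative pseudo-F, p → 1) rather than
clamping them.

`distance_matrix()` rarefies each sample once (not once per pair) so the
matrix is internally consistent, and records the seed it used.

## Replicate reproducibility procedures

`pseudo_beta_curve()` computes, at each requested depth $d$, all pairwise
dissimilarities among the technical replicates of one source sample,
rarefying every qualifying replicate to $d$ with `n_draws` independent
draws and averaging over pairs × draws. Depths that fewer than two
replicates can support are dropped with a warning. Whether published
depth curves of this kind use one rarefaction draw or an average is
usually unstated; `n_draws` exposes both conventions (default 10).

`detection_frequency()` tabulates, per OTU, the mean read count across all
replicate libraries (zeros included) and the fraction of libraries that
detected it. `fit_detection_model()` then fits a binomial GLM (logit link,
trials = number of replicates) of detection on $\log_{10}$ mean abundance.
Two zero-handling conventions exist in the literature — replacing zeros by
half the minimum observed value, or by a fixed 0.1 — and both are
implemented (`zero_policy`), defaulting to half-min; they genuinely give
different fits, so the choice is surfaced rather than buried. The
likelihood-ratio χ² compares against the intercept-only model. Under
perfect separation the fit is flagged `converged = FALSE` with finite,
capped estimates.

As an analytic reference, if reads of an OTU arrive approximately as
Poisson with mean μ per library, its detection probability is
$1 - e^{-\mu}$: an OTU averaging 10 reads is detected 99.995% of the time,
which is why detection curves saturate just above 10 reads.

`abundance_concordance()` regresses $\log_{10}(x + 1)$ read counts of one
replicate on another over the OTUs present in either, reporting the OLS
slope/intercept and Pearson r; a 1:1 line with high r means the treatment
difference (e.g. 1 vs 16 pooled PCRs) did not move relative abundances.

## Inference

`factorial_anova()` is least-squares ANOVA with sequential (Type-I) sums
of squares in formula order — the default behaviour of the analysis
environment such studies usually use — so term order matters and follows
the printed model (`~ pool_size * source_id * platform`). A constant
response returns F = 0, p = 1 instead of a 0/0 blow-up, and aliased terms
raise an error naming the offender.

`mantel()` correlates the upper triangles of two distance matrices and
permutes rows/columns of the second; `permanova()` partitions squared
dissimilarities one-way ($SS_{total} = \sum_{i<j} d_{ij}^2 / n$, within
groups analogously) and forms the pseudo-F
$(SS_B/(a-1)) / (SS_W/(n-a))$. Both use the $(1 + b)/(1 + m)$ p-value
estimator, so p is never 0 and never below $1/(m+1)$; permutation counts
default to 999. One-way tests suffice here because the platform and
region effects are tested separately; a multi-factor partition is out of
scope, as are dispersion tests and NMDS (group-structure claims are
carried by perMANOVA R²/p).

## The generative model

`simulate_experiment()` chains five stages, each independently seeded from
the master seed via `derive_seed()` so any stage can be replayed:

1. **Community.** `make_community()` draws a species-abundance
   distribution (lognormal by default, geometric optional), sorts and
   normalizes it. In the replication design each source soil receives an
   independent draw assigned to a permuted subset of the taxon pool and is
   thinned to a source-specific effective richness drawn from staggered
   sub-ranges of 50–100% of the pool, so the three sources differ
   decisively in both membership and richness — as soils from distinct
   biomes do.
2. **PCR.** `simulate_pcr()` samples `template_molecules` templates
   multinomially, runs `stochastic_cycles` (default 5) of exact binomial
   branching with per-taxon efficiencies, then applies the remaining
   cycles as deterministic growth $(1 + e_i)^{c - c_s}$. Early cycles
   carry essentially all of the compositional branching stochasticity,
   and exact 30-cycle branching would overflow count ranges. Efficiency
   $e_i$ = clamp(mean + taxon offset + reaction offset, 0.01, 1); taxon
   offsets are redrawn per platform (different primers), reaction offsets
   per PCR.
3. **Pooling.** `pool_replicates()` averages reaction profiles
   (equimolar by default) and renormalizes.
4. **Sequencing.** `sequence_sample()` masks platform-undetectable taxa
   (a seeded platform-stable subset), draws reads multinomially at the
   platform depth, then converts each read into a spurious OTU with
   probability `error_rate`. Spurious OTUs are labelled
   `ERR_<parent>_<j>` with geometric `j`, so repeated errors can collide
   on the same label and some noise OTUs recur across replicates — the
   behaviour that keeps binary Jaccard away from zero at any depth.
5. **Design.** The replication design yields 3 sources × pool sizes
   {1, 2, 4, 8, 16} × 2 platforms = 30 libraries. The cross-platform
   design yields 3 regions × 2 sites × 10 samples, each sequenced on both
   platforms; regional structure comes from independent regional
   profiles, with site and sample profiles drawn from Dirichlet
   distributions centred on them (`group_concentration` sets within-group
   similarity).

### Default parameter choices

| parameter | default | rationale |
|---|---|---|
| `n_taxa` | 200 | with the default SAD gives ~100–200 detectable taxa per soil and per-sample richness in the low hundreds at deep sequencing |
| `abundance_model` | lognormal(0, 1.2) | uneven but with the resident rare tail above ~10 expected templates per reaction |
| `template_molecules` | 10,000 | order of magnitude at which PCR/template sampling no longer limits detection relative to sequencing |
| `cycles` / `stochastic_cycles` | 30 / 5 | 30-cycle protocols are standard; branching noise concentrates in early cycles |
| `efficiency_mean` | 0.85 | high-efficiency hot-start amplification |
| `efficiency_sd_taxon` | 0.05 | persistent primer-binding bias per taxon and platform |
| `efficiency_sd_reaction` | 0.005 | run-to-run jitter per cycle; compounded over 25 deterministic cycles this yields a few-percent compositional wobble per reaction |
| `depth_by_platform` | 500–1,800 and 38,000–92,000 | the two platforms' realistic per-library read yields |
| `error_rate` | 0.005 | per-read probability of spawning a spurious OTU |
| `group_concentration` | 200 | within-region Bray–Curtis dissimilarities of roughly 0.3–0.5 |

A note on the interaction between `template_molecules` and the SAD: if a
large share of taxa have expected template counts near 1 per reaction
(relative abundance around $1/T$), pooling more PCRs *genuinely* increases
observed richness at deep sequencing, because detection probability is
concave in the pooled template weight. That is a real property of
template-limited libraries, not a bug — but it is not the regime of a
typical soil survey, where reactions start from far more templates than
the sequencer will ever sample. The default community therefore keeps its
resident taxa above the template resolution, which is the regime in which
the pooling null emerges and sequencing depth is the binding constraint.

### What the simulator does not model

Chimera formation, per-base error models and quality scores, read length,
primer thermodynamics, taxonomy, and sample dropout/mishandling. Passing
tests on simulated data therefore demonstrate the internal consistency of
the analysis chain and the qualitative depth/pooling/platform behaviour —
they do not certify any quantitative statement about a particular real
dataset. Note also that with the default 454-scale depth range
(500–1,800), rarefying the cross-platform design to 1,000 reads drops the
shallower third of libraries; the retained set is what all cross-platform
comparisons use.

## Study drivers and reproducibility of runs

`run_replication_study()` and `run_platform_study()` execute the full
analysis on a simulated design and write TSV outputs plus a
`manifest.json` (command, config hash, seed, package version, timestamp).
All randomness flows from the single `seed` in `sim_config()` through
`derive_seed()`, so all data outputs are byte-identical across runs with
the same configuration; the manifest's wall-clock timestamp is the one
non-reproducible field. Rarefaction depths follow the configured
per-platform values (defaults: 500 / 38,000 for the replication design,
1,000 / 40,000 for the cross-platform design).

## Numerical conventions and degenerate inputs

* Rarefaction at depth equal to the sample total returns the sample
  unchanged; depth above the total is an error left to the caller.
* Fisher's α at $N = S + 1$ returns a large finite value; $N \le S$ is an
  error.
* All-zero count vectors are errors for every diversity and dissimilarity
  function (never silently 0).
* Missing cells in input tables are errors, not implicit zeros.
* Permutation p-values are never 0 by construction.
* The test suite sizes its simulations to the smallest problem that still
  pins each property (e.g. 50 replication experiments for the ANOVA
  calibration, 400 null simulations at 99 permutations for type-I error,
  10,000 draws for hypergeometric agreement).
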