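# ampliconrep

Reproducibility analysis for amplicon (metabarcoding) sequencing
experiments: how do **PCR-replicate pooling**, **sequencing depth** and
**sequencing platform** affect the α- and β-diversity estimates that
microbial ecology studies are built on?

The package is aimed at molecular ecologists who work with OTU count
tables (samples × OTUs) and their technical-replicate structure. It
provides:

* **α-diversity** — observed richness, Chao1
  (`S + F1²/(2F2)`, bias-corrected fallback at `F2 = 0`), Fisher's α
  (the root of `S = α·ln(1 + N/α)`), Simpson (`1 − Σp²`) and Simpson's
  evenness (`(1/Σp²)/S`), all on seeded hypergeometric rarefaction.
* **β-diversity** — Bray–Curtis `Σ|x−y|/Σ(x+y)`, binary Jaccard
  `1 − |A∩B|/|A∪B|`, and the richness-insensitive β-sim
  `min(b,c)/(min(b,c)+a)`, with internally consistent distance matrices.
* **Pseudo-β-diversity** — the dissimilarity between re-sequenced
  technical replicates of the *same* sample, tracked as a function of
  rarefaction depth (`pseudo_beta_curve()`): purely technical "turnover"
  that should shrink as depth grows.
* **Detection consistency** — per-OTU detection frequency across
  replicates and a binomial logistic model of detection against
  log₁₀ mean abundance (`detection_frequency()`,
  `fit_detection_model()`), plus the Poisson reference `1 − e^(−μ)`.
* **Inference** — sequential-SS factorial ANOVA
  (`richness ~ pool_size * source_id * platform`), Mantel and one-way
  perMANOVA permutation tests, and cross-platform shared/unique OTU
  accounting.
* **A library-prep simulator** — true community → template sampling →
  stochastic PCR with per-taxon efficiencies → replicate pooling →
  platform-specific sequencing with spurious-OTU error
  (`sim_config()`, `simulate_experiment()`), with end-to-end study
  drivers (`run_replication_study()`, `run_platform_study()`).

## Worked example

Simulate a pooled-PCR replication experiment (3 soil sources × pool sizes
1/2/4/8/16 × two platforms) and interrogate one source's technical
replicates:

```r
library(ampliconrep)

cfg <- sim_config(seed = 42)
tab <- simulate_experiment(cfg, "replication")
tab
#> <count_table> 30 samples x 996 OTUs; total reads 1,004,838
#>   platforms: p454, illumina; groups: S1, S2, S3

## alpha diversity of the deep-platform libraries at 38,000 reads
illumina <- attach_metadata(
  count_table(tab$counts[tab$metadata$platform == "illumina", ]),
  tab$metadata[tab$metadata$platform == "illumina", ])
head(alpha_table(illumina, depth = 38000, seed = 1), 5)
#>        sample_id           metric        value depth
#> 1 S1_k1_illumina         observed 190.40000000 38000
#> 2 S1_k1_illumina            chao1 290.14589447 38000
#> 3 S1_k1_illumina    fishers_alpha  26.14847419 38000
#> 4 S1_k1_illumina          simpson   0.94554883 38000
#> 5 S1_k1_illumina simpson_evenness   0.09655764 38000

## pseudo-beta-diversity of source S1 vs sequencing depth
pseudo_beta_curve(tab, "S1", "bray_curtis",
                  depths = c(100, 1000, 10000, 40000),
                  n_draws = 10, seed = 1, platform = "illumina")
#>   depth mean_dissimilarity         sd n_pairs
#> 1   100          0.3771000 0.04274177      10
#> 2  1000          0.1492900 0.01380916      10
#> 3 10000          0.0631120 0.01049318      10
#> 4 40000          0.0462155 0.01186358      10

## does 1 pooled PCR predict 16 pooled PCRs?
abundance_concordance(tab, "S1", "S1_k1_illumina", "S1_k16_illumina")
#> <concordance_result> slope 0.9451, intercept -0.0119, r 0.9694 (310 OTUs)
```

Reading the output: between-replicate Bray–Curtis dissimilarity falls
from 0.38 at 100 reads to under 0.05 at 40,000 reads — apparent
"turnover" between re-sequencings of the same sample is almost entirely
a depth artefact. Meanwhile a single PCR predicts a 16-PCR pool with
slope ≈ 0.95 and r ≈ 0.97 on the log scale: pooling barely changes
relative abundances.

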