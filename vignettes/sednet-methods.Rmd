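---
title: "sednet: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sednet: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sednet)
```

# What the package analyses

`sednet` implements the downstream half of a sediment amplicon study: it
starts from an ASV (amplicon sequence variant) count table, a taxonomy table
and water-chemistry metadata, and answers four questions that recur in
rare-biosphere ecology of lake sediments:

1. How diverse is each sample, and how completely was it sampled?
2. Which taxa are abundant, which belong to the rare biosphere, and how much
   of the community's abundance does each fraction carry?
3. Which taxa co-occur strongly enough to form network structure, and which
   of them occupy structurally critical (keystone) positions?
4. Which taxa and keystones track the trophic state of the water and can be
   proposed as eutrophication indicators?

Everything upstream — read QC, denoising, chimera removal, taxonomic
classification — is out of scope: the package assumes a finished ASV table.
Functional prediction engines (PICRUSt2, FAPROTAX) are also out of scope;
`split_subcommunities()` produces the abundant/rare sub-tables those tools
consume.

# Preprocessing model

**Lineage exclusion.** Chloroplast, mitochondrial and domain-unassigned ASVs
are removed before any statistics (`exclude_lineages()`). "Unknown" is read
as *unassigned at the domain rank*, the interpretation under which it sits
naturally beside the two organelle rules; ASVs absent from the taxonomy are
treated the same way.

**Rarefaction.** `rarefy_table()` draws, within each sample, `depth` reads
without replacement — a multivariate hypergeometric draw — so every sample
sums exactly to the target depth and no count can exceed its input. The seed
is a required argument and is recorded in the output's `rarefaction`
attribute; rarefaction happens **after** lineage exclusion and **before**
relative abundances, classification and networks, which keeps all
per-sample thresholds on a common scale. The hypergeometric choice is
property-tested: the mean rarefied count over many seeds must match the
hypergeometric expectation `depth * count/total`.

# Abundance categories and the rare biosphere

Each ASV's per-sample relative abundances are reduced to the minimum `m` and
maximum `M` across samples and compared against two standard thresholds:
abundant = at least 1% of a sample, rare = below 0.01%. The six categories
are assigned by an ordered decision tree (`classify_asvs()`): always
abundant (AAT, `m >= 1%`), always rare (ART, `M < 0.01%`), conditionally
rare and abundant (CRAT, spans both thresholds), conditionally abundant
(CAT, reaches 1% without ever dropping below 0.01%), conditionally rare
(CRT, drops below 0.01% without ever reaching 1%), and moderate (MT,
always between the thresholds). Testing ART before CRT resolves the overlap
the verbal definitions of the two rare classes would otherwise have; the
tree provably covers every case, and a property test checks the partition on
random matrices.

Boundary conventions, fixed once: "at least 1%" is inclusive, "below 0.01%"
is exclusive, a zero count is below 0.01%, and an ASV at exactly 0.01% in
every sample is MT. The coarse grouping is the usual one — AAT/CAT/CRAT are
abundant, ART/CRT rare, MT moderate — and `summarize_partition()` reports
per-category ASV counts and average relative abundance (mean over samples of
the members' summed proportion), which sums to 100% across groups by
construction.

# Co-occurrence networks, Zi-Pi and keystones

Networks are built per domain (bacteria and archaea separately, if both are
analysed) on the rarefied, prevalence-filtered table. The prevalence rule is
strict: an ASV must be detected in *more than* half the samples, so 17 of 34
is dropped and 18 of 34 is kept.

**Correlation.** `spearman_all_pairs()` computes Spearman's rho with
average-rank tie handling and a two-sided p-value from the t approximation
`t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` degrees of freedom (`|rho| = 1`
maps to `p = 0`). The same engine drives the environmental screens, so a
single oracle-tested implementation backs every correlation in the package.
No multiple-testing correction is applied to edge p-values by default,
matching the conventional raw `p < 0.05` edge rule; screens and edges can be
BH-corrected downstream by the user since raw p-values are always reported.
Constant ASVs have undefined rank correlations; they are recorded as
no-edge and counted in a message rather than silently dropped.

**Edges.** An edge requires `|rho| > 0.6` *and* `p < 0.05`, both strict;
`rho = 0.6` exactly is not an edge. Sign is metadata: module detection runs
on the undirected, unsigned, unweighted graph, the behaviour of the usual
Gephi-style workflow. Isolated ASVs are not part of the network.

**Modules.** `detect_modules()` is Louvain greedy modularity maximization
(via igraph) under a caller-supplied seed, with modules relabelled by
decreasing size (ties by smallest member id) so that labels are stable,
meaningful descriptors across runs.

**Topological roles.** For node `i` with degree `k_i` and `k_is` links into
module `s`, `zi_pi()` computes within-module connectivity
`Zi = (k_ii - mean(k_jj)) / sd(k_jj)` (the z-score of within-own-module
degree among the node's module mates, sample standard deviation; 0 for
singleton or zero-spread modules) and the participation coefficient
`Pi = 1 - sum_s (k_is/k_i)^2`, bounded by `1 - 1/M` for `M` modules. Roles
use the classic cutoffs `Zi = 2.5` and `Pi = 0.62`; all four classes are
defined with strict inequalities on the high side, so boundary values fall
to the peripheral side. Keystones are all non-peripheral nodes (network
hubs, module hubs, connectors). `category_of_keystones()` then
cross-tabulates keystones against the abundance groups, the check of
whether structural importance concentrates in the rare biosphere.

# Trophic state and indicator screening

The package implements two trophic state composites
(`trophic_state_index()`), because different monitoring traditions use
different formulas and the choice materially shifts the absolute scale:

* **`tli_composite`** (default, the convention of Chinese lake monitoring):
  five sub-indices from Chl-a, TP, TN, Secchi depth and the permanganate
  index, weighted by their squared correlations with Chl-a
  (`r = 1, 0.84, 0.82, -0.83, 0.83`). `TLI(Chl) = 10(2.5 + 1.086 ln Chl)`,
  so 1 ug/L of Chl-a alone gives 25.
* **`carlson`**: the Secchi/Chl-a/TP triplet
  (`TSI(SD) = 60 - 14.41 ln SD`, etc.), averaged.

Both live on the 0–100 scale on which roughly 30–50 is mesotrophic. Missing
components are dropped with weight renormalization (and a message) rather
than invalidating the sample.

The screens (`diversity_env_screen()`, `taxa_env_screen()`,
`keystone_env_screen()`) report Spearman rho, p, direction and significance
stars at the exact thresholds `p < 0.05` (\*), `p < 0.01` (\*\*),
`p < 0.001` (\*\*\*), with TSI appended as an extra variable; pairs with
fewer than five complete observations are marked not-computed.
`indicator_call()` extracts taxa with a starred TSI association and its
output is invariant to screen row order. The screens are calibrated by
simulation: under independence at n = 34 the flag rate must sit within
binomial tolerance of 5%, and a planted Spearman association of 0.7 must be
detected in at least 90% of replicates.

# The synthetic community generator

`sim_config()`/`simulate_community()` generate the study the test-suite
runs on. Per-sample taxon intensities are
`exp(b_t + lambda * f_m(s) + eps)`: a lognormal baseline `b_t`
(`sdlog = 2`, the heavy tail that makes most taxa rare and a few dominant),
a shared standard-normal latent factor `f_m` per correlation module
(default four modules of 30 taxa at loading 1), and iid Gaussian log-noise
(sd 0.3). Intensities are normalised to proportions and counts drawn
multinomially at the configured depth; an optional Dirichlet layer adds
overdispersion but is off by default, which keeps the null calibration of
the correlation machinery analytically transparent. Default study
dimensions are 34 samples at 50,000 reads — the package's desk-scale
rendition of a full sediment survey; tests that need many replicates scale
`n_taxa` and `depth` down explicitly.

A configurable handful of taxa per category are *forced*: they receive
fixed per-sample expected proportions with wide margins around the 1% and
0.01% thresholds (e.g. always-abundant at 2%, always-rare at 2e-6, spanning
profiles for the conditional classes), so that at default depth the
realised counts force the intended category with overwhelming probability.
These margins are what makes "classification recovers 100% of planted
labels" a fair test; truth labels are only assigned to forced taxa.

`simulate_metadata()` maps each linked environmental variable through a
monotone (probit) transform of its module's latent factor plus noise into a
realistic field range — nutrients deliberately sit on narrow mesotrophic
intervals (TN 0.526–0.677 mg/L, TP 0.024–0.037 mg/L) — so planted
taxon–environment associations are Spearman-perfect at zero noise and
realistically attenuated otherwise. Unlinked variables are independent
noise, giving the screens a built-in null.

**Why hubs and connectors are planted at graph level.** A connector taxon
cannot be planted through the correlation route: a taxon loading equally on
`M` independent module factors has correlation at most `1/sqrt(M)` with any
single module member (0.5 for four modules), *regardless of signal
strength*, which can never clear the 0.6 edge threshold. The generator
therefore separates concerns: `planted_network()` plants correlation
*blocks* (recoverable as modules through the full Spearman-threshold
route), while `simulate_block_graph()`/`simulate_keystone_graph()` plant
adjacency directly — a hub wired to 80% of its 30-node module, connectors
wired to five nodes in each block, background densities 0.25 within / 0.01
between chosen so ordinary members' within-degrees stay well below a hub's.
On such graphs a planted connector's participation coefficient has the
exact analytic value `1 - 4 (5/20)^2 = 0.75` whenever modules are detected
correctly, which is what the keystone-recovery tests assert (recall >= 0.8,
Pi within 0.1 of 0.75, over 20 seeds; module recovery is asserted as mean
adjusted Rand index >= 0.9 on 4 blocks of 30 nodes at edge probabilities
0.6 within / 0.02 between).

**What the generator does not emulate.** Compositional coupling beyond the
shared multinomial denominator, sequencing error and chimeras, phylogenetic
correlation between related taxa, spatial autocorrelation between sites,
and negative ecological interactions (modules are positively driven;
negative edges arise only between modules). Passing tests therefore
demonstrate algorithmic correctness and statistical calibration on a
plausible data-generating process — not that the biological conclusions
drawn from any particular field data set are right.

# Numerical choices and degenerate inputs

* Shannon uses natural log; "Simpson" is Gini-Simpson `1 - sum p^2` (the
  dominant conventions in amplicon tooling).
* Chao1 uses the classic `S + F1^2/(2 F2)` with the bias-corrected
  `S + F1(F1-1)/2` branch when `F2 = 0`; ACE is Chao & Lee with rare cutoff
  10 (exposed as a parameter) and falls back to Chao1 when its sample
  coverage is zero. Estimators error on all-zero vectors.
* Zi uses the sample standard deviation; singleton and zero-spread modules
  give `Zi = 0` rather than NaN.
* Rank ties take average ranks everywhere.
* All randomised steps (rarefaction, Louvain, generators) take explicit
  seeds and restore the caller's RNG state, so `run_pipeline()` output is
  byte-identical across runs at a fixed seed.

# Worked example

```{r example}
cfg <- sim_config(n_samples = 20, n_taxa = 600, depth = 20000, seed = 7)
sim <- simulate_community(cfg)
meta <- simulate_metadata(cfg, sim$factors)
res <- run_pipeline(sim$table, sim$tax, meta,
                    out_dir = file.path(tempdir(), "demo"), seed = 1)
res$partition[res$partition$level == "group", ]
res$summary[c("n_nodes", "n_edges", "pct_positive", "n_modules", "n_keystones")]
range(res$tsi$TSI)
head(res$indicators)
```

# Known limitations

Spearman-threshold networks inherit the compositionality of relative
abundances; SparCC/SPIEC-EASI-style inference is intentionally out of
scope. Edge p-values use the t approximation, which is slightly liberal at
very small n; the calibration test pins its behaviour at n = 34. Louvain is
a heuristic: the seed argument makes it reproducible, not globally optimal.
TSI formula constants are monitoring conventions, not universal physical
constants — the method tag is stored with every result so downstream users
know which scale they are on.
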