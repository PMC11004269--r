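---
title: "Cross-domain co-occurrence networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-domain co-occurrence networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coonet` implements the network side of a common amplicon-survey workflow:
given 16S (bacterial) and ITS (fungal) ASV count tables from a designed
experiment, it infers a single *cross-domain* co-occurrence network whose
nodes span both kingdoms, characterises its topology and stability, and
classifies keystone taxa from their within- and between-module
connectivity. Around that core it provides the supporting community
statistics (alpha diversity, Bray–Curtis/ANOSIM) and treatment-effect
summaries (ANOVA with LSD letters, Pearson panels, LMG relative
importance) that such studies report alongside the network. This vignette
explains the models, the defaults, and the design decisions taken where
the methods literature leaves choices open.

## From counts to edges

**Filtering.** Network inference from rank correlations is unreliable for
taxa that are rare or sporadic, so the count table is screened first. A
taxon is retained when

* its grand-total relative abundance strictly exceeds
  `abundance_threshold` (default 0.001, i.e. 0.1% of all reads), and
* it is present in strictly more than `prevalence_threshold` of the
  samples (default 0.60).

The "top 0.1% by relative abundance" phrasing common in this literature is
ambiguous: taken literally as a fraction of the taxon list it would retain
only a handful of taxa, which is incompatible with the network sizes such
studies report (hundreds of nodes). The default therefore reads it as an
abundance proportion cutoff (`abundance_mode = "total-proportion"`); the
literal reading is available as `"top-fraction"`. Both screens are strict
inequalities, and `filter_taxa()` is idempotent.

**Edges.** `spearman_edges()` tests every unordered pair of retained taxa
with Spearman rank correlation (average ranks for ties) and keeps pairs
with ρ² > `rho2_threshold` and p < `alpha`. The default
`rho2_threshold = 0.9` reads the conventional "R² > 0.9" rule as a squared
correlation, i.e. |ρ| > 0.9487; packages that instead mean |ρ| > 0.9 are
matched by setting `rho2_threshold = 0.81`. P-values use the
t-approximation `t = ρ√((n−2)/(1−ρ²))`. With 12 samples, any |ρ| above
0.9487 is automatically significant at 0.05, so the p threshold is
effectively redundant at the default ρ² cutoff — it matters only when the
cutoff is relaxed. No multiple-testing correction is applied by default
(`correction = "BH"` enables Benjamini–Hochberg); at ρ² > 0.9 and n = 12
the per-pair false-positive rate is ~10⁻⁶, so the uncorrected and
corrected edge sets essentially coincide.

Per-treatment networks (`treatment_network()`) filter taxa on the
treatment's own samples. Because three replicates are far too few for rank
correlation, correlations default to the full sample set
(`samples = "all"`); `samples = "treatment"` restricts them to the
treatment's samples, with the hard floor of 5 samples enforced. Which
convention field studies use is typically unstated; both are supported and
the choice is recorded in the output.

## Topology and stability

`topology_summary()` reports the standard panel: edge/node counts split by
sign and domain, edge density 2E/(N(N−1)), average degree 2E/N, average
shortest-path length, and Freeman centralizations

* degree: Σ(d_max − d_i) / ((N−1)(N−2)),
* betweenness (unnormalized b): Σ(b_max − b_i) / ((N−1)²(N−2)/2),
* closeness (normalized c): Σ(c_max − c_i) / ((N−1)(N−2)/(2N−3)).

Different platforms normalize centralizations differently, so absolute
comparability of these three rows across software is limited; the count
and density rows are software-independent arithmetic identities. On
disconnected graphs the path length averages over connected pairs only and
closeness is computed within each node's component — conventions chosen to
avoid infinite distances, and stated here because they are invisible in
the output.

**Natural connectivity** is ln(mean(exp(λ_i))) over the eigenvalues of the
unweighted, *unsigned* adjacency matrix — a spectral measure of the
redundancy of closed walks. Edge signs are ignored because the stability
literature defines the measure on simple graphs; a sign-aware variant
would be a different statistic. It is 0 for an edgeless graph and
non-decreasing under edge addition, properties the test suite checks
against closed forms for complete graphs and an independent matrix
exponential.

**Robustness** removes ⌊fraction·N⌋ nodes uniformly at random (default
fraction 0.5), recomputes natural connectivity on the induced subgraph
(nodes that become isolated stay in), and reports the mean ± SE over
`n_reps` replicates (default 100) of the ratio to the intact value.
`connectivity_decay_curve()` traces the same quantity over increasing
removal counts.

## Modules and keystone taxa

`detect_modules()` maximizes modularity; the deterministic greedy
agglomeration is the default, seedable Louvain the alternative. The choice
of heuristic is deliberately conservative: keystone classification needs a
reproducible partition more than it needs the last few hundredths of Q.

`zi_pi()` computes the Guimerà–Amaral coordinates: the within-module
degree z-score Zi (z-scored over the node's own module) and the
participation coefficient Pi = 1 − Σ_s (k_is/k_i)². Conventions: Zi = 0
when a module has fewer than 2 nodes or no within-degree spread; Pi = 0
for isolated nodes (with a warning). `classify_nodes()` applies the
standard thresholds, strictly: network hub (Zi > 2.5 and Pi > 0.62),
module hub (Zi > 2.5 only), connector (Pi > 0.62 only), peripheral
otherwise — boundary values are peripheral. Keystone summaries default to
all non-peripheral nodes; `keystone = "hubs"` restricts them to module and
network hubs for studies that treat connectors separately.

## Diversity and treatment statistics

* **ACE** follows Chao & Lee with rare cutoff 10. When every rare read is
  a singleton the coverage estimate is 0 and the estimator is undefined;
  the bias-corrected Chao1 value is returned instead, mirroring common
  ecology software. The cutoff and the fallback are both assumptions —
  sequencing platforms rarely document theirs.
* **Simpson** is reported in the Gini–Simpson orientation 1 − Σp²:
  diverse amplicon communities then score near 1, which is the only
  orientation consistent with published values ≈ 0.99 for soil bacteria.
* **Rarefaction** uses the exact hypergeometric expectation (via
  `vegan::rarefy`), not subsampling.
* **ANOSIM** uses Clarke's statistic R = (r̄_B − r̄_W)/(n(n−1)/4) on
  average-ranked dissimilarities and the add-one permutation p-value
  (1 + #{R_perm ≥ R})/(1 + n_perm), which is valid (never anti-
  conservative) by construction.
* **LSD letters**: after one-way ANOVA, all pairwise t-tests with the
  pooled MSE; the compact letter display is derived from the maximal
  cliques of the non-significance graph, which makes "share a letter ⇔
  not significantly different" an exact property rather than a heuristic,
  for any significance pattern. A zero residual variance is handled
  explicitly (identical means share, distinct means differ).
* **LMG relative importance** averages incremental R² over all predictor
  orderings, computed by exact subset enumeration from centered
  cross-products. This restricts the decomposition to ≤ 8 predictors,
  which covers the soil-covariate panels it is meant for; shares are
  non-negative and sum to the full-model R² to numerical precision.
  Results are invariant to standardization, so raw predictors are used.

## The synthetic-data generator

No public accession accompanies many of the field studies this workflow
serves, so the generator is the package's test bed: it produces data whose
*ground truth* (module membership, hubs, filtered taxa, treatment effects)
is known exactly.

The default `study_design()` emulates a 4-treatment × 3-replicate
phosphorus-addition experiment: 505 bacterial and 87 fungal retained taxa
(the node counts of the emulated study's networks), 2000 low-abundance
background taxa, 80 000 reads per sample, and soil covariates/plant traits
whose treatment means follow the published dose-response (available P
rising 58–138% over the control, stem number 44–55%, and so on) with
replicate noise matched to the published standard errors. Treatment
effects on individual taxa default to none, which reproduces the emulated
study's headline null result: no alpha- or beta-diversity response.

Counts are compositional log-normal/multinomial draws. Each taxon's
log-abundance profile across samples is standardized (mean 0, sd 1), which
pins its long-run relative abundance at its base proportion — retained
taxa sit comfortably above the 0.1% filter, background taxa two orders of
magnitude below it, in every seed. Within a module, members share a latent
per-sample factor with squared loadings drawn just below the module's
`latent_correlation`; planted hubs load at 0.998, above every ordinary
member, so their stronger couplings are structural rather than lucky.
A fraction of members (30% in the default design) loads negatively.
This serves two purposes: the inferred network carries both edge signs,
and module mass stays roughly balanced across samples. The second point
is a genuinely compositional subtlety: when a module's total reads move
coherently, per-sample renormalization injects common noise that
selectively destroys *negative* rank correlations (positive pairs ride
the common term, negative pairs are washed out). Balanced modules keep
that coupling small. For the same reason, a module holding most of the
reads cannot express its own correlation — the shared factor cancels in
the ratios — so correlation-calibration checks embed the module in a
larger community.

What the generator does *not* emulate: sequencing error and chimeras
(upstream of the feature table), taxon-specific treatment responses
(unless configured), phylogenetic correlation structure, and the heavy
tails of real abundance distributions. Passing tests therefore demonstrate
that the algorithms recover planted structure under a known compositional
model, not that any particular biological dataset meets that model.

## Validation choices and problem sizes

The suite checks every operation against an independent route: brute-force
BFS and Freeman sums for the topology panel, matrix exponentials for
natural connectivity, complete-graph closed forms for robustness and decay
curves, per-node summation for Zi/Pi, permutation enumeration for LMG,
pairwise-test oracles for letter displays, `vegan` for ACE and the ANOSIM
statistic, and Monte-Carlo subsampling for rarefaction. Null calibrations
run ANOSIM on 200 simulated null datasets and the Pearson panel on 500,
checking ~5% rejection. Planted-module recovery is evaluated on
3-module designs (150 retained taxa, 12 samples) and on the full default
design; the recovery network is built at `rho2_threshold = 0.49`
(|ρ| > 0.7) because module detection benefits from a denser graph than
edge reporting does — at the reporting threshold the subgraph can
fragment, which degrades any partition metric for reasons unrelated to
the detector. Hub-recovery checks use `latent_correlation = 0.9`, where
the hub loading gap is widest. Stability tests use graphs up to ~600
nodes with 30–100 removal replicates, sized so the full suite runs in
well under a minute of numerical work per file.

## Known limitations

* Spearman correlation on compositions is biased (negative associations
  are attenuated, as above); compositionality-aware estimators (SparCC,
  SpiecEasi) are deliberately out of scope because the workflow being
  implemented specifies plain Spearman.
* With 12 samples, the discrete support of Spearman's ρ makes the
  |ρ| > 0.9487 criterion essentially a "near-perfect rank agreement"
  detector; users with more samples should revisit the threshold.
* Centralization values are comparable only within a fixed normalization
  convention (the one documented above).
* The LMG implementation enumerates subsets and is exponential in the
  predictor count; it refuses more than 8 predictors by design.
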