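---
title: "Spectral-count differential abundance and PPI network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count differential abundance and PPI network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectronet)
```

# The analysis

`spectronet` implements a biomarker-discovery workflow for label-free
spectral-count proteomics in small clinical cohorts — the setting where a
urine or plasma proteome of a few thousand proteins is profiled in three
groups of a handful of subjects each (the package's running example is a
healthy-donor group of 5 and two patient strata of 4 and 7). Abundance is
measured by peptide-spectrum-match (PSM) counts per protein, a
semi-quantitative measure that is non-negative, integer-valued, strongly
overdispersed, and sparse: many proteins are simply not detected in many
subjects, and that presence/absence pattern is itself biological signal.

The pipeline has three stages: selection of differentially abundant
proteins (DAPs), topological analysis of the protein–protein interaction
(PPI) networks they and each group's detected proteome form, and
functional-enrichment assignment.

## Differential abundance

**Normalization.** `normalize_total_signal()` rescales every subject column
so all column totals equal the mean of the original totals. The target
constant is a free choice (any common total gives the same downstream
ratios); the mean preserves the overall count magnitude, so normalized
values still read as PSM-sized numbers. A subject with an all-zero column
cannot be normalized and is reported by name instead of silently producing
`NaN`.

**Two complementary selection rules.** Variance-based selection misses
proteins that are *absent* rather than shifted, so `dap_fit()` combines:

* the **identification-frequency (IF) rule**: IF is the percentage of a
  group's subjects in which the protein is detected (PSM > 0), printed as
  an integer percent rounded half away from zero (4 of 7 → 57%). A protein
  is selected when IF is strictly above 50% in some group and strictly
  below 50% in at least one other. Both inequalities are strict: a 2-of-4
  group (exactly 50%) neither qualifies as high nor as low.
* the **F-ratio rule**: a per-protein one-way between/within-group variance
  ratio across all groups, with p from the F distribution on (g−1, N−g)
  degrees of freedom; selected when F ≥ 3.5 *and* p ≤ 0.05 jointly. This is
  the univariate F-to-enter criterion of stepwise linear discriminant
  analysis, used here as a reproducible stand-in for interactive LDA
  feature selection in commercial statistics software; it is an
  approximation of that practice, not a multivariate discriminant. Zero
  total variance is reported as F = 0, never selected.

**The DAve index.** Pairwise direction and effect size come from
`dave_index()`:

$$\mathrm{DAve}(A,B) \;=\; \frac{(\overline{\mathrm{PSM}}_A -
\overline{\mathrm{PSM}}_B)/(\overline{\mathrm{PSM}}_A +
\overline{\mathrm{PSM}}_B)}{0.5} \in [-2, 2],$$

with the convention that a protein detected exclusively in one condition
takes the boundary value ±2. DAve is antisymmetric and invariant to common
rescaling of both means, so it does not depend on the normalization
target. A comparison is called only at |DAve| ≥ 0.4; the threshold is
read as a two-sided magnitude cut, and `dap_fit()` applies it to the
F-derived selection (an F-selected protein with no pair reaching the cut
shows no interpretable direction and is dropped). Both means zero is
undefined and propagates as `NA`.

**Presence testing.** `presence_test()` compares two groups on detection
indicators alone. Under the permutation null over group assignments, the
number of detected subjects landing in the first group is hypergeometric;
the two-sided p doubles the smaller exact tail (clamped at 1). The null is
evaluated in closed form, which is exact for any group sizes — no normal
approximation is ever used — and the test suite checks it against full
enumeration of all assignments up to N = 12. For 5-of-5 present versus
0-of-11 this gives p = 2/C(16,5) ≈ 4.58×10⁻⁴. Benjamini–Hochberg adjusted
values are reported alongside raw p-values.

**QC.** `cluster_qc()` (also `plot()` on a `dap_fit`) clusters subjects
with Euclidean distance and Ward linkage (`hclust(method = "ward.D2")`,
the Ward implementation consistent with squared Euclidean merge costs) and
runs a subject-space PCA with per-component variance shares.

## Network topology

`ppi_network()` reconstructs an undirected simple network from a
STRING-style scored edge list. Only the curated-database and experimental
channels are used; an edge survives when databases ≥ 0.3 **or**
experiments ≥ 0.15 (inclusive thresholds — the channels are alternative
evidence, so the filter is an OR). Duplicate pairs merge keeping the
maximum per-channel score. `group_network()` instead starts from the
proteins detected in at least `ceiling(n/2)` of a group's n subjects — a
majority rule that gives 3-of-5, 2-of-4 and 4-of-7 for the default cohort.
By default all membership-passing proteins become nodes; a `daps=`
argument restricts to a selection when the tighter network is wanted.

`centrality_table()` computes the centralities used for hub calling, under
the conventions of the Centiscape Cytoscape plugin (the field's standard
tool for this analysis; the conventions matter because several of its
definitions differ from textbook ones):

* betweenness and stress are **unnormalized** counts over unordered pairs:
  betweenness sums the fraction of shortest s–t paths through v, stress
  the raw number of such paths;
* closeness is the **reciprocal of the summed distances** within the
  component (not the average-distance form), and eccentricity is the
  reciprocal of the maximum distance, so larger is always more central;
* radiality of v is $\sum_w (\Delta + 1 - d(v,w))/(n_c - 1)$ with Δ the
  component diameter and $n_c$ the component size;
* centroid value is $\min_{w \ne v} (\gamma_v(w) - \gamma_w(v))$ where
  $\gamma_v(w)$ counts nodes strictly closer to v than to w;
* bridging is betweenness × the bridging coefficient
  $(1/\deg v)/\sum_{i \in N(v)} 1/\deg i$;
* eigenvector centrality is the principal eigenvector of the component
  adjacency, scaled to maximum 1; edge betweenness, diameter, average
  distance and average degree (the latter three on the largest component)
  complete the table.

Distance-based quantities are computed per connected component; isolated
nodes keep degree 0 and `NA` elsewhere, and are excluded from the
averages used below. Graph representation, shortest-path distances,
betweenness, edge betweenness, eigenvector and the rewiring null use
\pkg{igraph}; stress, centroid, radiality, reciprocal
closeness/eccentricity and bridging are computed by the package, and all
six path/distance centralities are verified in the test suite against an
independent brute-force oracle that enumerates every shortest path
explicitly, over every connected graph on up to 7 nodes (995 graphs, up to
isomorphism) plus seeded random graphs up to 30 nodes.

**Hubs and bottlenecks.** `hub_selection()` pairs betweenness with a
second centrality, flagging nodes with both values strictly above the
network averages: betweenness + centroid → hub, betweenness + bridging →
bottleneck. On a complete graph nothing is strictly above the mean, so
nothing is flagged.

**Random-model validation.** `random_ensemble()` draws degree-preserving
replicas by double-edge-swap rewiring (igraph's `keeping_degseq`), with
10×|E| swap attempts per replica — enough swaps that the replica's edge
set is effectively randomized while every node keeps its exact degree.
1000 replicas (the default) give the null distribution of mean
betweenness; `compare_real_vs_random()` reports the observed network's
empirical quantile as #(replica mean ≤ observed)/n, and `plot()` draws
the null density with the observed value marked. Graphs admitting no
valid swap (e.g. stars) are detected per replica and flagged
`unchanged`. The whole ensemble is reproducible from one integer seed.

## Enrichment

`hypergeometric_enrichment()` scores each annotation term by the
upper-tail hypergeometric probability of its overlap with a protein
selection, with the universe made explicit — results depend strongly on
it, so the package refuses implicit defaults at the API level;
`subject_enrichment_matrix()` uses the detected proteome as the natural
universe. BH adjustment runs across all tested terms and a term is called
enriched at adjusted p ≤ 0.01. `differential_enrichment()` applies the
same F ≥ 3.5 / p ≤ 0.05 kernel as protein selection to a term-by-subject
score matrix; scores default to −log10(raw p) per subject, and the score
scale is recorded in the output since the F rule is scale-dependent.
Annotation collections are read from and written to GMT.

# The synthetic cohort generator

Downstream stages are tested end to end against `simulate_cohort()`,
`simulate_interactome()` and `simulate_annotations()`, which generate data
with the statistical structure the analysis assumes plus planted ground
truth.

**Count model.** Per-protein baselines are log-normal
(`baseline_log_mean = 3`, `baseline_log_sd = 1`: median ≈ 20 PSMs and a
dynamic range of roughly three orders of magnitude, typical of a urine
proteome's spectral counts). Detected counts are zero-truncated negative
binomial — `1 + NB(mu − 1, size = 1/dispersion)`, so a *detected* protein
always carries at least one spectrum and the cell mean equals `mu` exactly
whenever `mu ≥ 1` (means below one spectrum are not representable for a
detected protein; the generator clamps there). Zeros arise from two
explicit mechanisms only: structural exclusivity and detection dropout,
which zeroes cells independently with probability `1 − detection_prob`
(default 0.85). This separation is deliberate: the IF rule operates on
presence/absence, and with full detection the planted exclusive set is
recoverable with sensitivity and specificity exactly 1, which the tests
assert. The default dispersion 0.3 gives the super-Poisson variance
(`mu + 0.3 mu²`) characteristic of spectral counts.

**Planted signal.** `n_exclusive_per_group = 20` proteins per group are
structurally zero outside their group; `n_foldchange_daps = 40` proteins
have their baseline multiplied (direction "up") or divided ("down") by
`fold_change = 4` in one random group. Group sizes default to 5/4/7. All
draws descend from a single root seed.

**Interactome and annotations.** `simulate_interactome()` grows a simple
scale-free graph by preferential attachment (`attach_edges = 2` per new
node) over a subset of the cohort's protein IDs and scores each edge with
independent uniform databases/experiments confidences; the heavy-tailed
degree sequence reproduces the hub structure real interactomes show, and
the top-degree nodes are recorded as truth. `simulate_annotations()` makes
uniform random term memberships except for planted terms, which draw 80%
of their members (`planting_strength`) from a designated pool, making
their enrichment recoverable.

**What the generator does not emulate.** Spectra, peptides and protein
inference (it starts at the protein-level matrix); technical replicates
(one column per subject); correlated dropout (real missingness is
abundance-dependent, here it is uniform); biologically structured
interactomes (edges are independent of the planted abundance signal); and
term overlap/GO hierarchy (terms are sampled independently). Passing the
recovery tests therefore demonstrates that the *implementation* of each
rule is correct under the model the rules assume — not that the pipeline's
thresholds are optimal for any particular real dataset.

# Numerical and design choices

* **Percent rounding** is half-away-from-zero (`round()` in R rounds half
  to even and would print 2-of-8 groups differently than the field does).
* **"−0.4 ≥ DAve ≥ 0.4"**, the conventional way this filter is quoted, is
  implemented as |DAve| ≥ 0.4; the literal chain is unsatisfiable.
* **Strictness**: IF-rule and hub/bottleneck comparisons are strict
  (ties at a mean or at 50% do not select); F/p and DAve thresholds are
  inclusive, and the edge score filter is inclusive (a score of exactly
  0.15 retains the edge).
* **Constant profiles** have no defined rank correlation; Spearman entries
  are reported `NA`, never coerced to 0, and the diagonal is fixed at 1.
* **Disconnected graphs**: per-component computation avoids infinite
  distances; network-level summaries describe the largest component;
  isolates are excluded from hub/bottleneck averages but kept in every
  table.
* **Determinism**: every stochastic function takes an explicit integer
  seed (`sim_config(seed=)`, `random_ensemble(seed=)`, ...) and is
  byte-reproducible from it.
* **Problem sizes in the test suite** were chosen to exercise the
  asymptotics each property needs while staying quick: exhaustive oracle
  comparison over all 995 connected ≤7-node graphs plus 100 random
  ≤30-node graphs; 1000 rewired replicas of a 200-node scale-free graph;
  fold-change recovery at 50 subjects per group under low dispersion and
  full detection (the empirical mean ratio of a low-count protein cannot
  meet a 15% tolerance at n = 50 — counting noise alone exceeds it — so
  the convergence check uses baselines where overdispersion, not
  1/sqrt(mu), dominates the CV).

# A worked example

```{r example}
sim <- simulate_cohort(sim_config(n_proteins = 300, seed = 7))
fit <- dap_fit(sim$matrix, sim$design)
fit

int <- simulate_interactome(rownames(sim$matrix), n_nodes = 150, seed = 3)
net <- group_network(sim$matrix, sim$design, "HRPCa", int$interactions)
net
hubs <- hub_selection(centrality_table(net))
hubs

ens <- random_ensemble(net, n = 200, seed = 11)
ens

ann <- simulate_annotations(rownames(sim$matrix), n_terms = 30,
                            planted_terms = 3, planted_pool = daps(fit),
                            seed = 2)
head(hypergeometric_enrichment(daps(fit), ann$annotations,
                               fdr_threshold = 0.01), 5)
```

# Known limitations

The F-ratio selection is a univariate approximation of interactive LDA
practice. The exact presence test's two-sided convention (double the
smaller tail) is one of several defensible choices for discrete nulls and
printed p-values from other software may differ. The hypergeometric test
treats annotation terms as independent; no GO-graph propagation or term
de-redundancy is attempted. Centrality conventions follow Centiscape, and
values will differ from textbook-normalized variants. The generator's
dropout is uncorrelated with abundance, which is optimistic for low-count
proteins.
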