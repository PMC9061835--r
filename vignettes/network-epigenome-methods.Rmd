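---
title: "Methods: signed co-expression networks with epigenome and copy-number integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed co-expression networks with epigenome and copy-number integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modulomics)
```

## The analysis in one paragraph

Tumour transcriptomes contain groups of genes whose expression fluctuates in
a coordinated way — co-expression modules that often correspond to cell
states or regulatory programmes. `modulomics` infers these modules from a
signed weighted co-expression network, summarizes each module as a
per-sample eigengene, ranks hub genes by connectivity and graph centrality,
and then asks two integrative questions about a focal module: is its
expression mirrored by promoter DNA demethylation (particularly at CpG
island shores, the principal substrate of lineage-specific methylation), and
is it driven by recurrent copy-number alterations of its member genes? A
seeded synthetic-cohort generator plants exactly the structure these
analyses assume, so every stage is testable against ground truth.

## Network model

For genes $i, j$ with Pearson correlation $r_{ij}$ across samples, the
signed soft-thresholded adjacency is

$$a_{ij} = \left(\frac{1 + r_{ij}}{2}\right)^\beta,$$

which maps perfect anti-correlation to 0 and perfect correlation to 1, so
positively and negatively co-regulated genes are not conflated. The
topological overlap

$$\mathrm{TOM}_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad L_{ij} = \sum_u a_{iu} a_{uj},\; k_i = \sum_u a_{iu}$$

measures net connection weight, crediting shared neighbours as well as the
direct edge. Modules are found by average-linkage hierarchical clustering of
the dissimilarity $1 - \mathrm{TOM}$.

### Parameter choices

* **Soft power** `soft_power = 12` (pipeline default). Twelve is the
  conventional choice for signed networks, and on the package's reference
  simulation it separates planted modules cleanly (adjusted Rand index 1.0)
  where lower powers blur module and background genes together (ARI 0.42 at
  $\beta = 6$). The classical scale-free criterion is available through
  `select_soft_threshold()` (smallest candidate power whose binned
  $\log_{10} p(k)$ vs $\log_{10} k$ regression reaches $R^2 \ge 0.85$ with
  negative slope, falling back to the largest candidate with a warning).
  It is advisory rather than the default because a latent-factor cohort —
  like many real expression matrices — is not scale-free: across powers
  1–20 the fit never exceeds $R^2 \approx 0.49$, and the fallback power of
  20 flattens all topology. Set `network_config(soft_power = NULL)` to
  select the power from the data anyway.
* **Cut height** `cut_height = 0.95`. Average-linkage merge heights are
  bounded above by the maximum pairwise dissimilarity, which for soft-
  thresholded TOM matrices sits near but below 1 (about 0.985 on the
  reference design); a cut at 0.99 therefore returns a single cluster on
  essentially any input. 0.95 is the conventional static cut for signed-TOM
  dendrograms and leaves unstructured genes as singletons below the minimum
  module size.
* **Minimum module size** default 30 (10 in the recovery analyses, whose
  planted modules hold 50 genes); smaller clusters are relabelled 0
  ("unassigned", the grey-gene convention).
* **Eigengene merging** at dissimilarity $1 - \mathrm{cor}(\mathrm{ME}_a,
  \mathrm{ME}_b) < 0.25$, the conventional merge height, applied iteratively
  until stable. This static cut + minimum size + merge scheme is a
  deliberately reproducible reduction of dynamic tree cutting; it recovers
  planted structure exactly and has no stochastic elements.

### Module eigengenes

The module eigengene (ME) is the first principal component of the module's
standardized expression submatrix (samples × genes), unit-norm over samples
and oriented so its mean correlation with member genes is positive. The
principal component is computed from the expression matrix, not from the
adjacency matrix: the ME's role as a per-sample summary requires a quantity
defined over samples, and the expression-based first component is the
variance-optimal such summary (a property the test suite verifies against
1000 random unit vectors and an independent power-iteration oracle).
Membership (kME) is the gene–ME Pearson correlation with a two-sided
$t$-test on $n - 2$ degrees of freedom and per-module BH correction;
connectivity splits each gene's summed adjacency into within-module and
outside components. Per-sample module fractions shift each ME by its cohort
minimum and normalize across modules, supporting threshold classification
of samples as module-high (default cutoff 0.33).

## Hub metrics and substructure

Within a focal module the package reports three complementary centralities:
intramodular connectivity (summed signed adjacency to co-members),
eigenvector centrality (the Perron eigenvector of the TOM weight matrix,
computed exactly by symmetric eigendecomposition on the largest connected
component and scaled to maximum 1), and unnormalized shortest-path
betweenness. Betweenness runs on edge *lengths* — by default
$1 - \mathrm{TOM}$, so strong overlap means short paths; feeding raw
similarities in as distances would invert their meaning, which is why the
`one_minus` mode is the default and `reciprocal` is the exposed alternative.
Eigencentrality, by contrast, runs on the weights themselves: the two
centralities answer different questions (local influence vs conduit
position). Hub ranking orders by kWithin with eigencentrality, betweenness,
then gene id as documented tie-breaks. Substructure is described by cosine
similarity of co-expression profiles and by greedy modularity-maximizing
agglomeration ($Q = \sum_c (e_c - a_c^2)$ on weight fractions), which is
deterministic given input order and asserts per merge that $Q$ never
decreases.

## Geneset scoring and enrichment

The single-sample score ranks a sample's genes ascending and normalizes the
mean rank $\bar\mu$ of set members to its attainable range,
$(\bar\mu - \mu_{\min})/(\mu_{\max} - \mu_{\min}) - 1/2$ with
$\mu_{\min} = (m+1)/2$, $\mu_{\max} = N - (m-1)/2$; it is bounded in
$[-0.5, 0.5]$ and invariant under any strictly monotone transform of the
sample (up-set direction only; bidirectional scoring is out of scope).
Preranked enrichment walks a list ordered by Spearman correlation with an
eigengene: hits add $|\mathrm{metric}|^p$ normalized over hits, misses
subtract $1/(N - m)$, and the enrichment score is the signed maximal
deviation. The weighting exponent defaults to $p = 1$ (the classic weighted
statistic, cross-checked against `fgsea::calcGseaStat`); $p = 0$ is exposed
for the analytic cases. The null is a seeded gene-label permutation —
matching preranked semantics, where no phenotype labels exist — with
$\mathrm{NES} = \mathrm{ES} / \overline{|\mathrm{ES}_{\mathrm{null}}|}$
over same-sign permutations and an add-one exceedance p-value that stays in
$(0, 1]$; BH correction is applied across sets.

## Promoter methylation integration

Probes flagged as sex-chromosomal, multi-mapping, SNP-adjacent or non-CpG
are removed first, with per-reason counts. Promoter probes (TSS1500, TSS200,
5′UTR — exactly this set) are then location-normalized to correct the
bimodal beta-value distribution: per sample $s$ the reference level $G_s$
is the median beta over all promoter probes, and per probe the offset is
the median over samples of $\beta_{ps} - G_s$, subtracted from the probe's
values. The inner median runs over probes within a sample and the outer
over samples per probe; this reading preserves each probe's cross-sample
variation (required by the later rank correlations) while removing its
location, whereas any reading in which both medians run over the same index
set collapses to the identity. The transform is exactly idempotent when the
matrix decomposes additively into probe offsets plus sample effects — the
structure it targets — though not for arbitrary matrices; the test suite
pins the additive case to machine precision. Gene-level promoter profiles
average a gene's probes per sample, dropping genes with more than 2 probes
containing missing data or more than 2% of samples unobserved
(normalization precedes averaging). Profiles are Spearman-correlated with
every module eigengene (pairwise-complete), clustered by Euclidean
average-linkage with silhouette validation (singletons and degenerate
inputs score 0), and summarized per regional stratum — each region-group ×
CGI-relation cross plus the solo-WCpGW stratum of late-replicating loci —
with BH correction across strata and a stringent default flag at
$q < 10^{-7}$ appropriate to genome-scale methylation scans.

## Copy-number driver decision tree

A gene is a candidate driver of the focal module when both its integer
copy-number calls and its expression correlate with the module eigengene at
BH $q < 0.05$ (per family, exposed as `alpha`) *and* the two correlations
share a sign — a gene whose dosage and expression point opposite ways is
not copy-number-driven, so discordant genes are counted and excluded.
Direction maps the CN correlation sign to gain or loss; constant-CN genes
are excluded with a reported count. Candidate gains are tested for module
over-representation with the 1-df chi-square *without* continuity
correction — the uncorrected statistic is the one that reproduces published
worked examples on large sparse tables — and overlap is reported as a
percentage of the candidate list. Chromosome-level colocation is reported
descriptively (candidates per chromosome; no segmentation inference).

## The synthetic cohort

`simulate_cohort()` draws, under one master seed split into per-generator
streams (so adding a generator never perturbs another's draws):

* **Expression** — module gene $g$ in module $m$ follows
  $x_{gs} = w_g e_{ms} + \varepsilon_{gs}$ with loadings
  $w_g \sim U(0.6, 0.95)$ and noise sd 0.6; the latent eigengenes $e_m$ are
  standardized per module, and the loading gradient plants a hub hierarchy.
  Background genes are pure $N(0, 1)$. The reference conditions are three
  50-gene modules, 200 background genes, 120 samples — large enough for
  stable rank correlations, small enough that the full suite runs in well
  under a minute.
* **Methylation** — coupled genes (half of module 1) get promoter probes
  with $\beta_{ps} = \mathrm{logit}^{-1}(b_0 - c\, e_{1s} + \eta)$, others
  drop the coupling term; $b_0$ comes from two logit modes ($\pm 2$,
  promoter probes predominantly unmethylated), giving the genome-wide
  bimodal beta distribution, and the logistic squash keeps $\beta \in
  (0,1)$ while preserving monotone (Spearman-detectable) coupling. Coupled
  probes are shores with probability 0.7 (islands otherwise), concentrating
  the anti-correlation where lineage-specific methylation lives. At the
  default coupling $c = 4$ with 3 probes per gene, the probe noise sd of 7
  on the logit scale was calibrated once so that coupled genes' promoter
  profiles average a Spearman of about $-0.6$ against the latent
  eigengene — a strong but unsaturated coupling; this default was frozen
  before the recovery analyses were run. Solo-WCpGW flags are confined to
  uncoupled non-promoter probes, so that stratum is null by construction.
* **Copy number** — 20 driver genes follow $\mathrm{cn} =
  \mathrm{round}(\mathrm{clip}(\pm\gamma e_{1s} + \zeta, -2, 2))$
  ($\gamma = 1.5$, 70% gains), mimicking GISTIC discreteness without
  modelling segmentation; non-drivers get independent integer calls.
  Driver expression receives an additive dosage term $\delta\,\mathrm{cn}$
  ($\delta = 0.8$).
* **Genesets** — one planted set of 200 genes overlapping module 1 by
  `round(fraction × size)` members capped at the module size, plus a fully
  random control set. The default fraction 0.25 makes the planted set carry
  the whole module programme; smaller overlaps than the module's universe
  share (50/350) would actually *deplete* the set and flip the sign of its
  score–eigengene association, because the single-sample score is a
  relative-rank statistic.

What the generator does **not** emulate: tumour purity mixtures, batch
effects, mutational signatures, array probe chemistry (type-1/type-2 bias),
segmentation structure in copy number, or co-regulation of geneset members
beyond literal overlap. Passing recovery tests therefore demonstrate the
statistical machinery, not robustness to those real-data artefacts.

## Numerical conventions and degenerate inputs

Ties use average ranks throughout; Spearman p-values use the
$t$-approximation. Zero-variance genes are dropped at correlation time with
their ids in the warning; constant genes in ranking are recorded as
$\rho = 0$ with a flag; constant covariates and empty regional strata are
reported missing rather than erroring. Zero-norm profiles get cosine rows
of 0 (diagonal kept at 1) with a warning. Single-gene modules use the
gene's standardized profile as ME, with a warning. Mann–Whitney tests
enumerate all assignments exactly when $n_1 + n_2 \le 12$ and otherwise use
the tie-corrected normal approximation without continuity correction.
Exact-zero permutation p-values are avoided by add-one correction. Module
labels are renumbered by descending size with ties broken by previous
numbering; all output floats are written at 10 significant digits so
load–write round trips are byte-stable.

## Problem sizes

The test suite and the reproduction script run the full analysis on the
reference cohort (350 genes × 120 samples, 1050 methylation probes), with
betweenness oracles on graphs of up to 8 nodes, 100-table chi-square
checks, 400-trial enrichment-null calibration at 199 permutations, and
200-permutation preservation runs — sizes chosen so the complete suite
executes in about half a minute on one core while every statistic remains
stable to the tolerances asserted.

## Known limitations

Pearson is the only correlation implemented (the config knob is reserved;
robust biweight correlation would harden the network against outliers).
Preservation uses a reduced two-statistic Z (density + connectivity) rather
than a full permutation battery. Cross-cohort consensus is reported as a
module match table, not re-derived consensus clustering. Community
detection is one deterministic greedy algorithm; on large flat modules it
can under-split relative to multi-restart methods.
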