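---
title: "Models and methods behind phosphosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosphosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphosplice)
```

phosphosplice chains five analyses that together characterize splicing
dysregulation in a disease model: reporter-ion (iTRAQ-style)
phosphoproteome quantification, exon-skipping statistics from junction
read counts, kinase-downstream enrichment on a protein–protein
interaction (PPI) graph, GO-term enrichment with shared-gene term
grouping, and betweenness-centrality core-gene ranking. Every stage can
be driven by synthetic data with planted ground truth, which is how the
package tests itself. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic studies do and
do not demonstrate about real data.

## Reporter-ion quantification and differential phosphorylation

Reporter intensities are modeled as log-normal: a fragment's intensity in
channel $k$ is

$$ y = b_k \cdot \mu \cdot 2^{\delta \,[k \in \text{case}]} \cdot e^{\varepsilon},
\qquad \varepsilon \sim N(0, \sigma^2), $$

where $b_k$ is a channel-specific bias, $\mu$ a baseline intensity and
$\delta$ the true log2 fold change of the site. The analysis follows the
structure of vendor-style iTRAQ processing:

1. **Filtering** (`filter_peptides`): peptides without an isobaric label,
   peptides sharing MS/MS spectra with other proteins, low-intensity rows
   (default cutoff: the 1% intensity quantile, configurable — no universal
   threshold exists) and identifications at confidence $\le$ 0.95 are
   removed. The confidence rule is strictly greater-than: a peptide at
   exactly 0.95 is rejected.
2. **Bias correction** (`normalize_channels`): each channel is rescaled so
   all channel totals equal the grand mean of the original totals — the
   assumption is that total reporter signal should be equal across
   channels. The operation preserves within-channel structure and is
   idempotent.
3. **Aggregation**: fragment intensities covering a phospho-site are
   combined by geometric mean (`fragment_site_quantity`); peptides mapping
   to the same site are combined per channel by a weighted geometric mean
   (`protein_site_ratio`), the weighted-average analogue of vendor "error
   factor" weighting. The default weight is the inverse variance of a
   peptide's fragment log intensities within channels, with a uniform
   fallback when that variance is undefined (single-fragment peptides).
   All aggregation happens on the log scale, consistent with the
   log-normal model; reported fold changes use log2.
4. **Testing** (`site_differential_test`): per site, per-channel log
   ratios to the control geometric mean are compared between case and
   control channels by Welch's $t$-test — the groups are treated as
   heteroscedastic, so no pooled-variance assumption is made — and
   p-values are adjusted across all tested sites by Benjamini–Hochberg
   (one adjustment family per comparison). Significance defaults to
   $q < 0.05$.

**Median-ratio recentering.** Total-signal scaling forces equal channel
sums, so when the true changes are asymmetric (say, fifty sites all
4-fold up and none down), every null site inherits a compensating global
offset in its ratio — with a 5% spike fraction at $\delta = 2$ the offset
is $\log_2(1.15) \approx 0.2$, enough to distort estimates and inflate
calls. Under the standard assumption that most sites are unchanged,
`site_differential_test(center_ratios = TRUE)` (the default) subtracts the
median site log ratio before testing, which removes the offset while
leaving a symmetric or sparse signal untouched. Set
`center_ratios = FALSE` when analysing data where a majority of sites are
genuinely shifted in one direction.

Degenerate inputs return documented sentinels rather than errors so
pipeline stages can filter: identical constant groups give $t = 0, p = 1$;
two constant groups with different means give $p = 0$.

## Exon-skipping statistics

For an internal exon $i$, **inclusion reads** overlap the exon body by at
least 1 bp, and **skipping reads** carry a splice junction whose gap runs
from the annotated end of exon $i-1$ to the annotated start of exon
$i+1$. Boundary matching is exact by default; a `tolerance` in bp is
available because alignment pipelines differ in how precisely they place
junctions, but 0 is the defensible default for counting annotated
events. Coordinates are 0-based half-open throughout. Strand is ignored
for counting; gene models may carry a strand column for provenance.

The per-exon statistic is the **adjusted log2 skipping/inclusion ratio**

$$ L = \log_2\!\left(\frac{S_{\text{case}}/I_{\text{case}}}
{S_{\text{ctrl}}/I_{\text{ctrl}}}\right), $$

and significance comes from the two-sided Fisher exact test on the 2×2
table of skipping and inclusion counts, with Benjamini–Hochberg
adjustment and a default threshold of $q < 0.05$. Three rules matter:

- **Positive-integer rule**: every cell of the table must contain a
  positive integer; exons failing it are excluded *before* adjustment
  (they get no p-value at all), shrinking the family rather than padding
  it with $p = 1$.
- **Replicates are summed within group** before table construction: the
  2×2 test needs one count per cell, and summing is the maximum-likelihood
  pooling under the Poisson count model.
- **Sidedness**: the Fisher test is two-sided by the probability rule
  (the p-value sums the probabilities of all tables with the observed
  margins that are no more probable than the observed one). Skipping can
  move in either direction, so a one-sided test would encode an
  unjustified prior.

Downstream procedures operate on called results: `overlap_significant`
intersects the significant exon sets of two independent comparisons (for
example two disease models against a common background) and counts the
distinct genes; `recovery_analysis` scores a rescue experiment — an exon
is *recovered* when it is significant in the disease comparison but no
longer significant after treatment. Non-significance after treatment is
the default recovery rule; a stricter effect-reversion rule (adjusted
log2 ratio shrinking below half its disease magnitude) is available via
`rule = "reversion"`, since "no longer significant" conflates rescue with
loss of power. `rpkm` is provided for expression-level reporting
alongside the splicing ratios.

## Kinase-downstream enrichment

The downstream pathway of one or more seed kinases is the set of nodes
within `max_degree` (default 2) interaction steps of any seed —
degree-1 and degree-2 neighbors are pooled into a single "inside"
stratum. `downstream_enrichment` compares the fraction of
phosphorylation-changed proteins inside versus outside that set with the
two-sided Fisher exact test. Two exclusions apply:

- **Undetected proteins are excluded** from the table: only proteins with
  detected phosphorylation sites carry evidence either way.
- **The seed kinases themselves are excluded** by default
  (`include_seeds = FALSE`): they are the hypothesis being tested, not
  evidence for it.

When a stratum contains no detected protein the result is an `NA`
sentinel with a warning rather than an error, since sparse graphs
legitimately produce empty neighborhoods.

## GO-term enrichment and term grouping

`enrich_terms` scores each term by the hypergeometric upper tail
$P(X \ge k)$ for drawing $k$ term genes in a selection of $n$ from a
universe of $N$ containing $K$, with Benjamini–Hochberg adjustment across
all tested terms and a default threshold of $q < 0.01$. This is the
plain enrichment statistic; the more conservative one-gene-discount
variant popularized by annotation servers is available behind
`ease = TRUE`. The default universe is all genes in the annotation
table; pass a universe of "all genes with tested exons" when the
selection comes from the splicing stage, which is closer to the sampling
actually performed.

Enriched terms are grouped by how many genes they share:
`term_distance` is the Jaccard complement
$1 - |A \cap B|/|A \cup B|$ (the overlap coefficient was considered and
rejected because it degenerates when one term nests inside another), and
`cluster_terms` applies agglomerative clustering with Ward linkage
(`ward.D2` convention, i.e. the Lance–Williams update on squared
dissimilarities) to the distance matrix. Ward linkage on a non-Euclidean
Jaccard matrix is a pragmatic choice — it produces compact, interpretable
term groups — and the tree should be read as a grouping device, not a
metric embedding. Clustering is deterministic given the distance matrix;
ties are resolved by `hclust`'s documented ordering. The tree can be
exported as Newick via `write_term_tree` for inspection in any tree
viewer.

## Network construction and core genes

`build_pathological_network` expands the selected (splicing-significant,
database-mapped) genes by one interaction step on the database graph and
induces the subgraph on the result, so every added node sits one edge
from a selected gene and all database edges among kept nodes are
retained. `betweenness_scores` computes unnormalized shortest-path
betweenness (each unordered pair counted once, endpoints excluded,
fractional credit across equally short paths). Normalization is moot
because the downstream top-quantile rule is scale-invariant. Scoring runs
on the expanded graph — linker nodes mediate paths and must count — while
reporting can be restricted to the originally selected genes
(`restrict_to`), which is what the demonstration pipeline does.
`core_genes` flags the top 25% (configurable) as core; boundary ties are
inclusive, so an all-tied network makes every node core, and the report
is deterministically ordered by score then node ID. Node pairs in
different components contribute nothing, the standard convention for
disconnected graphs.

## The synthetic-data generators

Each generator is a pure function of its config, including the seed:
reruns are bit-identical, and a master seed is split into per-stage
substreams with `derive_seed` so any stage can be reproduced alone.

- `simulate_phospho` draws the log-normal reporter model above. Defaults:
  3 case and 3 control channels (the replicate design of small-cohort
  mouse phosphoproteomics), log-intensity noise SD 0.1 (typical
  fragment-level spread after vendor preprocessing), 3 fragments per
  peptide.
- `simulate_splicing_counts` draws, per exon and replicate,
  $I \sim \text{Pois}(d\psi)$ and $S \sim \text{Pois}(d(1-\psi))$ with
  depth $d$ and inclusion level $\psi$. The Poisson model was chosen for
  the analytic tractability of its planted truth, not realism of
  overdispersion (see limitations). Defaults: $\psi = 0.8$ (most exons
  are predominantly included), depth 100, 3 replicates per group (a
  typical bulk RNA-seq design; the count model needs no more because
  replicates are summed).
- `simulate_spliced_reads` emits explicit gene models (100 bp exons,
  100 bp introns) and block-level alignments so the read-counting path is
  exercised against exact ground truth; a skipping read's anchor blocks
  overlap the flanking exons and the returned truth accounts for that.
- `simulate_ppi` draws an Erdős–Rényi graph and labels nodes inside the
  seed neighborhood "changed" with probability `p_changed_in`, outside
  with `p_changed_out`; equality of the two is the planted null.
- `simulate_annotations` draws random term memberships
  (sizes $1 + \text{Pois}(\bar m - 1)$) over the same gene namespace as
  the splicing simulator, so the stages compose.

What the simulators deliberately do **not** emulate: overdispersed or
correlated counts, mappability and positional read biases, isoform
structure beyond single-exon skipping, peptide misidentification,
missing-value patterns in MS, scale-free PPI topology, and the
hierarchical structure of real GO annotations. Passing tests therefore
demonstrate correctness of the statistics and plumbing under the stated
models — they do not certify performance on real libraries, where
overdispersion in particular will make the Fisher test anti-conservative
across biological replicates.

## The demonstration pipeline

`run_pipeline(pipeline_config(...))` composes all stages into one
deterministic run and writes TSV tables plus a JSON manifest (package
version, seed, thresholds, stage counters, file digests). The default
study: 300 genes × 5 exons at depth 100 with 50 exons planted at
$\psi$ 0.8→0.2 in two disease models, a treated group in which 40% of
those exons revert, 200 proteins with 20 sites spiked at $\delta = 2$, a
250-node PPI graph with `p_changed_in` 0.8 vs 0.1 outside, and 40 random
annotation terms plus 4 planted terms drawn from the spiked genes so the
enrichment and grouping stages have signal. These sizes give every
stage near-complete power on its planted effects while a full run stays
in the seconds range; the same sizes back the test suite and
`scripts/acceptance.R`. The planted annotation terms are constructed by
the pipeline (not the annotation simulator) because they encode the
scenario, not the null model.

## Known limitations

- Fisher-based splicing calls treat replicate sums as one library;
  between-replicate overdispersion is not modeled (a beta-binomial
  extension would be the natural upgrade).
- The vendor "error factor" weighting formulas are proprietary; the
  inverse-variance weighting here is a documented, behaviourally
  reasonable stand-in.
- The recovery rule conflates rescue with loss of power by design
  (matching how such rescues are usually reported); use the reversion
  rule for a stricter reading.
- Ward-on-Jaccard is a grouping heuristic, not a metric-space guarantee.
- With very few quantified sites, median-ratio recentering itself becomes
  noisy; it is skipped for single-site inputs.
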