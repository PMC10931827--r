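---
title: "Selecting and characterising brain-region-specific genes with brsgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and characterising brain-region-specific genes with brsgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brsgkit)
```

## The problem

Bulk RNA-seq of dissected brain regions yields an FPKM matrix of genes by
samples. Some genes are expressed almost exclusively in one region — these
brain-region-specific genes (BRSGs) mark the dominant neuronal machinery of
that region (dopaminoceptive cAMP signalling in the dorsal striatum,
hormonal peptides in the hypothalamus, glutamatergic synapse genes in the
hippocampus, monoamine synthesis and axonal transport in the midbrain).
`brsgkit` implements the selection of such genes and the downstream
characterisation of the selected sets: how densely they are interconnected
in a protein-interaction network, how they project in a PCA biplot against
samples, and how named functional panels behave across experimental groups.

The package targets a design of five regions (HPC, HPT, STR, MRN, VTA),
three groups (control, chronically aggressive, chronically defeated mice),
and three replicates per region-and-group cell — 45 samples — but every
function takes arbitrary label sets.

## The specificity model

For gene $g$ let $x_i$ be its mean FPKM over all samples of region $i$
(groups pooled — specificity is a property of the region, not of the
treatment). The tissue-specificity index is

$$\mathrm{TSI}_g = \frac{\max_i x_i}{\sum_{i=1}^{n} x_i},$$

which ranges from $1/n$ (uniform expression) to 1 (fully confined). Two
regions can share one expression programme — here the dopaminergic VTA and
serotonergic MRN, whose neurons share axonal architecture — so a
combined-pair variant replaces the numerator by $x_a + x_b$ for one
designated pair. A gene is selected when its index strictly exceeds a soft
threshold $\tau$ (default 0.5: the region, or pair, carries more signal
than all other regions together).

Decisions that the model leaves open, and how `brsg()` resolves them:

* **Rule precedence.** A gene passing the single-region rule is assigned to
  its argmax region even if the combined value is larger; the combined rule
  only catches genes the single rule missed. This keeps genuinely
  single-region genes (e.g. a gene confined to VTA alone) out of the shared
  set.
* **Strictness.** Selection uses strict `>` at `tau`; a gene at exactly the
  threshold is excluded.
* **Ties.** An argmax tie is broken by declared region order and flagged in
  the output (`tie` column); exact ties have measure zero in real FPKM data.
* **Degenerate genes.** All-zero genes have no defined index; they are
  skipped with a log message rather than failing the run.
* **No expression floor by default.** Genes with maximal means of only a
  few FPKM can legitimately pass; a `min_max_fpkm` floor is available but
  defaults to 0.
* **Rounding.** Outputs report TSI at 2 decimals; full precision is kept in
  the fitted object.

The expression-tier breakdown (`breakdown()`) counts selected genes per
region whose assigned-region mean strictly exceeds 100 and 1000 FPKM —
separating moderately from very highly expressed markers. Combined-pair
genes count in both member regions, each with that region's own mean.

A bundled reference table (`vta_mrn_reference()`) holds published
region-mean profiles for 25 VTA/MRN marker genes together with their
published indices; recomputing the TSI column from the printed means
reproduces every value at 2 decimals, and the test suite asserts this.

## Network enrichment

If a region's BRSGs work in one functional programme they should be more
interconnected in a protein-interaction network than a random gene set of
the same size. `read_string_links()` parses a scored links table (0–1000
integer or 0–1 real scores), merges duplicate and reversed edges keeping
the maximal score, and drops self-loops. Confidence tiers are strict
cutoffs at 0.150 / 0.4 / 0.7 / 0.9 (low / medium / high / highest).

The enrichment null is authored by this package and labelled in every
output, because database-side enrichment p-values are produced by an
unpublished null and are not reproducible offline:

* `permutation_enrichment()` draws `B` node sets of equal size uniformly
  without replacement and reports
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$, with the permutation
  mean as the expected edge count. Genes absent from the graph are excluded
  from the set size, mirroring how interaction databases silently restrict
  to mapped proteins. A degree-binned sampler is available for sensitivity
  analysis when the gene set has unusual degree composition.
* `expected_edges_density()` gives the analytic expectation
  $\binom{k}{2} \times$ (global edge density at the tier), exact for
  degree-homogeneous graphs.

The permutation p-value is valid but *discrete*: it cannot fall below
$1/(B+1)$, and when the within-set edge count takes few distinct values
(sparse graphs, small sets) the test is visibly conservative —
$P(p \le \alpha)$ can sit well below $\alpha$. The calibration test in the
suite therefore measures type-I error on a graph dense enough for the count
statistic to be fine-grained near its null 95th percentile; for sparse
regimes, expect conservatism, not inflation.

## Projection statistics

`pca_biplot()` performs correlation-mode PCA: genes are standardised across
the chosen samples before the SVD, because FPKM spans four orders of
magnitude and covariance-mode PCA would be dominated by a handful of
highly expressed genes (covariance mode remains available via
`scale = FALSE`). Sample scores and gene coordinates (loadings scaled by
component standard deviations) share the axes. The sign of an SVD axis is
arbitrary, so PC1 is oriented such that gene PC1 coordinates correlate
non-negatively with gene mean expression — "right of the plot = elevated
overall expression" — and PC2's largest-magnitude gene coordinate is made
positive. All side-preference statistics are computed after orientation and
are therefore invariant to the raw SVD sign.

`side_counts()` counts items left/right of zero on an axis; exact zeros
count as right and are flagged. `binomial_side_test()` is the exact
binomial test at $p_0 = 0.5$ by direct pmf summation (two-sided: all
outcomes with pmf not exceeding that of the observed count). Both
conventions are always reported by `side_preference()`: the upper tail is
the honest choice when the direction was predicted in advance (e.g. "all 18
midbrain samples on the right"), the two-sided p when it was not. The test
equals full $2^n$ enumeration for small $n$, which the suite verifies.

`ahc_cluster()` performs agglomerative hierarchical clustering of
standardised gene profiles with Euclidean distance and Ward linkage by
default (`ward.D2`; complete/average/single available). Merges are
deterministic given the input, and memberships at a fixed cut are invariant
to input order up to relabelling.

## Gene panels

`builtin_panels()` ships small marker panels as an editable TSV: vesicular
glutamate/GABA transporters, glycinergic transport plus the neurofilament
master gene, the neurofilament triplet, the striatal phosphodiesterase
quartet, and five major TCA-cycle enzymes. The mitophagy panel contains
only its publicly named members (Prkcd, Pink1, Park2, Gak) and is named
`mitophagy_partial` to make its incompleteness explicit; the myelin panel
ships as a single-seed `myelin_seed` (Mbp) because published membership
lists disagree (5 vs 7 genes) — both files are meant to be extended by the
user rather than silently guessed at. `prefix_panel()` builds families like
the 64 cytosolic ribosomal subunit genes from anchored, case-sensitive
prefixes (`Rpl` never matches `Mrpl`). `panel_profile()` returns per-sample
values and region-by-group means; `group_contrast()` reports per-gene mean
ratios and differences between groups, flagging zero denominators instead
of emitting infinities.

## The synthetic test bed

`simulate_expression()` generates the study design from scratch so every
stage can be validated without downloads:

* baseline FPKM per gene drawn log-normal (`meanlog = 2`, `sdlog = 1.5`:
  median ~7 FPKM, right-skewed over several orders of magnitude, the shape
  of real FPKM distributions);
* planted single-region genes multiplied by a fold `f` (default 10) in
  their target region, shared-pair genes in both pair regions, group-effect
  genes by `g` (default 3) in affected groups, optionally restricted to a
  region mask (so a hypothalamus-only hormonal elevation can be emulated);
* multiplicative log-normal noise with unit mean and coefficient of
  variation `cv` (default 0.3 — replicate-level spread typical of bulk
  RNA-seq at moderate depth). With `cv = 0` every value equals its
  expectation, giving closed-form checks: a planted gene's TSI is exactly
  $f/(f + n - 1)$, e.g. $10/14 \approx 0.714$ for five regions.

`simulate_ppi()` plants high-connectivity modules in an Erdős–Rényi
background (edge probability `within_p` inside a module *replaces*
`background_p`, so equal probabilities give an exact null), and draws each
edge's confidence score uniformly within a uniformly chosen tier band so
every tier is exercised.

What the generator does **not** emulate: gene–gene correlation beyond the
planted blocks, library-size or length biases, zero inflation, batch
effects, and any attempt to match the real study's per-gene parameters.
Passing tests therefore demonstrate correctness of the algorithms under a
clean generative model, not performance claims about real tissue data.

Under the default planted conditions (fold 10, cv 0.3, 5 regions × 9
samples), selection at $\tau = 0.5$ recovers ≥ 95% of planted single-region
genes with a background false-positive rate below 1%; the suite asserts
this against the generator's ground truth.

## Pipeline and reproducibility

`run_brsg_pipeline()` executes the full chain from a validated YAML
configuration (`validate_run_config()` applies defaults — $\tau = 0.5$,
tiers 100/1000, cutoffs 0.150/0.4/0.7/0.9, B = 999 — and rejects unknown
keys with aggregated messages). One seed governs all stochastic stages via
deterministically derived sub-seeds; a rerun with the same inputs and seed
produces byte-identical tables, recorded in `manifest.tsv` as MD5 checksums
alongside the package version and seed. A stage failure aborts with the
stage name and removes partial outputs. The `exec/brsg-kit` script exposes
`simulate`, `run` and `tsi` subcommands for shell use.

Problem sizes used by the test suite are deliberately modest — a few
hundred to two thousand genes, graphs of 150 nodes, 200 calibration
replicates at B = 999 — chosen so the complete suite runs in well under a
minute while keeping Monte-Carlo error small relative to the asserted
margins.

## Known limitations

* The specificity index is relative to the declared region set; a gene
  called specific among five regions may be expressed elsewhere in the
  brain.
* The combined rule supports exactly one declared pair per fit; discovering
  which pair (if any) shares a programme is out of scope.
* The permutation null treats genes as exchangeable nodes; for gene sets
  with strongly atypical degree distributions use the degree-binned
  sampler.
* Enrichment p-values from external interaction databases are not
  reproduced, by design; only this package's labelled nulls are.
* The binomial side tests presuppose independent gene (or sample)
  placements; co-expressed genes violate independence, so the p-values are
  descriptive strength-of-asymmetry summaries rather than strict error
  rates.
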