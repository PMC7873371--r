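---
title: "Methods: marker set enrichment and key driver analysis in netMSEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker set enrichment and key driver analysis in netMSEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netMSEA)
```

`netMSEA` links GWAS summary statistics to biological pathways,
coexpression modules and network key drivers. This vignette records the
statistical model, the parameters that matter, the design decisions that
were genuinely open, and the limitations a user should know about. The
package never touches genotype-level data: its inputs are per-marker
p-values, marker-to-gene evidence tables, pairwise LD, gene sets and
directed edge lists.

## The enrichment model

For one trait and one marker-to-gene mapping, let the *background* be the
set of all markers that appear in the (LD-pruned) mapping, with their
association p-values. For a gene set, collect the unique markers of its
mapped genes (a marker shared by several genes in the set counts once:
one association signal should not be double-counted). With background
quantile levels $q_1 < \dots < q_J$ of the $-\log_{10} p$ distribution,
define per level

$$O_j = \#\{\text{set markers with } -\log_{10} p \ge \theta_j\}, \qquad
  E_j = n \,(1 - q_j),$$

where $\theta_j$ is the $q_j$ background quantile and $n$ the set's
unique marker count, and score

$$X = \sum_{j=1}^{J} \frac{O_j - E_j}{\sqrt{E_j + \kappa}}.$$

Defaults are $J = 10$ levels $\{0.50, 0.60, 0.70, 0.80, 0.90, 0.95,
0.975, 0.99, 0.995, 0.999\}$ and $\kappa = 1$. The exact statistic used
by the enrichment literature varies between implementations; this
chi-square-like form with a stabilizer in the denominator is the
established choice for quantile-cutoff marker-set statistics, and both
the levels and $\kappa$ are exposed in `MseaParams()` so an alternative
reading is one configuration away.

**Null distribution.** Significance is assessed against random gene
collections with the same number of mapped genes. Naive gene sampling
favors sets whose genes carry many markers, so by default
(`matchBins = TRUE`) the universe is split into marker-count quartile
bins and each null collection preserves the observed set's per-bin gene
counts. The one-sided empirical p carries a +1 pseudocount,
$p = (1 + \#\{X_\text{null} \ge X_\text{obs}\})/(n_\text{perm} + 1)$,
so it is exactly valid at finite permutation counts; a Gaussian tail
approximation from the null mean and standard deviation is available as
`pMode = "gaussian"` for cheap screening. Enrichment is one-sided
throughout: depletion is not tested.

**Multiplicity.** Benjamini–Hochberg FDR is applied across all tested
sets of a run, with FDR < 10 % the conventional significance call. When
two independent datasets are analyzed (e.g. a genome-wide scan and an
independent chip-based study), `combineTwoDatasets()` intersects the
significant sets; under independence the intersection's FDR is bounded
by the product of the two thresholds (10 % × 10 % = 1 %,
10 % × 25 % = 2.5 %).

## Parameters and defaults

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `windowBp` | 50,000 bp | distance mapping window, inclusive at both ends ("within 50 kb" read as ≤) |
| `fdrMax` (eQTL) | 0.10 | eSNP inclusion cutoff; cis boundary 1 Mb, ≤ is cis |
| `r2Max` | 0.5 | LD pruning cutoff; pairs at or above it are redundant |
| `quantileLevels` | 10 levels 0.50–0.999 | tail-weighted comparison grid |
| `kappa` | 1 | stabilizes near-empty tail bins |
| `nPerm` | 1000 | permutation count (validity enforces ≥ 100) |
| `minGenes`, `maxGenes` | 10, 500 | set-size bounds; outside → skip with recorded reason |
| `rho` | 0.33 | overlap-coefficient merge threshold |
| `depth`, `direction` | 1, out | KDA neighborhood: directed one step from the hub |
| `minNbhd` | 5 | smallest tested neighborhood (avoids degenerate hits) |
| `edgeMinStudies` | 1 (2 for subnetwork export) | per-edge study support filter |

## Numerical and procedural choices

- **p-values of exactly 0 are rejected**, not clamped: the $-\log_{10}$
  transform must stay finite, and silent clamping would hide an upstream
  problem. Users must pre-clamp deliberately.
- **Gene identifiers are uppercased once** at object construction; all
  joins happen on that convention. Cross-species or cross-ID translation
  is the caller's responsibility.
- **Missing LD pairs are r² = 0.** LD tables are sparse by construction;
  absence of evidence is treated as unlinked.
- **LD pruning is greedy best-p-first** with lexicographic tie-breaking
  on marker id, so output is deterministic. Within every clique of
  mutually linked markers exactly the smallest-p member survives, and on
  universes small enough to enumerate, the greedy result equals the
  lexicographically best maximal independent set of the conflict graph.
- **Merging ties** (equal overlap coefficients) break toward the
  lexicographically smallest pair of cluster keys (a cluster's key is its
  smallest member set id), so agglomeration is deterministic and repeated
  merging of the output is the identity.
- **KDA conditions on the hub**: the hub is removed from both the
  population ($N = |\text{nodes}| - 1$) and, if it belongs to the
  superset, the success count. The expectation a hub is compared against
  concerns its *neighbors*, not itself. Edge weights are carried but not
  used by the test; only the study-support filter consumes edge metadata.
- **Enrichment universes**: disease enrichment defaults to the genes of
  the trait's marker-gene mapping — the frame from which genes could have
  entered the results at all. Whether a whole-genome universe is more
  appropriate depends on how the disease lists were curated, so the
  universe is always an explicit argument.
- **Seeding**: `runMsea()` seeds once from `MseaParams@seed` and tests
  sets in input order, making whole result tables bit-reproducible. The
  generators seed themselves from `SimConfig@seed` plus a fixed per-stage
  offset (mapping +0, GWAS +1, network +2) so stages draw from
  decorrelated streams while remaining pure functions of the config.

## What the synthetic generator emulates — and what it does not

`simulateStudy()` emulates the statistical structure each stage consumes:
uniform null p-values with gene-level planted signal (all markers of a
signal gene draw from Beta($\alpha$, 1), $\alpha = 0.1$ by default,
mirroring the premise that functional variants concentrate in causal
genes), a many-to-many marker–gene map with a zero-truncated geometric
markers-per-gene distribution (mean 3), idealized LD in equal-r² blocks
(the pruner consumes only pairwise r², so block structure is all it
needs), and a directed network with zero-truncated geometric out-degree
and planted hubs wired to a known fraction of superset genes.

Default scale — 5,000 markers, 500 genes, 100 sets of 20 genes with 10
signal sets drawn from an overlapping 100-gene pool, a 1,000-node network
with mean out-degree 30 and one planted hub with 10 targets of which 8
are superset genes — was chosen once as a desk-scale stand-in for a
consortium GWAS analysis. Two choices deserve explanation:

- *Null sets are drawn from non-signal genes*, so recovery and
  false-positive counts against the recorded truth are unambiguous.
  Setting `nSignalSets = 0` reverts to drawing from the full universe.
- *Mean out-degree 30 and calibration supersets of ~30 % of nodes* were
  fixed from an analytic computation of the hypergeometric attainable
  tail: the KDA p-value is discrete, and with small neighborhoods the
  probability of $p < 0.05$ under the exact null falls well below 0.05
  purely through discreteness. The chosen scale keeps the null
  calibration informative rather than vacuously conservative.

What the generator does **not** emulate: realistic human LD maps and
allele-frequency spectra, chromosome-scale positional structure,
scale-free in-degree correlations, overlapping pathway ontologies, or
expression data. Passing tests therefore demonstrate the statistical
machinery — calibration, recovery of planted structure, agreement with
brute-force oracles — not performance on any particular real cohort.

## Known limitations

- **Greedy pruning is not monotone in `r2Max` in general.** For graded
  LD values one can construct inputs where raising the cutoff removes a
  previously kept marker (acceptance order shifts). Under block-structured
  LD — equal r² within a block, zero across — kept sets do nest as the
  cutoff rises, and that is the regime the generator produces and the
  tests verify. Users applying unusual graded LD tables should not assume
  nesting across cutoffs.
- **Discrete hypergeometric conservatism.** KDA p-values are exact but
  discrete; for sparse networks (typical Bayesian gene regulatory
  networks have low mean degree) the fraction of null nodes below any
  nominal level is below that level. Interpret KDA FDRs as conservative.
- **Permutation resolution.** The smallest achievable empirical p is
  $1/(n_\text{perm}+1)$; with 1,000 permutations and BH correction over
  many sets, ties at the floor are expected. Raise `nPerm` when ranking
  among top sets matters.
- **Calibration estimates at 100 sets are noisy.** A fraction of sets
  below 0.05 estimated from 100 (correlated) sets has a standard error
  near 0.02; single-seed estimates scatter accordingly.
- The second-round confirmation reuses the same GWAS data that selected
  the sets; it guards against merge artifacts, not selection bias — the
  two-dataset intersection is the replication instrument.

## Problem sizes used by the test suite

Unit tests run on purpose-built fixtures of a dozen markers and a handful
of genes, where every expected value is enumerable by brute force. The
property and calibration tests use the generator defaults above (100 sets
× 1,000 permutations; 20 networks of 1,000 nodes for null calibration; 10
seeds for planted-driver recovery), sizes chosen so the whole suite runs
in a few minutes on one CPU while keeping Monte-Carlo error well inside
the asserted bands.
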