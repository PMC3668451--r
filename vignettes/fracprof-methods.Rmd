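---
title: "Methods: size-fractionated metagenome profiling with fracprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-fractionated metagenome profiling with fracprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracprof)
```

## Scope and inputs

`fracprof` analyses *post-annotation* hit tables from size-fractionated
shotgun metagenomes. Annotation itself (BLAST/HMM searches against
COG, KEGG, Pfam or SSU rRNA reference databases) is upstream and out of
scope: the package consumes the tables such pipelines emit — one row per
read with a lineage, a percent identity, an alignment fraction,
functional category IDs and an optional single-copy-marker flag — plus
per-fraction metadata (habitat, post-QC read totals, environmental
measurements). All coordinates are 1-based inclusive throughout.

## Identity tiers

Peptide annotations are filtered at a minimum percent amino-acid
identity over a minimum fraction of the read's aligned peptide length.
The conventional operating points are 30, 60 and 90 % identity over 70 %
of the alignment length: the permissive tier resolves domain-to-family
structure, the middle tier family-to-genus, and the strict tier
genus-to-species at a heavy cost in retained reads. Both comparisons are
inclusive (`>=`), so a hit at exactly 30.0 % and 0.70 passes the default
tier; the filter is monotone, with each stricter tier a subset of the
looser ones.

## Abundance denominators and the unclassified pool

A taxon's relative abundance in a fraction is
`100 * n(taxon) / N`. The denominator `N` is an explicit mode, because
published community profiles switch between conventions: total post-QC
reads (the default, taken from the metadata), total prokaryotic,
bacterial or eukaryotic annotated peptides (computed from the hit table
itself), or total SSU rRNA reads for rRNA composition. Reads lacking the
requested rank are pooled into an explicit `unclassified` row rather
than silently dropped, so columns over an exhaustive, mutually exclusive
taxon set sum to exactly 100 when the denominator matches the hit
universe. The prokaryotic-peptide denominator counts only reads
classified to Bacteria or Archaea at the domain rank; domain-unclassified
reads are excluded from it (the alternative — counting them in — is not
recoverable from an annotated table without a classifier, so the
narrower, well-defined convention was chosen).

## Significance between percentages

Abundances are percentages with known count denominators, so their
sampling structure is binomial. The package therefore tests differences
with the pooled two-proportion z statistic

$$z = \frac{p_1 - p_2}
{\sqrt{\bar p (1-\bar p)\,(1/n_1 + 1/n_2)}},$$

with a two-sided normal p-value, rather than a t-test on the two
percentages (which would have no replicate variance to estimate). A
Welch-style unpooled variant is available via `method = "welch"` for
users who want the alternative kernel. Degenerate pools
($\bar p \in \{0, 1\}$) are defined as $z = 0$, $p = 1$. The statistic is
exactly antisymmetric under swapping the samples.

## D-score differential functional abundance

The same kernel, applied to a functional category's counts in two
fractions, is the D-score. The conventional decision rule flags
categories with $|D| > 2.33$; 2.33 is the ~0.99 normal quantile, so the
one-sided tail is ≈ 0.0099 — coherent with the usual "p < 0.009"
phrasing of the rule. The threshold is applied to $|D|$ with the sign
reported (positive = enriched in the first fraction); under the null the
flagged share is ≈ 2 % of categories, which the test-suite verifies over
1000 simulated null categories. No multiple-testing correction is
applied by default, matching the fixed-threshold convention; a
`p_adjust` argument switches one on. Totals default to the fractions'
annotated peptide counts and can be overridden (e.g. with
genome-equivalent-scaled totals) through `n1`/`n2`.

## Effective genome size

Genome equivalents and effective genome size (EGS) derive from the
density of a set of 35 near-universal, mostly single-copy bacterial
marker proteins among bacterial peptides. The model is deliberately
transparent: an average genome of size $S$ Mbp at gene density $d$
genes/Mbp carries 35 markers among $S\,d$ genes, so the expected marker
fraction is $35/(S\,d)$ and

$$\mathrm{EGS} = \frac{N_\mathrm{bact}}{G \cdot d},\qquad
G = \frac{m}{35},$$

for $m$ marker hits among $N_\mathrm{bact}$ bacterial peptides. The
calibration density $d$ defaults to 1000 genes/Mbp — the canonical ~1
gene per kilobase of prokaryotic genomes — and is an explicit parameter,
so published regression calibrations can be dropped in. The estimate is
scale-invariant (doubling all counts changes nothing) and monotone
decreasing in marker density. Because real annotation pipelines classify
only a fraction of reads, absolute EGS values from real tables are
magnitude estimates, not exact genome sizes; the test-suite instead
verifies *parameter recovery*: on simulated communities the estimator
returns the known genome size (or the read-share harmonic mean of a
mixture) within 10 % at 10^5 reads. Per-genome-equivalent category
abundance is then simply `category hits / G`, the "hits per average
bacterial genome" scale on which 1.0 means about one gene copy per
genome. Multi-copy markers are not modelled (per-marker copy weights
would enter as a correction to the 35); the marker set itself is a
configurable argument everywhere.

## Recruitment profiles

Hits pre-placed on a reference chromosome are binned into identity tiers
(default [30, 90) and [90, 100]; the boundary hit at exactly 90 % goes
to the upper tier — one side must be closed, and closing the
high-identity tier keeps "same-species" recruitment conservative).
Depth is residue-based: each hit increments every position of its
interval, and X-coverage is the summed aligned length divided by the
reference length, the standard coverage definition (an alternative
read-count × mean-length convention would differ only by rounding).
Locus-window counts use ≥1-position overlap. Mean-identity contrasts
between two metagenomes use a two-sample Welch t-test on the per-hit
identities; sets with fewer than two hits are rejected rather than
returning an undefined variance.

## SSU rRNA diversity

rRNA hits are filtered at E ≤ 1e-30 (the cutoff is inclusive — "cutoff"
is ambiguous and the inclusive reading was fixed and documented).
Fragments are then dereplicated to < 97 % identity, the conventional
species-level OTU radius, by greedy longest-first clustering: fragments
are scanned from longest to shortest and each joins the first
representative with which it shares ≥ 97 % identity, where identity is
the number of matching positions within the two fragments'
reference-coordinate overlap divided by the shorter fragment's length
(disjoint fragments score 0 and can never merge). Greedy longest-first
is the standard radius heuristic (cd-hit style); its output is
idempotent and pairwise below the radius. OTU richness is the **maximum
alignment depth**: the largest number of dereplicated fragments covering
any single position of the full-length reference gene. This estimator is
conservative — it can only count co-located variants — which is exactly
why the synthetic fragment generator places all planted OTU clusters
over a common anchor position: the construction makes the true count
recoverable, and the suite checks exact recovery for 1, 5 and 23 planted
OTUs. A `raw_depth` flag counts depth on the filtered but
un-dereplicated fragments instead, for comparison. Normalized diversity
is OTUs per total group rRNA hit, and group contrasts are reported as
percent difference of normalized diversities.

## Clustering and PCA

Family-level matrices are reduced to families exceeding 0.1 % abundance
(strict inequality) in at least one fraction, then clustered in 2D with
complete linkage under 1 − Pearson correlation distance — the
convention of the classic Cluster/TreeView lineage of tools; Euclidean
distance is available, and is suggested automatically when a constant
row makes the correlation undefined. Inputs are label-sorted before
clustering so results are invariant under input permutation, with ties
broken deterministically by label order. Abundances are clustered on the
raw percentage scale by default (a log10(x + ε) transform is a
pre-processing choice left to the caller, since the appropriate ε
depends on the detection floor of the data). Dendrograms serialize to
Newick with the standard ultrametric convention (tip-to-tip path length
equals merge height). PCA is centered (optionally unit-scaled), with
each component's sign fixed so its largest-magnitude loading is
positive, making scores reproducible across linear-algebra backends.

## Replicate-read filter

454-style artificial replicates are removed by a greedy single pass:
a read is dropped iff it begins with the same three nucleotides as an
earlier *kept* read and exceeds 90 % nucleotide identity with it. The
identity computation is ungapped and prefix-anchored over the shorter
read's length — the natural reading for same-start pyrosequencing
duplicates, mirroring cd-hit-style dereplication — since replicate
artifacts share their start by construction. First occurrence wins, so
the filter is idempotent.

## The synthetic-data generator

`community_truth()` + the three `simulate_*()` generators emulate what
an annotation pipeline would emit for a known community:

- taxa are drawn multinomially from the truth weights;
- percent identity per read follows a per-taxon truncated normal on
  [30, 100] (inverse-CDF sampling, not clamping), so close relatives
  recruit into the 30–90 band and same-species taxa into ≥ 90;
- alignment fraction has a configurable mass (default 0.15) below the
  0.7 length cutoff;
- marker incidence is Bernoulli with probability $35/(S\,d)$ tied to the
  source taxon's genome size, which is what makes EGS recovery a
  meaningful test;
- categories are per-read Bernoulli draws from per-taxon profiles.

Every generator is a pure function of (parameters, seed): it saves and
restores the caller's RNG state. What the generators do **not** emulate:
annotation errors (mis-assigned lineages), database bias, chimeras, or
raw-read artifacts — so green tests demonstrate the correctness of the
downstream computations, not robustness to upstream annotation noise.

## Problem sizes and numerical choices

The test-suite and acceptance script run at desk scale: EGS recovery on
10^5-read communities, the D-score null on 1000 categories × 2×10^5
draws, OTU recovery on 230- and 75-fragment designs, clustering oracles
on 6×6 matrices, and the demo pipeline at 4 habitats × 3 fractions ×
5000 reads — sizes chosen so the whole suite completes in well under a
minute while keeping sampling error far inside the asserted tolerances.
Headline quantities from the original multi-Gbp field datasets (e.g.
absolute family counts or EGS values of specific samples) are not
desk-scale reproducible and are treated as magnitude envelopes only:
the demo communities are patterned to land in the plausible 0.5–5 Mbp
EGS band for marine bacterioplankton.

Degenerate inputs follow fixed conventions: 0/0 pigment ratios return
0 % with a warning (aphotic deep water has no pigments); zero marker
hits leave EGS undefined rather than infinite; zero denominators error
naming the offending column; empty fragment sets yield OTU count 0.

## Known limitations

- EGS assumes single-copy markers and a uniform gene density; both are
  configurable but not estimated from data.
- The OTU-by-depth estimator undercounts when variants of a group tile
  disjoint parts of the gene.
- The D-score's fixed 2.33 threshold controls per-comparison error only;
  use `p_adjust` when scanning many categories.
- Lineages are taken verbatim from the input annotation; no taxonomy
  reconciliation is attempted.
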