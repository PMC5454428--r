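---
title: "Linking prasinovirus gene content to marker-gene phylogeny"
author: "PanPhylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking prasinovirus gene content to marker-gene phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanPhylo)
```

## The question and the model

Prasinoviruses carry a small conserved core genome and a large flexible
pan-genome. Whole-genome comparisons are only possible for cultured
isolates; environmental surveys see short marker-gene amplicons (family-B
DNA polymerase, DNApol). The analysis this package implements asks: does
the phylogeny of the marker predict overall gene content? If yes, the
distribution of marker sequences across environments is informative about
the distribution of genetic repertoires.

Three quantitative layers make that question testable.

**Gene-content distance.** Predicted proteins from all genomes are pooled
and clustered greedily at a fractional amino-acid identity threshold
(default 0.5). Identity is computed from a BLOSUM62 global alignment
(affine gaps, open 11 / extend 1) as identical residue pairs over
alignment columns, with terminal-gap columns excluded and internal gap
columns counted — the same identity definition BLAST reports. From the
genome-by-cluster incidence matrix, the distance between genomes $i$ and
$j$ is

$$D_{ij} = -\ln\!\left(\frac{S_{ij}}{\sqrt{N_i N_j}}\right),$$

where $S_{ij}$ is the number of shared clusters and $N_i$, $N_j$ the
per-genome cluster counts. Identical repertoires give 0; disjoint
repertoires are undefined, so $S_{ij}=0$ is replaced by a 0.5 pseudo-count
and the pair is flagged (`attr(d, "cappedPairs")`) rather than made
infinite, keeping neighbor joining defined.

**Marker distance.** Pairwise maximum-likelihood distances between aligned
DNApol proteins under the WAG replacement model: columns gapped in either
sequence are dropped (pairwise deletion maximizes usable signal per pair),
and the per-site log-likelihood $\sum \log(\pi_x P_{xy}(t))$ is maximized
over $t \in [10^{-6}, 20]$ by bracketed 1-D optimization (tolerance
$10^{-8}$), with $P(t) = e^{Qt}$ from the eigendecomposition of the
normalized rate matrix. No among-site rate variation is modeled; the model
name is the only published detail of the original distance computation, and
a gamma extension would slot into `SubstitutionModel` without interface
changes. Note this replaces a full ML tree search: the congruence analysis
consumes *distance matrices*, so pairwise ML distances plus neighbor
joining are sufficient, and the shipped reference DNApol matrix is the
fixture of record. Exact reproduction of that matrix from raw sequences is
not claimed.

**Congruence.** A Mantel test correlates the two distance matrices:
Pearson correlation of the strict lower triangles after aligning label
order, with significance from permuting one matrix's labels (default 999
permutations, upper tail, $p = (\#\{r_\pi \ge r\} + 1)/(B + 1)$). Pearson
is used because it reproduces the published correlation for the
11-prasinovirus panel exactly; a rank-based variant would be a
one-argument change but is not claimed.

## Trees and support

Neighbor joining is delegated to `ape::nj` — the implementation used in
the original analyses of this field — with negative branch lengths clamped
to zero (total deficit recorded in an attribute). Branch support comes
from resampling gene-cluster columns of the presence-absence matrix:
bootstrap (with replacement, full column count) by default, because
"bootstrap" is the established name for this procedure; an 80% jackknife
is available as a flagged alternative. Resampled matrices that leave a
genome with an empty repertoire are redrawn, since $D_{ij}$ is undefined
there. Supports are the fraction of replicate trees containing each
bipartition of the reference tree.

## Amplicon calibration and environmental OTUs

Short amplicons must be clustered at an identity level that makes clusters
specific to full-length marker divergence. `calibrationCurve()` clusters
the reference amplicons at each candidate threshold, pools the full-length
pairwise distances within multi-member clusters, and reports the sample
(n−1) standard deviation; `selectThreshold()` picks the smallest threshold
whose spread falls below a tolerance (default 0.05 distance units). On the
packaged-style reference panels this selects 0.97, the threshold then used
for environmental reads.

Environmental analysis pools reads with reference amplicons, seeds the
references as the first centroids (so reference-anchored OTUs keep stable
ids regardless of read order), clusters at 0.97, discards singleton
clusters (a read-less reference cluster counts as a singleton unless
explicitly kept), assigns reads to their best centroid at the same
threshold (ties to the earliest centroid; sub-threshold reads tallied as
unassigned), and rarefies every sample without replacement to the minimum
cumulative depth via `vegan::rrarefy`. Exact duplicate reads are collapsed
before alignment and re-expanded afterwards.

## What the simulator emulates

The synthetic-data module generates the study system at roughly the scale
of the real one: a dozen genomes of a few hundred protein-coding genes, a
~900-residue marker, 140-residue amplicon windows, and per-sample read
abundances.

- **Tree**: pure-birth (Yule, unit rate) with branch lengths rescaled to
  tree height 1. The real data are isolates, not a generative sample, so
  any branching prior suffices for recovery tests; Yule is the simplest.
- **Gene content**: the root carries `rootFamilyCount` families; along a
  branch of length $t$ each family is lost with probability
  $1 - e^{-\mu t}$ and $\mathrm{Poisson}(\lambda t)$ families are gained,
  each gain being novel or (with probability `hgtFraction`) copied from a
  uniformly chosen branch alive at the event time. The donor contributes
  its branch-start repertoire; within-branch event ordering is not
  tracked. Defaults: 12 taxa, $G_0 = 150$, $\mu = \lambda = 0.3$,
  `hgtFraction` 0.2 — chosen to keep leaf repertoires in the 100–250 range
  of real prasinovirus CDS counts with a realistic flexible fraction.
- **Family sequences**: each family gets a random prototype (length
  uniform in 65–800 residues, honoring the 65-aa minimum ORF length of the
  emulated annotation pipeline; residues from WAG stationary frequencies);
  genome copies are mutated to ~80% identity, far above the 50% clustering
  threshold, while unrelated families sit near random-sequence identity
  (<0.3), far below it. Substitutions draw from the stationary
  distribution excluding the current residue.
- **Marker**: root from WAG stationary frequencies, sites evolving
  independently via $P(t)$; no indels, so leaves form a gap-free
  alignment.
- **Environmental samples**: lineage pool = references plus novel
  lineages (a reference mutated to a uniform 85–95% identity, i.e. below
  the 97% OTU threshold but recognizably related); per-sample abundances
  log-normal (meanlog 0, sdlog 1), reads multinomial at fixed depth, with
  ≤1% per-residue read noise (default 0.5%).

What the simulator does **not** emulate: indels and alignment error,
sequencing chimeras and denoising artifacts, within-genome paralogy,
GC/codon structure (everything is amino-acid level), and any ecological
covariate structure. Passing recovery tests therefore demonstrates the
correctness of the statistical machinery on clean, model-consistent data,
not robustness to those real-data complications.

## Numerical choices and degenerate inputs

- Identity threshold comparisons use `>=`; records are processed in
  decreasing length order with lexicographic (C-collation) id
  tie-breaking, so clustering is deterministic for a given input set.
- `X` residues match nothing in identity counting (conservative), and
  columns containing `X` or gaps are dropped from model-based distances.
- Distance matrices must be exactly symmetric with zero diagonal; readers
  validate this. TSV serialization uses 4 decimals.
- The ML distance of identical sequences is reported as the optimizer's
  lower bracket ($\approx 10^{-6}$), not exactly 0.
- Rarefaction errors on zero-total samples; an OTU table that is already
  at even depth passes through unchanged apart from the rarefied flag.
- All stochastic operations take explicit seeds and restore the caller's
  RNG state, so runs are byte-reproducible.

## Scale of the validation suite

The test suite exercises the pipeline at deliberately modest sizes chosen
as representative rather than exhaustive: clustering recovery on 4 genomes
with a 15-family root repertoire (alignment-based clustering is the one
expensive step; identity structure is what the property tests), tree
recovery on 50 simulated 12-taxon replicates, Mantel calibration on 500
independent 10-label matrices, and threshold calibration on a 30-sequence
strain-structured reference panel (10 divergent lineages, each with two
strains at short WAG branch lengths 0.01 and 0.03, giving within-cluster
full-length distances that shrink as the amplicon threshold rises).

## Known limitations

- With the default simulation parameters, the shortest internal edges of a
  height-1 Yule tree on 12 taxa carry well under one expected gene
  gain/loss event at $G_0 = 150$, so neighbor joining cannot resolve every
  split from a single presence-absence matrix; perfect topology recovery
  should only be expected on the analytic (expected-distance) matrices,
  which the suite verifies separately.
- The greedy clustering is order-dependent by design (it emulates
  centroid-led clustering); centroids are not guaranteed mutually below
  the threshold.
- $D_{ij}$ is not guaranteed metric; NJ is applied regardless, as in the
  original analysis.
- The amplicon window position within the marker is configurable and not
  claimed to match the real PCR primer coordinates, which are unpublished.
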