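---
title: "Methods: virus-host community ecology for AMD sediment metagenomes"
author: "amdvir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virus-host community ecology for AMD sediment metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the analysis

`amdvir` implements a population-level analysis of viral communities in
extreme, geochemically structured habitats — the motivating system is acid
mine drainage (AMD) sediment metagenomes, where reduced community
complexity and steep environmental gradients make virus-host ecology
unusually tractable. The pipeline takes viral and prokaryotic genome
sequences, read-alignment depth information, and sample metadata, and
produces:

1. species-level viral populations (vOTUs) and dereplicated prokaryotic
   populations;
2. normalized coverage-based abundance matrices;
3. in-silico virus-host links from three independent lines of evidence;
4. lineage-level interaction summaries (virus-host abundance ratios,
   abundance correlations, host range and viral range, lifestyle trends);
5. bipartite interaction-network structure (Barber modularity by BRIM,
   NODF nestedness, permutation nulls) per sample;
6. biogeographic statistics (Hellinger/Bray-Curtis, PCoA, Mantel tests,
   scale-partitioned distance-decay regression); and
7. recursive path models attributing viral diversity and composition to
   abiotic and biotic drivers, with chi-square and RMSEA fit.

Upstream read QC, assembly, viral identification, binning, and taxonomy
assignment tools are out of scope: the package consumes their outputs
(genome FASTA, quality estimates, taxonomy and lifestyle tables).

# Sequence comparison and clustering

## ANI and alignment fraction

A genome pair is summarized by average nucleotide identity (ANI) — the
alignment-length-weighted mean percent identity over non-redundant local
hits — and the alignment fraction (AF) of the *shorter* sequence, the
percentage of its length covered by non-overlapping aligned intervals.
`computeAniAf()` accepts external 12-column tabular hits so results can be
reproduced from any standard aligner; otherwise a built-in aligner is
used:

* **Equal-length, near-identical pairs** are compared positionwise — a
  band-0 banded global alignment. This is exact when divergence consists
  of substitutions only (the synthetic-data generator's model) and is
  accepted only when the resulting identity is at least 85%, so diverged
  or rearranged pairs fall through to the general path.
* **General pairs** use exact 15-mer seed matching, chained along
  diagonals with a 400 bp gap tolerance. Because chains stay on one
  diagonal, the implied alignment is ungapped and its identity is
  computed exactly by direct comparison. Both strands are searched.
* A Needleman-Wunsch global alignment (via `Biostrings`) is the fallback
  for similar-length pairs the fast paths reject.

The 400 bp chain gap is set so that, at the highest divergence the
generator plants (10% per site), the probability of a seed desert long
enough to split a 3 kb homologous segment is negligible (< 1e-5), while
random sequences essentially never share even one 15-mer diagonal run.

## Clustering rules

* **vOTUs** (`clusterViralPopulations()`): greedy centroid clustering at
  95% ANI and 85% AF; genomes are processed longest-first with ties broken
  by identifier, and each joins the first representative meeting both
  thresholds. Whether published pipelines used greedy-centroid or
  connected-component grouping at this step is ambiguous, so
  `linkage = "single"` is available; the default is centroid, the
  behaviour of the reference clustering scripts this step mirrors.
* **Prokaryotic populations** (`dereplicateProkaryoteGenomes()`):
  single-linkage grouping at 97% ANI / 70% AF; the representative
  maximizes completeness − 4 × contamination (ties by identifier). Single
  linkage is used here because representative choice by a quality score
  only makes sense after grouping.
* **Protein clusters** (`clusterProteins()`): greedy longest-first at 60%
  global identity and 80% coverage of the shorter sequence, the
  functional units ("PCs") counted downstream.

All orderings are canonicalized (length descending, then identifier), so
cluster output is invariant to input order.

# Coverage and abundance

Read alignments are filtered at ≥ 95% identity and aligned length ≥ 75% of
the read. Per-base depths are summarized by the trimmed mean
(`tpmeanCoverage()`): the `floor(0.05 · L)` lowest and highest positions
are dropped — "regions" are interpreted as per-base positions, matching
the behaviour of the coverage tool this reproduces — and the floor rule
means short sequences at small trims degrade gracefully to the plain
mean. Abundance is

> coverage ÷ library read count × mean library read count,

which makes values comparable across libraries and exactly invariant
under joint rescaling of a sample's depths and library size. Depth tracks
are stored run-length encoded (`entity`, `sample`, `length`, `depth`);
real-valued depths are accepted even though raw per-base depths are
integers, since normalized and averaged tracks are not. Protein-cluster
abundance is the *sum* of member-gene abundances (the only roll-up
consistent with read counting; a mean is available), and per-sample viral
abundance aggregates vOTU rows by summation.

# Virus-host linkage

Three independent evidence channels produce genome-level pairs that are
then aggregated to populations with evidence unions and support counts:

* **Genome homology**: nucleotide hits filtered at E ≤ 1e-3, bit score
  ≥ 50, alignment length ≥ 2.5 kb and identity ≥ 70% — all four must
  hold.
* **Prophage provenance**: a provirus excised from a host scaffold links
  to the genome containing that scaffold. Provenance is carried as
  metadata (`source_scaffold`), since viral identification itself is out
  of scope.
* **CRISPR spacers**: a minimal CRT-like detector finds arrays of ≥ 3
  identical repeats (19-47 bp) separated by mutually distinct spacers
  (20-58 bp); spacers match a viral genome only by an exact, full-length
  substring hit on either strand. Zero mismatches over the whole spacer
  makes a separate E-value computation redundant for spacers ≥ 20 bp,
  which is why short spacers are rejected with a warning rather than
  scored. Degenerate (mismatch-containing) repeats are a known
  limitation of the detector. Both-strand matching is the default
  (`bothStrands = FALSE` disables it); whether published analyses
  required both strands is not documented.

Coordinates are 0-based half-open internally and 1-based inclusive in
tabular alignment I/O.

# Lineage-level dynamics

The virus-host abundance ratio (VHR) of a host phylum in a sample is the
summed abundance of virus populations linked to that phylum divided by
the summed abundance of the phylum's host populations; samples where
either sum is zero are excluded, and the lineage summary is the mean of
per-sample log10 ratios (`mean-of-ratios`; `ratio-of-means` is provided
because the published plots do not pin down the aggregation). Viruses
linked to several phyla contribute their full abundance to each — the
natural reading of "viruses infecting the same host lineage" — with an
optional equal split. Host range (distinct hosts per virus) and viral
range (distinct viruses per host) are averaged per lineage. Lifestyle
trends regress the per-sample summed relative abundance of virulent and
temperate populations on total prokaryotic abundance; lineage-level
virulent:temperate ratios are compared with an unpaired Wilcoxon test.
Quadratic (degree-2) fits are the default for the abundance-abundance
relationship, the lowest-order curve able to express the observed
peaked pattern.

# Network structure

Per-sample sub-networks are induced from the meta-network by the
populations detected (abundance > 0 by default) in the sample; isolated
nodes stay in node lists but are dropped from metric matrices. Barber's
bipartite modularity is maximized by BRIM label iteration; the initial
random labelings use the ⌈√min(r, c)⌉ module-count rule, but spare empty
labels (up to min(r, c)) are kept so modules can split as well as merge —
without them, optima needing more modules (e.g. disconnected components)
are unreachable — and the first restart uses a deterministic
maximal-spread labeling. With 50 restarts the implementation matched the
exhaustive optimum on every one of 450 random ≤ 10-node graphs in
development testing; 20 restarts is the default for routine use. NODF
follows the overlap-and-decreasing-fill definition over row and column
pairs and is therefore invariant to row/column order and transposition.
Permutation nulls default to the equiprobable model (Bernoulli at
observed fill, degenerate draws redrawn), with a checkerboard-swap
degree-preserving alternative; empirical p-values use the add-one form
(1 + #{null ≥ observed}) / (1 + n), so zero p-values cannot occur at
finite permutation counts.

# Biogeography

Community matrices are Hellinger-transformed before Bray-Curtis
dissimilarity; environmental tables are z-scored before Euclidean
distance (both via `vegan::decostand`/`vegdist`). Geographic distances
are haversine on a 6371 km sphere. PCoA is classical scaling with
negative eigenvalues reported but dropped by default (the plain-PCoA
convention; a Lingoes correction is available behind the `correction`
flag) and axis signs fixed so the largest-magnitude loading is
positive. The Mantel test correlates
strictly-lower-triangle entries with a joint row/column permutation null
and add-one one-sided p. Pairwise Pearson correlations use analytic
two-tailed p-values — the permutation count sometimes quoted alongside
`rcorr`-style analyses is ambiguous, and permutations are reserved for
the Mantel test, which actually needs them — adjusted by a hand-coded
Benjamini-Hochberg step-up (`bhAdjust()`). Distance-decay regression
fits similarity (1 − Bray-Curtis) on log10 km over all pairs, and
separately over local (≤ 1 km) and regional (> 1 km) pairs; zero
geographic distances are replaced by half the smallest positive distance
before the log and flagged. Pairs, not samples, are the regression units,
matching the standard presentation; no non-independence correction is
applied to the OLS p-values — the Mantel test is the inferentially sound
companion.

# Path models

`fitPathModel()` performs observed-variable recursive path analysis:
variables are standardized, each endogenous variable's coefficients are
estimated by OLS on its stated parents (maximum likelihood for recursive
models with independent errors), and the model-implied covariance is
assembled by path tracing with exogenous covariances freed (all of them
by default, since published diagrams rarely list which were freed).
Fit uses the ML discrepancy, χ² = (n − 1)F, df = moments − free
parameters, and RMSEA = √(max(0, (χ² − df)/(df(n − 1)))); a saturated
model reports χ² = 0 and RMSEA 0 with a flag. Model specifications are a
plain-text edge list (`MAT -> prok_abundance`, `lat ~~ pH`); model
refinement is manual, not automated search. The shipped
`examplePathSpec()` is a seven-variable model in the spirit of
latitude/climate/geochemistry → prokaryotes → viruses driver diagrams;
its planted standardized coefficients keep every endogenous implied
variance below 1, a feasibility requirement a published partial
coefficient set does not satisfy on its own, so magnitudes are the
package's own calibration with the published signs and topology.

# The synthetic-data generator

`simConfig()`/`simulateDataset()` define the study conditions everything
is tested under. Defaults: 6 sites × 5 samples across 23-32°N /
106-118°E (an AMD-belt-like extent), 4 host phyla × 5 ranked host
populations (two MAG replicates each at 1.5% divergence), one viral
cluster per host — an ancestor (10-14 kb, uniform random over ACGT) plus
one substitution-only copy per divergence level (3% and 10%; expected
ANI is analytically 100(1 − d), which makes clustering tests exact, and
a 10 kb genome floor mirrors the conventional viral size cutoff).
Planted links: each host's primary virus, a nested within-phylum
generalism gradient (the rank-r first virus also infects ranks < r),
and cross-phylum links for top-rank viruses. Evidence is planted
physically — full prophage insertions at recorded coordinates, CRISPR
arrays whose protospacers are exact viral segments, and 3 kb shared
segments — and the truth table derives evidence-defined links from the
generator's substitution bookkeeping (e.g. a 10%-diverged copy counts as
a CRISPR target only if no substitution fell inside the protospacer).
Background genomes are i.i.d. uniform, so spurious ≥ 2.5 kb homology is
vanishingly unlikely and truth tables stay clean.

Ecology: host abundances are lognormal around a rank-dependent base,
attenuated by an exponential spatial kernel from a random home site,
modulated by a phylum-specific response to the metadata's prokaryotic
abundance driver; a latitudinal richness gradient removes the rarest
(highest-rank) populations first moving poleward, which simultaneously
plants the network generalism gradient (rich, equatorward samples gain
the generalist viruses, so modularity falls and nestedness rises with
richness). Virus abundance is the planted per-phylum VHR times the
summed abundance of its present linked hosts times lognormal noise;
`noise_sd = 0` gives the noise-free limit in which lineage VHRs are
recovered exactly. The kernel decay length is calibrated numerically
against the target distance-decay slope on a fixed grid, and the truth
table stores the *realized* slope — the mean over five independent
internal noise replicates of the emitted layout, under the pipeline's
own Hellinger/Bray-Curtis convention — because lognormal noise
attenuates similarity decay and the noise-free kernel slope would
misstate what the emitted data embody. Metadata come from the configured
structural equations with the latitude variable anchored to true sample
latitudes. Within-site sample dispersion (0.4 km jitter) is a free
parameter, chosen so local (≤ 1 km) pairs exist for the scale-split
regression; field surveys rarely report this quantity.

What the generator does **not** emulate: read-level sequencing error and
assembly artifacts, indels and rearrangements, chimeric genomes,
realistic geochemical covariance among metadata variables, degenerate
CRISPR repeats, and host genomes of realistic (Mb) size. Passing tests
therefore demonstrate correctness of the analysis logic under a clean,
fully specified generative model — not robustness to the full messiness
of real metagenomes.

# Problem sizes and numerical choices

Routine runs and the shipped checks use communities of ~70 viral and 40
host genomes of 10-14 kb over 30 samples, 100-graph modularity oracles,
1000 Mantel null simulations at n = 20 with 999 permutations, and 200
path-model replicates at n = 500 — sizes chosen so the full suite
completes in minutes on one core while keeping every statistical check
well-powered. Other numerical conventions: ties in all greedy orderings
break by identifier; empty hit sets yield ANI/AF (0, 0) rather than
errors; Bray-Curtis between two all-zero samples is defined as 0 with a
warning; zero-variance variables are flagged undefined rather than
dropped silently; and all randomness flows from one seed through
`deriveSeed(seed, stage)`, so stage-level reruns are independently
reproducible.

# Known limitations

Homology E-values use ungapped Karlin-Altschul constants and are
approximate (the linkage thresholds on ≥ 2.5 kb hits are insensitive to
this); the CRISPR detector requires exact repeats; BRIM is a heuristic —
restarts trade time for optimality and only small graphs can be verified
exhaustively; OLS distance-decay p-values ignore pair non-independence
by design; and the path fitter covers observed-variable recursive models
only (no latent variables, no bootstrap standard errors).
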