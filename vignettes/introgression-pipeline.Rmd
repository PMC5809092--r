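---
title: "Painting donor ancestry and scoring introgression in conjugation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting donor ancestry and scoring introgression in conjugation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The analysis problem

In an evolve-and-resequence experiment with horizontal gene transfer, Hfr
donor strains (here, *E. coli* K-12 derivatives) are repeatedly mixed into
recipient populations (*E. coli* B derivatives adapted to the experimental
environment) and allowed to conjugate. After hundreds of generations, each
sequenced recombinant clone is a mosaic: a recipient "clonal frame"
interrupted by donor-derived tracts. Because the two source strains differ
at roughly 8 sites per kilobase, almost every transferred tract carries
dense diagnostic markers, and the analysis reduces to set algebra over
variant call tables from donors, recipients, and recombinants — all called
against one shared reference chromosome with 1-based, inclusive
coordinates.

`introscan` implements that pipeline end to end: provenance labeling,
chromosome painting, genome-binned introgression statistics, locus-level
allelic-state and gene-conversion analysis, two-timepoint allele-frequency
dynamics, and a forward simulator of the whole experiment that produces
truth files for testing.

## Provenance labels

`label_mutations()` classifies every site that appears in the recombinant
(R), its parent recipient (P), or the union of donor call sets (D), by
membership alone:

* R∩P, not D — a recipient-lineage (`LTEE`) mutation that survived.
* R∩D, not P — a horizontally transferred donor allele (`K12`); when the
  site is specific to exactly one donor strain it is additionally
  attributed to that donor (`donor_origin`), giving the per-donor
  subcategories used by `donor_marker_counts()`.
* R only — a `NEW` mutation that arose during the experiment.
* D only (not P, not R) — a `REL606` marker: a site differentiating the
  donor and recipient backgrounds at which the clone retains the recipient
  allele.
* P, not R — a `DELETED` recipient mutation, erased by recombination or
  lost; `in_deleted_region` flags those inside a large deletion called in
  the recombinant.

Sites present in all three inputs are uninformative and are ignored. Two
boundary conventions deserve note. First, the transferred category
additionally requires absence from the recipient, so that it is disjoint
from the recipient-shared category; a marker carried by both parents has no
ancestry signal. Second, donor-side markers that fall inside a deletion
called in the recombinant can support neither ancestry state; they are
dropped with a logged count rather than silently labeled.

Site identity is the exact tuple (chrom, pos, kind, alt). Near-miss indel
positions are not merged: all inputs come from one caller on one reference,
so coordinate jitter between samples is not expected.

## Chromosome painting

True recombination breakpoints fall somewhere between the last marker of
one ancestry and the first marker of the other, so any painting is an
estimate. `infer_segments()` uses the alternating state machine with the
minimal estimate on the left edge of a donor segment (the segment starts at
its first donor marker) and the maximal estimate on the right (it ends at
the following recipient marker). Averaged over many segments, lengths tend
to the midpoint of the minimum and maximum estimates. The recipient-side
evidence is the `REL606` label: at a differentiating site, *absence* of the
donor allele is positive evidence for recipient ancestry.

Conventions, stated explicitly because the boundary cases are genuinely
underdetermined:

* The segment containing the first marker extends left to position 1. In
  circular mode (the default — the chromosome is circular and no forced
  break exists) the closure step re-applies the same switch rules across
  the origin, so this convention only matters for linear runs.
* If the first and last circular segments share a state they merge into one
  wrapping segment (`wraps = TRUE`, `start > end`).
* A recipient marker immediately followed by a donor marker leaves a
  zero-length recipient segment; it is dropped and its donor neighbours
  merge, preserving alternation.

Painting resolution is inherently marker-limited: a transferred tract
without donor-specific markers nearby cannot be assigned, and this is
reported through `n_markers` rather than special-cased. The bracketing
guarantee — every truly transferred marker falls inside a painted donor
segment, and painted donor length exceeds the true tract by at most one
inter-marker gap per side when tracts are contiguous — is enforced by the
test suite against simulated truth.

## Introgression and divergence statistics

`make_binning()` tiles the chromosome into fixed-width, half-open bins
(reported 1-based inclusive; the reference chromosome of 4,629,812 bp at
8,327 bp per bin gives 556 bins). `parallel_introgression()` counts, for
every differentiating site, the number of included clones carrying the
donor allele — one clone per population, with aberrant lineages excluded by
name. We count per differentiating site, not per linked event: adjacent
markers transferred together each contribute, which is the natural
site-resolution reading of a parallel-introgression profile.

`smooth_profile()` realizes "a natural cubic spline with 100 degrees of
freedom" as an ordinary least-squares fit on a natural cubic spline basis
(`splines::ns`) with knots at quantiles of the marker positions. Quantile
knots make the fit invariant to coordinate rescaling; the exact knot rule
is otherwise a free choice. The fit is a linear model and therefore
bit-reproducible.

`divergence_tests()` computes the Spearman rank correlation (tie-handled,
`stats::cor.test`) between per-bin divergence and per-bin event counts, and
a Kruskal–Wallis comparison of divergence between bins with and without
events. Constant inputs make the correlation undefined and are reported as
`NA`, not an error. Breakpoints are intervals, not points; for binning,
each segment boundary is assigned to the bin containing the midpoint of its
inter-marker uncertainty interval (`breakpoints_per_bin()`).

## Locus-level analyses

`classify_allelic_state()` compares variable-site sequences of one locus
across ancestor, donor, recipient, and recombinant, and returns one of four
states: donor-matching with donor ≠ ancestor; donor-matching with donor =
ancestor; ancestor-matching with ancestor ≠ donor; or a new (patchwork)
allele. Gaps act as a fifth symbol. The comparison consumes pre-aligned
variable sites; alignment construction is out of scope. The packaged
30-locus fixture (`replaced_loci_fixture()`) encodes the published allelic
relations of the replaced loci in odd-numbered non-mutator clones with
synthetic sequences — the relations among the four sequences are data, the
nucleotides themselves are constructed, and the file is named accordingly.
The strong-positive-selection flag is consumed as an input annotation; no
G-score threshold is derived, because the underlying statistic is an
external annotation (a parallelism-based evidence score from the asexual
long-term experiment).

Gene conversion is detected as three or more new mutations in the same gene
in the same genome (`detect_gene_conversion()`); the threshold is strictly
within-genome, since independent point mutations essentially never cluster
that densely, while a single non-orthologous replacement does.
`gscore_welch_test()` compares G scores between conversion-hit genes and
genes with other new nonsynonymous mutations using Welch's
unequal-variance t-test with Welch–Satterthwaite degrees of freedom.
`rec_mut_ratio()` computes the recombination:mutation ratio bounds for
synonymous changes, counting donor-segment mutations in the denominator for
the lower bound and excluding them for the upper; a zero denominator yields
an undefined (`NA`) bound — a value, not an error.

## Continuation dynamics

`frequency_change()` matches population samples from two timepoints by site
identity, treating sites absent from a sample as frequency 0 (the caller
reports variant sites only). `infer_lca()` takes "frequency equal to 1"
literally (within 1e-9 for float safety, since no tolerance is defined by
the experimental design) and intersects four sets: fixed at both
timepoints and present in both sequenced clones. `plasmid_frequency()` is
the ratio of mean plasmid to mean chromosome read coverage under the
one-chromosome-per-cell, one-plasmid-per-carrier assumption; values above 1
indicate multi-copy plasmids and are flagged, never clipped. Reported
values are rounded by the caller (two significant figures reproduces the
published table). `ratchet_fixation_probability()` states the hitchhiking
ratchet: a neutral donor allele at frequency *p* fixes with probability *p*
at the next clonal sweep.

## What the simulator emulates

`simulate_experiment()` generates the statistical structure the analysis
assumes, with truth files:

* **Marker landscape** — uniform differentiating sites at 8 per kb (the
  observed inter-strain density), a configurable fraction (default 0.2)
  specific to one of four donors, on a circular chromosome.
* **Transfer decay** — per-exposure transfer probability 10^-2.5 at 100 kb
  from oriT declining log-linearly to 10^-6 at 2.3 Mb, flat below the near
  anchor, zero beyond 60% of the chromosome. The two anchors only constrain
  two points; the log-linear interpolation between them is this package's
  choice. Tract lengths are drawn by inverting this law as a survival
  function.
* **Scaled-down default** — simulations default to a 200-kb circular
  chromosome, 10 populations, N = 1000, 30 conjugation pulses at
  33-generation intervals, which keeps a full run under a minute while
  preserving marker density. Because the decay anchors are absolute
  distances on a ~4.6-Mb chromosome, a 200-kb genome would otherwise sit
  entirely inside the flat part of the law; the default pipeline therefore
  rescales the anchor *distances* by the genome-length ratio
  (`scale_decay_distances()`), preserving the decay geometry relative to
  chromosome length. Anchor probabilities are untouched.
* **Mating intensity** — donors are added at a 4:1 excess and left to
  conjugate for an extended exposure, so each recipient experiences
  multiple donor contacts per pulse (default 20). This, together with
  roughly one clonal sweep every 50 generations (`sweep_rate = 0.02`),
  reproduces experiment-scale outcomes: most final clones carry several
  donor tracts, on the order of 10–30% donor genome, with occasional
  donor-free lineages.
* **Selection** — each donor carries one auxotrophy allele among its
  specific marker sites; recombinants that acquire any donor auxotrophy
  allele are discarded at integration when selection is on, mimicking
  lethality in minimal medium.
* **Sweeps as instant clonal replacement** — a sweep founder is drawn
  uniformly and replaces the population. This is exactly the ratchet model
  above, so the simulated fixation fraction of a neutral allele at
  frequency *p* converges to *p* by construction of the mechanism, and the
  Monte-Carlo test verifies the mechanism, not an independent route.
* **Two-timepoint sampling** — population allele frequencies are recorded
  at the end of the pulsed phase and after a conjugation-free continuation
  (default 200 generations), plus two sampled clones, mirroring the real
  sampling design.

Features of real data the simulator does **not** emulate: mismatch-repair
dependence of recombination efficiency, genomic islands present in only one
background, structural rearrangements beyond simple deletions, sequencing
or calling error (input tables are treated as ground truth), clonal
interference between co-segregating beneficial mutations, and F-plasmid
epidemic spread. Fragmentation of tracts into mosaic pieces is available
(`fragmentation_rate`, per-kb break probability with each interior piece
integrated with probability 1/2) but defaults to 0, because no quantitative
mosaicism model is available to calibrate against. Passing tests on
simulated data therefore demonstrate the correctness of the set algebra,
painting, and statistics — not robustness to caller artifacts or
repair-pathway biology.

New mutations are placed at positions not already segregating, so every
simulated site has a single unambiguous identity in the truth files; this
slightly understates homoplasy, which is negligible at the simulated
densities.

## Numerical and testing choices

All stochastic entry points take an explicit integer seed; there is no
reliance on ambient RNG state, and emitted files are byte-identical across
runs with the same seed. Output row order is always the site-identity sort
(chrom, pos, kind, alt). The Kruskal–Wallis heterogeneity test reports the
tie-corrected chi-squared approximation by default (matching how such
tests are conventionally reported); an exact mode enumerates all group
assignments for total n ≤ 10. Spearman p-values come from `stats::cor.test`
(exact for small tie-free samples). The test suite sizes its simulations to
run in about a minute: structural checks of conjugation use a
high-transfer-rate law so that a few hundred matings yield many transfers,
while calibration checks of the decay law itself use the default law at
10,000 matings; the property suite covering the full pipeline uses 10
populations at the default 200-kb scale.

## Known limitations

Painting assumes a single shared reference and exact site identity; it will
not tolerate coordinate disagreement between callers. The allelic-state
classifier requires pre-aligned equal-length variable-site sequences. The
spline smoother requires at least df + 1 points and is a smoother, not an
inference procedure — no uncertainty bands are produced. The simulator's
sweep model is deliberately minimal (instantaneous replacement); it cannot
represent partial sweeps or clonal interference, which is acceptable for
testing the ratchet arithmetic but not for inference about sweep dynamics.
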