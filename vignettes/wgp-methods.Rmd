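---
title: "Methods: sequence-tag physical mapping in wgpmap"
author: "wgpmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-tag physical mapping in wgpmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgpmap)
```

This vignette records the models, parameter choices and numerical decisions
behind `wgpmap`, in the spirit of a methods supplement. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The profiling model

Whole Genome Profiling fingerprints a BAC clone by the set of short sequence
tags found at its *Eco*RI restriction sites. The package models the data
production chain explicitly:

1. **Digestion.** All GAATTC (*Eco*RI) and TTAA (*Mse*I) sites are located;
   cuts fall after the G (*Eco*RI) and after the first T (*Mse*I). Every
   restriction fragment bounded by two cuts and possessing an *Eco*RI end
   yields one tag read inward from that end, so an internal *Eco*RI site
   yields up to two tags (one per side). Fragments shorter than 26 nt yield
   nothing; fragments of 26–29 nt yield truncated tags; all others are cut
   to the 30 nt default. Tags *include* the 5-base AATTC remnant: reads
   start at the restriction site, and keeping the remnant makes every tag an
   exact substring of the genome (alignable with plain string matching).
   Fragments that run into a sequence end have no second adaptor and are
   not amplified, so they emit no tag. Left-side tags are computed as the
   right-side tags of the reverse complement, which makes digestion
   strand-consistent by construction (the property suite checks this).

2. **Pooling.** Each 384-well plate is pooled three ways: 8 row pools of two
   plate rows (48 clones), 8 column pools of three plate columns (48
   clones), and 6 split-box pools (64 clones) that distinguish the six wells
   of each 2×3 row-by-column block — 22 pools per plate, and every clone in
   exactly one pool per dimension.

3. **Sequencing.** Each (pool, member clone, tag) triple emits
   `barcode + tag` reads truncated to 36 nt, with uniform substitution
   errors. Default barcodes are 6 nt with a parity base, giving the set a
   minimum Hamming distance of 2 so a single error cannot convert one valid
   barcode into another. At the default 0.5% per-base error rate roughly
   `(1 - 0.005)^11 ≈ 95%` of reads keep their 11 barcode + remnant bases
   intact and parse as valid, which is the regime a well-behaved run sits
   in.

## Deconvolution

Within one plate, a tag observed in exactly one row pool, one column pool
and one split-box pool is assigned to the unique well at their
intersection; implementation-wise the assigned clone is the clone present in
all three pools, which is the same thing and needs no well geometry. Any
tag seen in two pools of one dimension is ambiguous *for that plate* and
all its observations there are discarded; tags seen in fewer than three
dimensions are incomplete and likewise discarded (both are counted, not
errors). Plates are independent, so a tag may legitimately be assigned to
one clone per plate.

Two clones in the same plate that share a tag always differ in at least one
pooling dimension, so the shared tag is always ambiguous — deconvolution is
therefore *sound* (no false assignments on noiseless data; tested), at the
cost of losing every co-pooled shared tag. This is the central trade-off of
pooled profiling: the more of the genome a pooling set covers, the more
likely two clones from one region (or two repeat copies) co-occur, and the
deconvoluted fraction falls. The test suite demonstrates the monotone loss
by raising clone density per plate. `clones_per_plate` (with `scatter`)
exists precisely to set this coverage in simulations; the acceptance script
uses ~22% per-plate coverage.

`min_reads` (default 1) optionally requires a per-pool read count before a
tag counts as present, suppressing sequencing-error ghost tags; no
pool-level depth threshold is inherent to the method.

## Filtering

Tag filters run in a fixed order, because the single-BAC rule depends on
what was removed before it: contaminant screen (exact substring match of
the tag, either strand, against the vector/host/chloroplast set) →
homopolymer runs ≥ 5 nt → tags in exactly one BAC (uninformative for
overlaps) → tags in more than 12 BACs (repeat-derived, ambiguity-prone).
Fingerprint filters then drop BACs with fewer than 30% or more than 2.5
times the mean tag count; the mean is computed on the tag-filtered
assignment, and absolute cutoffs (for example ≤ 4 / ≥ 40) are supported
because 2.5 × a mean of ~16 sits just above 40 — with skewed tag-count
distributions the two modes differ slightly and both are legitimate.

## The Sulston score and stepwise assembly

For band counts `n_lo <= n_hi` sharing `M` bands, with single-band
coincidence `p = (2t + 1)/G` and `q = 1 - (1 - p)^n_lo`, the score is
`P(Bin(n_hi, q) >= M)`, computed as a log-sum-exp over the tail terms. This
stays exact (to double precision) at cutoffs of 1e-75 and far below, where a
naive product underflows. Two independent checks guard it: agreement with
`pbinom`'s upper tail, and a Monte-Carlo oracle that draws band multisets
uniformly from `G` cells. The oracle treats the band space as circular so
each band matches exactly `2t + 1` cells, as `p` assumes. A known
limitation surfaced by that oracle: the binomial form treats the `n_hi`
per-band coincidence events as independent, which they are not (they share
one realisation of the other clone's bands). At tolerance 0 the resulting
bias is far below Monte-Carlo noise at 10^6 trials; at tolerance ≥ 1 with
`n ≈ 8` it reaches ~2×10⁻³. Tag-based profiling always runs at tolerance 0,
so the score is used where its approximation is best.

Defaults follow the tag-mode parameterisation: gel length `G = 110000`
(the virtual band space a 30-nt tag effectively draws from), tolerance 0,
`FromEnd = 8`, `Match = 1`, and a 15-step cutoff schedule from 1e-75 to
1e-05 (+5 in the exponent per step). The stepwise protocol is:

* initial incremental build (single linkage over pairs passing the first
  cutoff — on ≤ 8 clones this provably equals brute-force connected
  components, and the suite checks it);
* at each later cutoff, singleton-to-end joins (a singleton joins the
  contig whose *end clone* — placement starting within `FromEnd` CB slots
  of a contig end — it matches best below the cutoff; ties go to the
  smallest contig id, so the procedure is deterministic given input order),
  then end-to-end merges, then the DQer.

Because later steps only join singletons to contig ends and merge contig
ends, fingerprints too information-poor to seed any contig at the first
cutoff stay singletons throughout — with ~16 tags per clone nothing can
reach 1e-75 (a perfect 16-band match scores ~1e-61), so scaled-down
simulations open their schedules at a stringency their band counts can
meet. The acceptance script opens study A at 1e-30 for exactly this reason.

**DQer.** A contig with more than 10% questionable clones is dissolved and
its members re-assembled 3 schedule steps (×10⁻¹⁵) more stringent. The
"3 steps" reading of the underlying FPC parameter is an interpretation and
is configurable (`dq_step`).

**CB map.** Clones of a contig are ordered by spectral seriation: the
Fiedler vector of the Laplacian of the shared-band-count matrix. Greedy
seed-and-extend seriation was the obvious alternative; the spectral
ordering was chosen because it is a single deterministic linear-algebra
step, has no tie-breaking cascade, and empirically recovers the true clone
order on clean simulations (rank correlation ≈ 1; layout-recovery tests).
Band slots are the union of bands ordered by mean clone rank; `length_cb`
is the number of slots, so a perfect tiling path has `length_cb` equal to
its distinct tag count.

**Q clones.** A clone is questionable when (a) fewer than 50% of its bands
fit one placement window of width ~1.25× its band count — counting only
bands shared with another contig member, since unshared bands carry no
placement evidence — or (b) its placement interval stretches over more than
3× its band count in slots. The stretch criterion matters: clones merged
into a contig through ubiquitous repeat tags have those bands pulled to the
consensus centre, which the fit window alone does not notice. With both
criteria, repeat-rich simulations reproduce the characteristic inflation of
Q clones at permissive cutoffs (≥ 1e-10) that motivates stopping the
schedule earlier; thresholds are configurable
(`q_threshold`, `q_window`, `q_stretch`).

## Evaluation against reference sequence

Tag placement is exact, full-length, both strands (`PDict` matching); a
placement's *site coordinate* is derived from its strand so the two tags
flanking one *Eco*RI site coincide, making the inter-tag distance of a
left/right pair 0 — one third of real inter-tag distances are such zeros,
and the distance statistics reproduce that structure on simulated digests.
A BAC is *matched* when strictly more than 50% of its tags map. A contig
with ≥ 2 matched BACs is *chimeric* when its matched BACs fall on two
reference sequences or when consecutive placements gap by more than
`slack_bp` (default 276 kb = 2 clone lengths; the original check was
manual, so the quantification is necessarily a choice). Mis-assembled BACs
are the unmatched clones of evaluable contigs, as a percentage. The CB unit
is calibrated per contig as spanned reference kb ÷ `length_cb`; on
simulations it recovers the mean inter-tag spacing (parameter-recovery
test), and map length in Mb is `length_cb` × CB-unit summed over contigs,
singletons excluded and reported separately.

The C1²/C2 chimera score (shared-tag pair fraction squared over tag
density) is computed per contig with no default verdict threshold — a
usable threshold is genome-dependent and the score is known to miss
reference-detected chimeras, so it is reported as a flag-only diagnostic.
N90/L90 use the *fixed reference length* as denominator, not the assembly
total, and return a sentinel when 90% is not reached. k-mer uniqueness is
canonical (strand-collapsed); a homopolymer therefore scores 0 (its one
distinct k-mer recurs), the internally consistent reading of
"fraction of distinct k-mers occurring exactly once".

## Scaffolding

A draft sequence contig may be linked only on evidence of ≥ 2 distinct tags
from ≥ 2 distinct restriction sites out of a single WGP contig or singleton
clone — one site contributes two tags, so the two-site rule is the real
repeat guard. Exact intra-BAC tag positions are unknown (the stated cause
of order ambiguity in tag-integrated assemblies), so sequence contigs are
ordered along a WGP contig by the mean CB-map centre of the clones carrying
their tags; contigs with indistinguishable proxies form unordered bins.
Contigs hit by several WGP contigs act as bridges: bridge edges are
accepted strongest-first (most supporting tags) subject to each WGP contig
having at most two neighbours and no cycles; rejected edges are reported as
conflicts (ties drop both). Unit orders along a chain are stitched through
their shared contigs, reversing a unit when its anchors run against the
established order. Inter-element gaps are unsized — written as 100-N
spacers in FASTA and type-U gaps in AGP v2 — because gap sizes are
unknowable de novo. Element orientation is the majority strand of its
placements. Superscaffold order error is scored orientation-invariantly
(the better of forward and reversed readings), so a fully reversed
reconstruction scores 0%.

## What the simulations do and do not show

The generator reproduces the statistical structure that drives the method's
behaviour: repeat-induced tag collisions (mutated copies of a few master TE
families, 2% per-copy substitution), pooling-coverage-dependent
deconvolution loss, truncated-tag length distributions, and
substitution-error read loss. It does **not** model position-specific
Illumina error profiles, PCR or coverage bias, partial digestion, chimeric
clones beyond planted fixtures, or instrument-specific artefacts. Passing
tests therefore certify the algorithms and their interactions under the
modelled noise, not performance on any particular wet-lab dataset.
Problem sizes were chosen so the whole suite runs in minutes on one CPU:
the layout-recovery study uses a repeat-free 5 Mb genome at 9× coverage of
138 kb clones (326 clones, ~20,000 tags) assembled through the full
schedule to 1e-11; the pooled profiling study in the acceptance script uses
a 2.5 Mb genome at 80% TE, 9.6× depth and ~22% per-plate coverage; the
Monte-Carlo oracle uses 10 parameterisations at 10^6 trials each. Those
sizes are large enough that the qualitative regimes (clean recovery,
repeat-driven Q inflation, pooling loss) are all visible and stable across
seeds.

## Degenerate inputs and numerical conventions

Coordinates are 0-based half-open everywhere; BED input is validated as
such. All stochastic operations take an explicit integer seed and restore
the caller's RNG state. Zero-variance landscape columns return r = 0 with a
warning instead of NaN. Empty digests, empty pools and empty assignments
are returned as empty objects, not errors, except where a statistic is
undefined (BAC filtering of an empty assignment, CB calibration with no
mappable contig, C1²/C2 with zero density). `match_count` in banded mode
uses greedy one-to-one matching on sorted bands, which equals the exhaustive
maximum matching (checked against a brute-force oracle) because band
intervals are laminar at a fixed tolerance.
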