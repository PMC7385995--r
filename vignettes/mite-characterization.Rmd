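---
title: "Characterizing MITE families: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing MITE families: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescout)
```

## The problem

Miniature inverted-repeat transposable elements (MITEs) are short
(< 1 kb), non-autonomous class II transposons. They are defined purely
structurally: a terminal inverted repeat (TIR) of at least ~10 bp at each
end, flanked by a short (2–10 bp) target site duplication (TSD) created
by the insertion itself, with a typically AT-rich interior. Because the
TSD length is diagnostic of the transposase that mobilized the element
(an 8 bp TSD marks the hAT superfamily, a "TA" TSD Tc1/mariner, and so
on), and because divergence from the family consensus clocks the
insertion time, a handful of alignment and counting operations support a
complete characterization workflow: find the elements, group them into
families, count copies within and across genomes, locate them relative
to genes, date them, and type their presence/absence across accessions.

`mitescout` implements that workflow end to end and, just as
importantly, ships a synthetic-data module that plants families of known
geometry and age into simulated genomes so every stage can be validated
against a truth table.

## Discovery model

The structural scan (`find_tir_candidates()`) examines every window of
100–1000 bp (`min_element_len`, `max_element_len`) and asks whether its
first *t* bases reverse-complement-pair with its last *t* bases for some
*t* between `min_tir_len` (10) and `max_tir_len` (40), at
`tir_min_identity` (90 %) Hamming identity — no indels inside the TIR,
and ambiguity codes never match. Two details matter:

* **Maximality requires a pairing endpoint.** Within a 90 % budget, one
  or two trailing mismatches would otherwise "extend" every TIR past its
  real arm; the scanner only extends the reported TIR through positions
  that themselves pair.
* **Overlap resolution is TSD-anchored.** All raw windows get a TSD call
  (longest exact flanking duplication of 2–10 bp), and competing
  overlapping windows are resolved by longest TSD, then longest TIR,
  then leftmost start. The TSD is physical evidence of the insertion
  boundary; resolving by TIR length alone lets chance 1–3 bp inverted
  extensions into the flank nudge element boundaries off the true frame
  and destroy the TSD call.

Chance inverted repeats are abundant (a random megabase yields on the
order of a thousand non-overlapping candidate windows at these
thresholds), so candidates only graduate to *elements* through family
evidence:

1. **Clustering** (`cluster_families()`): deterministic exemplar
   clustering with a shared-k-mer prefilter. The family edge is identity
   ≥ `intact_min_identity` (80 %) over ≥ `intact_min_coverage` (80 %) of
   the shorter sequence, either strand, with at most 5 % of alignment
   columns gapped — family members differ by substitutions, not
   rearrangement, and the indel cap stops low-complexity AT-rich
   windows from clustering through gap-riddled alignments. Families need
   `min_family_size` (2) members: MITEs are by definition multi-copy.
2. **Consensus**: a per-column majority over a progressive alignment of
   the family's *full-length* members (those within 2 % of the modal
   member length), with a gap-plurality rule per column. Diverged copies
   are often detected at inward-shifted frames — the TIR pairing works
   equally well offset into the element — and letting those shorter
   frames vote erodes the consensus ends.
3. **Homology sweep** (`find_intact_copies()`): each family consensus is
   searched back against the genome on both strands; hits at ≥ 80 %
   identity over ≥ 80 % of the consensus, greedily non-overlapping by
   score, form the final element table. This mirrors standard practice
   (de novo discovery to seed families, then homology search to count
   copies) and is where sensitivity to diverged copies comes from; the
   structural scan can stay strict.

`discover_mites()` chains these stages and returns the candidate,
family, and element tables; `tidy()` and `glance()` give the element
table and a one-row summary.

## Copy numbers

Two estimators, deliberately independent:

* **Intact copies** in an assembly: the sweep above; thresholds are
  inclusive (≥ 80 % / ≥ 80 %).
* **Read depth** (`map_reads()`, `copy_number_from_depth()`): reads are
  locally aligned to the consensus (after a shared 16-mer prefilter,
  both strands, best hit only) and contribute depth where identity
  exceeds 80 % over more than 50 % of the read — both *strict*
  inequalities, mirroring the usual read-mapping convention, and
  deliberately different from the inclusive intact-copy thresholds.
  Depth is summarized as a trimmed mean over the central 80 % of the
  consensus (element ends systematically under-recruit reads) and
  divided by haploid coverage (total read bases / genome size).

On a well-assembled genome the two agree; read depth exceeding the
intact count flags collapsed repeats.

## Genic context

`classify_position()` assigns each element one category with precedence
exon > intron > upstream/downstream > intergenic. "Proximal" means
within `genic_window` (2 kb, the conventional cutoff for potential
regulatory influence) of a gene; upstream/downstream are strand-aware
relative to the transcription start/stop. Overlap uses the full element
interval; distance profiles (`tss_tts_profile()`) use the element
midpoint, binned within ± `tss_profile_window` (5 kb) of the nearest
site. Percentages are rounded half-up, so reported integers match
count/total arithmetic deterministically.

## Dating insertions

An element stops exchanging sequence with its family at insertion, so
its divergence from the family consensus — a proxy for the ancestral
sequence — clocks its age. `k2p_distance()` implements the Kimura
two-parameter distance with pairwise deletion (sites with a gap or
ambiguity in either row are dropped):

$$k = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$$

with $P$ and $Q$ the transition and transversion proportions per
compared site. Ages follow from $T = k / (2r)$ with
$r = 1.3\times10^{-8}$ substitutions·site⁻¹·year⁻¹ (`substitution_rate_r`,
a plant nuclear rate; configurable). Distances outside the formula's
domain are *saturated*: flagged and excluded from histograms with a
reported count, never capped, since capping would silently pile mass
into the oldest bin.

To avoid biasing the consensus toward the most numerous subfamily,
`balanced_consensus()` samples an equal number of members per clade
(seeded, deterministic) before the majority vote; ties go A < C < G < T
so the consensus stays a plain nucleotide string. Ages can be computed
against either a global or a per-clade consensus by changing the clade
map — both are exposed because the choice is a genuine analysis degree
of freedom.

`neighbor_joining()` is a standard Q-criterion agglomeration with a
deterministic smallest-index tie-break; negative branch lengths are
clamped to zero with the deficit moved to the sister branch.
`bootstrap_support()` resamples alignment columns
(`bootstrap_replicates`, default 1000), rebuilds each replicate tree,
and reports the percentage of replicates containing each internal
bipartition of the full-data tree; replicates with saturated pairs are
redrawn up to 10 times, then dropped and counted.

## Insertion polymorphism in silico

`extract_loci()` takes 300 bp flanks around each element (long enough to
map uniquely in these genomes, short enough not to span neighbouring
insertions); `type_locus()` locates both flanks in a target assembly
(identity ≥ 0.9 over ≥ 0.8 of the flank, unique hits only) and calls the
locus **occupied** when the inter-flank gap is within ±20 % of the
element length, **empty** when it is ≤ 50 bp (an excision leaves a
single copy of the target duplication, so flank matches may even overlap
by the TSD length — the gap is then negative), and **ambiguous**
otherwise, including missing or multi-mapped flanks. The gap tolerances
are calibrated to separate ~670 bp elements from empty sites about as
coarsely as product sizes on an agarose gel would; multi-mapped flanks
are ambiguous rather than best-hit because the wet assay would fail the
same way. `polymorphism_summary()` reduces a locus × assembly call
matrix to the amplified / polymorphic / shared-occupied percentages.

## The synthetic study system

`simulate_genome()` draws i.i.d. background at a chosen GC content and
places non-overlapping genes with 1–5 exons. `mite_plant_spec()`
describes a family: by default a ~670 bp, AT-rich (70 %) element with an
8 bp TSD, i.e. the geometry of a compact hAT MITE, and an age mixture
concentrated on a 2–3 Myr amplification burst. `plant_mites()` draws an
age *T* per copy, sets $k = 2rT$, evolves the element and — separately —
each TSD copy under a K2P substitution process (transition:transversion
rate ratio 2:1, exact finite-time probabilities), and inserts it with
the target duplicated, recording everything in a truth table.
`excise()` reverses an insertion exactly; `simulate_reads()` generates
uniform single-end reads with optional substitution errors;
`evaluate_discovery()` scores predictions against truth at ≥ 80 %
reciprocal overlap with greedy one-to-one matching.

Generator properties worth knowing:

* Substitution-only evolution — no indels — so TIR/TSD structure
  survives by construction at age 0 and erodes statistically with age,
  and the dating model matches the generating process class. Indel decay
  is a documented extension, not the default.
* Insertion sites are rejected when a flanking base would extend the
  TSD ambiguously (element's terminal base equal to the base adjacent to
  the target), and generated consensi pin the few positions inward of
  each TIR arm so an undiverged copy reports exactly the designed TIR
  length. Without these, roughly 1 in 16 undiverged copies would carry a
  legitimately ambiguous (longer) TSD annotation.
* Insertion points keep ≥ 800 bp apart and ≥ 400 bp from sequence ends,
  which guarantees clean polymorphism-locus flanks and keeps gene-biased
  copies within the 2 kb genic window even when another copy lands
  between element and gene.

What the generator does *not* emulate: nested/fragmented repeat
landscapes, tandem arrays, indel decay, sequencing-quality artefacts,
paired-end structure, and real genomes' compositional heterogeneity.
Passing the recovery suites therefore demonstrates that the machinery is
correct and well-calibrated on the stated model, not that real-genome
annotation is this clean — on real data the structural scan's chance-hit
load and the clustering thresholds are the knobs to revisit first.

## Numerical and scale choices

* Alignment scoring defaults (+2/−3, gap open −5, extend −2) mimic
  megablast-like behaviour in the 80–100 % identity regime where all the
  thresholds operate; ambiguity codes always score as mismatches.
* Seed lengths: 12 bp for assembly search (sensitivity at 80 %
  identity), 16 bp for read mapping (speed at scale); both exact-match.
* The exhaustive K2P validation compares the closed form against
  brute-force per-site counting on all $4^6 \times 4^6$ pairs of
  length-6 sequences; the all-pairs distance path is vectorized
  row-against-all to keep this and the bootstrap affordable.
* Validation problem sizes: a 1 Mb genome with two 50-copy families for
  discovery recovery; 100 × 670 bp elements per age point for clock
  recovery; 20 copies at 10× error-free coverage for copy-number
  recovery; 20 loci for the polymorphism round trip. These sizes give
  recovery metrics with comfortable sampling margins while keeping a
  full run in minutes on one core.
* All stochastic steps take explicit seeds; the same seed reproduces
  genomes, reads, and bootstrap resamples byte-identically.

## Known limitations

* The structural scan is exhaustive O(genome × element-length-range);
  practical to a few megabases per run, not to whole crucifer genomes —
  there the intended use is scan-on-sample, then sweep genome-wide with
  family consensi.
* Families are defined by a single-pass exemplar rule; pathological
  chains of borderline-similarity candidates could split or merge
  differently than full single-linkage (irrelevant for well-separated
  families, which is the regime the TSD-based classification assumes).
* The read mapper is single-end, best-hit, substitution-aware only; it
  is a quantification device, not a general aligner.
* Superfamily classification is a TSD lookup table; it names the usual
  plant superfamilies and returns "unknown" otherwise, by design.
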