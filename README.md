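# mitescout

Discovery and characterization of **miniature inverted-repeat
transposable elements** (MITEs) in genome assemblies, with a synthetic
study system for validating every stage against known truth.

MITEs are short (< 1 kb), AT-rich, non-autonomous DNA transposons
defined by their structure alone: a terminal inverted repeat (TIR,
≥ 10 bp) at each end, flanked by a target site duplication (TSD,
2–10 bp) created at insertion. The TSD is diagnostic — an 8 bp TSD marks
the hAT superfamily — and, because an element stops exchanging sequence
with its family once inserted, its Kimura two-parameter divergence *k*
from the family consensus dates the insertion through the molecular
clock

```
k = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q),      T = k / (2r)
```

with *P*, *Q* the transition/transversion proportions per compared site
and *r* the neutral substitution rate (default 1.3 × 10⁻⁸
substitutions · site⁻¹ · year⁻¹).

The package is aimed at plant repeat biologists who want a desk-scale,
fully scriptable version of the standard MITE workflow:

* de novo structural discovery (TIR scan, TSD detection, overlap
  resolution), family clustering with consensus building, and TSD-based
  superfamily classification — `discover_mites()` and friends;
* copy numbers two ways: intact-copy counts in assemblies (≥ 80 %
  identity over ≥ 80 % of the consensus) and read-depth estimates
  normalized to haploid coverage (> 80 % identity over > 50 % of the
  read) — `find_intact_copies()`, `map_reads()`,
  `copy_number_from_depth()`, `genome_specificity()`;
* genic context: exon/intron/upstream/downstream/intergenic calls,
  gene-proximity percentages, TSS/TTS distance profiles —
  `classify_position()`, `proximal_fraction()`, `tss_tts_profile()`;
* insertion dating and phylogenetics: balanced-clade consensus, K2P
  distances with pairwise deletion and saturation flagging,
  neighbor-joining trees with bootstrap support — `element_ages()`,
  `neighbor_joining()`, `bootstrap_support()`;
* in-silico insertion-polymorphism typing across assemblies
  (occupied / empty / ambiguous per locus) — `extract_loci()`,
  `type_locus()`, `polymorphism_summary()`;
* a first-class synthetic-data module — `simulate_genome()`,
  `mite_plant_spec()`, `plant_mites()`, `simulate_reads()`, `excise()`,
  `evaluate_discovery()` — that plants families of chosen geometry
  (length, TIR, TSD, AT content) and age distribution and emits truth
  tables.

Results are tibbles (or small list objects with `tidy()` / `glance()` /
`autoplot()` methods), so everything chains with the usual tidyverse
verbs.

## Worked example

Simulate a 200 kb genome with 20 genes, plant 25 copies of a
hAT-geometry family (673 bp, 25 bp TIR, 8 bp TSD, 70 % AT, ages drawn
from a 2–3 Myr burst, half the copies near genes), and run the pipeline:

```r
library(mitescout)
cfg <- mite_config()

sim <- simulate_genome(200000, gc = 0.36, n_genes = 20, seed = 11)
fam <- mite_plant_spec("demo_hat", length = 673, tir_len = 25, tsd_len = 8,
                       at_fraction = 0.70, n_copies = 25, genic_bias = 0.5)
sim <- plant_mites(sim, fam, cfg, seed = 12)

disc <- discover_mites(sim$genome, cfg)
disc
#> <mite_discovery>
#>   structural candidates : 323
#>   families (>= 2 members): 2
#>   elements (consensus hits): 25
#>   family_id n_members consensus_len tsd_len_mode superfamily at_fraction
#> 1 fam01            19           673            8 hAT               0.686
#> 2 fam02             2           880            2 unknown           0.664
```

The strict structural scan recovers 19 of the 25 copies; clustering
them yields a 673 bp consensus whose modal TSD length (8 bp) classifies
the family as hAT, and the consensus sweep then recovers the diverged
copies (fam02 is a two-member chance cluster from the random
background — multi-copy evidence is deliberately the only thing
separating elements from the genome's abundant chance inverted
repeats). Scored against the truth table:

```r
evaluate_discovery(tidy(disc), sim$truth)
#>   n_truth n_predicted n_matched precision recall precision_defined
#> 1      25          25        24      0.96   0.96 TRUE

proximal_fraction(classify_position(tidy(disc), sim$genes, cfg))
#>   n_proximal n_total percent
#> 1         21      25      84
```

Date the family's members against their consensus and estimate copy
number from simulated reads:

```r
members <- tidy(disc) |> dplyr::filter(family_id == "fam01")
msa <- progressive_msa(setNames(members$seq, members$element_id))
glance(element_ages(msa, config = cfg))
#>       n n_saturated mean_k   mean_T median_T
#> 1    24           0 0.0580 2229396. 2229142.

reads <- simulate_reads(sim$genome, coverage = 10, read_len = 100, seed = 13)
prof <- map_reads(reads, disc$families$consensus[1], cfg)
hc <- estimate_haploid_coverage(sum(nchar(reads$seq)), sim$genome$length)
copy_number_from_depth(prof, hc)
#> [1] 24.4757
```

The mean estimated age (~2.2 Myr) recovers the planted mixture's mean
(2.15 Myr), and the depth-based copy number (~24.5) matches the 25
planted copies.

## Documentation

The methods vignette
(`vignettes/mite-characterization.Rmd`) describes the discovery model
and its thresholds, the two copy-number estimators, the dating and
bootstrap machinery, what the synthetic generator does and does not
emulate, and the package's numerical conventions.
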