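---
title: "Annotating translational regulatory elements in 5'UTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating translational regulatory elements in 5'UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utr5scan)
```

## The problem

The 5' untranslated region (5'UTR) of an mRNA carries most of the
cis-acting signals that modulate translation initiation: upstream ATG
codons (uATGs) and upstream open reading frames (uORFs) that divert
scanning ribosomes, the Kozak context around start codons, RNA
G-quadruplexes (RG4s) and stem loops that impede scanning, and introns
whose excision marks influence downstream fate. utr5scan annotates all
of these on spliced 5'UTR sequences and summarises them per gene, so
that gene families can be compared feature by feature. The package
bundles a curated annotation of the 5'UTRs of the 12 human ABCA
transporter genes (principal transcript isoforms) that serves as a
worked example and as the regression fixture for the statistics below.

## Coordinates

Every position is stored relative to the A of the main-ORF start codon
(sATG): that A is +1, the base 5' of it is -1, and **there is no
coordinate 0**. This is the convention in which published per-gene
feature positions are reported, and it forces the inclusive length rule
implemented in `interval_length()`: an interval from -525 to -376 spans
150 nt, and one from -3 to +3 spans 6 nt because 0 is skipped.
`satg_to_tss()` converts to 1-based positions from the transcription
start site. BED and GFF3 writers perform the conversion to 0-based
half-open / 1-based inclusive transcript coordinates and are round-trip
tested.

Sequences are normalised internally to the uppercase DNA alphabet
(U becomes T); `N` is accepted but never matches an ATG, a stop codon or
a G-run, which keeps every scanner conservative on ambiguous bases.

## uATGs, uORFs and context

`scan_uatgs()` reports every ATG triplet lying wholly within the UTR.
The flanking context is graded on a four-level scale driven by the two
key Kozak positions, -3 (favourable A/G) and +4 (favourable G): weak
(neither), adequate (exactly one), strong (both), optimal (the full
`GCC(A/G)CCATGG` motif). For an ATG so close to the 5' end that -3 does
not exist, the visible key base alone decides between weak and adequate
and the site is flagged `truncated_context` — the scale itself defines
no rule there, so the choice is deliberately the conservative reading.

`find_uorfs()` extends each uATG codon by codon through the UTR and the
entire CDS prefix supplied with the record. The first in-frame stop
closes the uORF (stop included in the length); a uORF that never meets a
stop is reported open-ended with a lower-bound length equal to the
complete in-frame codons available, which is exactly how open uORF
lengths are printed in the bundled annotation (e.g. a uORF starting at
-262 prints ">261" = 3 * floor(262/3)). The default minimum closed-uORF
length is 30 nt: the shortest uORF in the bundled annotation is 33 nt,
so 30 keeps every annotated uORF while suppressing trivially short
reads; common ORF finders default to 75 nt and would miss a third of
them. Translation-initiation-site scores from an external predictor are
consumed as inputs and only binned (`bin_tis()`: < 0.1 low, 0.1-0.5
middle with both bounds included, > 0.5 high).

## Conservation profiling and phylogeny

`profile_alignment()` reduces an ortholog alignment to per-column
identity (modal non-gap residue among non-gap rows — alignment viewers
colour "percentage identity" this way without defining it formally, so
the definition is stated here and configurable) and occupancy (non-gap
fraction of all rows). `find_conserved_subregions()` reports maximal
runs of columns passing both cut-offs, 80% by default, with at least
`min_run = 5` human-mapped columns — the shortest subregion in the
bundled annotation spans 6 nt, so 5 retains it. Whether the cut-offs
should apply jointly per column or to window averages is a genuinely
open choice; per-column joint passing is implemented because it is the
stricter reading and makes regions invariant to all-gap padding.

uATG conservation uses a six-level ordinal scale over vertebrate
subgroups (primates, rodents, other placental mammals, sauropsids,
fishes/coelacanth). A subgroup carries the uATG when at least one of its
rows shows a gapless ATG in the three columns aligned to the human
uATG; the category is the highest *nested* requirement fully met, so a
primates+fishes pattern grades as 1 with a warning rather than
inventing a level. Strictness (exact gapless ATG) is intentional;
genome-scale studies often accept any ortholog overlap, which would
inflate categories.

Distances for the neighbor-joining tree default to the p-distance over
pairwise-shared (both non-gap) columns, with Jukes-Cantor available;
the JC transform is undefined at p >= 0.75 and such pairs are capped
with a warning. The tree itself is Saitou-Nei neighbor joining (via
ape) with taxa pre-sorted by label for deterministic tie-breaking and
negative branch lengths clamped to zero. On any additive matrix the
path lengths of the recovered tree match the input to 1e-9, which the
suite checks over random trees of up to 8 taxa.

## G-quadruplex detection

Three detectors with different philosophies run side by side:

* `pattern_g4()` — the classical motif `G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+`,
  with overlapping matches merged into maximal regions;
* `qgrs_scan()` — an enumerative G-score: candidates of four G-runs
  within 45 nt score `10*(tetrads - 2) + (45 - span) - sum|loop_i -
  mean(loop)|`, rewarding stacked tetrads, compactness and even loops;
  the formula is this package's own, preserving the documented
  qualitative behaviour of published G-score mappers, and a greedy pass
  keeps the best non-overlapping set;
* `g4hunter()` — a window scorer in which each base of a G-run of
  length k scores min(k, 4) (C-runs score the negative); windows of 25
  with mean >= 1.2 are merged into candidate regions. Scores are bounded
  in [-4, 4] and antisymmetric under reverse complement, both tested.

`consensus_g4()` reports interval intersections supported by at least
two detectors, preferring pattern ∩ window-scorer and falling back to
pattern ∩ G-score, then window-scorer ∩ G-score, with a 12-nt minimum —
below that a "quadruplex" cannot hold four tetrads. One detector slot
in the published analysis this consensus mirrors was a trained neural
network; a trained model is not reproducible from printed parameters,
so the arithmetic window scorer takes that slot and the substitution is
stated prominently here. Consequently the bundled per-gene RG4
intervals are documentation of the published annotation, not a parity
target for these detectors, and no test pretends otherwise.

## Secondary structure

Stem loops are counted on dot-bracket strings (`parse_dotbracket()`,
`count_hairpins()`): a hairpin is an innermost pair enclosing only
unpaired bases, so a stem with bulges still counts once. Thermodynamic
folding stays external — the intended input is the MFE structure line
of a folding engine — but `nussinov_fold()` provides a maximum-pairing
fallback (Watson-Crick plus optional G:U, hairpin loops >= 3) so the
counting pipeline is testable without a binary. Its traceback is
deterministic (position i pairs with the smallest admissible partner),
and its pair counts equal a naive exhaustive search for all tested
sequences up to 14 nt. Published stem-loop counts depend on the folding
engine and version, so they are bundled as documentation, not gated.

## Ribosome profiling

`relative_coverage()` compares region means: 100 * mean(region) /
mean(reference), the reference defaulting to the first 30 codons of the
main ORF — the published qualitative scores name no window, and the
early mORF is the natural internal standard for initiation-competent
transcripts. Peak-height comparison is the other defensible reading;
region means were chosen for robustness at low depth. Bins are 1 (<25%),
2 (25-75%, bounds included — "between X and Y" is read inclusively and
pinned in tests), 3 (>75%).

## Descriptive and correlation statistics

`describe_values()` reports n, min, max, sum, mean, sample variance,
median and mode. The mode takes the smallest value on frequency ties
and is NA when no value repeats; table display uses half-away-from-zero
rounding (`round_half_away()`), which is what makes a median of 211.5
print as 212. Spearman's rs is the Pearson correlation of midranks and
Kendall's tau is tau-b; significance is available three ways —
two-tailed t with n-2 df (`cor_p_t()`), the normal approximation for
tau (`tau_p_normal()`), and a seeded Monte-Carlo permutation test with
estimator (1 + exceedances)/(1 + permutations). On the bundled
12-gene table the t route for rs and the normal route for tau reproduce
the published significance pattern for UTR length vs uATG count
(p = 0.004 and 0.006), retained as a regression. No multiple-testing
correction is applied by default, matching the source analysis;
Benjamini-Hochberg columns are available via `adjust = "BH"`.

The per-gene element total counts uATGs + introns + RG4s + stem loops.
uORFs are deliberately excluded: every uORF already contributes its
uATG, and every row and the column sums of the bundled table obey this
identity exactly — the composition was reverse-engineered from those
sums and is stated here rather than hidden.

## Variant annotation

`classify_variant()` intersects a variant's affected interval with the
feature map. Changing any base of a uORF-start ATG away from ATG is a
start disruption and suppresses the within-uORF coding-effect call for
that variant; SNVs inside uORFs are translated in the uORF's own frame
(synonymous / nonsynonymous / stop_gain / stop_loss); indels of length
not divisible by three are frameshifts. Open-ended uORFs extend to the
base before the sATG for containment. Variants printed with genomic
alleles for minus-strand genes are complemented (positions already
follow the transcript) by `to_transcript_alleles()` — the bundled
variant table is only internally consistent under this reading: the
annotated start-disrupting T>C at ABCA10 -482 is an A>G change on the
transcript, turning ATG into GTG.

## The simulator and what passing tests mean

`sim_utr()` builds UTRs in which the planted features are the *only*
features: the background is sampled with per-base rejection so that no
accidental ATG and no G-run of three arises, uORF bodies are assembled
from codons that cannot create stops, ATGs or G-runs even across codon
junctions, standalone uATGs get a 12-nt terminated reading frame so
they never seed a reportable uORF, and hairpin inserts use an A/C arm,
an all-C loop and the complementary arm so no scanner signal leaks out
of them. `sim_ortholog_msa()` derives orthologs at per-group
substitution rates (2%, 8%, 12%, 22%, 32% per site from primates to
fishes — chosen once to make the divergence grades cleanly separable,
not estimated from data) and then preserves or destroys each uATG per
its target conservation category, so recovery is exact by construction.
`sim_coverage()` draws Poisson counts (background 5% of mORF depth by
default), and `sim_variants()` plants one variant per class using the
genetic code.

This design makes recovery tests sharp — recall and precision of
planted features are exactly 1 over 50 seeded replicates in the
acceptance suite — but it also bounds what they show: real 5'UTRs have
GC-rich, repeat-laden backgrounds where detectors face borderline
calls, real alignments have gaps and lineage-specific indels (the
simulated alignment is ungapped), and real ribosome profiles have
strong positional biases that Poisson noise does not model. Passing
these tests certifies the algorithms' correctness on unambiguous
signals, not detector performance on genomic sequence.

## Problem sizes

The test and acceptance workloads use 300-nt simulated UTRs, ortholog
sets of 11 sequences, folding oracles to 14 nt, NJ recovery to 8 taxa,
exact permutation enumeration at n = 6 and 9,999-permutation Monte
Carlo runs — sizes at which every brute-force oracle is exact and the
whole suite runs in well under a minute, while matching the scale of
the bundled 12-gene annotation (UTRs of 26-910 nt).

## Known limitations

* Non-ATG starts (CUG/GUG) are out of scope, as are ribosome-scanning
  models and reinitiation logic.
* Alignments are consumed, never computed; quality of conservation
  calls is bounded by the upstream aligner.
* The G-score formula is artifact-defined; absolute scores are not
  comparable to any external mapper, only the ordering properties are.
* "Stem loop" is operationalised as "hairpin loop"; counting stems with
  internal loops as single units is available but both remain proxies
  for what a thermodynamic ensemble would call a stable stem.
* Intron records describe positions between spliced bases plus excised
  lengths; genome-coordinate liftover is out of scope.
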