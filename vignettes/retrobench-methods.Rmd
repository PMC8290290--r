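---
title: "Methods: retrotransposon integrity as an assembly quality benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrotransposon integrity as an assembly quality benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In large cereal genomes, 80–90 % of the sequence derives from transposable
elements, and the most informative test of an assembly is not the gene
space (which even fragmented short-read assemblies represent well) but the
repeat-rich intergenic space. LTR retrotransposons provide a built-in
assay: a full-length element (fl-LTR) carries two long terminal repeats
that are *identical at insertion* and diverge neutrally afterwards, is
bounded by a `TG…CA` motif, and is flanked by a short (here 5 bp)
target-site duplication (TSD) created by the insertion machinery. An
assembly that collapses near-identical repeats, or fills them with `N`
runs, loses exactly the young, highly similar copies — so the recovered
fl-LTR count, the insertion-age spectrum, the TSD rate, and the
positional distribution of SNPs and gaps along tracked elements all
measure assembly quality in the intergenic space.

`retrobench` implements this benchmark end to end: structural fl-LTR and
solo-LTR detection, Kimura 2-parameter (K2P) insertion dating,
junction-anchored tracking of elements between assembly versions, and a
panel of general assembly metrics (Nx statistics, stringent transcript
completeness, in-silico optical label maps, scaffold retention and gene
confidence rules). Because the real data of interest are multi-gigabase
genomes, the package ships a simulator that plants elements of known age
and position and then damages the genome the way short-read assembly
does; every analysis stage is validated against that planted truth.

## The simulator: what it states and what it does not

A simulated world is: an i.i.d. background sequence (default GC 0.44, a
cereal-like value); full-length elements and solo-LTRs copied from a
*shared ancestral sequence per family* and aged individually; designated
genes; and a degradation step.

Key modelling choices:

* **Shared ancestry.** All copies of a family descend from one ancestral
  LTR + internal sequence. This is what makes "near-identical copy pairs"
  (the collapse substrate) and consensus-based solo-LTR search meaningful.
  Element age `T` enters as `Poisson(L · mu · T)` substitution events per
  LTR copy (`mu = 1.3e-8`/site/year, the rate used for dating;
  transition:transversion ratio `kappa = 2`, a standard plant nuclear
  value). Events are drawn *with replacement* and applied sequentially, so
  the per-site process is the Markov chain that the K2P correction
  inverts exactly — expected pairwise LTR divergence is `≈ 2·mu·T`, with
  proper saturation at high ages.
* **Terminal motifs are protected** from mutation by default. The subject
  under test is the detector's use of the motif, not motif decay; a
  toggle (`mutate_motif`) exists.
* **TSDs are duplications of the insertion site**, never random sequence,
  and insertion is exactly reversible (excising the element plus one TSD
  copy restores the pre-insertion genome byte-for-byte; this is a tested
  invariant).
* **Genes are designated background windows**, not inserted foreign
  sequence: they are recorded verbatim in the truth and then suffer
  whatever degradation the genome suffers, which is what the completeness
  metrics need.
* **Dispersed insertions.** `simulate_genome` spaces insertion points at
  least `max_dist` (25 kb) apart by default. Nested and clustered
  insertion graphs are explicitly out of the simulator's scope
  (single-level insertions only), and dispersed planting makes each
  element an isolated test case for the detector. Real barley intergenic
  space is *more* clustered than this; a green recall test therefore
  establishes detector correctness on isolated elements, not performance
  inside TE nests.
* **Degradation** applies, in order: N-runs targeted at LTR intervals
  (geometric lengths, mean 300 bp, capped at 2 kb — free parameters, not
  calibrated claims, since the source data do not quantify gap-length
  distributions inside LTRs); collapse of one copy of selected ≥99 %
  identical element pairs; uniform substitutions; fragmentation into
  contigs. Per-LTR gap decisions come from fixed uniform draws, so for a
  given seed the gapped set at a low rate is a subset of the set at any
  higher rate — degradation severity is *nested*, which is what makes the
  monotonicity acceptance criterion a property of the pipeline rather
  than of RNG luck. N-masking preserves coordinates; collapse and
  fragmentation record edits so truth can be lifted into degraded
  coordinates (`removed`/`broken` flags).

## Detection

`find_candidates` finds exact 30-mer seed matches whose separation is
compatible with the inter-LTR distance window (3–25 kb at LTR lengths
100–2,000 bp), merges co-diagonal seeds, and extends each merged repeat
with an x-drop rule (+2/−2 scoring, stop when the running score falls 5
below its maximum). A repeat pair becomes a candidate when both repeat
lengths, the start-to-start distance and the global LTR similarity
(≥85 %) pass. Overlapping candidates are resolved greedily by score
("overlaps best"), ties by leftmost start, then shorter element; the
greedy pass compares against *kept* candidates only, so a spurious
repeat pair bridging two neighbouring same-family elements (which scores
below the younger of the two) can never displace both genuine elements.

`refine_boundaries` searches ±60 bp for the terminal `TG…CA` (at most one
mismatch over the four motif bases — candidates failing this are
dropped) and a flanking exact direct repeat of 4–20 bp. Ranking is
lexicographic: motif mismatches, then TSD presence, then smallest
boundary shift, then TSD length. TSD presence before shift (rather than
longest-TSD-first) matters: with a ±60 bp search square, chance ≥6 bp
direct repeats occur often enough to drag boundaries off the true
position.

Superfamily assignment reads the internal domain order along the element
strand (`INT-RT-RH` → RLC/Copia, `RT-RH-INT` → RLG/Gypsy, missing INT or
RH → RLX); domain hits are consumed as a table, not computed (HMM
scanning is out of scope). The quality filter requires a gap-free span,
tandem coverage ≤30 % (internal) / ≤35 % (each LTR), no gene-domain hit,
no duplicated TE domain kind, and strand consistency among TE domains.

The tandem scorer is a module definition (no external tool): a self-
comparison dot-strip scan over periods 2–50 bp at ≥80 % local identity,
with a 20 bp minimum aligned-run floor. The floor is essential: without
it, chance 2–4 bp self-matches cover ~30 % of random DNA and the filter
misfires on clean elements.

Solo-LTRs are consensus hits at ≥80 % identity over ≥80 % of the
consensus (module-defined thresholds), on either strand, that neither
overlap a detected full-length span nor have a partner hit within the
25 kb window on the same strand (which would indicate an undetected
pair).

## Dating and TSD arithmetic

The two LTRs of each element are globally aligned and their K2P distance
`d = −½·ln(1−2P−Q) − ¼·ln(1−2Q)` (gap/N columns excluded by pairwise
deletion) is converted to an age `T = d/(2·mu)`. At the reported mean age
of 700,000 years, a 5 bp TSD accumulates `100·5·mu·T = 4.55 %` expected
substitutions (`tsd_decay_fraction`, `expected_count` model) — the
"approximately 5 %" figure; a Poisson at-least-one-hit model (4.45 %) is
provided alongside, and the five sites of a single TSD copy reproduce
the printed number.

Repetitivity is the median assembly-wide frequency of an element's
20-mers in canonical (lexicographically minimal strand) orientation.

## Tracking and the divergence profile

For each element, the two junctions (100 bp flank + terminal 100 bp of
element) are searched in the target assembly with a seeded (k = 16) local
aligner; an element is accepted when both junctions hit the same target
sequence in the same orientation and the observed span is within 10 % of
the expected span. Accepted pairs are locally aligned (match +2,
mismatch −2, gap open −10, extend −0.5); SNP columns (two determinate
unequal bases) and N columns (target base `N`) are mapped to
query-relative coordinates, normalized to 1,000 bins, and summed over
10-bin windows into a 100-window profile. N bases score 0 against
everything in these alignments, so masked regions stay aligned as
N-columns instead of degenerating into gap pairs — otherwise the
N-channel of the profile would be empty by construction.

## Assembly benchmarks

* **Transcript completeness**: best seeded local hit per transcript;
  coverage is the percent of transcript bases aligned to determinate
  target bases, identity the percent of matching determinate columns.
  The two stock threshold pairs are (90, 97) for transcript-level
  evidence and (99, 100) for base-accuracy-sensitive gene models.
  Alignment is unspliced by design — the synthetic genes are unspliced,
  and the metric, not the spliced aligner, is the subject.
* **Label maps**: in-silico digestion at the DLE-1 motif `CTTAAG` (its
  own reverse complement, so one strand suffices; non-palindromic motifs
  are scanned on both strands). Map alignment is a dynamic program over
  monotone site matchings: +2 per matched site, −1 per skipped site
  inside the chain, a sizing penalty proportional to the relative
  spacing discrepancy (chains cannot cross discrepancies >10 %), terminal
  skips free. The confidence score is this DP total; the proprietary
  score of the optical-map platform is not reproducible, so the ≥20
  retention threshold maps onto this scale *by construction*: a 20-site
  self-alignment scores 40, a uniformly 3×-rescaled map scores ~2. For
  maps of ≤8 sites the DP provably equals exhaustive enumeration of all
  monotone matchings (tested). Label-site coverage digests the assembly,
  aligns every reference map sequence ≥100 kb to its best single
  assembly target, and counts matched reference sites over alignments
  with confidence ≥20.
* **Scaffold retention / gene confidence** are pure decision rules,
  tested against exhaustive enumeration of their input domains. One
  prose ambiguity was resolved: the second HC branch (UniPoa-only hit)
  requires a *complete* protein, which both the rule source and the
  worked examples imply.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally and in
  data-frame outputs; GFF3 emission converts to 1-based inclusive.
* Non-ACGTN letters are normalized to `N` on ingestion (count reported).
* K2P raises distinct errors for zero usable sites and for saturation
  (`1−2P−Q ≤ 0` or `1−2Q ≤ 0`); `date_elements` converts those to `NA`
  ages rather than aborting a batch.
* Elements at sequence edges keep `tsd = NA` and are flagged rather than
  dropped; junction flanks truncate at contig edges with flags.
* Ages are reported in years (`mu` is per year); histograms default to
  100 kyr bins.

## What a green test establishes — and what it does not

The simulator emulates: age-dependent LTR divergence, TSD creation,
solo-LTR structure, N-gap enrichment in LTRs, collapse of near-identical
copies, fragmentation, and base errors. It does not emulate: nested TE
insertions, indel mutation processes (substitutions only, so detector
diagonals are exact), realistic repeat landscapes (one or two families,
dispersed placement), read-level artefacts, or spliced genes. Recall,
boundary-error and age-recovery results therefore validate the
*implementation* of the detection/dating contracts, not their expected
performance on a real 4.5 Gb genome; conversely the decision-rule and
oracle-equivalence suites (K2P, Nx, label-map DP) are exact and carry
over unchanged.
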