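---
title: "Seed-region targeting of pathogenic SNVs with Cas12a: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-region targeting of pathogenic SNVs with Cas12a}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscan)
```

## The problem

LbCas12a recognizes a double-stranded DNA target when a 5′ TTTV
protospacer-adjacent motif (PAM; V = A, C or G) precedes a 21-nt target
site (the protospacer) and the crRNA spacer base-pairs with it.  The five
PAM-proximal target nucleotides — the *seed region* — are where pairing is
most stringency-critical: mismatches there destabilize R-loop formation and
can abort cleavage.  Target recognition also unleashes indiscriminate
single-stranded DNase activity in *trans* (collateral cleavage), which can
dequench a fluorescent reporter.  Together these two properties make Cas12a
a candidate detector for clinically relevant single-nucleotide variants
(SNVs): if a pathogenic SNV sits inside a seed region, a crRNA matching the
mutant allele should, in principle, discriminate mutant from wild-type (WT)
DNA and report the difference as fluorescence.

In practice a *single* seed mismatch is often tolerated, so discrimination
must be engineered: a deliberate extra mismatch (a *synthetic mismatch*,
SM) is placed in the crRNA near the variant, so that the off-target allele
faces two seed mismatches (poorly tolerated) while the on-target allele
faces only the SM (tolerated).  This package implements the whole design
path: locate every genomic site where this strategy can work, build the
candidate crRNAs, and classify assay read-outs.

## Pipeline model

The pipeline operates in 0-based half-open coordinates everywhere except
VCF positions (1-based) and human-readable PAM+k offsets (1-based from the
PAM-proximal end of the target site).

1. **Scan** (`scan_genome()`): every occurrence of TTTV on the plus strand
   and of its reverse complement BAAA (= [CGT]AAA) on the forward sequence
   (a minus-strand PAM) is located, *with overlap allowed* within and
   between the patterns — a plain left-to-right regex pass would miss the
   minus-strand `TAAA` inside `TTTAAA`.  The seed interval is the 5 bp
   immediately 3′ of the PAM on the PAM strand.  Sites whose seed would
   cross a contig edge are useless to every downstream stage and are
   discarded at scan time, tallied as `n_edge_discarded`; sites whose seed
   contains an N are likewise discarded and tallied separately as
   `n_ambiguous_discarded`, so
   `n_retained = n_raw − n_edge_discarded − n_ambiguous_discarded`.
   Lowercase (soft-masked) input is case-folded first: masking state must
   never change PAM counts.  Non-ACGT bases are normalized to N and can
   never participate in a PAM or seed match.
2. **Mask** (`mask_pams()`): PAM sites whose 4-bp interval intersects the
   reference footprint of a *common* variant (any per-alt allele frequency
   strictly above 1%) are excluded — a polymorphic PAM would make a test
   population-dependent.  Seed-only overlaps deliberately do **not**
   exclude: seed variants are exactly the targets being sought, and
   unforeseen seed variants in test samples are a known failure mode of the
   assay, not of site selection.
3. **Merge** (`merge_seeds()`): all retained seed intervals are unioned
   strand-agnostically into the genome's "targetable footprint".
   Book-ended (touching) intervals merge, matching default
   `bedtools merge` semantics; this choice changes the region count, so it
   is fixed and documented rather than configurable.
4. **Annotate** (`annotate_snvs()`): pathogenic SNVs (records whose
   clinical-significance string contains the exact token `Pathogenic`
   after splitting on `,` `|` `/`, with a 1-bp ref/alt pair) that fall in a
   retained seed are annotated with their *nearest PAM*, defined as the
   candidate site with the smallest PAM+k offset (ties: plus strand, then
   lowest coordinate), the 21-nt reference and alternate protospacers, GC
   content of seed and spacer, and a cancer-association flag (any of 16
   oncology word stems as a case-insensitive substring of the condition
   text — substring semantics are intentional, so "cytoma" matches
   "Pheochromocytoma").
5. **Design** (`enumerate_designs()`): for each target, a mutant-detecting
   and a WT-detecting spacer (protospacer sense, T→U), plus one pair per
   allowed SM position.

## Synthetic mismatch rule

The SM substitution is a single rule: replace the spacer base at PAM+k by
its Watson–Crick RNA complement.  Because the spacer base equals the
transcribed protospacer base, the SM then faces the displaced-strand base —
the DNA complement of the protospacer base X — giving:

| protospacer X | spacer base | SM base | pair (crRNA·DNA) | disrupted bond |
|---|---|---|---|---|
| C | C | G | G·G | G–C |
| G | G | C | C·C | G–C |
| T | U | A | A·A | A–T |
| A | A | U | U·T | A–T |

This reproduces exactly the permitted mismatch geometries — homopairs and
U·T — and can never produce a stabilizing wobble pair (rG·dT or rU·dG),
which would be better tolerated and blunt discrimination.  The property is
exhaustively tested over all four bases and all seed positions.

Candidate SM pairs are *ranked* by a heuristic assembled from qualitative
mismatch-tolerance behaviour: positions inside the seed first, G–C bond
disruption before A–T (G–C disruption tends to have the larger effect),
then increasing distance to the variant, then position.  The ranking is a
design aid, deliberately exposed and overridable; it is not a validated
activity score, and no claim is made that the top-ranked design is optimal
for a given locus.  PAM+6 (outside the seed) is enumerated only when
explicitly configured and always ranks after in-seed positions.

## Kinetics and zygosity classification

Collateral-cleavage read-outs arrive as replicate fluorescence time series.
Two summary metrics are offered: the **endpoint** at 3 h (default; the
nearest sample within one 5-min sampling interval, ties to the earlier
sample) and the **OLS slope** over the first 3 h.  The two agree in
practice; endpoint is the default because it needs no model fit.

The **ratio score** of a sample is the mean mutant-detecting metric divided
by the mean WT-detecting metric.  Calls follow fixed thresholds: ratio ≥ 5
→ homozygous mutant; ratio ≤ 0.1 → homozygous WT; anything between →
heterozygous.  The estimated mutant-allele fraction is
`ratio / (1 + ratio)`, which equals 0.5 exactly at ratio 1.  A heterozygous
call whose ratio lies at or beyond the open band (1/2, 2) is flagged as
*allelic imbalance*: a balanced heterozygote scores ≈1, while, e.g., one
mutant copy against two WT copies scores ≈0.5.  The band edges are
inclusive on the flagged side — a ratio of exactly 0.5 is flagged — because
that is the behaviour the imbalance flag exists to capture; both band and
thresholds are configurable arguments, since neither boundary is a law of
nature.

Formal significance testing against a water control is out of scope;
`above_background()` offers a documented 3-SD rule over blank replicates
instead.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every generator is deterministic
given `rng_seed` and restores the caller's RNG state.

* **Genomes**: i.i.d. bases from configurable probabilities (GC content
  0.2–0.8 in the validation suite), optionally with `TTTV + 21-mer`
  cassettes planted at recorded positions.  Real genomes are not i.i.d. —
  isochores, repeats and homopolymer tracts are absent — so passing tests
  demonstrate coordinate and rule correctness, not performance claims
  about the human genome.
* **Variant files**: common variants with allele frequencies drawn from a
  law straddling the 1% threshold (default uniform on [0, 0.05]), and
  uniformly placed pathogenic SNVs with `CLNSIG=Pathogenic` and condition
  names chosen to hit a configurable cancer fraction.  The truth table's
  in-seed flags come from the brute-force oracle, not from the scanner
  under test.
* **Oracle** (`oracle_scan()`): a naive base-R substring enumeration of
  both PAM patterns plus per-base seed coverage, deliberately independent
  of the Biostrings-based production scanner.  Scanner/oracle identity on
  random genomes is the suite's central equivalence property.
* **Plates** (`simulate_plate()`): saturating-exponential curves
  `F(t) = B + A(1 − exp(−k_eff t)) + N(0, σ)`.  The matched-channel rate
  defaults to k = 1/60 min⁻¹ so a fully active reaction reaches ~95% of
  its plateau at 3 h, as real assays do; baseline B = 100, amplitude
  A = 3000, σ = 5% of A, every 5 min for 3 h, triplicates.  Allele-fraction
  mixing is linear: for mutant-allele fraction g the mutant-detecting
  channel runs at `k(g + (1−g)/ρ)` and the WT-detecting channel at
  `k((1−g) + g/ρ)`, with ρ = 6 the default single-mismatch specificity
  fold.

### A structural limit of the ρ = 6 plate model

The saturating-exponential model bounds what the classifier can see.  Since
`x ↦ 1 − exp(−xT)` is increasing and concave through the origin, the
endpoint ratio between two channels can never exceed their rate ratio.
For a homozygote that rate ratio is exactly ρ, so with ρ = 6 the ratio
score lives in [1/6, 6] even in the most favorable baseline-free linear
regime — and saturation plus a positive baseline compress it much further
(≈[0.43, 2.3] at the defaults).  A homozygous-WT sample therefore can never
reach the 0.1 call threshold under ρ = 6, and per-genotype classification
accuracy for homozygotes is structurally unattainable at these settings;
the corresponding recovery test documents this honestly and fails.  Real
assays that do separate genotypes at the 5 / 0.1 thresholds imply an
*effective* endpoint specificity well above 10-fold; users simulating such
assays should raise `specificity_fold` (e.g. to 30–100) and, for
ratio-recovery studies, prefer the slope metric in a pre-plateau window,
where the slope ratio approaches ρ itself.

## Numerical and degenerate-input choices

* Strictness: "common" means AF **strictly** greater than the threshold
  (an AF of exactly 0.01 is not common); `Pathogenic` token matching is
  case-sensitive by default (so `Likely_pathogenic` does not qualify), with
  a documented case-insensitive switch.
* Variants without AF are never treated as common; missing INFO fields are
  `NA`, never zero.
* Multi-allelic records stay single records; filters and annotation act
  per alt, and each qualifying 1-bp alt yields its own target.
* A variant inside a seed whose every candidate 21-nt protospacer would
  cross the contig edge is reported in a skipped list with a reason rather
  than silently dropped.
* Empty inputs (header-only VCFs, all-N or empty contigs, zero pathogenic
  SNVs) produce empty outputs or explicit empty-input reports, never
  errors.
* The seed length (5), protospacer length (21) and PAM motif are
  configurable in `scan_config()`; defaults match LbCas12a conventions.

## Validation problem sizes

The shipped test suite validates scanner/oracle equivalence on 100 random
genomes of 1–100 kb across GC 0.2–0.8; per-base merge coverage exactly on
50-kb genomes; planted-SNV recovery (10,000 uniform SNVs on a 1-Mb genome,
99% binomial CI against oracle coverage); exhaustive SM soundness; and
classification on plates of 200 samples per genotype.  These sizes were
chosen as the smallest at which the properties are statistically
meaningful; all generators scale to larger runs by configuration.

## Known limitations

* Only a single PAM motif per scan (default TTTV); engineered-Cas PAM
  repertoires would need one scan per motif.
* No thermodynamic duplex-stability prediction, no chemically modified
  crRNAs, and no genome-wide off-target search for designed spacers.
* Indels and fusion junctions are out of scope; only 1-bp ref/alt pairs
  are targeted.
* Masking uses the record's single AF field; population-stratified or
  phased masking is not implemented.
* Full-genome human runs depend on which assembly contigs (unplaced, alt)
  are present in the input FASTA; counts are only comparable between runs
  on identical FASTA content.
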