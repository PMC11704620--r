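# seedscan

Genome-wide discovery of Cas12a-targetable pathogenic SNVs and
synthetic-mismatch crRNA design for CRISPR-based diagnostics (CRISPRdx).

## The problem

LbCas12a binds a DNA target when a 5′ **TTTV PAM** (V = A/C/G) precedes a
21-nt target site, and target recognition triggers collateral cleavage of a
quenched fluorescent reporter.  The five PAM-proximal target nucleotides —
the **seed region** — are the most stringency-critical part of
crRNA:target pairing, which makes SNVs located inside a seed the natural
candidates for Cas12a-based point-of-care detection (e.g. *BRAF* p.V600E
in melanoma liquid biopsies).  But a single seed mismatch is often
tolerated, so discrimination has to be engineered with a **synthetic
mismatch (SM)**: a deliberate extra mismatch in the crRNA seed, chosen so
the off-target allele faces two seed mismatches (poorly tolerated) while
the on-target allele faces only one.

`seedscan` implements the complete computational path, for genome analysts
and assay designers:

* **scan** — find every TTTV PAM on both strands (overlaps included),
  derive strand-aware 5-bp seed and 21-nt protospacer intervals;
* **mask** — exclude PAM sites overlapping common variants (allele
  frequency > 1%), merge seed regions into the genome's targetable
  footprint;
* **annotate** — select `Pathogenic` SNVs (1-bp ref/alt), intersect with
  seeds, attach the nearest PAM, PAM+k offset, ref/alt protospacers, GC
  content and a cancer-keyword flag;
* **design** — build mutant- and WT-detecting spacers and enumerate SM
  variants restricted to homopair (G·G, C·C, A·A) or U·T geometries, never
  stabilizing wobble pairs (rG·dT, rU·dG), ranked by seed membership, G–C
  vs A–T bond disruption and distance to the variant;
* **kinetics** — summarize collateral-cleavage fluorescence curves (3-h
  endpoint or OLS slope), compute mutant/WT **ratio scores** and call
  zygosity: ratio ≥ 5 → homozygous mutant, ≤ 0.1 → homozygous WT,
  between → heterozygous, with an allelic-imbalance flag outside the
  (1/2, 2) band and estimated mutant-allele fraction `ratio/(1+ratio)`;
* **simulate** — synthetic genomes, variant files and fluorescence plates
  with known ground truth, plus a brute-force scanning oracle, so the
  whole pipeline is testable offline.

## Worked example

```r
library(seedscan)

g <- c(chr7 = "TTTACACTGTAGCTAGACCAAAATGAATATAT")
sites <- scan_genome(g)$sites
sites
#>   contig pam_start pam_end strand pam_seq seed_start seed_end seed_seq
#> 1   chr7         0       4      +    TTTA          4        9    CACTG
#> 2   chr7        18      22      -    TTTG         13       18    GTCTA
```

Both strands are scanned: the minus-strand site is the `CAAA` at position
18, reported with its PAM (`TTTG`) and seed read 5′→3′ on the PAM strand.
A pathogenic SNV at position 5 sits at PAM+1 of the first site:

```r
v <- data.frame(contig = "chr7", pos1 = 5L, ref = "C", alt = "A",
                af = NA, clnsig = "Pathogenic",
                condition = "Malignant_melanoma")
ann <- annotate_snvs(v, sites, g)
ann$targets[, c("pos1", "offset", "protospacer_ref", "protospacer_alt",
                "cancer_associated")]
#>   pos1 offset       protospacer_ref       protospacer_alt cancer_associated
#> 1    5      1 CACTGTAGCTAGACCAAAATG AACTGTAGCTAGACCAAAATG              TRUE
```

The two protospacers differ exactly at the offset, and the condition text
matched the keyword "melanoma".  Enumerating mutant-detecting designs:

```r
d <- enumerate_designs(ann$targets[1, ])
d[d$detects == "mutant", c("pair_rank", "sm_position", "spacer_rna",
                           "pair_type", "disrupted_bond")]
#>   pair_rank sm_position            spacer_rna pair_type disrupted_bond
#> 1         0          NA AACUGUAGCUAGACCAAAAUG      none           none
#> 3         1           3 AAGUGUAGCUAGACCAAAAUG       G.G            G-C
#> 5         2           5 AACUCUAGCUAGACCAAAAUG       C.C            G-C
#> 7         3           2 AUCUGUAGCUAGACCAAAAUG       U.T            A-T
#> 9         4           4 AACAGUAGCUAGACCAAAAUG       A.A            A-T
```

Rank 0 is the no-SM baseline; G–C-disrupting SMs rank before A–T ones,
closer-to-variant first.  Classifying assay ratio scores:

```r
ratio_score(curves_for_one_sample)   # curves: time_min, value, role, replicate
#>   sample ratio   metric              call imbalance_flag est_mut_fraction
#> 1      s  6.00 endpoint homozygous_mutant          FALSE        0.857
#> 2      s  1.00 endpoint      heterozygous          FALSE        0.500
#> 3      s  0.05 endpoint     homozygous_wt          FALSE        0.048
#> 4      s  0.50 endpoint      heterozygous           TRUE        0.333
```

(one row per sample; four samples shown).  A ratio of 1 means both crRNAs
contribute equally (balanced heterozygote); 0.5 is called heterozygous but
flagged as allelic imbalance.

A thin shell front end is installed as `exec/seedscan`
(`seedscan scan|run|kinetics|simulate --key value ...`), writing BED6/TSV
artifacts and `key=value` stats.

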