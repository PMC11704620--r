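Package: seedscan
Title: Cas12a Seed-Region Targeting of Pathogenic SNVs and
    Synthetic-Mismatch crRNA Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide discovery of Cas12a (TTTV PAM) target sites whose
    five-nucleotide seed region overlaps clinically relevant single-nucleotide
    variants, for CRISPR-based diagnostics (CRISPRdx) of point mutations such
    as BRAF p.V600E. Scans both strands of a reference genome for PAM motifs,
    derives strand-aware seed and 21-nt protospacer intervals, excludes PAM
    sites hit by common population variants, merges seed regions into a
    targetable footprint, and annotates pathogenic SNVs with their nearest PAM
    and PAM-relative offset. Builds mutant- and wild-type-detecting crRNA
    spacers with synthetic mismatches restricted to homopair or U-T geometries
    (never wobble pairs), and classifies sample zygosity from collateral
    trans-cleavage fluorescence kinetics via mutant/wild-type ratio scores.
    Includes a synthetic-data module (random genomes, variant files with
    allele-frequency and clinical-significance fields, saturating-exponential
    fluorescence plates) and brute-force oracles so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
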