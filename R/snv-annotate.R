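#' Default cancer-association keyword list
#'
#' Lower-case substrings scanned case-insensitively against a variant's
#' condition text.  Substring semantics are deliberate: "cytoma" matches
#' "Pheochromocytoma".  The list covers the common oncology word stems
#' (cancer, carcinoma, leukemia, lymphoma, ... ), deduplicated.
#'
#' @return Character vector of lowercase keywords.
#' @export
cancer_keywords <- function() {
  c("cancer", "carcinoma", "leukemia", "lymphoma", "blastoma", "sarcoma",
    "cytoma", "glioma", "adenoma", "tumor", "melanoma", "thelioma",
    "fibroma", "neoplasm", "myoma", "canthoma")
}

#' Select pathogenic single-nucleotide variants
#'
#' Keeps records whose clinical-significance string, split on `,` `|` `/`,
#' contains the given token exactly (case-sensitive by default, so
#' "Likely_pathogenic" does not qualify for token "Pathogenic") and which
#' carry at least one 1-bp ref / 1-bp alt allele pair.
#'
#' @param variants Variant data.frame from [read_vcf()].
#' @param significance_token Token to require (default `"Pathogenic"`).
#' @param ignore_case Match the token case-insensitively (default `FALSE`).
#' @return The qualifying subset of `variants`.
#' @export
select_pathogenic_snvs <- function(variants,
                                   significance_token = "Pathogenic",
                                   ignore_case = FALSE) {
  if (nrow(variants) == 0L) return(variants)
  tokens <- strsplit(ifelse(is.na(variants$clnsig), "", variants$clnsig),
                     "[,|/]")
  tok <- if (ignore_case) tolower(significance_token) else significance_token
  has_token <- vapply(tokens, function(tt) {
    if (ignore_case) tt <- tolower(tt)
    tok %in% tt
  }, logical(1))
  has_snv_alt <- nchar(variants$ref) == 1L &
    vapply(split_field(variants$alt), function(a) any(nchar(a) == 1L),
           logical(1))
  out <- variants[has_token & has_snv_alt, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PAM-relative offset of a position within the seed
#'
#' PAM+k numbering is 1-based from the PAM-proximal end of the target site:
#' on a plus-strand site `k = pos0 - pam_end + 1`, on a minus-strand site
#' `k = pam_start - pos0`.  Values outside `[1, seed_len]` return `NA`.
#'
#' @param sites Site data.frame (rows aligned with `pos0`).
#' @param pos0 Integer vector of 0-based variant positions.
#' @param config A [scan_config()].
#' @return Integer vector of offsets or `NA`.
#' @export
offset_from_pam <- function(sites, pos0, config = scan_config()) {
  k <- ifelse(sites$strand == "+",
              pos0 - sites$pam_end + 1L,
              sites$pam_start - pos0)
  k <- as.integer(k)
  ifelse(k >= 1L & k <= config$seed_len, k, NA_integer_)
}

# one row per (variant record, 1-bp alt): helper for annotate_snvs
expand_snv_alts <- function(variants) {
  alts <- split_field(variants$alt)
  afs <- split_field(variants$af)
  rows <- rep(seq_len(nrow(variants)), lengths(alts))
  alt <- unlist(alts, use.names = FALSE)
  af <- unlist(lapply(seq_along(alts), function(i) {
    a <- afs[[i]]
    if (length(a) == length(alts[[i]])) a else
      rep(NA_character_, length(alts[[i]]))
  }), use.names = FALSE)
  keep <- nchar(alt) == 1L & nchar(variants$ref[rows]) == 1L
  data.frame(
    row = rows[keep],
    contig = variants$contig[rows[keep]],
    pos1 = variants$pos1[rows[keep]],
    ref = variants$ref[rows[keep]],
    alt = alt[keep],
    af = af[keep],
    condition = if (is.null(variants$condition)) NA_character_ else
      variants$condition[rows[keep]],
    stringsAsFactors = FALSE
  )
}

#' Annotate pathogenic SNVs with their nearest Cas12a PAM
#'
#' Each qualifying 1-bp alt of each pathogenic SNV that falls inside at
#' least one retained seed region yields one annotated target.  Among
#' candidate sites whose full protospacer lies within the contig, the site
#' with the smallest PAM-relative offset is chosen ("nearest PAM"), breaking
#' ties towards the plus strand and then the lowest PAM start.  Variants in a
#' seed whose every candidate protospacer runs out of bounds are reported in
#' the skipped list.
#'
#' @param snvs Pathogenic SNV data.frame (see [select_pathogenic_snvs()]).
#' @param sites Retained site data.frame from [mask_pams()].
#' @param genome Named character vector of contig sequences.
#' @param config A [scan_config()].
#' @param keywords Lowercase keyword vector for the cancer-association flag
#'   (default [cancer_keywords()]).
#' @return List with `targets` and `skipped` data.frames.  `targets` columns:
#'   `contig`, `pos1`, `ref`, `alt`, `strand`, `pam_start`, `offset`
#'   (PAM+k, in 1..seed_len), `protospacer_ref`, `protospacer_alt` (21-mers
#'   read 5'->3' on the PAM strand; on a minus-strand site the substituted
#'   base is the complement of the VCF alt), `seed_gc`, `spacer_gc`,
#'   `cancer_associated`, `n_candidate_pams`, `condition`.
#' @export
annotate_snvs <- function(snvs, sites, genome, config = scan_config(),
                          keywords = cancer_keywords()) {
  plen <- config$protospacer_len
  lens <- contig_lengths(genome)
  targets_empty <- data.frame(
    contig = character(), pos1 = integer(), ref = character(),
    alt = character(), strand = character(), pam_start = integer(),
    offset = integer(), protospacer_ref = character(),
    protospacer_alt = character(), seed_gc = numeric(),
    spacer_gc = numeric(), cancer_associated = logical(),
    n_candidate_pams = integer(), condition = character(),
    stringsAsFactors = FALSE)
  skipped_empty <- data.frame(contig = character(), pos1 = integer(),
                              ref = character(), alt = character(),
                              reason = character(), stringsAsFactors = FALSE)
  if (nrow(snvs) == 0L || nrow(sites) == 0L) {
    return(list(targets = targets_empty, skipped = skipped_empty))
  }
  va <- expand_snv_alts(snvs)
  if (nrow(va) == 0L) {
    return(list(targets = targets_empty, skipped = skipped_empty))
  }
  seed_gr <- GenomicRanges::GRanges(
    sites$contig,
    IRanges::IRanges(start = sites$seed_start + 1L, end = sites$seed_end))
  var_gr <- GenomicRanges::GRanges(va$contig,
                                   IRanges::IRanges(start = va$pos1, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(var_gr, seed_gr))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(q) == 0L) {
    return(list(targets = targets_empty, skipped = skipped_empty))
  }
  pos0 <- va$pos1[q] - 1L
  offs <- offset_from_pam(sites[s, , drop = FALSE], pos0, config)
  proto <- protospacer_interval(sites[s, , drop = FALSE], lens, config)
  n_cand <- as.integer(table(factor(q, levels = seq_len(nrow(va)))))

  cand <- data.frame(q = q, s = s, offset = offs,
                     strand = sites$strand[s],
                     pam_start = sites$pam_start[s],
                     in_bounds = is.na(proto$reason),
                     stringsAsFactors = FALSE)
  # variants whose every candidate protospacer is out of bounds
  any_cand <- unique(q)
  ok <- cand[cand$in_bounds & !is.na(cand$offset), , drop = FALSE]
  skipped_q <- setdiff(any_cand, unique(ok$q))
  skipped <- if (length(skipped_q)) {
    data.frame(contig = va$contig[skipped_q], pos1 = va$pos1[skipped_q],
               ref = va$ref[skipped_q], alt = va$alt[skipped_q],
               reason = "protospacer_out_of_bounds",
               stringsAsFactors = FALSE)
  } else skipped_empty
  if (nrow(ok) == 0L) {
    return(list(targets = targets_empty, skipped = skipped))
  }
  # nearest PAM: minimal offset, tie-break plus strand then lowest pam_start
  ok <- ok[order(ok$q, ok$offset, ok$strand, ok$pam_start), , drop = FALSE]
  best <- ok[!duplicated(ok$q), , drop = FALSE]

  bi <- best$s
  vi <- best$q
  st <- sites[bi, , drop = FALSE]
  plus <- st$strand == "+"
  seqs <- genome[st$contig]
  raw <- ifelse(plus,
                substr(seqs, st$pam_end + 1L, st$pam_end + plen),
                substr(seqs, st$pam_start - plen + 1L, st$pam_start))
  proto_ref <- ifelse(plus, raw, revcomp(raw))
  # protospacer position k corresponds to the variant's PAM+k offset
  off <- best$offset
  expect_ref <- ifelse(plus, va$ref[vi], revcomp(va$ref[vi]))
  ref_ok <- substr(proto_ref, off, off) == expect_ref
  sub_base <- ifelse(plus, va$alt[vi], revcomp(va$alt[vi]))
  proto_alt <- proto_ref
  substr(proto_alt, off, off) <- sub_base
  cond <- va$condition[vi]
  cancer <- vapply(tolower(ifelse(is.na(cond), "", cond)), function(cc) {
    any(vapply(keywords, grepl, logical(1), x = cc, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)

  targets <- data.frame(
    contig = va$contig[vi], pos1 = va$pos1[vi], ref = va$ref[vi],
    alt = va$alt[vi], strand = st$strand, pam_start = st$pam_start,
    offset = off, protospacer_ref = proto_ref, protospacer_alt = proto_alt,
    seed_gc = gc_fraction(st$seed_seq), spacer_gc = gc_fraction(proto_ref),
    cancer_associated = cancer, n_candidate_pams = n_cand[vi],
    condition = cond, stringsAsFactors = FALSE)
  if (any(!ref_ok)) {
    skipped <- rbind(skipped, data.frame(
      contig = targets$contig[!ref_ok], pos1 = targets$pos1[!ref_ok],
      ref = targets$ref[!ref_ok], alt = targets$alt[!ref_ok],
      reason = "ref_allele_mismatch", stringsAsFactors = FALSE))
    targets <- targets[ref_ok, , drop = FALSE]
  }
  rownames(targets) <- NULL
  rownames(skipped) <- NULL
  list(targets = targets, skipped = skipped)
}

#' Summary statistics for an annotation run
#'
#' @param targets Target data.frame from [annotate_snvs()].
#' @param merged Merged-seed result from [merge_seeds()].
#' @param all_pathogenic_count Total number of pathogenic SNVs considered.
#' @return List with `n_in_seed` (distinct variants annotated), `frac_in_seed`,
#'   `pct_in_seed` (formatted to 1 decimal), `n_cancer_associated`,
#'   `genome_fraction`, and `empty_input` flag.
#' @export
summarize_targets <- function(targets, merged, all_pathogenic_count) {
  if (all_pathogenic_count == 0L) {
    return(list(n_in_seed = 0L, frac_in_seed = NA_real_,
                pct_in_seed = NA_character_, n_cancer_associated = 0L,
                genome_fraction = merged$genome_fraction,
                empty_input = TRUE))
  }
  key <- paste(targets$contig, targets$pos1, targets$ref, targets$alt)
  n_in_seed <- length(unique(key))
  frac <- n_in_seed / all_pathogenic_count
  n_cancer <- length(unique(key[targets$cancer_associated]))
  list(n_in_seed = n_in_seed, frac_in_seed = frac,
       pct_in_seed = sprintf("%.1f%%", 100 * frac),
       n_cancer_associated = n_cancer,
       genome_fraction = merged$genome_fraction,
       empty_input = FALSE)
}
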