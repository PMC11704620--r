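#' Is a variant common?
#'
#' A record is common when any of its per-alt allele frequencies is strictly
#' greater than the threshold ("more than 1%" at the default).  Records
#' without allele-frequency information are never called common.
#'
#' @param variants Variant data.frame from [read_vcf()].
#' @param af_threshold Allele-frequency threshold as a fraction
#'   (default 0.01).
#' @return Logical vector, one element per record.
#' @export
is_common <- function(variants, af_threshold = 0.01) {
  stopifnot(af_threshold >= 0, af_threshold <= 1)
  vapply(split_field(variants$af), function(a) {
    if (length(a) == 0L) return(FALSE)
    af <- suppressWarnings(as.numeric(a))
    af <- af[!is.na(af)]
    if (length(af) == 0L) return(FALSE)
    if (any(af < 0 | af > 1)) {
      stop("allele frequency outside [0, 1]: ", paste(af, collapse = ","))
    }
    any(af > af_threshold)
  }, logical(1))
}

#' Exclude PAM sites hit by common variants
#'
#' A PAM site is excluded when the reference footprint of a common variant,
#' `[pos1 - 1, pos1 - 1 + nchar(ref))` in 0-based coordinates, intersects the
#' 4-bp PAM interval.  Overlap with the seed alone does not exclude: the
#' filter protects PAM recognition, and seed variants are exactly what the
#' downstream annotation is looking for.
#'
#' @param sites Site data.frame from [scan_genome()].
#' @param variants Variant data.frame from [read_vcf()] (the common-variant
#'   call set).
#' @param af_threshold Allele-frequency threshold passed to [is_common()].
#' @param contigs Optional character vector of known contig names; variants
#'   on other contigs are skipped with a warning.  Default `NULL` skips the
#'   check.
#' @return List with `retained` (site data.frame), `excluded` (site rows plus
#'   `variant_pos1`, `variant_ref`, `variant_af` of one offending variant)
#'   and `af_threshold`.  Retained and excluded partition the input exactly.
#' @export
mask_pams <- function(sites, variants, af_threshold = 0.01, contigs = NULL) {
  if (!is.null(contigs)) {
    unknown <- !(variants$contig %in% contigs)
    if (any(unknown)) {
      warning(sum(unknown), " variant(s) on unknown contig(s) skipped: ",
              paste(unique(variants$contig[unknown]), collapse = ", "))
      variants <- variants[!unknown, , drop = FALSE]
    }
  }
  common <- variants[is_common(variants, af_threshold), , drop = FALSE]
  if (nrow(sites) == 0L || nrow(common) == 0L) {
    excluded <- cbind(sites[0L, , drop = FALSE],
                      data.frame(variant_pos1 = integer(),
                                 variant_ref = character(),
                                 variant_af = character(),
                                 stringsAsFactors = FALSE))
    return(list(retained = sites, excluded = excluded,
                af_threshold = af_threshold))
  }
  pam_gr <- GenomicRanges::GRanges(
    sites$contig,
    IRanges::IRanges(start = sites$pam_start + 1L, end = sites$pam_end))
  var_gr <- GenomicRanges::GRanges(
    common$contig,
    IRanges::IRanges(start = common$pos1,
                     width = nchar(common$ref)))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pam_gr, var_gr))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  first <- !duplicated(q)
  excl_idx <- q[first]
  var_idx <- s[first]
  is_excl <- logical(nrow(sites))
  is_excl[excl_idx] <- TRUE
  excluded <- sites[excl_idx, , drop = FALSE]
  excluded$variant_pos1 <- common$pos1[var_idx]
  excluded$variant_ref <- common$ref[var_idx]
  excluded$variant_af <- common$af[var_idx]
  rownames(excluded) <- NULL
  retained <- sites[!is_excl, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded, af_threshold = af_threshold)
}

#' Merge seed intervals into a strand-agnostic targetable footprint
#'
#' Takes the union of all seed intervals, ignoring strand, merging intervals
#' that overlap or touch (book-ended intervals merge, matching default
#' `bedtools merge` behaviour), and reports coverage statistics over the
#' genome.
#'
#' @param sites Site data.frame from [scan_genome()].
#' @param lengths Named integer vector of contig lengths
#'   (see [contig_lengths()]).
#' @return List with `intervals` (data.frame `contig`, `start`, `end`,
#'   0-based half-open, sorted and pairwise disjoint), `n_regions`,
#'   `total_bp` and `genome_fraction` (= total_bp / total genome bp).
#' @export
merge_seeds <- function(sites, lengths) {
  total_len <- sum(as.numeric(lengths))
  if (nrow(sites) == 0L) {
    return(list(intervals = data.frame(contig = character(),
                                       start = integer(), end = integer(),
                                       stringsAsFactors = FALSE),
                n_regions = 0L, total_bp = 0,
                genome_fraction = if (total_len > 0) 0 else NA_real_))
  }
  gr <- GenomicRanges::GRanges(
    factor(sites$contig, levels = names(lengths)),
    IRanges::IRanges(start = sites$seed_start + 1L, end = sites$seed_end))
  merged <- GenomicRanges::reduce(gr)  # merges overlapping and book-ended
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(merged)),
    start = BiocGenerics::start(merged) - 1L,
    end = BiocGenerics::end(merged),
    stringsAsFactors = FALSE
  )
  total_bp <- sum(as.numeric(df$end - df$start))
  list(intervals = df, n_regions = nrow(df), total_bp = total_bp,
       genome_fraction = total_bp / total_len)
}
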