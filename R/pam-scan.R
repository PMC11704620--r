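#' Scan configuration
#'
#' Bundles the motif and length conventions used across the scanner: the PAM
#' motif (default TTTV, the LbCas12a preference), the seed length (the five
#' PAM-proximal target nucleotides whose pairing with the crRNA is most
#' stringency-critical) and the protospacer length (21 nt).
#'
#' @param pam_pattern PAM motif as an IUPAC string read 5'->3' on the PAM
#'   strand (default `"TTTV"`).
#' @param seed_len Seed length in bp (default 5).
#' @param protospacer_len Protospacer length in bp (default 21).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(pam_pattern = "TTTV", seed_len = 5L,
                        protospacer_len = 21L) {
  seed_len <- as.integer(seed_len)
  protospacer_len <- as.integer(protospacer_len)
  stopifnot(nchar(pam_pattern) >= 1L, seed_len >= 1L,
            protospacer_len >= seed_len)
  structure(list(pam_pattern = toupper(pam_pattern), seed_len = seed_len,
                 protospacer_len = protospacer_len),
            class = "scan_config")
}

empty_sites <- function() {
  data.frame(contig = character(), pam_start = integer(),
             pam_end = integer(), strand = character(),
             pam_seq = character(), seed_start = integer(),
             seed_end = integer(), seed_seq = character(),
             stringsAsFactors = FALSE)
}

#' Find all PAM sites on one contig
#'
#' Locates every occurrence of the PAM motif on the plus strand and every
#' occurrence of its reverse complement (a minus-strand PAM) in a single
#' left-to-right pass, with overlapping matches allowed both within and
#' between the two patterns: `TTTAAA`, for instance, carries a plus-strand
#' `TTTA` at offset 0 and a minus-strand `TAAA` at offset 2.  Coordinates are
#' 0-based half-open.  The seed interval sits immediately 3' of the PAM on
#' the PAM strand: `[pam_end, pam_end + seed_len)` on plus,
#' `[pam_start - seed_len, pam_start)` on minus.  Sites whose seed would run
#' past a contig edge, or whose seed contains an N, are discarded and
#' tallied.  Matches whose PAM contains an N are never reported.
#'
#' @param sequence Normalized contig sequence (A/C/G/T/N upper case).
#' @param contig_name Contig name for the output rows.
#' @param config A [scan_config()].
#' @return Data.frame of retained sites, sorted by `(pam_start, strand)`,
#'   with columns `contig`, `pam_start`, `pam_end`, `strand`, `pam_seq`,
#'   `seed_start`, `seed_end`, `seed_seq`; `pam_seq` and `seed_seq` are read
#'   5'->3' on the PAM strand.  A `stats` attribute carries the integer
#'   vector `c(n_raw, n_retained, n_edge_discarded, n_ambiguous_discarded)`.
#' @examples
#' scan_contig("TTTACGTACGTAC", "c1", scan_config())
#' @export
scan_contig <- function(sequence, contig_name, config = scan_config()) {
  L <- nchar(sequence)
  k <- config$seed_len
  plen <- nchar(config$pam_pattern)
  minus_pattern <- revcomp(config$pam_pattern)
  if (L < plen) {
    out <- empty_sites()
    attr(out, "stats") <- c(n_raw = 0L, n_retained = 0L,
                            n_edge_discarded = 0L,
                            n_ambiguous_discarded = 0L)
    return(out)
  }
  subj <- Biostrings::DNAString(sequence)
  # fixed subject: IUPAC codes in the pattern are expanded, but N in the
  # subject only matches a literal N, so a PAM can never contain N
  fx <- c(pattern = FALSE, subject = TRUE)
  plus0 <- BiocGenerics::start(
    Biostrings::matchPattern(config$pam_pattern, subj, fixed = fx)) - 1L
  minus0 <- BiocGenerics::start(
    Biostrings::matchPattern(minus_pattern, subj, fixed = fx)) - 1L
  n_raw <- length(plus0) + length(minus0)

  # seed intervals, 0-based half-open
  p_seed_start <- plus0 + plen
  p_seed_end <- p_seed_start + k
  m_seed_start <- minus0 - k
  m_seed_end <- minus0

  p_edge <- p_seed_end > L
  m_edge <- m_seed_start < 0L
  p_seed <- ifelse(p_edge, NA_character_,
                   substr(rep(sequence, length(plus0)),
                          p_seed_start + 1L, p_seed_end))
  m_seed_raw <- ifelse(m_edge, NA_character_,
                       substr(rep(sequence, length(minus0)),
                              m_seed_start + 1L, m_seed_end))
  p_ambig <- !p_edge & grepl("N", p_seed, fixed = TRUE)
  m_ambig <- !m_edge & grepl("N", m_seed_raw, fixed = TRUE)
  p_keep <- !p_edge & !p_ambig
  m_keep <- !m_edge & !m_ambig

  n_edge <- sum(p_edge) + sum(m_edge)
  n_ambig <- sum(p_ambig) + sum(m_ambig)

  plus_df <- data.frame(
    contig = rep(contig_name, sum(p_keep)),
    pam_start = plus0[p_keep],
    pam_end = plus0[p_keep] + plen,
    strand = rep("+", sum(p_keep)),
    pam_seq = substr(rep(sequence, sum(p_keep)),
                     plus0[p_keep] + 1L, plus0[p_keep] + plen),
    seed_start = p_seed_start[p_keep],
    seed_end = p_seed_end[p_keep],
    seed_seq = p_seed[p_keep],
    stringsAsFactors = FALSE
  )
  minus_kept <- minus0[m_keep]
  minus_df <- data.frame(
    contig = rep(contig_name, sum(m_keep)),
    pam_start = minus_kept,
    pam_end = minus_kept + plen,
    strand = rep("-", sum(m_keep)),
    pam_seq = if (sum(m_keep)) revcomp(
      substr(rep(sequence, sum(m_keep)), minus_kept + 1L,
             minus_kept + plen)) else character(0),
    seed_start = m_seed_start[m_keep],
    seed_end = m_seed_end[m_keep],
    seed_seq = if (sum(m_keep)) revcomp(m_seed_raw[m_keep]) else character(0),
    stringsAsFactors = FALSE
  )
  out <- rbind(plus_df, minus_df)
  out <- out[order(out$pam_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stats") <- c(n_raw = n_raw,
                          n_retained = nrow(out),
                          n_edge_discarded = as.integer(n_edge),
                          n_ambiguous_discarded = as.integer(n_ambig))
  out
}

#' Scan a whole genome for PAM sites
#'
#' Concatenates per-contig scans (see [scan_contig()]) in the genome's
#' contig order and sums their tallies.
#'
#' @param genome Named character vector of normalized contig sequences.
#' @param config A [scan_config()].
#' @return List with `sites` (data.frame as in [scan_contig()]) and `stats`
#'   (named integer vector `n_raw`, `n_retained`, `n_edge_discarded`,
#'   `n_ambiguous_discarded`).
#' @export
scan_genome <- function(genome, config = scan_config()) {
  per <- lapply(names(genome), function(nm) {
    scan_contig(genome[[nm]], nm, config)
  })
  stats <- Reduce(`+`, lapply(per, attr, "stats"),
                  c(n_raw = 0L, n_retained = 0L, n_edge_discarded = 0L,
                    n_ambiguous_discarded = 0L))
  sites <- do.call(rbind, c(list(empty_sites()), per))
  rownames(sites) <- NULL
  attr(sites, "stats") <- NULL
  list(sites = sites, stats = stats)
}

#' Protospacer intervals for PAM sites
#'
#' The protospacer is the `protospacer_len` (default 21) bp target stretch
#' immediately 3' of the PAM on the PAM strand: `[pam_end, pam_end + 21)` for
#' a plus-strand site, `[pam_start - 21, pam_start)` for a minus-strand site.
#' Sites whose protospacer would run past the contig edge get `NA` bounds and
#' a reason.
#'
#' @param sites Site data.frame from [scan_contig()] or [scan_genome()].
#' @param lengths Named integer vector of contig lengths
#'   (see [contig_lengths()]).
#' @param config A [scan_config()].
#' @return Data.frame with columns `proto_start`, `proto_end` (0-based
#'   half-open, `NA` when out of bounds) and `reason` (`NA` or
#'   `"out_of_bounds"`), row-aligned with `sites`.
#' @export
protospacer_interval <- function(sites, lengths, config = scan_config()) {
  n <- nrow(sites)
  plen <- config$protospacer_len
  L <- unname(lengths[sites$contig])
  plus <- sites$strand == "+"
  start <- ifelse(plus, sites$pam_end, sites$pam_start - plen)
  end <- ifelse(plus, sites$pam_end + plen, sites$pam_start)
  oob <- start < 0L | end > L
  data.frame(
    proto_start = ifelse(oob, NA_integer_, as.integer(start)),
    proto_end = ifelse(oob, NA_integer_, as.integer(end)),
    reason = ifelse(oob, "out_of_bounds", NA_character_),
    stringsAsFactors = FALSE
  )
}
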