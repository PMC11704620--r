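#' Read a multi-contig FASTA file into a normalized genome
#'
#' Sequences are case-folded to upper case and any IUPAC ambiguity code other
#' than N (e.g. R, Y, S, W) is mapped to N with a warning.  Soft-masked
#' (lowercase) bases are treated identically to their uppercase counterparts,
#' so repeat masking never changes downstream PAM counts.  Bases stored as N
#' can never take part in a PAM or seed match.
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @return A named character vector, one element per contig, in file order.
#'   Sequences contain only A, C, G, T, N.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  head_lines <- readLines(con, n = 50L, warn = FALSE)
  close(con)
  nonblank <- which(nzchar(trimws(head_lines)))
  if (length(nonblank) == 0L) {
    stop("FASTA format error at line 1: file is empty: ", path)
  }
  if (!startsWith(trimws(head_lines[nonblank[1L]]), ">")) {
    stop("FASTA format error at line ", nonblank[1L],
         ": expected a '>' header before sequence data")
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) {
    stop("FASTA format error at line 1: no sequences found in ", path)
  }
  # keep only the first whitespace-delimited token of each header
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  genome <- toupper(as.character(seqs))
  names(genome) <- nm
  n_ambig <- sum(vapply(genome, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, integer(1)))
  if (n_ambig > 0L) {
    genome <- vapply(genome, function(s) gsub("[^ACGTN]", "N", s),
                     character(1))
    warning(n_ambig, " non-ACGTN base(s) mapped to N")
  }
  genome
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Contig lengths of a genome
#'
#' @param genome Named character vector of contig sequences.
#' @return Named integer vector of lengths in bp.
#' @export
contig_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}

#' Read a VCF file into a variant table
#'
#' One row per VCF line; multi-allelic records are kept as single rows with
#' comma-separated `alt` (and, when present, per-alt `af`).  Missing INFO
#' fields yield `NA`, never zeros.  The INFO keys used for allele frequency,
#' clinical significance and condition text are configurable because ClinVar
#' and population call-set dialects differ.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @param af_key INFO key holding per-alt allele frequencies (default `"AF"`).
#' @param clnsig_key INFO key holding the clinical-significance string
#'   (default `"CLNSIG"`).
#' @param condition_key INFO key holding free-text condition/disease names
#'   (default `"CLNDN"`).
#' @return A data.frame with columns `contig`, `pos1` (1-based), `ref`,
#'   `alt` (comma-separated), `af` (comma-separated string or `NA`),
#'   `clnsig`, `condition`.
#' @export
read_vcf <- function(path, af_key = "AF", clnsig_key = "CLNSIG",
                     condition_key = "CLNDN") {
  if (!file.exists(path)) {
    stop("VCF file does not exist: ", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # always a CHROM..INFO character matrix, even for 0/1 rows
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.frame(contig = character(), pos1 = integer(),
                      ref = character(), alt = character(),
                      af = character(), clnsig = character(),
                      condition = character(), stringsAsFactors = FALSE))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos) || any(pos < 1L)) {
    bad <- which(is.na(pos) | pos < 1L)[1L]
    stop("VCF format error: POS is not a positive integer at record ", bad)
  }
  out <- data.frame(
    contig = as.character(fix[, "CHROM"]),
    pos1 = pos,
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    af = as.character(vcfR::extract.info(v, element = af_key)),
    clnsig = as.character(vcfR::extract.info(v, element = clnsig_key)),
    condition = as.character(vcfR::extract.info(v, element = condition_key)),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$ref) | is.na(out$ref))) {
    stop("VCF format error: empty REF allele")
  }
  n_alts <- lengths(strsplit(out$alt, ",", fixed = TRUE))
  n_afs <- ifelse(is.na(out$af), NA_integer_,
                  lengths(strsplit(out$af, ",", fixed = TRUE)))
  bad <- which(!is.na(n_afs) & n_afs != n_alts)
  if (length(bad) > 0L) {
    stop("VCF format error: ", af_key,
         " count does not match ALT count at record ", bad[1L])
  }
  out
}

#' Write a variant table as a minimal VCF 4.2 file
#'
#' Intended for synthetic fixtures; writes AF/CLNSIG/CLNDN INFO fields when
#' the corresponding columns are present and non-missing.  Full header
#' fidelity for arbitrary VCFs is out of scope.
#'
#' @param variants Data.frame as returned by [read_vcf()].
#' @param path Output path (written uncompressed).
#' @param af_key,clnsig_key,condition_key INFO keys to write under.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, path, af_key = "AF", clnsig_key = "CLNSIG",
                      condition_key = "CLNDN") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="Allele frequency">',
            af_key),
    sprintf('##INFO=<ID=%s,Number=.,Type=String,Description="Clinical significance">',
            clnsig_key),
    sprintf('##INFO=<ID=%s,Number=.,Type=String,Description="Condition">',
            condition_key),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  info_of <- function(i) {
    parts <- character(0)
    if (!is.null(variants$af) && !is.na(variants$af[i])) {
      parts <- c(parts, paste0(af_key, "=", variants$af[i]))
    }
    if (!is.null(variants$clnsig) && !is.na(variants$clnsig[i])) {
      parts <- c(parts, paste0(clnsig_key, "=", variants$clnsig[i]))
    }
    if (!is.null(variants$condition) && !is.na(variants$condition[i])) {
      parts <- c(parts, paste0(condition_key, "=", variants$condition[i]))
    }
    if (length(parts) == 0L) "." else paste(parts, collapse = ";")
  }
  body <- if (nrow(variants) == 0L) character(0) else {
    vapply(seq_len(nrow(variants)), function(i) {
      paste(variants$contig[i], variants$pos1[i], ".", variants$ref[i],
            variants$alt[i], ".", ".", info_of(i), sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write intervals to a BED6 file
#'
#' Coordinates are 0-based half-open per BED convention.  When a `strand`
#' column is present it goes in column 6; name and score default to ".".
#'
#' @param intervals Data.frame with columns `contig`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (any(intervals$start < 0 | intervals$end <= intervals$start)) {
    stop("invalid interval: require 0 <= start < end")
  }
  df <- data.frame(
    contig = intervals$contig,
    start = intervals$start,
    end = intervals$end,
    name = if (is.null(intervals$name)) "." else intervals$name,
    score = if (is.null(intervals$score)) "." else intervals$score,
    strand = if (is.null(intervals$strand)) "." else intervals$strand,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write BED file: ", path, " (",
                        conditionMessage(ok), ")")
  invisible(path)
}

#' Read a BED file (3 to 6 columns)
#'
#' @param path Path to a BED file.
#' @return Data.frame with columns `contig`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with "." ).
#' @export
read_bed <- function(path) {
  cols <- c("contig", "start", "end", "name", "score", "strand")
  if (length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(),
                      score = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  names(df) <- cols[seq_len(ncol(df))]
  for (miss in setdiff(cols, names(df))) df[[miss]] <- "."
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[cols]
}

#' Write a data.frame as a tab-separated file with a header row
#'
#' @param records Data.frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(records, path) {
  ok <- tryCatch({
    write.table(records, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write TSV file: ", path, " (",
                        conditionMessage(ok), ")")
  invisible(path)
}

#' Read a tab-separated file with a header row
#'
#' @param path Path to a TSV file.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "", quote = "")
}

# reverse complement of DNA character vector
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# GC fraction of sequence strings (N counted in the denominator)
gc_fraction <- function(x) {
  gc <- nchar(gsub("[^GCgc]", "", x))
  n <- nchar(x)
  ifelse(n == 0L, NA_real_, gc / n)
}

# split per-alt comma-joined fields into character lists
split_field <- function(x) {
  if (length(x) == 0L) return(list())
  strsplit(ifelse(is.na(x), "", as.character(x)), ",", fixed = TRUE)
}
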