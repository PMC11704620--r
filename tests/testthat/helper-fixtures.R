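# shared fixture builders; everything is generated in code at test time

# random genome as a named character vector
random_genome <- function(len, gc = 0.5, seed = 1L, name = "c1") {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  setNames(paste(sample(names(probs), len, replace = TRUE, prob = probs),
                 collapse = ""), name)
}

# independent per-base seed coverage count from a site table (not oracle_scan)
brute_seed_bp <- function(sites, lengths) {
  total <- 0L
  for (nm in names(lengths)) {
    cov <- logical(lengths[[nm]])
    ss <- sites[sites$contig == nm, , drop = FALSE]
    for (i in seq_len(nrow(ss))) {
      cov[(ss$seed_start[i] + 1L):ss$seed_end[i]] <- TRUE
    }
    total <- total + sum(cov)
  }
  total
}

site_key <- function(sites) {
  sort(paste(sites$contig, sites$pam_start, sites$strand))
}

# flat replicate curves producing an exact endpoint value
flat_curves <- function(sample, role, value, crrna = role, n_rep = 3,
                        times = seq(0, 180, 5)) {
  do.call(rbind, lapply(seq_len(n_rep), function(r) {
    data.frame(sample = sample, crrna = crrna, role = role, replicate = r,
               time_min = times, value = value, stringsAsFactors = FALSE)
  }))
}

# a sample whose ratio score is exactly `ratio` (wt endpoint fixed at 1000)
ratio_fixture <- function(ratio, sample = "s") {
  rbind(flat_curves(sample, "mutant_detecting", 1000 * ratio),
        flat_curves(sample, "wt_detecting", 1000))
}

# a one-row annotated target with a chosen protospacer and variant offset
toy_target <- function(protospacer_ref = "ACATGACGTACGTACGTACGT",
                       offset = 1L, alt_base = "T") {
  proto_alt <- protospacer_ref
  substr(proto_alt, offset, offset) <- alt_base
  data.frame(contig = "c1", pos1 = 5L,
             ref = substr(protospacer_ref, offset, offset), alt = alt_base,
             strand = "+", pam_start = 0L, offset = as.integer(offset),
             protospacer_ref = protospacer_ref, protospacer_alt = proto_alt,
             seed_gc = seedscan:::gc_fraction(substr(protospacer_ref, 1, 5)),
             spacer_gc = seedscan:::gc_fraction(protospacer_ref),
             cancer_associated = TRUE, n_candidate_pams = 1L,
             condition = "Malignant_melanoma", stringsAsFactors = FALSE)
}
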