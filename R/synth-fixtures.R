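#' Simulation configuration for synthetic fixtures
#'
#' Bundles every knob of the synthetic-data generators.  All generators are
#' deterministic given `rng_seed` and leave the caller's RNG state untouched.
#'
#' @param rng_seed Integer seed.
#' @param genome_len Genome length in bp.
#' @param base_probs Named probabilities for A, C, G, T (must sum to 1).
#' @param n_cassettes Number of `TTTV + 21-mer` cassettes planted at recorded
#'   positions (default 0).
#' @param n_common Number of simulated common/population variants.
#' @param af_law Function `n -> n allele frequencies`; the default draws
#'   uniformly on `[0, 0.05]`, straddling the 1% threshold.
#' @param n_pathogenic Number of simulated pathogenic SNVs (uniformly
#'   placed).
#' @param cancer_fraction Fraction of pathogenic SNVs given a
#'   keyword-bearing (cancer) condition name.
#' @param curve Fluorescence-curve parameters: `baseline` B (arbitrary
#'   units), `amplitude` A, `rate` k per minute (default 1/60, so a fully
#'   matched reaction reaches ~95% of its plateau at 3 h), `noise_sd`
#'   (default 5% of the amplitude), `specificity_fold` rho (fold reduction
#'   of the cleavage rate caused by a single-allele mismatch; default 6),
#'   `times` (sampling grid in minutes; default every 5 min for 3 h) and
#'   `replicates`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       genome_len = 100000L,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_cassettes = 0L,
                       n_common = 100L,
                       af_law = function(n) runif(n, 0, 0.05),
                       n_pathogenic = 200L,
                       cancer_fraction = 0.3,
                       curve = list()) {
  stopifnot(abs(sum(base_probs) - 1) < 1e-8, all(base_probs >= 0),
            cancer_fraction >= 0, cancer_fraction <= 1)
  curve_defaults <- list(baseline = 100, amplitude = 3000, rate = 1 / 60,
                         noise_sd = 150, specificity_fold = 6,
                         times = seq(0, 180, by = 5), replicates = 3L)
  curve <- utils::modifyList(curve_defaults, curve)
  stopifnot(curve$specificity_fold >= 1, curve$noise_sd >= 0)
  structure(list(rng_seed = as.integer(rng_seed),
                 genome_len = as.integer(genome_len),
                 base_probs = base_probs,
                 n_cassettes = as.integer(n_cassettes),
                 n_common = as.integer(n_common),
                 af_law = af_law,
                 n_pathogenic = as.integer(n_pathogenic),
                 cancer_fraction = cancer_fraction,
                 curve = curve),
            class = "sim_config")
}

# evaluate expr under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random genome, optionally with planted PAM cassettes
#'
#' Bases are drawn i.i.d. from `base_probs`.  Cassettes of the form
#' `TTT[ACG]` + random 21-mer are written over the sequence at recorded,
#' non-overlapping positions, each guaranteed to surface as a plus-strand
#' PAM site in a scan.
#'
#' @param config A [sim_config()].
#' @param contig_name Name of the single generated contig.
#' @return List with `genome` (named character vector) and `manifest`
#'   (data.frame `contig`, `pam_start` 0-based, `pam_seq`, `protospacer`;
#'   zero rows when no cassettes are planted).
#' @export
make_genome <- function(config = sim_config(), contig_name = "chrS") {
  with_seed(config$rng_seed, {
    L <- config$genome_len
    bases <- sample(names(config$base_probs), L, replace = TRUE,
                    prob = config$base_probs)
    manifest <- data.frame(contig = character(), pam_start = integer(),
                           pam_seq = character(), protospacer = character(),
                           stringsAsFactors = FALSE)
    if (config$n_cassettes > 0L) {
      cass_len <- 4L + 21L
      # non-overlapping slots on a fixed grid, away from the contig edges
      slots <- seq(1L, L - cass_len - 5L, by = cass_len + 5L)
      if (length(slots) < config$n_cassettes) {
        stop("genome too short to plant ", config$n_cassettes, " cassettes")
      }
      at <- sort(sample(slots, config$n_cassettes))
      pam_seqs <- character(config$n_cassettes)
      protos <- character(config$n_cassettes)
      for (i in seq_along(at)) {
        p <- at[i]
        pam <- c("T", "T", "T", sample(c("A", "C", "G"), 1L))
        proto <- sample(c("A", "C", "G", "T"), 21L, replace = TRUE)
        bases[p:(p + cass_len - 1L)] <- c(pam, proto)
        pam_seqs[i] <- paste(pam, collapse = "")
        protos[i] <- paste(proto, collapse = "")
      }
      manifest <- data.frame(contig = contig_name, pam_start = at - 1L,
                             pam_seq = pam_seqs, protospacer = protos,
                             stringsAsFactors = FALSE)
    }
    genome <- setNames(paste(bases, collapse = ""), contig_name)
    list(genome = genome, manifest = manifest)
  })
}

cancer_condition_names <- c(
  "Malignant_melanoma", "Hepatocellular_carcinoma",
  "Acute_myeloid_leukemia", "Pheochromocytoma", "Retinoblastoma",
  "Ewing_sarcoma", "Glioma_susceptibility", "Colorectal_cancer",
  "Neoplasm_of_ovary", "Wilms_tumor")

noncancer_condition_names <- c(
  "Cystic_fibrosis", "Phenylketonuria", "Marfan_syndrome",
  "Sickle_cell_disease", "Hereditary_hemochromatosis", "Wilson_disease")

#' Simulate common and pathogenic variant tables for a genome
#'
#' Common variants get allele frequencies drawn from `af_law` (straddling
#' the 1% threshold by default).  Pathogenic SNVs are placed uniformly at
#' random with `CLNSIG=Pathogenic` and condition names drawn so that about
#' `cancer_fraction` of them carry a cancer keyword.  The truth table
#' records, via the brute-force [oracle_scan()], which pathogenic SNVs fall
#' inside a Cas12a seed region.
#'
#' @param genome Named character vector of contig sequences.
#' @param config A [sim_config()].
#' @return List with `common`, `pathogenic` (variant data.frames in
#'   [read_vcf()] layout) and `truth` (pathogenic rows plus `in_seed` and
#'   `is_cancer`).
#' @export
make_vcfs <- function(genome, config = sim_config()) {
  with_seed(config$rng_seed + 1L, {
    contig <- names(genome)[1L]
    seq1 <- genome[[1L]]
    L <- nchar(seq1)
    usable <- which(strsplit(seq1, "")[[1L]] != "N")
    draw_snvs <- function(n) {
      if (n == 0L) {
        return(data.frame(contig = character(), pos1 = integer(),
                          ref = character(), alt = character(),
                          stringsAsFactors = FALSE))
      }
      pos1 <- sort(sample(usable, n, replace = FALSE))
      ref <- substring(seq1, pos1, pos1)
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                            1L), character(1),
                    USE.NAMES = FALSE)
      data.frame(contig = contig, pos1 = pos1, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    }
    common <- draw_snvs(config$n_common)
    common$af <- sprintf("%.6g", config$af_law(config$n_common))
    common$clnsig <- rep(NA_character_, nrow(common))
    common$condition <- rep(NA_character_, nrow(common))

    pathogenic <- draw_snvs(config$n_pathogenic)
    pathogenic$af <- rep(NA_character_, nrow(pathogenic))
    pathogenic$clnsig <- rep("Pathogenic", nrow(pathogenic))
    n_cancer <- round(config$cancer_fraction * config$n_pathogenic)
    is_cancer <- sample(rep(c(TRUE, FALSE),
                            c(n_cancer, config$n_pathogenic - n_cancer)))
    pathogenic$condition <- ifelse(
      is_cancer,
      sample(cancer_condition_names, config$n_pathogenic, replace = TRUE),
      sample(noncancer_condition_names, config$n_pathogenic, replace = TRUE))

    oracle <- oracle_scan(genome)
    cov <- oracle$coverage[[contig]]
    truth <- pathogenic
    truth$in_seed <- cov[truth$pos1]
    truth$is_cancer <- is_cancer
    list(common = common, pathogenic = pathogenic, truth = truth)
  })
}

#' Brute-force oracle scan for TTTV PAM sites and seed coverage
#'
#' A deliberately naive position-by-position enumeration, independent of the
#' production scanner: every window is tested for membership in
#' {TTTA, TTTC, TTTG} (plus strand) and {CAAA, GAAA, TAAA} (a TTTV PAM on
#' the reverse complement).  The same retention rules apply as in
#' [scan_contig()]: seeds running past a contig edge or containing N are
#' discarded.  Also returns a per-base boolean seed-coverage array per
#' contig.  Intended for genomes up to ~1 Mb.
#'
#' @param genome Named character vector of contig sequences.
#' @param seed_len Seed length (default 5).
#' @return List with `sites` (data.frame `contig`, `pam_start`, `strand`),
#'   `coverage` (named list of logical vectors) and `stats`
#'   (`n_raw`, `n_retained`, `n_edge_discarded`, `n_ambiguous_discarded`).
#' @export
oracle_scan <- function(genome, seed_len = 5L) {
  plus_set <- c("TTTA", "TTTC", "TTTG")
  minus_set <- c("CAAA", "GAAA", "TAAA")
  sites <- list()
  coverage <- list()
  n_raw <- n_edge <- n_ambig <- 0L
  for (nm in names(genome)) {
    seq1 <- genome[[nm]]
    L <- nchar(seq1)
    cov <- logical(L)
    if (L >= 4L) {
      w <- substring(seq1, 1:(L - 3L), 4:L)
      plus0 <- which(w %in% plus_set) - 1L   # 0-based PAM starts
      minus0 <- which(w %in% minus_set) - 1L
      n_raw <- n_raw + length(plus0) + length(minus0)

      p_edge <- plus0 + 4L + seed_len > L
      n_edge <- n_edge + sum(p_edge)
      plus0 <- plus0[!p_edge]
      if (length(plus0)) {
        p_seed <- substring(seq1, plus0 + 5L, plus0 + 4L + seed_len)
        p_ambig <- grepl("N", p_seed, fixed = TRUE)
        n_ambig <- n_ambig + sum(p_ambig)
        plus0 <- plus0[!p_ambig]
      }

      m_edge <- minus0 - seed_len < 0L
      n_edge <- n_edge + sum(m_edge)
      minus0 <- minus0[!m_edge]
      if (length(minus0)) {
        m_seed <- substring(seq1, minus0 - seed_len + 1L, minus0)
        m_ambig <- grepl("N", m_seed, fixed = TRUE)
        n_ambig <- n_ambig + sum(m_ambig)
        minus0 <- minus0[!m_ambig]
      }

      seed_start0 <- c(plus0 + 4L, minus0 - seed_len)
      if (length(seed_start0)) {
        idx <- rep(seed_start0, each = seed_len) +
          rep(seq_len(seed_len) - 1L, times = length(seed_start0))
        cov[idx + 1L] <- TRUE
      }
      sites[[nm]] <- data.frame(
        contig = rep(nm, length(plus0) + length(minus0)),
        pam_start = c(plus0, minus0),
        strand = rep(c("+", "-"), c(length(plus0), length(minus0))),
        stringsAsFactors = FALSE)
    } else {
      sites[[nm]] <- data.frame(contig = character(), pam_start = integer(),
                                strand = character(), stringsAsFactors = FALSE)
    }
    coverage[[nm]] <- cov
  }
  sites <- do.call(rbind, c(sites, list(make.row.names = FALSE)))
  sites <- sites[order(match(sites$contig, names(genome)), sites$pam_start,
                       sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  n_retained <- nrow(sites)
  list(sites = sites, coverage = coverage,
       stats = c(n_raw = n_raw, n_retained = n_retained,
                 n_edge_discarded = n_edge,
                 n_ambiguous_discarded = n_ambig))
}

#' Simulate a fluorescence plate with known genotypes
#'
#' Each sample is assayed with a mutant-detecting and a WT-detecting crRNA
#' in `replicates` replicate reactions.  Curves follow a saturating
#' exponential, `F(t) = B + A (1 - exp(-k_eff t)) + N(0, sigma)`, with the
#' effective rate scaled by the fraction of matched activator alleles: for
#' the mutant-detecting crRNA `k_eff = k (g + (1 - g)/rho)` and for the
#' WT-detecting crRNA `k_eff = k ((1 - g) + g/rho)`, where `g` is the
#' mutant-allele fraction and `rho` the single-mismatch specificity fold.
#' A water blank (amplitude 0) is always included.
#'
#' @param genotypes Genotypes of the samples: either a character vector
#'   drawn from `"hom_wt"`, `"het"`, `"hom_mut"` or a numeric vector of
#'   mutant-allele fractions in `[0, 1]`; names become sample labels
#'   (defaults `sample_1`, `sample_2`, ...).
#' @param config A [sim_config()]; curve parameters come from
#'   `config$curve`.
#' @return List with `curves` (long-format data.frame `sample`, `crrna`,
#'   `role`, `replicate`, `time_min`, `value`) and `truth` (`sample`,
#'   `mut_fraction`, `genotype`).
#' @export
simulate_plate <- function(genotypes, config = sim_config()) {
  g <- if (is.character(genotypes)) {
    map <- c(hom_wt = 0, het = 0.5, hom_mut = 1)
    if (!all(genotypes %in% names(map))) {
      stop("character genotypes must be hom_wt, het or hom_mut")
    }
    unname(map[genotypes])
  } else as.numeric(genotypes)
  stopifnot(all(g >= 0 & g <= 1))
  nm <- names(genotypes)
  if (is.null(nm)) nm <- paste0("sample_", seq_along(g))
  cv <- config$curve
  with_seed(config$rng_seed + 2L, {
    grid <- expand.grid(sample = nm, role = c("mutant_detecting",
                                              "wt_detecting"),
                        replicate = seq_len(cv$replicates),
                        stringsAsFactors = FALSE)
    gg <- g[match(grid$sample, nm)]
    k_eff <- ifelse(grid$role == "mutant_detecting",
                    cv$rate * (gg + (1 - gg) / cv$specificity_fold),
                    cv$rate * ((1 - gg) + gg / cv$specificity_fold))
    nt <- length(cv$times)
    n_curves <- nrow(grid)
    times <- rep(cv$times, times = n_curves)
    mean_val <- cv$baseline +
      cv$amplitude * (1 - exp(-rep(k_eff, each = nt) * times))
    curves <- data.frame(
      sample = rep(grid$sample, each = nt),
      crrna = rep(ifelse(grid$role == "mutant_detecting", "crMUT", "crWT"),
                  each = nt),
      role = rep(grid$role, each = nt),
      replicate = rep(grid$replicate, each = nt),
      time_min = times,
      value = mean_val + rnorm(length(times), 0, cv$noise_sd),
      stringsAsFactors = FALSE)
    blanks <- data.frame(
      sample = rep("water_blank", nt * cv$replicates),
      crrna = "none",
      role = "control",
      replicate = rep(seq_len(cv$replicates), each = nt),
      time_min = rep(cv$times, times = cv$replicates),
      value = cv$baseline + rnorm(nt * cv$replicates, 0, cv$noise_sd),
      stringsAsFactors = FALSE)
    genotype_label <- if (is.character(genotypes)) genotypes else
      ifelse(g == 0, "hom_wt",
             ifelse(g == 1, "hom_mut",
                    ifelse(g == 0.5, "het", "imbalanced")))
    list(curves = rbind(curves, blanks),
         truth = data.frame(sample = nm, mut_fraction = g,
                            genotype = genotype_label,
                            stringsAsFactors = FALSE))
  })
}
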