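#' crRNA design configuration
#'
#' @param sm_positions PAM+k positions at which synthetic mismatches may be
#'   placed (default `1:5`, the seed; extend to 6 explicitly if wanted).
#' @param spacer_len Spacer length in nt (default 21; vendor designs vary
#'   20-23).
#' @param seed_len Seed length in nt (default 5).
#' @return A list of class `design_config`.
#' @export
design_config <- function(sm_positions = 1:5, spacer_len = 21L,
                          seed_len = 5L) {
  sm_positions <- sort(unique(as.integer(sm_positions)))
  spacer_len <- as.integer(spacer_len)
  stopifnot(length(sm_positions) >= 0L, all(sm_positions >= 1L),
            all(sm_positions <= spacer_len))
  structure(list(sm_positions = sm_positions, spacer_len = spacer_len,
                 seed_len = as.integer(seed_len)),
            class = "design_config")
}

rna_complement <- function(x) chartr("ACGU", "UGCA", x)

transcribe <- function(dna) chartr("T", "U", toupper(dna))

#' Build a crRNA spacer for an annotated target
#'
#' The spacer is represented in protospacer sense: position k of the spacer
#' corresponds to target position PAM+k, and the spacer sequence equals the
#' protospacer of the detected allele transcribed T->U.  A mutant-detecting
#' spacer carries the alternate allele, a WT-detecting spacer the reference
#' allele; the two differ only at the variant offset.
#'
#' @param target One-row data.frame from [annotate_snvs()] targets (or a
#'   list with fields `protospacer_ref`, `protospacer_alt`, `offset`,
#'   `seed_gc`, `spacer_gc`).
#' @param detects `"mutant"` or `"wt"`.
#' @return One-row data.frame: `detects`, `spacer_rna`, `variant_offset`,
#'   `sm_position` (`NA`), `sm_base` (`NA`), `pair_type` (`"none"`),
#'   `disrupted_bond` (`"none"`), `in_seed` (`NA`), `distance_to_variant`
#'   (`NA`), `seed_gc`, `spacer_gc`.
#' @export
build_spacer <- function(target, detects = c("mutant", "wt")) {
  detects <- match.arg(detects)
  proto <- if (detects == "mutant") target$protospacer_alt else
    target$protospacer_ref
  data.frame(
    detects = detects,
    spacer_rna = transcribe(proto),
    variant_offset = as.integer(target$offset),
    sm_position = NA_integer_,
    sm_base = NA_character_,
    pair_type = "none",
    disrupted_bond = "none",
    in_seed = NA,
    distance_to_variant = NA_integer_,
    seed_gc = if (is.null(target$seed_gc)) NA_real_ else target$seed_gc,
    spacer_gc = if (is.null(target$spacer_gc)) NA_real_ else target$spacer_gc,
    stringsAsFactors = FALSE
  )
}

#' Introduce a synthetic mismatch into a spacer
#'
#' Replaces the spacer base at PAM+k with its Watson-Crick RNA complement
#' (A<->U, C<->G).  Because the spacer base equals the transcribed
#' protospacer base, this single substitution rule yields, for protospacer
#' base X at position k: X = C -> rG against dG (G-G homopair), X = G ->
#' rC against dC (C-C), X = T -> rA against dA (A-A), X = A -> rU against dT
#' (U-T) -- exactly the homopair / U-T mismatch geometries that avoid
#' stabilizing wobble pairs (rG-dT, rU-dG), which would be better tolerated
#' and blunt the mismatch's discriminating effect.  A G-C base pair of the
#' original duplex is disrupted when X is G or C, an A-T pair otherwise.
#'
#' @param design One-row spacer data.frame from [build_spacer()].
#' @param k SM position (PAM+k); must differ from the variant offset.
#' @param config A [design_config()].
#' @return The modified one-row design data.frame with `sm_position`,
#'   `sm_base`, `pair_type` (one of `"G.G"`, `"C.C"`, `"A.A"`, `"U.T"`),
#'   `disrupted_bond` (`"G-C"` or `"A-T"`), `in_seed` and
#'   `distance_to_variant` filled in.
#' @export
apply_sm <- function(design, k, config = design_config()) {
  k <- as.integer(k)
  if (!is.na(design$sm_position)) {
    stop("invalid design: spacer already carries a synthetic mismatch at ",
         "PAM+", design$sm_position,
         " (at most two mismatches against the off-target allele: the ",
         "allele mismatch plus one SM)")
  }
  if (k == design$variant_offset) {
    stop("invalid design: synthetic mismatch position equals the variant ",
         "offset (PAM+", k, ")")
  }
  if (k < 1L || k > nchar(design$spacer_rna)) {
    stop("synthetic mismatch position out of spacer range: ", k)
  }
  base <- substr(design$spacer_rna, k, k)  # transcribed protospacer base
  sm <- rna_complement(base)
  spacer <- design$spacer_rna
  substr(spacer, k, k) <- sm
  # the SM base faces the displaced-strand base, i.e. the complement of the
  # protospacer base; pair written crRNA-base . DNA-base
  x <- chartr("U", "T", base)
  pair <- c(C = "G.G", G = "C.C", T = "A.A", A = "U.T")[[x]]
  out <- design
  out$spacer_rna <- spacer
  out$sm_position <- k
  out$sm_base <- sm
  out$pair_type <- pair
  out$disrupted_bond <- if (x %in% c("G", "C")) "G-C" else "A-T"
  out$in_seed <- k <= config$seed_len
  out$distance_to_variant <- abs(k - design$variant_offset)
  out
}

#' Enumerate ranked mutant/WT spacer design pairs for a target
#'
#' Produces the no-SM pair plus one mutant+WT pair per allowed SM position
#' (positions equal to the variant offset are excluded, so the mutant spacer
#' never carries more than two mismatches against the off-target allele: the
#' allele mismatch plus one SM).  SM pairs are ranked by a documented
#' heuristic assembled from qualitative mismatch-tolerance behaviour: SMs
#' inside the seed first, G-C bond disruption before A-T, then increasing
#' distance to the variant, then position.  The ranking is a design aid, not
#' a validated activity score.
#'
#' @param target One-row target data.frame from [annotate_snvs()].
#' @param config A [design_config()].
#' @return Data.frame with two rows (mutant, wt) per pair; columns as in
#'   [apply_sm()] plus `pair_rank` (0 = no-SM baseline, then 1, 2, ...) and
#'   `rationale`.
#' @export
enumerate_designs <- function(target, config = design_config()) {
  base_mut <- build_spacer(target, "mutant")
  base_wt <- build_spacer(target, "wt")
  positions <- setdiff(config$sm_positions, as.integer(target$offset))
  base_mut$pair_rank <- 0L
  base_wt$pair_rank <- 0L
  base_mut$rationale <- base_wt$rationale <- "no synthetic mismatch (baseline)"
  if (length(positions) == 0L) {
    warning("no allowed synthetic-mismatch positions; ",
            "returning the no-SM pair only")
    out <- rbind(base_mut, base_wt)
    rownames(out) <- NULL
    return(out)
  }
  sm_mut <- lapply(positions, function(k) apply_sm(base_mut, k, config))
  sm_wt <- lapply(positions, function(k) apply_sm(base_wt, k, config))
  key <- data.frame(
    k = positions,
    in_seed = vapply(sm_mut, `[[`, logical(1), "in_seed"),
    gc_bond = vapply(sm_mut, `[[`, character(1), "disrupted_bond") == "G-C",
    dist = vapply(sm_mut, `[[`, integer(1), "distance_to_variant")
  )
  ord <- order(!key$in_seed, !key$gc_bond, key$dist, key$k)
  pieces <- lapply(seq_along(ord), function(r) {
    i <- ord[r]
    m <- sm_mut[[i]]; w <- sm_wt[[i]]
    m$pair_rank <- w$pair_rank <- r
    m$rationale <- w$rationale <- sprintf(
      "SM at PAM+%d (%s): %s seed, disrupts %s, distance %d to variant",
      key$k[i], m$pair_type, if (key$in_seed[i]) "inside" else "outside",
      m$disrupted_bond, key$dist[i])
    rbind(m, w)
  })
  out <- do.call(rbind, c(list(rbind(base_mut, base_wt)), pieces))
  rownames(out) <- NULL
  out
}
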