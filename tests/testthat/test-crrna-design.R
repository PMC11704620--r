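test_that("spacers are transcribed protospacers and allele pairs differ at the offset", {
  tg <- toy_target("ACGTTACGTACGTACGTACGT", offset = 1L, alt_base = "T")
  wt <- build_spacer(tg, "wt")
  mut <- build_spacer(tg, "mutant")
  expect_equal(wt$spacer_rna, "ACGUUACGUACGUACGUACGU")
  expect_false(grepl("T", mut$spacer_rna))
  a <- strsplit(wt$spacer_rna, "")[[1]]
  b <- strsplit(mut$spacer_rna, "")[[1]]
  expect_identical(which(a != b), 1L)
})

test_that("synthetic mismatches form homopairs or U-T, disrupting the right bond", {
  # protospacer base C at PAM+2 -> rG against dG, disrupts G-C
  tg <- toy_target("ACATGACGTACGTACGTACGT", offset = 1L)
  d <- apply_sm(build_spacer(tg, "mutant"), 2L)
  expect_equal(d$sm_base, "G")
  expect_equal(d$pair_type, "G.G")
  expect_equal(d$disrupted_bond, "G-C")
  expect_true(d$in_seed)
  expect_equal(d$distance_to_variant, 1L)

  # protospacer base A at PAM+4 -> rU against dT, disrupts A-T
  tg2 <- toy_target("GCCATACGTACGTACGTACGT", offset = 1L)
  d2 <- apply_sm(build_spacer(tg2, "mutant"), 4L)
  expect_equal(d2$sm_base, "U")
  expect_equal(d2$pair_type, "U.T")
  expect_equal(d2$disrupted_bond, "A-T")
})

test_that("SM substitution is exhaustively wobble-free and involutive", {
  for (x in c("A", "C", "G", "T")) {
    proto <- paste0("G", strrep(x, 20))
    tg <- toy_target(proto, offset = 1L)
    base <- build_spacer(tg, "mutant")
    for (k in 2:21) {
      d <- apply_sm(base, k)
      expect_true(d$pair_type %in% c("G.G", "C.C", "A.A", "U.T"))
      # displaced-strand partner is the DNA complement of protospacer base x
      partner <- chartr("ACGT", "TGCA", x)
      expect_false(d$sm_base == "G" && partner == "T")  # no rG.dT
      expect_false(d$sm_base == "U" && partner == "G")  # no rU.dG
      # applying the complement substitution twice restores the spacer
      twice <- d
      substr(twice$spacer_rna, k, k) <-
        seedscan:::rna_complement(substr(twice$spacer_rna, k, k))
      expect_equal(twice$spacer_rna, base$spacer_rna)
    }
  }
})

test_that("an SM can never sit on the variant position or stack with another", {
  tg <- toy_target(offset = 3L)
  expect_error(apply_sm(build_spacer(tg, "mutant"), 3L), "variant")
  expect_error(apply_sm(build_spacer(tg, "mutant"), 25L), "range")
  one_sm <- apply_sm(build_spacer(tg, "mutant"), 2L)
  expect_error(apply_sm(one_sm, 4L), "already carries")
})

test_that("design enumeration ranks G-C disruption first, then distance", {
  # variant at PAM+1; seed bases +2..+5 are C, A, T, G
  tg <- toy_target("ACATGACGTACGTACGTACGT", offset = 1L)
  d <- enumerate_designs(tg)
  expect_equal(nrow(d), 10L)  # no-SM pair + 4 SM pairs, mutant + wt each
  mut <- d[d$detects == "mutant", ]
  expect_equal(mut$pair_rank, 0:4)
  expect_equal(mut$sm_position, c(NA, 2L, 5L, 3L, 4L))
  expect_equal(mut$pair_type, c("none", "G.G", "C.C", "U.T", "A.A"))
  # mutant and wt partners of a pair share the SM annotation
  wt <- d[d$detects == "wt", ]
  expect_equal(wt$sm_position, mut$sm_position)
  expect_equal(wt$pair_type, mut$pair_type)
})

test_that("the variant offset is excluded from the enumerated positions", {
  tg <- toy_target(offset = 3L)
  d <- enumerate_designs(tg)
  expect_setequal(d$sm_position[!is.na(d$sm_position)], c(1L, 2L, 4L, 5L))
})

test_that("an all-A seed ranks purely by distance with U-T pairs", {
  tg <- toy_target("GAAAAACGTACGTACGTACGT", offset = 1L)
  d <- enumerate_designs(tg)
  mut <- d[d$detects == "mutant" & !is.na(d$sm_position), ]
  expect_true(all(mut$pair_type == "U.T"))
  expect_equal(mut$sm_position, 2:5)  # increasing distance to the variant
})

test_that("with no allowed positions only the baseline pair is returned", {
  tg <- toy_target(offset = 1L)
  expect_warning(
    d <- enumerate_designs(tg, design_config(sm_positions = 1L)),
    "no allowed")
  expect_equal(nrow(d), 2L)
  expect_true(all(is.na(d$sm_position)))
})

test_that("PAM+6 positions are enumerated only when configured, out-of-seed last", {
  tg <- toy_target("ACATGACGTACGTACGTACGT", offset = 1L)
  d <- enumerate_designs(tg, design_config(sm_positions = 1:6))
  mut <- d[d$detects == "mutant" & !is.na(d$sm_position), ]
  expect_equal(max(mut$pair_rank), 5L)
  expect_equal(mut$sm_position[mut$pair_rank == 5L], 6L)
  expect_false(mut$in_seed[mut$pair_rank == 5L])
})
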