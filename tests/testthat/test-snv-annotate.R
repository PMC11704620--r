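pathogenic_df <- function(pos1, ref, alt, clnsig = "Pathogenic",
                          condition = NA_character_, contig = "c1") {
  data.frame(contig = contig, pos1 = pos1, ref = ref, alt = alt,
             af = NA_character_, clnsig = clnsig, condition = condition,
             stringsAsFactors = FALSE)
}

test_that("pathogenic selection requires the exact token and a 1-bp allele pair", {
  v <- rbind(pathogenic_df(3, "A", "T"),
             pathogenic_df(4, "A", "T", clnsig = "Likely_pathogenic"),
             pathogenic_df(5, "AT", "A"),
             pathogenic_df(6, "G", "C", clnsig = "Pathogenic|risk_factor"),
             pathogenic_df(7, "G", "C", clnsig = "pathogenic"))
  sel <- select_pathogenic_snvs(v)
  expect_equal(sel$pos1, c(3L, 6L))
  # case-insensitive mode is available but off by default
  expect_equal(select_pathogenic_snvs(v, ignore_case = TRUE)$pos1,
               c(3L, 6L, 7L))
  # multi-alt with one qualifying 1-bp alt still qualifies
  expect_equal(nrow(select_pathogenic_snvs(pathogenic_df(9, "A", "AT,G"))),
               1L)
})

test_that("PAM-relative offsets follow strand arithmetic and the seed bounds", {
  plus <- data.frame(pam_start = 0L, pam_end = 4L, strand = "+")
  expect_equal(offset_from_pam(plus, 4L), 1L)
  expect_equal(offset_from_pam(plus, 8L), 5L)
  expect_true(is.na(offset_from_pam(plus, 9L)))
  minus <- data.frame(pam_start = 5L, pam_end = 9L, strand = "-")
  expect_equal(offset_from_pam(minus, 4L), 1L)
  expect_equal(offset_from_pam(minus, 0L), 5L)
  expect_true(is.na(offset_from_pam(minus, 5L)))
})

test_that("a seed SNV is annotated with protospacers differing at the offset", {
  g <- c(c1 = "TTTACGTACGTACGTACGTACGTACG")
  sites <- scan_genome(g)$sites
  v <- pathogenic_df(5, "C", "T", condition = "Malignant_melanoma")
  ann <- annotate_snvs(v, sites, g)
  t1 <- ann$targets
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$offset, 1L)
  expect_true(t1$cancer_associated)
  expect_equal(t1$strand, "+")
  expect_equal(t1$protospacer_ref, substr(g[[1]], 5, 25))
  expect_equal(substr(t1$protospacer_alt, 1, 1), "T")
  expect_equal(substr(t1$protospacer_alt, 2, 21),
               substr(t1$protospacer_ref, 2, 21))
})

test_that("minus-strand targets substitute the complement of the VCF alt", {
  # GCGCG TAAA ...: minus PAM at [5,9), seed [0,5) = revcomp(GCGCG)
  g <- c(c1 = paste0(strrep("ACGTG", 5), "GCGCGTAAA"))
  sites <- scan_genome(g)$sites
  m <- sites[sites$strand == "-" & sites$pam_start == 30L, , drop = FALSE]
  expect_equal(nrow(m), 1L)
  v <- pathogenic_df(28, substr(g[[1]], 28, 28), "A")
  ann <- annotate_snvs(v, m, g)
  expect_equal(nrow(ann$targets), 1L)
  off <- ann$targets$offset
  expect_equal(off, 3L)  # pam_start 30 - pos0 27
  expect_equal(substr(ann$targets$protospacer_alt, off, off), "T")  # comp of A
  expect_equal(ann$targets$protospacer_ref,
               seedscan:::revcomp(substr(g[[1]], 10, 30)))
})

test_that("cancer keywords match as case-insensitive substrings", {
  g <- c(c1 = "TTTACGTACGTACGTACGTACGTACG")
  sites <- scan_genome(g)$sites
  ann <- function(cond) {
    annotate_snvs(pathogenic_df(5, "C", "T", condition = cond),
                  sites, g)$targets$cancer_associated
  }
  expect_false(ann("Cystic_fibrosis"))
  expect_true(ann("Pheochromocytoma"))  # via substring "cytoma"
  expect_true(ann("MALIGNANT_MELANOMA"))
})

test_that("nearest PAM wins by minimal offset among candidate seeds", {
  # plus PAMs at [0,4) and [4,8): their seeds [4,9) and [8,13) both contain
  # pos0 8, at offsets 5 and 1 respectively
  g <- c(c1 = paste0("TTTATTTA", strrep("CGTAC", 5)))
  sites <- scan_genome(g)$sites
  expect_true(all(c(0L, 4L) %in% sites$pam_start))
  v <- pathogenic_df(9, substr(g[[1]], 9, 9), "T")
  ann <- annotate_snvs(v, sites, g)
  expect_equal(ann$targets$pam_start, 4L)
  expect_equal(ann$targets$offset, 1L)
  expect_equal(ann$targets$n_candidate_pams, 2L)
})

test_that("variants whose every candidate protospacer leaves the contig are skipped", {
  g <- c(c1 = "TTTACGTACGT")  # seed fits, 21-nt protospacer does not
  sites <- scan_genome(g)$sites
  expect_equal(nrow(sites), 1L)
  ann <- annotate_snvs(pathogenic_df(5, "C", "T"), sites, g)
  expect_equal(nrow(ann$targets), 0L)
  expect_equal(ann$skipped$reason, "protospacer_out_of_bounds")
})

test_that("multi-alt records yield one target per qualifying alt", {
  g <- c(c1 = "TTTACGTACGTACGTACGTACGTACG")
  sites <- scan_genome(g)$sites
  ann <- annotate_snvs(pathogenic_df(5, "C", "T,G"), sites, g)
  expect_equal(nrow(ann$targets), 2L)
  expect_setequal(ann$targets$alt, c("T", "G"))
})

test_that("emitted offsets stay in the seed and protospacer pairs differ only there", {
  g <- random_genome(30000, gc = 0.5, seed = 21)
  sites <- scan_genome(g)$sites
  set.seed(22)
  pos <- sample(nchar(g[[1]]) - 50, 400) + 25
  ref <- substring(g[[1]], pos, pos)
  keep <- ref != "N"
  alt <- vapply(ref[keep],
                function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  v <- pathogenic_df(pos[keep], ref[keep], alt)
  ann <- annotate_snvs(v, sites, g)
  tt <- ann$targets
  expect_gt(nrow(tt), 0)
  expect_true(all(tt$offset >= 1 & tt$offset <= 5))
  for (i in seq_len(nrow(tt))) {
    a <- strsplit(tt$protospacer_ref[i], "")[[1]]
    b <- strsplit(tt$protospacer_alt[i], "")[[1]]
    expect_identical(which(a != b), as.integer(tt$offset[i]))
  }
})

test_that("summaries report the in-seed fraction to one decimal percent", {
  fake <- function(n, n_cancer = 0) {
    data.frame(contig = "c1", pos1 = seq_len(n), ref = "A", alt = "T",
               cancer_associated = seq_len(n) <= n_cancer,
               stringsAsFactors = FALSE)
  }
  merged <- list(genome_fraction = 0.1)
  s <- summarize_targets(fake(6243), merged, 50987L)
  expect_equal(s$pct_in_seed, "12.2%")
  s2 <- summarize_targets(fake(10, 4), merged, 40L)
  expect_equal(s2$pct_in_seed, "25.0%")
  expect_equal(s2$n_cancer_associated, 4L)
  s3 <- summarize_targets(fake(0), merged, 0L)
  expect_true(s3$empty_input)
  expect_true(is.na(s3$frac_in_seed))
})
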