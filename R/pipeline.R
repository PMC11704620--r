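#' Run the full seed-region targeting pipeline
#'
#' Chains the stages scan -> mask -> merge -> annotate -> design over a
#' reference genome and variant files, writing standard BED/TSV artifacts
#' plus a stats table.  The pipeline is deterministic: rerunning with the
#' same inputs reproduces byte-identical outputs.
#'
#' @param fasta Path to the reference genome FASTA.
#' @param common_vcf Path to a common-variant VCF with allele frequencies,
#'   or `NULL` to skip masking.
#' @param pathogenic_vcf Path to a pathogenic-variant VCF with
#'   clinical-significance annotations, or `NULL` to stop after merging.
#' @param out_dir Output directory (created if needed).
#' @param af_threshold Common-variant allele-frequency threshold
#'   (default 0.01).
#' @param config A [scan_config()].
#' @param design_cfg A [design_config()] for the crRNA stage.
#' @param keywords Cancer keyword list (default [cancer_keywords()]).
#' @param significance_token Clinical-significance token to require
#'   (default `"Pathogenic"`).
#' @param af_key,clnsig_key,condition_key INFO keys for [read_vcf()].
#' @param max_design_targets Cap on the number of targets taken through
#'   spacer design (default 1000; the full target table is always written).
#' @return Invisibly, a list with all intermediate objects (`sites`,
#'   `scan_stats`, `mask`, `merged`, `targets`, `skipped`, `designs`,
#'   `stats`) and the output paths.
#' @export
run_pipeline <- function(fasta, common_vcf = NULL, pathogenic_vcf = NULL,
                         out_dir = ".", af_threshold = 0.01,
                         config = scan_config(),
                         design_cfg = design_config(),
                         keywords = cancer_keywords(),
                         significance_token = "Pathogenic",
                         af_key = "AF", clnsig_key = "CLNSIG",
                         condition_key = "CLNDN",
                         max_design_targets = 1000L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  genome <- stage("read_fasta", read_fasta(fasta))
  lens <- contig_lengths(genome)

  scan <- stage("scan", scan_genome(genome, config))
  sites <- scan$sites
  write_bed(data.frame(contig = sites$contig, start = sites$pam_start,
                       end = sites$pam_end, name = sites$pam_seq,
                       score = ".", strand = sites$strand),
            p("pam.bed"))
  write_bed(data.frame(contig = sites$contig, start = sites$seed_start,
                       end = sites$seed_end, name = sites$seed_seq,
                       score = ".", strand = sites$strand),
            p("seed.bed"))

  mask <- if (!is.null(common_vcf)) {
    common <- stage("read_common_vcf",
                    read_vcf(common_vcf, af_key = af_key,
                             clnsig_key = clnsig_key,
                             condition_key = condition_key))
    stage("mask", mask_pams(sites, common, af_threshold))
  } else {
    list(retained = sites, excluded = sites[0L, , drop = FALSE],
         af_threshold = af_threshold)
  }
  retained <- mask$retained
  write_bed(data.frame(contig = retained$contig, start = retained$pam_start,
                       end = retained$pam_end, name = retained$pam_seq,
                       score = ".", strand = retained$strand),
            p("retained.bed"))
  if (nrow(mask$excluded) > 0L) {
    write_bed(data.frame(contig = mask$excluded$contig,
                         start = mask$excluded$pam_start,
                         end = mask$excluded$pam_end,
                         name = mask$excluded$pam_seq, score = ".",
                         strand = mask$excluded$strand),
              p("excluded.bed"))
  }

  merged <- stage("merge", merge_seeds(retained, lens))
  write_bed(merged$intervals, p("merged.bed"))

  targets <- skipped <- designs <- NULL
  n_pathogenic <- NA_integer_
  summary_stats <- NULL
  if (!is.null(pathogenic_vcf)) {
    clin <- stage("read_pathogenic_vcf",
                  read_vcf(pathogenic_vcf, af_key = af_key,
                           clnsig_key = clnsig_key,
                           condition_key = condition_key))
    snvs <- stage("select_pathogenic",
                  select_pathogenic_snvs(clin, significance_token))
    n_pathogenic <- nrow(snvs)
    ann <- stage("annotate", annotate_snvs(snvs, retained, genome, config,
                                           keywords))
    targets <- ann$targets
    skipped <- ann$skipped
    write_tsv(targets, p("targets.tsv"))
    write_tsv(skipped, p("skipped.tsv"))
    summary_stats <- summarize_targets(targets, merged, n_pathogenic)

    design_rows <- utils::head(seq_len(nrow(targets)), max_design_targets)
    designs <- stage("design", {
      if (length(design_rows) == 0L) NULL else {
        do.call(rbind, lapply(design_rows, function(i) {
          d <- enumerate_designs(targets[i, , drop = FALSE], design_cfg)
          d$target_contig <- targets$contig[i]
          d$target_pos1 <- targets$pos1[i]
          d$target_alt <- targets$alt[i]
          d
        }))
      }
    })
    if (!is.null(designs)) write_tsv(designs, p("designs.tsv"))
  }

  stats <- data.frame(
    key = c("n_raw_pams", "n_retained_pams", "n_edge_discarded",
            "n_ambiguous_discarded", "n_excluded", "n_merged_regions",
            "total_bp", "genome_fraction", "n_pathogenic", "n_in_seed",
            "n_cancer"),
    value = c(scan$stats[["n_raw"]], scan$stats[["n_retained"]],
              scan$stats[["n_edge_discarded"]],
              scan$stats[["n_ambiguous_discarded"]],
              nrow(mask$excluded), merged$n_regions, merged$total_bp,
              signif(merged$genome_fraction, 6), n_pathogenic,
              if (is.null(summary_stats)) NA else summary_stats$n_in_seed,
              if (is.null(summary_stats)) NA else
                summary_stats$n_cancer_associated),
    stringsAsFactors = FALSE)
  write_tsv(stats, p("stats.tsv"))

  invisible(list(genome = genome, sites = sites, scan_stats = scan$stats,
                 mask = mask, merged = merged, targets = targets,
                 skipped = skipped, designs = designs, stats = stats,
                 summary = summary_stats, out_dir = out_dir))
}
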