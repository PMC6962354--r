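#' Run the full synthetic end-to-end demonstration pipeline
#'
#' Generates every synthetic input at the given seed, runs each analysis
#' stage on it — coverage enrichment, assembly evaluation, SV
#' harmonization with filters, novelty classification, size spectrum,
#' superpopulation frequencies and repeat landscapes — and writes a
#' single JSON report embedding the resolved configuration. Identical
#' seed and configuration give byte-identical reports.
#'
#' @param seed master integer seed.
#' @param out_dir directory for the data files and `report.json`;
#'   created if needed.
#' @param config optional [sim_config()]; defaults to `sim_config(seed)`
#'   with a reduced read total so the demo runs in seconds.
#' @param overlap_threshold,ins_window,min_sv_length,min_ac analysis
#'   thresholds (defaults: 0.4 overlap, 500 bp insertion window, 50 bp
#'   minimum SV size, allele count > 2).
#' @return invisibly, the report list.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("chromsort_demo"),
                     config = NULL, overlap_threshold = 0.4,
                     ins_window = 500, min_sv_length = 50, min_ac = 2) {
  if (is.null(config))
    config <- sim_config(seed = seed, total_mapped_bases = 2e7,
                         n_true_svs = 400, n_samples = 250)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("simulate: writing synthetic bundle to ", out_dir)
  sim <- write_synthetic_bundle(config, out_dir)

  # enrich
  records <- read_paf(file.path(out_dir, "mappings.paf"))
  summ <- summarize_mappings(records, config$genome)
  enr <- enrichment_folds(summ, config$genome, config$target_chrom)
  message(sprintf("enrich: %d records in, fold(%s) = %.3f",
                  nrow(records), config$target_chrom, enr$fold_target))

  # asm-stats on a simulated assembly of the target chromosome
  tlen <- config$genome$chromosomes$length[
    config$genome$chromosomes$name == config$target_chrom]
  feat <- data.frame(chrom = "ref",
                     start = round(tlen * c(0.45, 0.80)),
                     end = round(tlen * c(0.55, 0.84)))
  asm <- gen_contigs(tlen, n_breakpoints = 40, features = feat,
                     feature_weight = 0.7,
                     seed = child_seed(seed, "contigs"))
  mc <- mutual_coverage(asm$blocks, asm$contig_lengths, tlen)
  bft <- boundary_feature_test(asm$blocks, feat, window = round(tlen * 0.002),
                               n_perm = 200, seed = child_seed(seed, "perm"))
  message(sprintf("asm-stats: %d contigs, N50 %.0f",
                  length(asm$contig_lengths),
                  nx_statistic(asm$contig_lengths, 50)))

  # sv-merge
  zones <- exclusion_zones(config$genome, config$exclusion_flank)
  A <- filter_calls(read_assemblytics_bed(file.path(out_dir, "callset_a.bed")),
                    zones, require_precise = FALSE,
                    min_length = min_sv_length)
  B <- filter_calls(read_sv_vcf(file.path(out_dir, "callset_b.vcf")),
                    zones, require_precise = TRUE,
                    min_length = min_sv_length)
  message(sprintf("sv-merge: %d/%d calls after filters", nrow(A), nrow(B)))
  isec <- intersect_callsets(A, B, threshold = overlap_threshold,
                             ins_window = ins_window)
  spec <- size_spectrum(rbind(A, B), bin_width = 50, range = c(0, 2000))
  novel <- classify_novel(A, list(caller_b = B),
                          threshold = overlap_threshold,
                          ins_window = ins_window)

  # popfreq
  tab <- read_genotype_vcf(file.path(out_dir, "population.vcf"),
                           file.path(out_dir, "sample_map.tsv"))
  tab_f <- filter_variants(tab, min_ac = min_ac, biallelic_only = TRUE)
  freqs <- superpop_frequencies(tab_f)
  message(sprintf("popfreq: %d of %d variants pass filters",
                  nrow(tab_f$variants), nrow(tab$variants)))

  # landscape
  hits <- read_repeat_tsv(file.path(out_dir, "repeats.tsv"))
  land <- build_landscape(hits, sim$repeats$denominator_bp)
  cmp <- compare_landscapes(land, land)

  report <- list(
    config = list(seed = seed, target_chrom = config$target_chrom,
                  total_mapped_bases = config$total_mapped_bases,
                  n_true_svs = config$n_true_svs,
                  n_samples = config$n_samples,
                  overlap_threshold = overlap_threshold,
                  ins_window = ins_window, min_sv_length = min_sv_length,
                  min_ac = min_ac,
                  exclusion_flank = config$exclusion_flank),
    enrichment = list(
      fold_target = enr$fold_target,
      fold_truth = sim$mappings$truth$fold_real,
      on_target_fraction = enr$on_target_fraction,
      mean_offtarget_fold = enr$mean_offtarget_fold),
    assembly = list(
      n_contigs = length(asm$contig_lengths),
      n50 = nx_statistic(asm$contig_lengths, 50),
      query_covered_fraction = unname(mc["query_covered_fraction"]),
      target_covered_fraction = unname(mc["target_covered_fraction"]),
      boundary_observed_near = bft$observed_fraction_near,
      boundary_empirical_p = bft$empirical_p),
    sv = list(
      n_a = nrow(A), n_b = nrow(B), n_matches = nrow(isec$matches),
      pct_unique_a = isec$pct_unique_a, pct_unique_b = isec$pct_unique_b,
      n_novel_a_vs_b = novel$n_novel,
      modal_size_bin_center = spec$modal_bin_center_overall,
      del_ins_ratio = spec$del_ins_ratio),
    popfreq = stats::setNames(as.list(freqs$summary$mean_af_pct),
                              freqs$summary$superpop),
    landscape = list(
      total_annotated = sum(land$matrix),
      cosine_self = cmp$cosine_similarity))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
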