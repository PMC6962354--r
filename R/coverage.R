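#' Summarize mapping records into per-chromosome coverage
#'
#' Accumulates aligned bases per chromosome from primary alignments at or
#' above a mapping-quality threshold. Aligned bases are counted as the
#' target span (`end - start`) of each record — the "Gb mapped" style of
#' accounting — rather than column-matched bases, which keeps the result
#' comparable between PAF and CIGAR-derived inputs.
#'
#' @param records mapping-record data.frame (see [read_paf()]).
#' @param model a [genome_model()]; every record's chromosome must be in
#'   the model.
#' @param min_mapq minimum mapping quality (default 0, i.e. no filter).
#' @return a `coverage_summary`: list with `per_chrom` (data.frame
#'   `chrom`, `length`, `copy_number`, `aligned_bases`, `mean_depth`,
#'   `observed_fraction`) and `totals` (`total_reads`,
#'   `total_read_bases`, `total_aligned_bases`).
#' @export
summarize_mappings <- function(records, model, min_mapq = 0) {
  stopifnot(inherits(model, "genome_model"))
  df <- model$chromosomes
  unknown <- setdiff(unique(records$chrom), df$name)
  if (length(unknown)) {
    bad <- records$read_id[match(unknown[1], records$chrom)]
    stop("record ", bad, " maps to unknown chromosome ", unknown[1])
  }
  use <- records$is_primary & records$mapq >= min_mapq
  span <- records$end[use] - records$start[use]
  if (any(span <= 0) || any(records$start[use] < 0))
    stop("malformed mapping span (need 0 <= start < end)")
  too_long <- records$end[use] > df$length[match(records$chrom[use], df$name)]
  if (any(too_long))
    stop("record ", records$read_id[use][which(too_long)[1]],
         " extends past the end of ", records$chrom[use][which(too_long)[1]])
  aligned <- vapply(df$name, function(ch)
    sum(span[records$chrom[use] == ch]), numeric(1))
  total_aligned <- sum(aligned)
  per_chrom <- data.frame(
    chrom = df$name, length = df$length, copy_number = df$copy_number,
    aligned_bases = unname(aligned),
    mean_depth = unname(aligned / df$length),
    observed_fraction = if (total_aligned > 0) unname(aligned / total_aligned)
                        else rep(0, nrow(df)),
    stringsAsFactors = FALSE)
  structure(list(
    per_chrom = per_chrom,
    totals = list(total_reads = length(unique(records$read_id)),
                  total_read_bases = sum(records$read_length[!duplicated(records$read_id)]),
                  total_aligned_bases = total_aligned)),
    class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage_summary: %d reads, %.4g aligned bases on %d chromosomes\n",
              x$totals$total_reads, x$totals$total_aligned_bases,
              sum(x$per_chrom$aligned_bases > 0)))
  invisible(x)
}

#' Per-chromosome enrichment/depletion folds against the sampling null
#'
#' The fold on a chromosome is its observed fraction of aligned bases
#' divided by its expected fraction under random sampling from the genome
#' (length x copy-number weighting). A fold of 1 means no enrichment;
#' the target chromosome of a flow-sorting experiment is expected to be
#' enriched (fold > 1) and all others depleted (fold < 1).
#'
#' @param summary a `coverage_summary` from [summarize_mappings()].
#' @param model the [genome_model()] defining the null.
#' @param target target chromosome name.
#' @return an `enrichment_report`: list with `per_chrom` (data.frame
#'   adding `expected_fraction` and `fold`), `target_chrom`,
#'   `on_target_fraction`, `fold_target`, `mean_offtarget_fold`
#'   (unweighted chromosome mean) and `weighted_offtarget_fold`
#'   (aligned-base weighted).
#' @export
enrichment_folds <- function(summary, model, target) {
  stopifnot(inherits(summary, "coverage_summary"),
            inherits(model, "genome_model"))
  if (summary$totals$total_aligned_bases <= 0)
    stop("no aligned bases: enrichment undefined")
  if (!target %in% model$chromosomes$name)
    stop("target chromosome ", target, " not in genome model")
  pc <- summary$per_chrom
  exp_fr <- expected_fractions(model)[pc$chrom]
  fold <- ifelse(exp_fr > 0, pc$observed_fraction / exp_fr,
                 ifelse(pc$observed_fraction > 0, Inf, NA_real_))
  if (any(is.infinite(fold)))
    warning("observed bases on chromosome(s) with zero expected fraction: ",
            paste(pc$chrom[is.infinite(fold)], collapse = ", "))
  pc$expected_fraction <- unname(exp_fr)
  pc$fold <- unname(fold)
  off <- pc$chrom != target & pc$copy_number > 0
  structure(list(
    per_chrom = pc,
    target_chrom = target,
    on_target_fraction = pc$observed_fraction[pc$chrom == target],
    fold_target = pc$fold[pc$chrom == target],
    mean_offtarget_fold = mean(pc$fold[off]),
    weighted_offtarget_fold = sum(pc$observed_fraction[off]) /
      sum(pc$expected_fraction[off])),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "enrichment_report: %s at %.2f-fold (%.1f%% of aligned bases); mean off-target fold %.2f\n",
    x$target_chrom, x$fold_target, 100 * x$on_target_fraction,
    x$mean_offtarget_fold))
  invisible(x)
}

#' Write an enrichment report as TSV
#'
#' One row per chromosome: chrom, length, copies, aligned_bases, depth,
#' observed_frac, expected_frac, fold.
#'
#' @param report an `enrichment_report`.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(report, path) {
  pc <- report$per_chrom
  out <- data.frame(chrom = pc$chrom, length = pc$length,
                    copies = pc$copy_number, aligned_bases = pc$aligned_bases,
                    depth = pc$mean_depth, observed_frac = pc$observed_fraction,
                    expected_frac = pc$expected_fraction, fold = pc$fold)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
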