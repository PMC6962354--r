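#' Variant-by-sample SV genotype table with superpopulation labels
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `n_alt_alleles`.
#' @param geno integer matrix of alt-allele dosages (0, 1, 2 or `NA`),
#'   variants in rows, samples in columns (column names are sample ids).
#' @param sample_map named character vector: sample id ->
#'   superpopulation label (e.g. AFR, AMR, EAS, EUR, SAS); every sample
#'   in `geno` must be labeled.
#' @return an object of class `sv_genotype_table`.
#' @export
sv_genotype_table <- function(variants, geno, sample_map) {
  stopifnot(is.data.frame(variants), is.matrix(geno),
            nrow(geno) == nrow(variants))
  if (ncol(geno) > 0 && is.null(colnames(geno)))
    stop("genotype matrix needs sample column names")
  unlabeled <- setdiff(colnames(geno), names(sample_map))
  if (length(unlabeled))
    stop("samples without superpopulation label: ",
         paste(utils::head(unlabeled, 3), collapse = ", "))
  if (any(geno > 2, na.rm = TRUE) || any(geno < 0, na.rm = TRUE))
    stop("dosages must be in 0..2")
  if (any(variants$n_alt_alleles < 1))
    stop("n_alt_alleles must be >= 1")
  structure(list(variants = variants, geno = geno,
                 sample_map = sample_map[colnames(geno)]),
            class = "sv_genotype_table")
}

#' @export
print.sv_genotype_table <- function(x, ...) {
  cat(sprintf("sv_genotype_table: %d variants x %d samples (%d superpopulations)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$sample_map))))
  invisible(x)
}

#' Filter variants by allele count and allele number
#'
#' Drops rare and multiallelic variants before frequency summarization:
#' variants whose global alt allele count (over non-missing genotypes) is
#' at or below `min_ac`, and, when `biallelic_only`, variants with more
#' than one alt allele. Missing dosages contribute to neither allele
#' counts nor denominators.
#'
#' @param table an [sv_genotype_table()].
#' @param min_ac drop variants with allele count <= this (default 2).
#' @param biallelic_only drop multiallelic variants (default `TRUE`).
#' @return the filtered `sv_genotype_table`.
#' @export
filter_variants <- function(table, min_ac = 2, biallelic_only = TRUE) {
  stopifnot(inherits(table, "sv_genotype_table"))
  ac <- rowSums(table$geno, na.rm = TRUE)
  keep <- ac > min_ac
  if (biallelic_only) keep <- keep & table$variants$n_alt_alleles == 1
  out <- table
  out$variants <- table$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$geno <- table$geno[keep, , drop = FALSE]
  out
}

#' Superpopulation allele frequencies
#'
#' Per variant and superpopulation, the alt allele frequency is the
#' dosage sum over twice the number of non-missing samples in that
#' superpopulation. The per-superpopulation summary is the unweighted
#' mean over variants, reported in percent (the median is also
#' emitted). A superpopulation with no non-missing genotypes for a
#' variant yields `NA` for that cell and is excluded from summaries.
#'
#' @param table an [sv_genotype_table()] (typically after
#'   [filter_variants()]).
#' @return list: `per_variant` (data.frame, one AF column per
#'   superpopulation plus `global`), `summary` (data.frame
#'   `superpop`, `mean_af_pct`, `median_af_pct`, `n_samples`).
#' @export
superpop_frequencies <- function(table) {
  stopifnot(inherits(table, "sv_genotype_table"))
  pops <- sort(unique(table$sample_map))
  af <- function(cols) {
    g <- table$geno[, cols, drop = FALSE]
    rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  }
  per_variant <- data.frame(id = table$variants$id, stringsAsFactors = FALSE)
  for (p in pops)
    per_variant[[p]] <- af(which(table$sample_map == p))
  per_variant$global <- af(seq_len(ncol(table$geno)))
  summary <- data.frame(
    superpop = pops,
    mean_af_pct = vapply(pops, function(p)
      100 * mean(per_variant[[p]], na.rm = TRUE), numeric(1)),
    median_af_pct = vapply(pops, function(p)
      100 * stats::median(per_variant[[p]], na.rm = TRUE), numeric(1)),
    n_samples = vapply(pops, function(p)
      sum(table$sample_map == p), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_variant = per_variant, summary = summary)
}

#' Write per-variant superpopulation frequencies as TSV
#'
#' @param freqs result of [superpop_frequencies()].
#' @param path output path.
#' @export
write_popfreq_tsv <- function(freqs, path) {
  data.table::fwrite(freqs$per_variant, path, sep = "\t", quote = FALSE)
  invisible(path)
}
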