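#' Karyotype-level genome model
#'
#' A genome model holds, per chromosome, the length in bp, the copy number
#' per cell under the sampling null (autosomes 2, X and Y 1 each in a
#' diploid male), an optional centromere interval and an optional GC
#' fraction. It defines the random-sampling null used to compute
#' enrichment folds and the exclusion geometry (centromere/telomere
#' flanks) used to filter structural-variant calls.
#'
#' All coordinates are 0-based half-open. Conversion to the 1-based closed
#' convention of [GenomicRanges::GRanges] happens only at the boundary,
#' via internal helpers.
#'
#' @param chromosomes a data.frame with columns `name`, `length`,
#'   `copy_number`, and optionally `cen_start`, `cen_end`, `gc_fraction`
#'   (`NA` allowed for the optional columns).
#' @return an object of class `genome_model`: a list with elements
#'   `chromosomes` (the validated data.frame) and `weighted_length`
#'   (sum of length x copy_number, bp).
#' @examples
#' gm <- genome_model(data.frame(
#'   name = c("A", "B", "X", "Y"),
#'   length = c(100, 100, 50, 20),
#'   copy_number = c(2, 2, 1, 1)))
#' expected_fractions(gm)
#' @export
genome_model <- function(chromosomes) {
  stopifnot(is.data.frame(chromosomes))
  req <- c("name", "length", "copy_number")
  missing_cols <- setdiff(req, names(chromosomes))
  if (length(missing_cols))
    stop("genome model table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  df$name <- as.character(df$name)
  for (col in c("cen_start", "cen_end", "gc_fraction"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (anyDuplicated(df$name))
    stop("duplicate chromosome names in genome model")
  if (any(df$length <= 0))
    stop("chromosome lengths must be positive")
  if (any(df$copy_number < 0))
    stop("copy numbers must be >= 0")
  if (all(df$copy_number == 0))
    stop("invalid genome model: all copy numbers are zero")
  has_cen <- !is.na(df$cen_start) | !is.na(df$cen_end)
  if (any(has_cen & (is.na(df$cen_start) | is.na(df$cen_end))))
    stop("centromere interval needs both cen_start and cen_end")
  bad <- has_cen & !(df$cen_start >= 0 & df$cen_start < df$cen_end &
                       df$cen_end <= df$length)
  if (any(bad))
    stop("malformed centromere interval on: ",
         paste(df$name[bad], collapse = ", "))
  structure(
    list(chromosomes = df,
         weighted_length = sum(as.numeric(df$length) * df$copy_number)),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, weighted length %.4g bp\n",
              nrow(x$chromosomes), x$weighted_length))
  invisible(x)
}

#' Expected per-chromosome base fractions under random sampling
#'
#' The fraction of sequenced bases expected to originate from each
#' chromosome if bases were sampled uniformly from the genome weighted by
#' chromosome length times copy number (the "random sampling from a
#' diploid male genome" null for a male sample).
#'
#' @param model a [genome_model()].
#' @return named numeric vector of fractions, one per chromosome, in model
#'   order; fractions over chromosomes with positive copy number sum to 1.
#' @export
expected_fractions <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  df <- model$chromosomes
  if (model$weighted_length <= 0)
    stop("invalid genome model: weighted length is zero")
  fr <- as.numeric(df$length) * df$copy_number / model$weighted_length
  names(fr) <- df$name
  fr
}

#' Centromere/telomere exclusion zones
#'
#' Builds, per chromosome, the intervals within `flank` bp of a telomere
#' (modeled as position 0 and position `length`) or of the centromere
#' interval, clipped to chromosome bounds and merged where they overlap.
#'
#' @param model a [genome_model()].
#' @param flank flank size in bp (>= 0); the study-standard value is 2 Mb.
#' @param merge merge overlapping zones per chromosome (default `TRUE`);
#'   when `FALSE` the raw zones carry a `kind` metadata column
#'   (`telomere_flank` / `centromere_flank`).
#' @return a [GenomicRanges::GRanges] of zones (1-based closed
#'   internally; use [gr_to_bed0()] to recover 0-based half-open
#'   coordinates).
#' @export
exclusion_zones <- function(model, flank, merge = TRUE) {
  stopifnot(inherits(model, "genome_model"), flank >= 0)
  df <- model$chromosomes
  chrom <- character(0); s0 <- numeric(0); e0 <- numeric(0); kind <- character(0)
  for (i in seq_len(nrow(df))) {
    L <- df$length[i]
    add <- function(a, b, k) {
      a <- max(0, a); b <- min(L, b)
      if (b > a) {
        chrom <<- c(chrom, df$name[i]); s0 <<- c(s0, a); e0 <<- c(e0, b)
        kind <<- c(kind, k)
      }
    }
    add(0, flank, "telomere_flank")
    add(L - flank, L, "telomere_flank")
    if (!is.na(df$cen_start[i]))
      add(df$cen_start[i] - flank, df$cen_end[i] + flank, "centromere_flank")
  }
  gr <- gr_from_bed0(chrom, s0, e0, seqlens = stats::setNames(df$length, df$name))
  if (!merge) {
    S4Vectors::mcols(gr)$kind <- kind
    return(gr)
  }
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

# ---- coordinate boundary helpers (0-based half-open <-> GRanges) ----

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom,start0,end0 vectors of chromosome names and 0-based
#'   half-open interval bounds; `end0 == start0` yields a 1-bp anchor at
#'   `start0` (used for insertion points).
#' @param seqlens optional named vector of chromosome lengths.
#' @return a `GRanges` (1-based closed).
#' @export
gr_from_bed0 <- function(chrom, start0, end0, seqlens = NULL) {
  if (length(chrom) == 0)
    return(GenomicRanges::GRanges(seqlengths = seqlens))
  end1 <- ifelse(end0 > start0, end0, start0 + 1)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end1))
  if (!is.null(seqlens)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlens)
    GenomeInfoDb::seqlengths(gr) <- seqlens
  }
  gr
}

#' Recover 0-based half-open coordinates from a GRanges
#'
#' @param gr a `GRanges`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
gr_to_bed0 <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# ---- model I/O ----

#' Read/write a genome model as TSV
#'
#' The table has columns `name`, `length`, `copy_number`, `cen_start`,
#' `cen_end`, `gc_fraction`; empty cells are allowed in the last three.
#'
#' @param path file path.
#' @return `read_genome_tsv`: a [genome_model()].
#' @export
read_genome_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"), data.table = FALSE)
  genome_model(df)
}

#' @rdname read_genome_tsv
#' @param model a [genome_model()].
#' @export
write_genome_tsv <- function(model, path) {
  stopifnot(inherits(model, "genome_model"))
  data.table::fwrite(model$chromosomes, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Build a genome model from a FASTA index and optional centromere BED
#'
#' @param fai path to a `.fai` file (as written by `samtools faidx`).
#' @param centromere_bed optional 3+-column BED with one centromere
#'   interval per chromosome.
#' @param haploid_chroms chromosome names carried at copy number 1 in the
#'   sampling null (default `c("chrX", "chrY")`, the diploid-male model).
#' @return a [genome_model()].
#' @export
read_fai_genome <- function(fai, centromere_bed = NULL,
                            haploid_chroms = c("chrX", "chrY")) {
  idx <- data.table::fread(fai, sep = "\t", header = FALSE, data.table = FALSE)
  df <- data.frame(name = as.character(idx[[1]]), length = as.numeric(idx[[2]]),
                   stringsAsFactors = FALSE)
  df$copy_number <- ifelse(df$name %in% haploid_chroms, 1L, 2L)
  df$cen_start <- NA_real_; df$cen_end <- NA_real_
  if (!is.null(centromere_bed)) {
    bed <- data.table::fread(centromere_bed, sep = "\t", header = FALSE,
                             data.table = FALSE)
    m <- match(df$name, as.character(bed[[1]]))
    df$cen_start <- as.numeric(bed[[2]])[m]
    df$cen_end <- as.numeric(bed[[3]])[m]
  }
  genome_model(df)
}

#' Human GRCh38-like genome model preset
#'
#' Chromosome lengths of the GRCh38 primary assembly with approximate
#' centromere intervals and per-chromosome GC fractions, at diploid-male
#' copy numbers. Shipped as a packaged table so analyses and tests run
#' without downloads; all operations accept arbitrary models.
#'
#' @return a [genome_model()].
#' @export
grch38_model <- function() {
  path <- system.file("extdata", "grch38_model.tsv", package = "chromsort",
                      mustWork = TRUE)
  read_genome_tsv(path)
}

#' Scaled-down diploid-male toy genome
#'
#' The GRCh38-like preset with every coordinate multiplied by `scale`,
#' keeping relative chromosome sizes, copy numbers and centromere
#' placement. Useful for simulations at desk scale.
#'
#' @param scale multiplicative factor on all coordinates (default 0.1).
#' @return a [genome_model()].
#' @export
toy_diploid_male <- function(scale = 0.1) {
  stopifnot(scale > 0)
  df <- grch38_model()$chromosomes
  df$length <- round(df$length * scale)
  df$cen_start <- round(df$cen_start * scale)
  df$cen_end <- round(df$cen_end * scale)
  genome_model(df)
}
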