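#' Nx contiguity statistic
#'
#' The largest length L such that contigs of length >= L together cover
#' at least x percent of the total assembly length (descending cumulative
#' rule; ties at exactly x percent include the boundary contig).
#'
#' @param lengths contig lengths in bp (non-empty, positive).
#' @param x percentage in (0, 100]; `x = 50` gives the N50.
#' @return the Nx length in bp.
#' @examples
#' nx_statistic(c(10, 5, 3, 2), 50)  # 10
#' @export
nx_statistic <- function(lengths, x = 50) {
  if (length(lengths) == 0) stop("empty contig set")
  stopifnot(all(lengths > 0), x > 0, x <= 100)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= x / 100 * sum(s))[1]]
}

#' Mutual coverage between assembly and reference
#'
#' Fraction of the assembly covered by alignment blocks (union of query
#' intervals over total contig length) and fraction of the reference
#' covered (union of target intervals over `reference_length`).
#' Overlapping blocks are merged before summing, so splitting a block at
#' an interior point leaves the result unchanged.
#'
#' @param blocks alignment-block data.frame (see [read_coords()]).
#' @param contig_lengths named vector of contig lengths in bp.
#' @param reference_length reference length in bp; when comparing against
#'   a reference with unresolved gaps, pass the non-N (resolved) length.
#' @return named numeric: `query_covered_fraction`,
#'   `target_covered_fraction`.
#' @export
mutual_coverage <- function(blocks, contig_lengths, reference_length) {
  stopifnot(reference_length > 0, all(contig_lengths > 0))
  if (nrow(blocks) == 0)
    return(c(query_covered_fraction = 0, target_covered_fraction = 0))
  unknown <- setdiff(unique(blocks$query), names(contig_lengths))
  if (length(unknown))
    stop("blocks reference undeclared contig(s): ",
         paste(unknown, collapse = ", "))
  if (any(blocks$qend > contig_lengths[blocks$query]))
    stop("alignment block exceeds declared contig length")
  if (any(blocks$tend > reference_length))
    stop("alignment block exceeds declared reference length")
  qcov <- sum(GenomicRanges::width(GenomicRanges::reduce(
    gr_from_bed0(blocks$query, blocks$qstart, blocks$qend))))
  tcov <- sum(GenomicRanges::width(GenomicRanges::reduce(
    gr_from_bed0(blocks$target, blocks$tstart, blocks$tend))))
  c(query_covered_fraction = qcov / sum(as.numeric(contig_lengths)),
    target_covered_fraction = tcov / reference_length)
}

#' Permutation test for contig-boundary association with features
#'
#' Projects each contig's boundaries to the reference as the outermost
#' target coordinates of its alignment blocks, measures the fraction of
#' boundary points lying within `window` bp of a feature interval, and
#' compares it against a null in which the same number of points is
#' redrawn uniformly over the aligned (covered) portion of the reference.
#' Contigs with no alignments are ignored (counted in `n_unaligned`).
#'
#' @param blocks alignment-block data.frame.
#' @param contig_names contig names expected in the assembly (for the
#'   unaligned count); defaults to those present in `blocks`.
#' @param features data.frame of feature intervals (`chrom`, `start`,
#'   `end`, 0-based half-open) on the reference, e.g. segmental
#'   duplications or satellite annotations.
#' @param window distance in bp within which a boundary counts as near a
#'   feature (0 = inside only).
#' @param n_perm number of null permutations (>= 1).
#' @param seed RNG seed for the null draws.
#' @return list: `observed_fraction_near`, `expected_fraction` (null
#'   mean), `empirical_p` = (1 + #{null >= observed}) / (1 + n_perm),
#'   `n_boundaries`, `n_unaligned`.
#' @export
boundary_feature_test <- function(blocks, features, window = 10000,
                                  n_perm = 1000, seed = 1,
                                  contig_names = unique(blocks$query)) {
  stopifnot(n_perm >= 1)
  aligned <- unique(blocks$query)
  if (length(aligned) == 0) stop("no aligned contigs: no boundaries to test")
  # outermost projected coordinates per contig, on its main target
  bounds <- do.call(rbind, lapply(aligned, function(ct) {
    b <- blocks[blocks$query == ct, ]
    main <- names(sort(table(b$target), decreasing = TRUE))[1]
    b <- b[b$target == main, ]
    data.frame(chrom = main, pos = c(min(b$tstart), max(b$tend) - 1))
  }))
  feat_gr <- gr_from_bed0(features$chrom, features$start, features$end)
  near_fraction <- function(chrom, pos) {
    if (length(feat_gr) == 0) return(0)
    pts <- gr_from_bed0(chrom, pos, pos + 1)
    d <- suppressWarnings(GenomicRanges::distanceToNearest(pts, feat_gr))
    hits <- rep(FALSE, length(pts))
    hits[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance <= window
    mean(hits)
  }
  observed <- near_fraction(bounds$chrom, bounds$pos)
  # null: redraw boundary points uniformly over the covered reference
  cov_gr <- GenomicRanges::reduce(gr_from_bed0(blocks$target, blocks$tstart,
                                               blocks$tend))
  widths <- GenomicRanges::width(cov_gr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    seg <- sample.int(length(cov_gr), nrow(bounds), replace = TRUE,
                      prob = widths)
    pos <- GenomicRanges::start(cov_gr)[seg] - 1 +
      floor(stats::runif(nrow(bounds)) * widths[seg])
    near_fraction(as.character(GenomeInfoDb::seqnames(cov_gr))[seg], pos)
  }, numeric(1))
  list(observed_fraction_near = observed,
       expected_fraction = mean(null_stats),
       empirical_p = (1 + sum(null_stats >= observed)) / (1 + n_perm),
       n_boundaries = nrow(bounds),
       n_unaligned = length(setdiff(contig_names, aligned)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
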