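#' Filter SV calls by exclusion zones, precision and size
#'
#' Applies the standard pre-intersection filters: drop calls overlapping
#' a centromere/telomere exclusion zone (insertions by their breakpoint
#' position), optionally drop calls not flagged precise by the caller,
#' and drop calls shorter than the SV size definition (50 bp by
#' default). Idempotent: filtering a filtered set changes nothing.
#'
#' @param calls SV call data.frame (see [read_sv_vcf()]).
#' @param zones exclusion zones as a `GRanges` from [exclusion_zones()],
#'   or `NULL` to skip positional filtering.
#' @param require_precise drop calls with `precise == FALSE`.
#' @param min_length minimum SV length in bp (default 50).
#' @return the filtered call data.frame.
#' @export
filter_calls <- function(calls, zones = NULL, require_precise = FALSE,
                         min_length = 50) {
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(zones) && length(zones) > 0 && nrow(calls) > 0) {
    call_gr <- calls_gr(calls)
    # seqlevel mismatch between calls and zones is expected, not a problem
    hit <- suppressWarnings(GenomicRanges::countOverlaps(call_gr, zones)) > 0
    keep <- keep & !hit
  }
  if (require_precise) keep <- keep & calls$precise
  keep <- keep & calls$length >= min_length
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# call spans as GRanges; INS anchored at its breakpoint base
calls_gr <- function(calls) {
  gr_from_bed0(calls$chrom, calls$start,
               ifelse(calls$svtype == "INS", calls$start, calls$end))
}

#' Overlap score between two SV calls
#'
#' For span types (DEL, DUP, INV) the score is the "either" rule: the
#' overlap length as a fraction of each call's length, taking the
#' maximum. For insertion pairs, which have no reference span, the score
#' is the size ratio `min(len)/max(len)` when the breakpoints lie within
#' `ins_window` bp of each other, else 0. Calls on different chromosomes
#' or of incompatible types score 0.
#'
#' @param a,b single-row SV call data.frames.
#' @param ins_window breakpoint window for insertion pairs (bp).
#' @return a symmetric score in `[0, 1]`.
#' @export
overlap_score <- function(a, b, ins_window = 500) {
  if (a$chrom != b$chrom || a$svtype != b$svtype) return(0)
  if (a$svtype == "INS") {
    if (abs(a$start - b$start) > ins_window) return(0)
    return(min(a$length, b$length) / max(a$length, b$length))
  }
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(0)
  max(ov / a$length, ov / b$length)
}

# all candidate pairs (ia, ib, score, bp_distance) with score > threshold
candidate_pairs <- function(A, B, threshold, ins_window) {
  if (nrow(A) == 0 || nrow(B) == 0)
    return(data.frame(ia = integer(0), ib = integer(0), score = numeric(0),
                      bp_distance = numeric(0)))
  pairs <- list()
  for (ty in intersect(unique(A$svtype), unique(B$svtype))) {
    ai <- which(A$svtype == ty); bi <- which(B$svtype == ty)
    if (ty == "INS") {
      ga <- gr_from_bed0(A$chrom[ai], pmax(0, A$start[ai] - ins_window),
                         A$start[ai] + ins_window + 1)
      gb <- gr_from_bed0(B$chrom[bi], B$start[bi], B$start[bi] + 1)
      h <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
      ia <- ai[S4Vectors::queryHits(h)]; ib <- bi[S4Vectors::subjectHits(h)]
      dist <- abs(A$start[ia] - B$start[ib])
      ok <- dist <= ins_window
      ia <- ia[ok]; ib <- ib[ok]; dist <- dist[ok]
      score <- pmin(A$length[ia], B$length[ib]) /
        pmax(A$length[ia], B$length[ib])
    } else {
      ga <- gr_from_bed0(A$chrom[ai], A$start[ai], A$end[ai])
      gb <- gr_from_bed0(B$chrom[bi], B$start[bi], B$end[bi])
      h <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
      ia <- ai[S4Vectors::queryHits(h)]; ib <- bi[S4Vectors::subjectHits(h)]
      ov <- pmin(A$end[ia], B$end[ib]) - pmax(A$start[ia], B$start[ib])
      score <- pmax(ov / A$length[ia], ov / B$length[ib])
      dist <- pmax(abs(A$start[ia] - B$start[ib]), abs(A$end[ia] - B$end[ib]))
    }
    keep <- score > threshold
    if (any(keep))
      pairs[[ty]] <- data.frame(ia = ia[keep], ib = ib[keep],
                                score = score[keep], bp_distance = dist[keep])
  }
  if (length(pairs) == 0)
    return(data.frame(ia = integer(0), ib = integer(0), score = numeric(0),
                      bp_distance = numeric(0)))
  do.call(rbind, pairs)
}

#' Intersect two SV callsets by one-to-one matching
#'
#' Candidate pairs are all compatible-type, same-chromosome pairs with
#' [overlap_score()] above `threshold`. Matching is one-to-one and
#' deterministic: pairs are first taken greedily by descending score
#' (ties broken by smaller breakpoint distance, then lexicographic ids),
#' and the result is then completed to a maximum-cardinality matching by
#' augmenting paths, so no pairable call is left unmatched because of an
#' unlucky greedy choice. One-to-one matching prevents double counting
#' in intersection tallies.
#'
#' @param A,B SV call data.frames (already filtered).
#' @param threshold minimum overlap score (exclusive; default 0.4, the
#'   "over 40% in either" rule).
#' @param ins_window breakpoint window for insertion pairs (bp).
#' @return list: `matches` (data.frame `id_a`, `id_b`, `score`,
#'   `bp_distance`), `unique_a`, `unique_b` (unmatched call
#'   data.frames), `pct_unique_a`, `pct_unique_b` (percent of each set
#'   unmatched).
#' @export
intersect_callsets <- function(A, B, threshold = 0.4, ins_window = 500) {
  cand <- candidate_pairs(A, B, threshold, ins_window)
  ord <- order(-cand$score, cand$bp_distance, A$id[cand$ia], B$id[cand$ib])
  cand <- cand[ord, , drop = FALSE]
  match_a <- rep(NA_integer_, nrow(A))   # index into B
  match_b <- rep(NA_integer_, nrow(B))   # index into A
  pair_row <- rep(NA_integer_, nrow(A))  # cand row backing each match
  for (k in seq_len(nrow(cand))) {
    i <- cand$ia[k]; j <- cand$ib[k]
    if (is.na(match_a[i]) && is.na(match_b[j])) {
      match_a[i] <- j; match_b[j] <- i; pair_row[i] <- k
    }
  }
  # complete to maximum cardinality; neighbor order = score preference
  adj <- split(seq_len(nrow(cand)),
               factor(cand$ia, levels = seq_len(nrow(A))))
  visited <- logical(nrow(B))
  augment <- function(i) {
    for (k in adj[[i]]) {
      j <- cand$ib[k]
      if (!visited[j]) {
        visited[j] <<- TRUE
        if (is.na(match_b[j]) || augment(match_b[j])) {
          match_a[i] <<- j; match_b[j] <<- i; pair_row[i] <<- k
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (i in seq_len(nrow(A))) {
    if (is.na(match_a[i]) && length(adj[[i]])) {
      visited[] <- FALSE
      augment(i)
    }
  }
  m <- cand[sort(pair_row[!is.na(pair_row)]), , drop = FALSE]
  matches <- data.frame(id_a = A$id[m$ia], id_b = B$id[m$ib],
                        score = m$score, bp_distance = m$bp_distance,
                        stringsAsFactors = FALSE)
  used_a <- !is.na(match_a); used_b <- !is.na(match_b)
  list(matches = matches,
       unique_a = A[!used_a, , drop = FALSE],
       unique_b = B[!used_b, , drop = FALSE],
       pct_unique_a = if (nrow(A)) 100 * sum(!used_a) / nrow(A) else NA_real_,
       pct_unique_b = if (nrow(B)) 100 * sum(!used_b) / nrow(B) else NA_real_)
}

#' Percent of a callset outside an intersection
#'
#' The worked arithmetic behind "x% unique to caller C": from a set of
#' size `n_set` of which `n_intersect` calls also appear in the other
#' set, the unique percentage is `(n_set - n_intersect) / n_set * 100`.
#'
#' @param n_set callset size.
#' @param n_intersect number of intersecting calls.
#' @return percentage in `[0, 100]`.
#' @examples
#' uniqueness_percent(940, 405)  # 56.9 for the read-based set
#' @export
uniqueness_percent <- function(n_set, n_intersect) {
  stopifnot(n_set > 0, n_intersect >= 0, n_intersect <= n_set)
  (n_set - n_intersect) / n_set * 100
}

#' Annotate SV calls with genic and coding overlap
#'
#' A call is genic if it overlaps any gene interval and coding if it
#' overlaps any CDS interval; insertions are tested by their breakpoint
#' position.
#'
#' @param calls SV call data.frame.
#' @param genes,cds data.frames of intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [read_bed()].
#' @return `calls` with logical columns `genic` and `coding` appended;
#'   attribute `counts` holds the two totals.
#' @export
annotate_regions <- function(calls, genes, cds) {
  flag <- function(feat) {
    if (nrow(calls) == 0 || is.null(feat) || nrow(feat) == 0)
      return(rep(FALSE, nrow(calls)))
    GenomicRanges::countOverlaps(
      calls_gr(calls), gr_from_bed0(feat$chrom, feat$start, feat$end)) > 0
  }
  calls$genic <- flag(genes)
  calls$coding <- flag(cds)
  attr(calls, "counts") <- c(genic = sum(calls$genic),
                             coding = sum(calls$coding))
  calls
}

#' Classify SV calls as known or novel against reference callsets
#'
#' A call is known in a reference set if that set contains a
#' compatible-type call with [overlap_score()] above `threshold`
#' (many-to-one allowed: classification, not matching); it is novel if
#' no reference set contains one.
#'
#' @param calls SV call data.frame.
#' @param reference_sets named list of SV call data.frames.
#' @param threshold minimum overlap score (default 0.4).
#' @param ins_window breakpoint window for insertion pairs (bp).
#' @return list: `novel` (data.frame of novel calls), `n_novel`,
#'   `known_per_set` (named counts), `known_any` (count known in at
#'   least one set), `known_matrix` (call x set logical matrix).
#' @export
classify_novel <- function(calls, reference_sets, threshold = 0.4,
                           ins_window = 500) {
  known <- matrix(FALSE, nrow = nrow(calls), ncol = length(reference_sets),
                  dimnames = list(NULL, names(reference_sets)))
  for (s in seq_along(reference_sets)) {
    cand <- candidate_pairs(calls, reference_sets[[s]], threshold, ins_window)
    known[unique(cand$ia), s] <- TRUE
  }
  any_known <- if (length(reference_sets)) rowSums(known) > 0
               else rep(FALSE, nrow(calls))
  novel <- calls[!any_known, , drop = FALSE]
  rownames(novel) <- NULL
  list(novel = novel, n_novel = nrow(novel),
       known_per_set = colSums(known), known_any = sum(any_known),
       known_matrix = known)
}

#' Size spectrum of an SV callset
#'
#' Histogram of call lengths per SV type in fixed-width bins, the modal
#' bin per type and overall, and the deletion:insertion count ratio.
#' Mobile-element insertions show up as a mode near their element length
#' (about 300 bp for Alu).
#'
#' @param calls SV call data.frame.
#' @param bin_width bin width in bp (default 50).
#' @param range two-element numeric range of sizes binned (default
#'   `c(0, 2000)`); calls outside contribute to type counts but not to
#'   the histogram.
#' @return list: `histogram` (data.frame `svtype`, `bin_start`,
#'   `bin_end`, `bin_center`, `count`), `per_type_counts`,
#'   `modal_bin_center` (named per type), `modal_bin_center_overall`,
#'   `del_ins_ratio` (`Inf` when there are no insertions).
#' @export
size_spectrum <- function(calls, bin_width = 50, range = c(0, 2000)) {
  stopifnot(bin_width > 0, length(range) == 2, range[2] > range[1])
  breaks <- seq(range[1], range[2], by = bin_width)
  in_range <- calls$length >= range[1] & calls$length < range[2]
  types <- sort(unique(calls$svtype))
  hist_list <- lapply(types, function(ty) {
    len <- calls$length[in_range & calls$svtype == ty]
    counts <- tabulate(findInterval(len, breaks), nbins = length(breaks) - 1)
    data.frame(svtype = ty, bin_start = breaks[-length(breaks)],
               bin_end = breaks[-1],
               bin_center = breaks[-length(breaks)] + bin_width / 2,
               count = counts, stringsAsFactors = FALSE)
  })
  hist <- if (length(hist_list)) do.call(rbind, hist_list)
          else data.frame(svtype = character(0), bin_start = numeric(0),
                          bin_end = numeric(0), bin_center = numeric(0),
                          count = numeric(0))
  modal <- vapply(types, function(ty) {
    h <- hist[hist$svtype == ty, ]
    if (sum(h$count) == 0) NA_real_ else h$bin_center[which.max(h$count)]
  }, numeric(1))
  overall <- if (nrow(hist)) {
    tot <- stats::aggregate(count ~ bin_center, hist, sum)
    if (sum(tot$count) == 0) NA_real_ else tot$bin_center[which.max(tot$count)]
  } else NA_real_
  n_del <- sum(calls$svtype == "DEL"); n_ins <- sum(calls$svtype == "INS")
  list(histogram = hist,
       per_type_counts = table(calls$svtype),
       modal_bin_center = modal,
       modal_bin_center_overall = overall,
       del_ins_ratio = if (n_ins > 0) n_del / n_ins else Inf)
}

#' Write an SV match table as TSV
#'
#' @param intersection result of [intersect_callsets()].
#' @param path output path.
#' @export
write_match_tsv <- function(intersection, path) {
  data.table::fwrite(intersection$matches, path, sep = "\t", quote = FALSE)
  invisible(path)
}
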