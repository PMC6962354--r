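#' Kimura 2-parameter divergence
#'
#' Substitutions-per-site estimate from the observed transition
#' proportion `p` and transversion proportion `q` of a repeat-to-
#' consensus alignment:
#' `K = -1/2 * ln((1 - 2p - q) * sqrt(1 - 2q))`.
#' Transitions and transversions are corrected separately, so K is
#' always at least the raw mismatch proportion.
#'
#' @param p transition proportion(s) (>= 0).
#' @param q transversion proportion(s) (>= 0).
#' @param on_saturation what to do when `1 - 2p - q <= 0` or
#'   `1 - 2q <= 0` (the estimator saturates): `"error"` (default) or
#'   `"na"` (returns `NA` for those elements with a warning).
#' @return divergence in substitutions per site (vectorized).
#' @examples
#' k2p_divergence(0.1, 0.05)  # 0.17019...
#' @export
k2p_divergence <- function(p, q, on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  stopifnot(all(p >= 0), all(q >= 0))
  n <- max(length(p), length(q))
  p <- rep_len(p, n); q <- rep_len(q, n)
  a <- 1 - 2 * p - q
  b <- 1 - 2 * q
  sat <- a <= 0 | b <= 0
  if (any(sat)) {
    if (on_saturation == "error")
      stop("K2P saturation: 1-2p-q or 1-2q is <= 0 for ", sum(sat), " hit(s)")
    warning(sum(sat), " saturated hit(s) set to NA")
  }
  k <- rep(NA_real_, length(sat))
  k[!sat] <- -0.5 * log(a[!sat] * sqrt(b[!sat]))
  k
}

#' Invert K2P divergence at a fixed transition:transversion ratio
#'
#' Finds substitution proportions `(p, q)` with `p = ts_tv_ratio * q`
#' whose [k2p_divergence()] equals `k`. Used by the synthetic repeat
#' generator; solved numerically (uniroot) per unique divergence value.
#'
#' @param k target divergence(s), substitutions per site (>= 0).
#' @param ts_tv_ratio transition:transversion ratio (default 2).
#' @return data.frame with columns `p` and `q`.
#' @export
k2p_invert <- function(k, ts_tv_ratio = 2) {
  stopifnot(all(k >= 0), ts_tv_ratio > 0)
  r <- ts_tv_ratio
  upper <- min(1 / (2 * r + 1), 0.5) - 1e-9  # q below both saturation walls
  solve_one <- function(kk) {
    if (kk == 0) return(0)
    f <- function(q) k2p_divergence(r * q, q) - kk
    stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  }
  uk <- unique(k)
  q <- vapply(uk, solve_one, numeric(1))[match(k, uk)]
  data.frame(p = r * q, q = q)
}

#' Build a repeat divergence landscape
#'
#' Bins each repeat hit's divergence-to-consensus and accumulates the
#' hit's length as a proportion of `denominator_bp`, per repeat
#' class/family. Hits for which the K2P estimator saturates are excluded
#' with a warning. Divergences at or beyond the last bin fall into an
#' overflow bin.
#'
#' @param hits repeat-hit data.frame with `chrom`, `start`, `end`,
#'   `class_family` and either `divergence` (fraction) or `p`/`q`
#'   proportions (see [read_repeatmasker_out()] / [read_repeat_tsv()]).
#' @param denominator_bp assembly length the proportions refer to.
#' @param bin_width_percent divergence bin width in percent (default 1).
#' @param max_percent start of the overflow bin (default 50).
#' @return a `repeat_landscape`: list with `matrix` (class x bin, bp
#'   proportions; column names are bin lower edges in percent),
#'   `bin_width_percent`, `denominator_bp`, `n_saturated`.
#' @export
build_landscape <- function(hits, denominator_bp, bin_width_percent = 1,
                            max_percent = 50) {
  stopifnot(denominator_bp > 0, bin_width_percent > 0)
  nbin <- ceiling(max_percent / bin_width_percent) + 1  # + overflow
  edges <- (seq_len(nbin) - 1) * bin_width_percent
  classes <- sort(unique(as.character(hits$class_family)))
  m <- matrix(0, nrow = length(classes), ncol = nbin,
              dimnames = list(classes, edges))
  n_sat <- 0L
  if (nrow(hits) > 0) {
    div <- if (!is.null(hits$divergence)) hits$divergence
           else k2p_divergence(hits$p, hits$q, on_saturation = "na")
    sat <- is.na(div)
    n_sat <- sum(sat)
    if (n_sat > 0) warning(n_sat, " saturated hit(s) excluded from landscape")
    h <- hits[!sat, , drop = FALSE]; div <- div[!sat]
    bin <- pmin(floor(div * 100 / bin_width_percent) + 1, nbin)
    w <- (h$end - h$start) / denominator_bp
    for (k in seq_along(bin))
      m[as.character(h$class_family[k]), bin[k]] <-
        m[as.character(h$class_family[k]), bin[k]] + w[k]
  }
  structure(list(matrix = m, bin_width_percent = bin_width_percent,
                 denominator_bp = denominator_bp, n_saturated = n_sat),
            class = "repeat_landscape")
}

#' @export
print.repeat_landscape <- function(x, ...) {
  cat(sprintf("repeat_landscape: %d classes, %.3f of assembly annotated\n",
              nrow(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Compare two repeat landscapes
#'
#' Per-class annotated proportions in each landscape and their ratio
#' (the repeat-resolution measure: proportion of bases annotated as a
#' given repeat type in one assembly relative to the other), plus the
#' cosine similarity of the flattened class x bin matrices.
#'
#' @param L1,L2 `repeat_landscape` objects (reference and comparison);
#'   classes are aligned by name, absent classes count as zero.
#' @return list: `per_class` (data.frame `class_family`,
#'   `proportion_1`, `proportion_2`, `ratio`, `abs_difference`),
#'   `cosine_similarity` in `[0, 1]`.
#' @export
compare_landscapes <- function(L1, L2) {
  stopifnot(inherits(L1, "repeat_landscape"), inherits(L2, "repeat_landscape"),
            L1$bin_width_percent == L2$bin_width_percent)
  classes <- sort(union(rownames(L1$matrix), rownames(L2$matrix)))
  nbin <- max(ncol(L1$matrix), ncol(L2$matrix))
  expand <- function(L) {
    m <- matrix(0, length(classes), nbin, dimnames = list(classes, NULL))
    if (nrow(L$matrix))
      m[rownames(L$matrix), seq_len(ncol(L$matrix))] <- L$matrix
    m
  }
  m1 <- expand(L1); m2 <- expand(L2)
  p1 <- rowSums(m1); p2 <- rowSums(m2)
  per_class <- data.frame(
    class_family = classes,
    proportion_1 = unname(p1), proportion_2 = unname(p2),
    ratio = unname(ifelse(p1 > 0, p2 / p1, ifelse(p2 > 0, Inf, NA_real_))),
    abs_difference = unname(abs(p1 - p2)),
    stringsAsFactors = FALSE)
  denom <- sqrt(sum(m1^2)) * sqrt(sum(m2^2))
  list(per_class = per_class,
       cosine_similarity = if (denom > 0) sum(m1 * m2) / denom else 0)
}

#' Write a landscape as a long-format TSV
#'
#' Columns: class_family, bin_low_pct, proportion.
#'
#' @param landscape a `repeat_landscape`.
#' @param path output path.
#' @export
write_landscape_tsv <- function(landscape, path) {
  m <- landscape$matrix
  out <- data.frame(
    class_family = rep(rownames(m), times = ncol(m)),
    bin_low_pct = rep(as.numeric(colnames(m)), each = nrow(m)),
    proportion = as.vector(m))
  data.table::fwrite(out[order(out$class_family, out$bin_low_pct), ],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
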