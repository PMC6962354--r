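# shared fixtures and independent oracles

toy_model <- function() {
  genome_model(data.frame(
    name = c("A", "B", "X", "Y"),
    length = c(100, 100, 50, 20),
    copy_number = c(2, 2, 1, 1)))
}

make_calls <- function(chrom, start, length, svtype, id = NULL,
                       precise = TRUE, source = "test") {
  n <- length(start)
  sv <- rep_len(svtype, n)
  data.frame(
    id = if (is.null(id)) sprintf("%s%03d", source, seq_len(n)) else id,
    chrom = rep_len(chrom, n), start = start,
    end = ifelse(sv == "INS", start, start + rep_len(length, n)),
    svtype = sv, length = rep_len(length, n),
    precise = rep_len(precise, n), source = rep_len(source, n),
    stringsAsFactors = FALSE)
}

# exhaustive maximum-cardinality one-to-one matching over candidate pairs
brute_force_max_matching <- function(pairs) {
  if (nrow(pairs) == 0) return(0L)
  recurse <- function(remaining) {
    if (nrow(remaining) == 0) return(0L)
    p <- remaining[1, ]
    rest <- remaining[-1, , drop = FALSE]
    with_p <- 1L + recurse(rest[rest$ia != p$ia & rest$ib != p$ib, ,
                                drop = FALSE])
    without_p <- recurse(rest)
    max(with_p, without_p)
  }
  recurse(pairs)
}

# brute-force per-base pileup: aligned bases per chromosome
pileup_aligned_bases <- function(records, model) {
  use <- records$is_primary
  vapply(model$chromosomes$name, function(ch) {
    rs <- records[use & records$chrom == ch, ]
    if (nrow(rs) == 0) return(0)
    L <- model$chromosomes$length[model$chromosomes$name == ch]
    depth <- integer(L)
    for (i in seq_len(nrow(rs)))
      depth[(rs$start[i] + 1):rs$end[i]] <- depth[(rs$start[i] + 1):rs$end[i]] + 1L
    sum(depth)
  }, numeric(1))
}

# descending cumulative Nx by explicit scan
nx_brute <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (L in s) {
    acc <- acc + L
    if (acc >= x / 100 * total) return(L)
  }
}
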