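one_record <- function(chrom, start, end, id = "r1", primary = TRUE,
                       mapq = 60L) {
  data.frame(read_id = id, read_length = end - start, chrom = chrom,
             start = start, end = end, matched_bases = end - start,
             mapq = mapq, is_primary = primary, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("coverage summary accumulates primary target spans", {
  gm <- genome_model(data.frame(name = c("A", "B"), length = c(1000, 400),
                                copy_number = c(2, 2)))
  s <- summarize_mappings(one_record("A", 0, 100), gm)
  pc <- s$per_chrom
  expect_equal(pc$aligned_bases[pc$chrom == "A"], 100)
  expect_equal(pc$mean_depth[pc$chrom == "A"], 0.1)
  expect_equal(pc$observed_fraction[pc$chrom == "A"], 1)

  # a duplicated secondary alignment changes nothing
  recs <- rbind(one_record("A", 0, 100),
                one_record("A", 0, 100, primary = FALSE))
  s2 <- summarize_mappings(recs, gm)
  expect_equal(s2$per_chrom$aligned_bases, s$per_chrom$aligned_bases)

  recs3 <- rbind(one_record("A", 0, 50, "r1"), one_record("A", 50, 150, "r2"),
                 one_record("B", 0, 100, "r3"))
  s3 <- summarize_mappings(recs3, gm)
  expect_equal(s3$per_chrom$observed_fraction, c(0.6, 0.4))
  expect_equal(s3$per_chrom$mean_depth, c(0.15, 0.25))

  expect_error(summarize_mappings(one_record("Z", 0, 10), gm), "unknown")
})

test_that("summary agrees with a brute-force per-base pileup", {
  gm <- genome_model(data.frame(name = c("A", "B"), length = c(500, 300),
                                copy_number = c(2, 1)))
  set.seed(42)
  n <- 80
  chrom <- sample(c("A", "B"), n, replace = TRUE)
  L <- c(A = 500, B = 300)[chrom]
  start <- floor(runif(n) * (L - 20))
  recs <- data.frame(read_id = sprintf("r%02d", 1:n), read_length = 20,
                     chrom = chrom, start = start, end = start + 20,
                     matched_bases = 18, mapq = 60L, is_primary = TRUE,
                     strand = "+", stringsAsFactors = FALSE)
  s <- summarize_mappings(recs, gm)
  expect_equal(stats::setNames(s$per_chrom$aligned_bases, s$per_chrom$chrom),
               pileup_aligned_bases(recs, gm))
})

test_that("mapq threshold drops low-quality records", {
  gm <- genome_model(data.frame(name = "A", length = 1000, copy_number = 2))
  recs <- rbind(one_record("A", 0, 100, "r1", mapq = 60L),
                one_record("A", 200, 300, "r2", mapq = 5L))
  s <- summarize_mappings(recs, gm, min_mapq = 20)
  expect_equal(s$per_chrom$aligned_bases, 100)
  expect_equal(s$totals$total_reads, 2)
})

test_that("enrichment folds reproduce hand arithmetic and the null", {
  gm <- toy_model()
  obs <- c(A = 0.85, B = 0.10, X = 0.03, Y = 0.02)
  recs <- do.call(rbind, lapply(names(obs), function(ch)
    one_record(ch, 0, obs[[ch]] * 100, id = paste0("r", ch))))
  s <- summarize_mappings(recs, gm)
  rep <- enrichment_folds(s, gm, "A")
  expect_equal(rep$fold_target, 0.85 / (200 / 470), tolerance = 1e-12)
  expect_equal(rep$on_target_fraction, 0.85)

  # observed == expected -> all folds 1 (spans at 1/10 of the weights)
  fr <- expected_fractions(gm)
  recs_null <- do.call(rbind, lapply(names(fr), function(ch)
    one_record(ch, 0, fr[[ch]] * 47, id = paste0("n", ch))))
  rep_null <- enrichment_folds(summarize_mappings(recs_null, gm), gm, "A")
  expect_equal(rep_null$per_chrom$fold, rep(1, 4), tolerance = 1e-9)
  expect_equal(rep_null$mean_offtarget_fold, 1, tolerance = 1e-9)
})

test_that("every enrichment report conserves sum(expected * fold) = 1", {
  gm <- toy_diploid_male(0.02)
  set.seed(7)
  for (i in 1:5) {
    chrom <- sample(gm$chromosomes$name, 50, replace = TRUE)
    L <- stats::setNames(gm$chromosomes$length, gm$chromosomes$name)[chrom]
    start <- floor(runif(50) * (L - 1000))
    recs <- data.frame(read_id = sprintf("r%02d", 1:50), read_length = 1000,
                       chrom = chrom, start = start, end = start + 1000,
                       matched_bases = 900, mapq = 60L, is_primary = TRUE,
                       strand = "+", stringsAsFactors = FALSE)
    rep <- enrichment_folds(summarize_mappings(recs, gm), gm, "chr1")
    expect_equal(sum(rep$per_chrom$expected_fraction * rep$per_chrom$fold),
                 1, tolerance = 1e-9)
  }
})

test_that("adding target bases raises the target fold and lowers others", {
  gm <- genome_model(data.frame(name = c("A", "B", "X", "Y"),
                                length = c(1000, 1000, 500, 200),
                                copy_number = c(2, 2, 1, 1)))
  base <- rbind(one_record("A", 0, 100, "r1"), one_record("B", 0, 100, "r2"))
  more <- rbind(base, one_record("A", 200, 400, "r3"))
  r1 <- enrichment_folds(summarize_mappings(base, gm), gm, "A")
  r2 <- enrichment_folds(summarize_mappings(more, gm), gm, "A")
  expect_gt(r2$fold_target, r1$fold_target)
  off1 <- r1$per_chrom$fold[r1$per_chrom$chrom != "A"]
  off2 <- r2$per_chrom$fold[r2$per_chrom$chrom != "A"]
  expect_true(all(off2 <= off1))
})

empty_mappings_df <- function() {
  data.frame(read_id = character(0), read_length = numeric(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             matched_bases = numeric(0), mapq = integer(0),
             is_primary = logical(0), strand = character(0),
             stringsAsFactors = FALSE)
}

test_that("zero-expected chromosomes with observed bases get Inf + warning", {
  gm <- genome_model(data.frame(name = c("A", "B"), length = c(100, 100),
                                copy_number = c(2, 0)))
  recs <- rbind(one_record("A", 0, 50, "r1"), one_record("B", 0, 50, "r2"))
  s <- summarize_mappings(recs, gm)
  expect_warning(rep <- enrichment_folds(s, gm, "A"), "zero expected")
  expect_true(is.infinite(rep$per_chrom$fold[rep$per_chrom$chrom == "B"]))
  expect_error(enrichment_folds(summarize_mappings(empty_mappings_df(), gm),
                                gm, "A"), "no aligned bases")
})
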