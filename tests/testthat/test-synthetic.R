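test_that("child seeds are stable and distinct across streams", {
  expect_identical(child_seed(7, "mappings"), child_seed(7, "mappings"))
  expect_false(child_seed(7, "mappings") == child_seed(7, "svsets"))
  expect_false(child_seed(7, "mappings") == child_seed(8, "mappings"))
  expect_true(child_seed(.Machine$integer.max, "x") < 2^31)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 12, total_mapped_bases = 5e6, n_true_svs = 100,
                    n_samples = 60)
  expect_identical(gen_mappings(cfg)$records, gen_mappings(cfg)$records)
  expect_identical(gen_svsets(cfg)$callset_b, gen_svsets(cfg)$callset_b)
  sv <- gen_svsets(cfg)
  expect_identical(gen_population(sv$truth, cfg)$table$geno,
                   gen_population(sv$truth, cfg)$table$geno)
  expect_identical(gen_repeats(cfg)$hits, gen_repeats(cfg)$hits)
})

test_that("mapping generator hits its base budget within chromosome bounds", {
  cfg <- sim_config(seed = 3, total_mapped_bases = 1e7)
  m <- gen_mappings(cfg)
  r <- m$records
  expect_gte(sum(r$read_length), 1e7)
  lens <- stats::setNames(cfg$genome$chromosomes$length,
                          cfg$genome$chromosomes$name)
  expect_true(all(r$start >= 0 & r$end <= lens[r$chrom]))
  expect_true(all(r$read_length >= 500))
  expect_true(all(r$end - r$start == r$read_length))
})

test_that("the reported ground-truth fold matches the boost algebra", {
  gm <- toy_model()
  boost <- enrichment_for_fold(gm, "A", 2.0)
  cfg <- sim_config(seed = 1, genome = gm, target_chrom = "A",
                    enrichment_fold = boost, total_mapped_bases = 0)
  m <- gen_mappings(cfg)
  expect_equal(m$truth$fold_real, 2.0, tolerance = 1e-12)
  expect_equal(nrow(m$records), 0)
  # infeasible folds are refused
  expect_error(enrichment_for_fold(gm, "A", 3), "infeasible")
})

test_that("a unit enrichment fold leaves all chromosomes near fold 1", {
  cfg <- sim_config(seed = 19, target_fold = 1, total_mapped_bases = 5e7)
  m <- gen_mappings(cfg)
  expect_equal(m$truth$fold_real, 1, tolerance = 1e-12)
  rep <- enrichment_folds(summarize_mappings(m$records, cfg$genome),
                          cfg$genome, cfg$target_chrom)
  n <- nrow(m$records)
  for (i in seq_len(nrow(rep$per_chrom))) {
    e <- rep$per_chrom$expected_fraction[i]
    # ~4 sd binomial envelope on the observed fraction, in fold units
    tol <- 4 * sqrt(e * (1 - e) / n) / e * 2
    expect_lt(abs(rep$per_chrom$fold[i] - 1), tol)
  }
})

test_that("true SVs avoid exclusion zones and follow the type ratio", {
  cfg <- sim_config(seed = 29, n_true_svs = 600)
  sv <- gen_svsets(cfg)
  hits <- GenomicRanges::countOverlaps(
    gr_from_bed0(sv$truth$chrom, sv$truth$start,
                 pmax(sv$truth$end, sv$truth$start)), sv$zones)
  expect_true(all(hits == 0))
  expect_true(all(sv$truth$length >= 50))
  ratio <- sum(sv$truth$svtype == "DEL") / sum(sv$truth$svtype == "INS")
  expect_equal(ratio, 2, tolerance = 0.25)
})

test_that("the recorded pairing maps truth calls onto caller ids", {
  cfg <- sim_config(seed = 37, n_true_svs = 120, breakpoint_jitter_sd = 0,
                    fp_rate = 0)
  sv <- gen_svsets(cfg)
  p <- sv$pairing
  expect_equal(sum(!is.na(p$id_a)),
               sum(!grepl("FP", sv$callset_a$id)))
  expect_equal(sum(!is.na(p$id_b)),
               sum(!grepl("FP", sv$callset_b$id)))
  # a paired B call is the same variant shifted by zero jitter
  i <- which(!is.na(p$id_b))[1]
  tru <- sv$truth[sv$truth$id == p$truth_id[i], ]
  got <- sv$callset_b[sv$callset_b$id == p$id_b[i], ]
  expect_equal(got$start, tru$start)
  expect_equal(got$length, tru$length)
})

test_that("contig generator respects feature-seeded breakpoints", {
  feat <- data.frame(chrom = "ref", start = 4000, end = 6000)
  asm <- gen_contigs(1e5, 12, features = feat, feature_weight = 1, seed = 5)
  expect_true(all(asm$breakpoints >= 4000 & asm$breakpoints < 6000))
  expect_equal(sum(asm$contig_lengths), 1e5)

  solid <- gen_contigs(1e5, 0, seed = 5)
  expect_equal(length(solid$contig_lengths), 1)
  mc <- mutual_coverage(solid$blocks, solid$contig_lengths, 1e5)
  expect_equal(unname(mc), c(1, 1))
})

test_that("the synthetic bundle round-trips through every reader", {
  cfg <- sim_config(seed = 43, total_mapped_bases = 2e6, n_true_svs = 60,
                    n_samples = 40)
  dir <- withr::local_tempdir()
  sim <- write_synthetic_bundle(cfg, dir)

  maps <- read_paf(file.path(dir, "mappings.paf"))
  expect_equal(nrow(maps), nrow(sim$mappings$records))
  expect_equal(maps$start, sim$mappings$records$start)
  expect_equal(maps$chrom, sim$mappings$records$chrom)

  A <- read_assemblytics_bed(file.path(dir, "callset_a.bed"))
  expect_equal(nrow(A), nrow(sim$svsets$callset_a))
  expect_equal(A$start, sim$svsets$callset_a$start)
  expect_equal(A$svtype, sim$svsets$callset_a$svtype)
  expect_equal(A$length, sim$svsets$callset_a$length)

  B <- read_sv_vcf(file.path(dir, "callset_b.vcf"))
  expect_equal(nrow(B), nrow(sim$svsets$callset_b))
  expect_equal(B$start, sim$svsets$callset_b$start)
  expect_equal(B$precise, sim$svsets$callset_b$precise)
  expect_equal(B$length, sim$svsets$callset_b$length)

  reps <- read_repeat_tsv(file.path(dir, "repeats.tsv"))
  expect_equal(reps$p, sim$repeats$hits$p, tolerance = 1e-9)
  out <- read_repeatmasker_out(file.path(dir, "repeats.out"))
  expect_equal(nrow(out), nrow(sim$repeats$hits))
  expect_equal(out$divergence, sim$repeats$hits$divergence, tolerance = 5e-5)
  expect_equal(out$start, sim$repeats$hits$start)

  truth <- jsonlite::read_json(file.path(dir, "truth_manifest.json"))
  expect_equal(truth$fold_real, sim$mappings$truth$fold_real)
})

test_that("an empty configuration yields valid empty files", {
  cfg <- sim_config(seed = 51, total_mapped_bases = 0, n_true_svs = 0,
                    n_samples = 0,
                    repeat_classes = data.frame(class_family = character(0),
                                                fraction = numeric(0),
                                                div_mean_pct = numeric(0),
                                                div_sd_pct = numeric(0),
                                                mean_hit_length = numeric(0)))
  dir <- withr::local_tempdir()
  write_synthetic_bundle(cfg, dir)
  expect_equal(nrow(read_paf(file.path(dir, "mappings.paf"))), 0)
  out <- read_repeatmasker_out(file.path(dir, "repeats.out"))
  expect_equal(nrow(out), 0)
  expect_equal(length(readLines(file.path(dir, "repeats.out"))), 3)
})
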