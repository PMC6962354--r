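test_that("overlap score implements the either rule and INS size ratio", {
  del1 <- make_calls("c", 100, 100, "DEL")
  expect_equal(overlap_score(del1, del1), 1.0)
  del2 <- make_calls("c", 150, 200, "DEL")
  expect_equal(overlap_score(del1, del2), 0.5)  # ov = 50; max(50/100, 50/200)

  ins1 <- make_calls("c", 1000, 300, "INS")
  ins2 <- make_calls("c", 1400, 290, "INS")
  expect_equal(overlap_score(ins1, ins2, ins_window = 300), 0)
  expect_equal(overlap_score(ins1, ins2, ins_window = 500), 290 / 300)

  expect_equal(overlap_score(del1, ins1), 0)  # incompatible types
  other <- make_calls("d", 100, 100, "DEL")
  expect_equal(overlap_score(del1, other), 0)  # different chromosome
})

test_that("overlap score is symmetric on random call pairs", {
  set.seed(19)
  for (i in 1:50) {
    ty <- sample(c("DEL", "INS", "DUP", "INV"), 2, replace = TRUE)
    a <- make_calls("c", sample(0:2000, 1), sample(50:500, 1), ty[1])
    b <- make_calls("c", sample(0:2000, 1), sample(50:500, 1), ty[2])
    expect_equal(overlap_score(a, b), overlap_score(b, a))
  }
})

test_that("filter_calls honors half-open zones, precision and size", {
  gm <- genome_model(data.frame(name = "c", length = 10e6, copy_number = 2,
                                cen_start = 4e6, cen_end = 5e6))
  zones <- exclusion_zones(gm, 1e6)  # [0,1M), [3M,6M), [9M,10M)
  calls <- make_calls("c", c(6e6, 5e6, 2e6, 3.5e6, 9.5e6),
                      c(100, 100, 100, 100, 60),
                      c("DEL", "DEL", "INS", "INS", "DEL"))
  kept <- filter_calls(calls, zones)
  # start exactly at zone end (6e6) retained; inside-zone calls dropped
  expect_equal(kept$start, c(6e6, 2e6))

  imprecise <- make_calls("c", 2e6, 100, "DEL", precise = FALSE)
  expect_equal(nrow(filter_calls(imprecise, zones, require_precise = TRUE)), 0)

  short <- make_calls("c", 2e6, 30, "DEL")
  expect_equal(nrow(filter_calls(short, zones, min_length = 50)), 0)
})

test_that("filter_calls is idempotent and never grows the set", {
  cfg <- sim_config(seed = 5, n_true_svs = 200)
  sv <- gen_svsets(cfg)
  zones <- exclusion_zones(cfg$genome, cfg$exclusion_flank * 2)
  f1 <- filter_calls(sv$callset_b, zones, require_precise = TRUE)
  f2 <- filter_calls(f1, zones, require_precise = TRUE)
  expect_lte(nrow(f1), nrow(sv$callset_b))
  expect_identical(f1, f2)
})

test_that("intersection matches perfect callers exactly and swaps cleanly", {
  cfg <- sim_config(seed = 8, n_true_svs = 150,
                    caller_sensitivity = c(1, 1),
                    breakpoint_jitter_sd = 0, fp_rate = 0, precise_prob = 1)
  sv <- gen_svsets(cfg)
  isec <- intersect_callsets(sv$callset_a, sv$callset_b)
  expect_equal(nrow(isec$matches), 150)
  expect_equal(nrow(isec$unique_a), 0)
  expect_equal(nrow(isec$unique_b), 0)

  swapped <- intersect_callsets(sv$callset_b, sv$callset_a)
  expect_equal(nrow(swapped$matches), nrow(isec$matches))
  expect_equal(sort(swapped$matches$id_b), sort(isec$matches$id_a))

  self <- intersect_callsets(sv$callset_a, sv$callset_a)
  expect_equal(nrow(self$matches), nrow(sv$callset_a))
  expect_equal(self$pct_unique_a, 0)
})

test_that("independent sensitivities give the closed-form intersection rate", {
  n <- 1200
  cfg <- sim_config(seed = 13, n_true_svs = n,
                    caller_sensitivity = c(0.8, 0.7),
                    breakpoint_jitter_sd = 0, fp_rate = 0)
  sv <- gen_svsets(cfg)
  isec <- intersect_callsets(sv$callset_a, sv$callset_b)
  expected <- 0.8 * 0.7 * n
  # 4 sd binomial envelope
  tol <- 4 * sqrt(n * 0.56 * 0.44)
  expect_lt(abs(nrow(isec$matches) - expected), tol)
  expect_lte(nrow(isec$matches), min(nrow(sv$callset_a), nrow(sv$callset_b)))
})

test_that("greedy matching attains brute-force maximum cardinality", {
  set.seed(23)
  for (i in 1:20) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    A <- make_calls("c", sort(sample(0:1500, na)), sample(80:400, na,
                    replace = TRUE), "DEL", source = "A")
    B <- make_calls("c", sort(sample(0:1500, nb)), sample(80:400, nb,
                    replace = TRUE), "DEL", source = "B")
    isec <- intersect_callsets(A, B, threshold = 0.4)
    cand <- chromsort:::candidate_pairs(A, B, 0.4, 500)
    expect_equal(nrow(isec$matches), brute_force_max_matching(cand))
  }
})

test_that("the printed uniqueness percentages follow from the set sizes", {
  expect_equal(round(uniqueness_percent(940, 405), 1), 56.9)
  # the assembly-based direction, from the same arithmetic
  expect_equal(round(uniqueness_percent(1325, 405), 1), 69.4)
})

test_that("genic and coding annotation uses any-overlap with INS points", {
  genes <- data.frame(chrom = "c", start = c(100, 1000), end = c(500, 1500))
  cds <- data.frame(chrom = "c", start = 1100, end = 1200)
  calls <- make_calls("c", c(150, 1150, 1450, 700, 2000),
                      c(60, 60, 60, 60, 60),
                      c("DEL", "DEL", "INS", "DEL", "INS"))
  ann <- annotate_regions(calls, genes, cds)
  expect_equal(ann$genic, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(ann$coding, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(ann, "counts"), c(genic = 3, coding = 1))

  none <- annotate_regions(calls, genes[0, ], cds[0, ])
  expect_false(any(none$genic) || any(none$coding))
})

test_that("novelty classification counts calls absent from all references", {
  calls <- make_calls("c", seq(1000, 100000, length.out = 100), 200, "DEL",
                      source = "Q")
  ref1 <- calls[1:50, ]; ref1$id <- paste0("r1_", ref1$id)
  ref2 <- calls[41:75, ]; ref2$id <- paste0("r2_", ref2$id)
  res <- classify_novel(calls, list(s1 = ref1, s2 = ref2))
  expect_equal(res$n_novel, 25)
  expect_equal(unname(res$known_per_set), c(50, 35))
  expect_equal(res$known_any, 75)

  all_novel <- classify_novel(calls, list())
  expect_equal(all_novel$n_novel, 100)
  none_novel <- classify_novel(calls, list(self = calls))
  expect_equal(none_novel$n_novel, 0)
})

test_that("size spectrum finds modes and the deletion bias", {
  calls <- make_calls("c", seq(1000, 9000, by = 100), 120,
                      rep(c("DEL", "DEL", "INS"), length.out = 81))
  spec <- size_spectrum(calls, bin_width = 50, range = c(0, 1000))
  expect_equal(spec$modal_bin_center_overall, 125)
  expect_equal(spec$del_ins_ratio, 2, tolerance = 0.05)

  no_ins <- make_calls("c", c(100, 300), 70, "DEL")
  expect_equal(size_spectrum(no_ins)$del_ins_ratio, Inf)
})

test_that("generator size mixture and DEL:INS weights surface in spectra", {
  cfg <- sim_config(seed = 31, n_true_svs = 2000, del_ins_ratio = 2)
  sv <- gen_svsets(cfg)
  spec <- size_spectrum(sv$truth, bin_width = 50, range = c(0, 1000))
  expect_lte(abs(spec$modal_bin_center_overall - 300), 25)
  expect_equal(spec$del_ins_ratio, 2, tolerance = 0.15)
})
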