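#' Deterministic child seed from a master seed and stream name
#'
#' Each generator draws from its own stream, derived by stable string
#' hashing of the master seed and the generator name, so adding reads
#' does not perturb the simulated callsets and vice versa.
#'
#' @param master integer master seed.
#' @param name stream name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, name) {
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Simulation configuration for the synthetic-data generators
#'
#' Defaults emulate the study conditions of a flow-sorted chromosome 1
#' experiment on a diploid male: 8-fold target enrichment, long-tailed
#' (log-normal) read lengths, an SV size mixture with an Alu-like
#' component at 300 bp, deletions twice as frequent as insertions, and
#' 1000-Genomes-like superpopulation allele frequencies peaking in East
#' Asian samples.
#'
#' @param seed master integer seed; all child streams derive from it.
#' @param genome a [genome_model()] (default [toy_diploid_male()] at
#'   scale 0.1).
#' @param target_chrom flow-sorting target chromosome.
#' @param target_fold ground-truth enrichment fold on the target; the
#'   per-chromosome sampling boost is solved from it (see
#'   [enrichment_for_fold()]). Ignored when `enrichment_fold` is given.
#' @param enrichment_fold raw multiplicative sampling boost on the
#'   target chromosome (before renormalization), overriding
#'   `target_fold`.
#' @param total_mapped_bases total aligned bases to simulate.
#' @param read_length_mean,read_length_sd log-normal read length moments
#'   (bp); lengths are truncated to `[500, chromosome length]`.
#' @param n_true_svs number of true structural variants.
#' @param sv_size_mixture data.frame `weight`, `mean`, `sd` (bp) of
#'   normal mixture components for SV sizes, truncated at 50 bp;
#'   weights must sum to 1.
#' @param del_ins_ratio deletion:insertion ratio in the truth set.
#' @param caller_sensitivity length-2 vector: detection probability of
#'   the assembly-based (A) and read-based (B) caller, independent per
#'   variant.
#' @param breakpoint_jitter_sd sd (bp) of Gaussian jitter on the
#'   read-based caller's breakpoints.
#' @param precise_prob probability a read-based call is flagged precise.
#' @param fp_rate false-positive calls added to each callset, as a
#'   fraction of its true detections.
#' @param exclusion_flank centromere/telomere flank (bp) the truth SVs
#'   avoid (the filtering default, 2 Mb, scaled with the genome).
#' @param n_samples population panel size (split evenly over
#'   superpopulations).
#' @param superpop_freqs named vector of mean allele frequencies per
#'   superpopulation.
#' @param af_concentration Beta concentration of per-variant allele
#'   frequencies around the superpopulation mean.
#' @param multiallelic_frac fraction of variants made multiallelic.
#' @param low_ac_frac fraction of variants forced to allele count <= 2.
#' @param repeat_classes data.frame `class_family`, `fraction` (of the
#'   genome), `div_mean_pct`, `div_sd_pct`, `mean_hit_length` (bp).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome = toy_diploid_male(0.1),
                       target_chrom = "chr1",
                       target_fold = 8,
                       enrichment_fold = NULL,
                       total_mapped_bases = 1.4e9,
                       read_length_mean = 7000,
                       read_length_sd = 7000,
                       n_true_svs = 1000,
                       sv_size_mixture = data.frame(
                         weight = c(0.4, 0.3, 0.3),
                         mean = c(300, 100, 1200),
                         sd = c(30, 40, 800)),
                       del_ins_ratio = 2,
                       caller_sensitivity = c(0.8, 0.7),
                       breakpoint_jitter_sd = 20,
                       precise_prob = 0.9,
                       fp_rate = 0.1,
                       exclusion_flank = 2e6 * 0.1,
                       n_samples = 1000,
                       superpop_freqs = c(EAS = 0.205, SAS = 0.188,
                                          AMR = 0.184, EUR = 0.147,
                                          AFR = 0.098),
                       af_concentration = 30,
                       multiallelic_frac = 0.05,
                       low_ac_frac = 0.05,
                       repeat_classes = data.frame(
                         class_family = c("LINE/L1", "SINE/Alu", "LTR/ERVL",
                                          "Satellite", "DNA/hAT"),
                         fraction = c(0.17, 0.10, 0.05, 0.03, 0.03),
                         div_mean_pct = c(18, 12, 22, 8, 20),
                         div_sd_pct = c(8, 6, 8, 6, 7),
                         mean_hit_length = c(3000, 300, 800, 2000, 500))) {
  stopifnot(inherits(genome, "genome_model"),
            target_chrom %in% genome$chromosomes$name,
            abs(sum(sv_size_mixture$weight) - 1) < 1e-9,
            all(caller_sensitivity >= 0 & caller_sensitivity <= 1),
            n_true_svs >= 0, n_samples >= 0, total_mapped_bases >= 0)
  if (is.null(enrichment_fold))
    enrichment_fold <- enrichment_for_fold(genome, target_chrom, target_fold)
  cfg <- list(seed = seed, genome = genome, target_chrom = target_chrom,
              enrichment_fold = enrichment_fold,
              total_mapped_bases = total_mapped_bases,
              read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              n_true_svs = n_true_svs, sv_size_mixture = sv_size_mixture,
              del_ins_ratio = del_ins_ratio,
              caller_sensitivity = caller_sensitivity,
              breakpoint_jitter_sd = breakpoint_jitter_sd,
              precise_prob = precise_prob, fp_rate = fp_rate,
              exclusion_flank = exclusion_flank, n_samples = n_samples,
              superpop_freqs = superpop_freqs,
              af_concentration = af_concentration,
              multiallelic_frac = multiallelic_frac,
              low_ac_frac = low_ac_frac, repeat_classes = repeat_classes)
  class(cfg) <- "sim_config"
  cfg
}

#' Sampling boost achieving a target realized enrichment fold
#'
#' The generator draws each read's chromosome with probability
#' proportional to `expected_fraction * boost` (boost on the target
#' only). The realized fold is `boost / Z` with
#' `Z = e_t * boost + (1 - e_t)`; solving for the boost that realizes
#' fold `F` gives `b = F (1 - e_t) / (1 - F e_t)`, which requires
#' `F * e_t < 1` (a chromosome cannot exceed all-of-the-data
#' enrichment).
#'
#' @param model a [genome_model()].
#' @param target target chromosome name.
#' @param fold desired realized fold (> 0).
#' @return the raw boost.
#' @export
enrichment_for_fold <- function(model, target, fold) {
  e <- expected_fractions(model)[[target]]
  if (fold * e >= 1)
    stop(sprintf("fold %.3g infeasible: target expected fraction %.3g caps fold at %.3g",
                 fold, e, 1 / e))
  fold * (1 - e) / (1 - fold * e)
}

#' Simulate chromosome-enriched long-read mappings
#'
#' Draws each read's chromosome from the enrichment-boosted sampling
#' null, its length from a truncated log-normal and its start uniformly,
#' until the configured total of mapped bases is reached. Reads align
#' end-to-end (target span equals read length) at mapping quality 60.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_mappings`: `records` (mapping-record
#'   data.frame, see [read_paf()]), `truth` (list: `fold_real` — the
#'   ground-truth realized enrichment fold on the target,
#'   `sampling_prob` — per-chromosome read probabilities).
#' @export
gen_mappings <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gm <- config$genome
  e <- expected_fractions(gm)
  boost <- ifelse(names(e) == config$target_chrom, config$enrichment_fold, 1)
  p <- e * boost / sum(e * boost)
  fold_real <- p[[config$target_chrom]] / e[[config$target_chrom]]
  truth <- list(fold_real = fold_real, sampling_prob = p)
  if (config$total_mapped_bases == 0)
    return(structure(list(records = empty_mappings(), truth = truth),
                     class = "sim_mappings"))
  m <- config$read_length_mean; s <- config$read_length_sd
  meanlog <- log(m^2 / sqrt(m^2 + s^2))
  sdlog <- sqrt(log(1 + s^2 / m^2))
  chrom_len <- stats::setNames(gm$chromosomes$length, gm$chromosomes$name)
  records <- with_seed(child_seed(config$seed, "mappings"), {
    n_guess <- ceiling(config$total_mapped_bases / m * 1.2) + 10
    len <- pmax(500, round(stats::rlnorm(n_guess, meanlog, sdlog)))
    while (sum(len) < config$total_mapped_bases)
      len <- c(len, pmax(500, round(stats::rlnorm(n_guess, meanlog, sdlog))))
    n <- which(cumsum(len) >= config$total_mapped_bases)[1]
    len <- len[seq_len(n)]
    chrom <- sample(names(p), n, replace = TRUE, prob = p)
    len <- pmin(len, chrom_len[chrom])
    start <- floor(stats::runif(n) * (chrom_len[chrom] - len + 1))
    data.frame(
      read_id = sprintf("read%07d", seq_len(n)),
      read_length = len, chrom = chrom, start = start, end = start + len,
      matched_bases = round(len * 0.9), mapq = 60L, is_primary = TRUE,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(list(records = records, truth = truth), class = "sim_mappings")
}

# sample n SV loci of given sizes uniformly outside exclusion zones
place_svs <- function(genome, zones, sizes) {
  if (length(sizes) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      stringsAsFactors = FALSE))
  allowed <- GenomicRanges::setdiff(
    gr_from_bed0(genome$chromosomes$name, 0, genome$chromosomes$length,
                 seqlens = stats::setNames(genome$chromosomes$length,
                                           genome$chromosomes$name)),
    zones)
  bed <- gr_to_bed0(allowed)
  bed <- bed[bed$end - bed$start > max(sizes) + 1, , drop = FALSE]
  if (nrow(bed) == 0) stop("no allowed region large enough for the SV sizes")
  w <- bed$end - bed$start
  seg <- sample.int(nrow(bed), length(sizes), replace = TRUE, prob = w)
  start <- bed$start[seg] +
    floor(stats::runif(length(sizes)) * (w[seg] - sizes))
  data.frame(chrom = bed$chrom[seg], start = start, stringsAsFactors = FALSE)
}

draw_sizes <- function(n, mixture) {
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  pmax(50, round(stats::rnorm(n, mixture$mean[comp], mixture$sd[comp])))
}

#' Simulate paired SV callsets with known ground truth
#'
#' Places true insertions and deletions uniformly outside the
#' centromere/telomere exclusion zones, then derives two callsets: an
#' assembly-based caller (A, exact breakpoints, always precise) and a
#' read-based caller (B, Gaussian breakpoint jitter, precise with a
#' configurable probability), each detecting a true variant
#' independently with its configured sensitivity and each padded with
#' false positives drawn from the same size mixture.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_svsets`: `truth`, `callset_a`,
#'   `callset_b` (SV call data.frames), `pairing` (data.frame
#'   `truth_id`, `id_a`, `id_b`; `NA` where undetected), `zones` (the
#'   exclusion `GRanges` used).
#' @export
gen_svsets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gm <- config$genome
  zones <- exclusion_zones(gm, config$exclusion_flank)
  with_seed(child_seed(config$seed, "svsets"), {
    n <- config$n_true_svs
    sizes <- draw_sizes(n, config$sv_size_mixture)
    pos <- place_svs(gm, zones, sizes)
    p_del <- config$del_ins_ratio / (config$del_ins_ratio + 1)
    svtype <- ifelse(stats::runif(n) < p_del, "DEL", "INS")
    truth <- data.frame(
      id = sprintf("TRU%05d", seq_len(n)), chrom = pos$chrom,
      start = pos$start,
      end = ifelse(svtype == "INS", pos$start, pos$start + sizes),
      svtype = svtype, length = sizes, precise = rep(TRUE, n),
      source = rep("truth", n), stringsAsFactors = FALSE)
    det_a <- stats::runif(n) < config$caller_sensitivity[1]
    det_b <- stats::runif(n) < config$caller_sensitivity[2]

    mk_fp <- function(n_fp, prefix, jitter) {
      if (n_fp == 0) return(empty_calls())
      fs <- draw_sizes(n_fp, config$sv_size_mixture)
      fp_pos <- place_svs(gm, zones, fs)
      ft <- ifelse(stats::runif(n_fp) < p_del, "DEL", "INS")
      data.frame(
        id = sprintf("%s_FP%04d", prefix, seq_len(n_fp)),
        chrom = fp_pos$chrom, start = fp_pos$start,
        end = ifelse(ft == "INS", fp_pos$start, fp_pos$start + fs),
        svtype = ft, length = fs,
        precise = if (jitter) stats::runif(n_fp) < config$precise_prob else TRUE,
        source = prefix, stringsAsFactors = FALSE)
    }

    callset_a <- truth[det_a, , drop = FALSE]
    callset_a$id <- sprintf("A%05d", seq_len(nrow(callset_a)))
    callset_a$source <- rep("caller_a", nrow(callset_a))
    callset_a <- rbind(callset_a,
                       mk_fp(round(config$fp_rate * nrow(callset_a)),
                             "caller_a", jitter = FALSE))

    callset_b <- truth[det_b, , drop = FALSE]
    nb <- nrow(callset_b)
    if (nb > 0) {
      chrom_len <- stats::setNames(gm$chromosomes$length, gm$chromosomes$name)
      shift <- round(stats::rnorm(nb, 0, config$breakpoint_jitter_sd))
      new_start <- pmax(0, pmin(callset_b$start + shift,
                                chrom_len[callset_b$chrom] - callset_b$length))
      callset_b$start <- new_start
      callset_b$end <- ifelse(callset_b$svtype == "INS", new_start,
                              new_start + callset_b$length)
      callset_b$precise <- stats::runif(nb) < config$precise_prob
      callset_b$id <- sprintf("B%05d", seq_len(nb))
      callset_b$source <- "caller_b"
    }
    callset_b <- rbind(callset_b,
                       mk_fp(round(config$fp_rate * nb), "caller_b",
                             jitter = TRUE))
    rownames(callset_a) <- rownames(callset_b) <- NULL
    pairing <- data.frame(
      truth_id = truth$id,
      id_a = ifelse(det_a, c(NA, callset_a$id)[cumsum(det_a) * det_a + 1],
                    NA_character_),
      id_b = ifelse(det_b, c(NA, callset_b$id)[cumsum(det_b) * det_b + 1],
                    NA_character_),
      stringsAsFactors = FALSE)
    structure(list(truth = truth, callset_a = callset_a,
                   callset_b = callset_b, pairing = pairing, zones = zones),
              class = "sim_svsets")
  })
}

#' Simulate a superpopulation-stratified SV genotype table
#'
#' Each variant receives a superpopulation-specific allele frequency
#' drawn from a Beta distribution around the configured superpopulation
#' mean; diploid genotypes are sampled binomially. A configured fraction
#' of variants is made multiallelic and another forced to allele count
#' <= 2, to exercise the population filters.
#'
#' @param truth_svs SV call data.frame providing variant ids and
#'   positions (e.g. the truth set of [gen_svsets()]).
#' @param config a [sim_config()].
#' @return list of class `sim_population`: `table` (an
#'   [sv_genotype_table()]), `truth` (list: `superpop_freqs` configured
#'   means, `af` variant x superpop matrix of drawn frequencies,
#'   `multiallelic`, `low_ac` logical vectors).
#' @export
gen_population <- function(truth_svs, config) {
  stopifnot(inherits(config, "sim_config"))
  nv <- nrow(truth_svs)
  pops <- names(config$superpop_freqs)
  per_pop <- floor(config$n_samples / length(pops))
  counts <- rep(per_pop, length(pops))
  counts[seq_len(config$n_samples - per_pop * length(pops))] <-
    counts[seq_len(config$n_samples - per_pop * length(pops))] + 1
  sample_map <- stats::setNames(
    rep(pops, counts),
    sprintf("S%04d", seq_len(sum(counts))))
  names(sample_map) <- sprintf("%s%04d", rep(pops, counts),
                               unlist(lapply(counts, seq_len)))
  with_seed(child_seed(config$seed, "population"), {
    k <- config$af_concentration
    af <- matrix(0, nrow = nv, ncol = length(pops),
                 dimnames = list(truth_svs$id, pops))
    for (p in pops) {
      m <- config$superpop_freqs[[p]]
      if (nv > 0 && m > 0) af[, p] <- stats::rbeta(nv, k * m, k * (1 - m))
    }
    geno <- matrix(NA_integer_, nrow = nv, ncol = length(sample_map),
                   dimnames = list(NULL, names(sample_map)))
    for (p in pops) {
      cols <- which(sample_map == p)
      geno[, cols] <- stats::rbinom(nv * length(cols), 2, rep(af[, p],
                                                              length(cols)))
    }
    low_ac <- stats::runif(nv) < config$low_ac_frac
    if (any(low_ac)) {
      geno[low_ac, ] <- 0L
      for (i in which(low_ac))
        geno[i, sample.int(ncol(geno), 1)] <- sample(0:2, 1)
    }
    multi <- stats::runif(nv) < config$multiallelic_frac
    variants <- data.frame(
      id = truth_svs$id, chrom = truth_svs$chrom, pos = truth_svs$start,
      n_alt_alleles = ifelse(multi, 2L, 1L), stringsAsFactors = FALSE)
    structure(list(
      table = sv_genotype_table(variants, geno, sample_map),
      truth = list(superpop_freqs = config$superpop_freqs, af = af,
                   multiallelic = multi, low_ac = low_ac)),
      class = "sim_population")
  })
}

#' Simulate repeat annotations with controlled divergence distributions
#'
#' For each configured repeat class, hits are generated until they tile
#' the configured fraction of the genome exactly (the last hit is
#' trimmed); each hit's divergence is drawn from the class Normal
#' distribution (truncated to [0, 40]%) and converted to transition/
#' transversion proportions by inverting the K2P estimator at a 2:1
#' transition:transversion ratio.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_repeats`: `hits` (data.frame with `p`,
#'   `q` and `divergence`), `truth` (the `repeat_classes` table),
#'   `denominator_bp`.
#' @export
gen_repeats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gm <- config$genome
  denom <- sum(as.numeric(gm$chromosomes$length))
  rc <- config$repeat_classes
  chrom_len <- stats::setNames(gm$chromosomes$length, gm$chromosomes$name)
  hits <- with_seed(child_seed(config$seed, "repeats"), {
    out <- lapply(seq_len(nrow(rc)), function(i) {
      target <- rc$fraction[i] * denom
      if (target <= 0) return(NULL)
      mlen <- rc$mean_hit_length[i]
      lens <- numeric(0)
      while (sum(lens) < target) {
        need <- ceiling((target - sum(lens)) / mlen * 1.2) + 5
        lens <- c(lens, pmax(50, round(stats::rnorm(need, mlen, 0.3 * mlen))))
      }
      n <- which(cumsum(lens) >= target)[1]
      lens <- lens[seq_len(n)]
      lens[n] <- lens[n] - (sum(lens) - target)  # exact class fraction
      div_pct <- round(pmin(40, pmax(0, stats::rnorm(
        n, rc$div_mean_pct[i], rc$div_sd_pct[i]))), 2)
      pq <- k2p_invert(div_pct / 100)
      chrom <- sample(names(chrom_len), n, replace = TRUE,
                      prob = chrom_len / denom)
      start <- floor(stats::runif(n) * pmax(1, chrom_len[chrom] - lens))
      data.frame(chrom = chrom, start = start, end = start + lens,
                 repeat_name = sprintf("%s_rep", basename(rc$class_family[i])),
                 class_family = rc$class_family[i],
                 p = pq$p, q = pq$q, divergence = div_pct / 100,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, out)
  })
  if (is.null(hits))
    hits <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), repeat_name = character(0),
                       class_family = character(0), p = numeric(0),
                       q = numeric(0), divergence = numeric(0))
  structure(list(hits = hits, truth = rc, denominator_bp = denom),
            class = "sim_repeats")
}

#' Simulate an assembly: contigs and alignment blocks over a reference
#'
#' Partitions a reference of length `reference_length` at
#' `n_breakpoints` internal breakpoints; with probability
#' `feature_weight` a breakpoint falls uniformly inside a supplied
#' feature interval (emulating contigs breaking at segmental
#' duplications and satellites), otherwise uniformly anywhere. Alignment
#' blocks map each contig back to its reference span minus `margin`
#' unaligned bp at each end.
#'
#' @param reference_length reference length (bp).
#' @param n_breakpoints number of internal contig boundaries.
#' @param features data.frame of feature intervals (`chrom`, `start`,
#'   `end`) on the reference; required when `feature_weight > 0`.
#' @param feature_weight probability a breakpoint is drawn from the
#'   features.
#' @param margin unaligned bp trimmed from each contig end in the
#'   alignment blocks.
#' @param seed integer seed.
#' @param ref_name reference sequence name.
#' @return list of class `sim_contigs`: `contig_lengths` (named),
#'   `blocks` (alignment-block data.frame), `breakpoints` (positions).
#' @export
gen_contigs <- function(reference_length, n_breakpoints, features = NULL,
                        feature_weight = 0, margin = 0, seed = 1,
                        ref_name = "ref") {
  stopifnot(reference_length > 0, n_breakpoints >= 0,
            feature_weight >= 0, feature_weight <= 1)
  if (feature_weight > 0 && (is.null(features) || nrow(features) == 0))
    stop("feature_weight > 0 requires feature intervals")
  with_seed(seed, {
    from_feat <- stats::runif(n_breakpoints) < feature_weight
    bp <- numeric(n_breakpoints)
    if (any(from_feat)) {
      w <- features$end - features$start
      fi <- sample.int(nrow(features), sum(from_feat), replace = TRUE, prob = w)
      bp[from_feat] <- features$start[fi] +
        floor(stats::runif(sum(from_feat)) * w[fi])
    }
    bp[!from_feat] <- floor(stats::runif(sum(!from_feat)) *
                              (reference_length - 1)) + 1
    bp <- sort(unique(pmin(pmax(bp, 1), reference_length - 1)))
    cuts <- c(0, bp, reference_length)
    lens <- diff(cuts)
    names(lens) <- sprintf("ctg%04d", seq_along(lens))
    ok <- lens > 2 * margin
    blocks <- data.frame(
      query = names(lens)[ok],
      qstart = margin, qend = lens[ok] - margin,
      target = ref_name,
      tstart = cuts[-length(cuts)][ok] + margin,
      tend = cuts[-1][ok] - margin,
      identity = pmin(1, stats::rnorm(sum(ok), 0.97, 0.01)),
      strand = "+", stringsAsFactors = FALSE, row.names = NULL)
    structure(list(contig_lengths = lens, blocks = blocks, breakpoints = bp),
              class = "sim_contigs")
  })
}

#' Write every synthetic dataset plus ground-truth manifests to a
#' directory
#'
#' Emits the PAF mappings, both SV callsets (Assemblytics-style BED and
#' VCF), the genotype VCF with its sample map, the RepeatMasker-style
#' `.out` and p/q TSV, the genome model TSV and JSON ground-truth
#' manifests, so the whole pipeline can be run from files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the generated objects.
#' @export
write_synthetic_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  maps <- gen_mappings(config)
  svs <- gen_svsets(config)
  pop <- gen_population(svs$truth, config)
  reps <- gen_repeats(config)
  write_genome_tsv(config$genome, pth("genome.tsv"))
  write_paf(maps$records, pth("mappings.paf"), config$genome)
  write_assemblytics_bed(svs$callset_a, pth("callset_a.bed"))
  write_sv_vcf(svs$callset_b, pth("callset_b.vcf"), config$genome)
  write_genotype_vcf(pop$table, pth("population.vcf"))
  data.table::fwrite(
    data.frame(sample = names(pop$table$sample_map),
               superpop = unname(pop$table$sample_map)),
    pth("sample_map.tsv"), sep = "\t", col.names = FALSE, quote = FALSE)
  write_repeatmasker_out(reps$hits, pth("repeats.out"))
  write_repeat_tsv(reps$hits, pth("repeats.tsv"))
  data.table::fwrite(svs$truth, pth("truth_svs.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(svs$pairing, pth("truth_pairing.tsv"), sep = "\t",
                     quote = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         fold_real = maps$truth$fold_real,
         sampling_prob = as.list(maps$truth$sampling_prob),
         superpop_freqs = as.list(config$superpop_freqs),
         del_ins_ratio = config$del_ins_ratio),
    pth("truth_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(mappings = maps, svsets = svs, population = pop,
                 repeats = reps))
}
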