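# chromsort

Downstream analysis for **chromosome flow-sorting enrichment
experiments** sequenced with long reads — the setting in which a single
chromosome type is physically isolated by flow cytometry and sequenced
(e.g. on a nanopore device), yielding a chromosome-enriched read set
and, after assembly, a single-chromosome assembly to compare against a
reference.

The package is aimed at people running or evaluating such experiments.
It covers five analysis stages plus a synthetic-data generator with
known ground truth so every stage is testable without sequencing data:

1. **Coverage enrichment** — per-chromosome aligned-base summaries from
   PAF mappings and enrichment/depletion folds against a diploid-male
   sampling null: the expected base fraction of chromosome *c* is
   *e<sub>c</sub>* = *L<sub>c</sub>k<sub>c</sub>* / Σ*L<sub>j</sub>k<sub>j</sub>*
   (length × copy number), and the fold is *f<sub>c</sub>* =
   *o<sub>c</sub>*/*e<sub>c</sub>* with Σ*e<sub>c</sub>f<sub>c</sub>* = 1.
2. **Assembly evaluation** — Nx contiguity statistics, assembly↔reference
   mutual coverage from alignment blocks (PAF or nucmer
   `show-coords -T -H`), and a permutation test for contig-boundary
   association with annotation features such as segmental duplications.
3. **SV harmonization** — filtering (centromere/telomere exclusion
   zones, "precise" flag, ≥ 50 bp), one-to-one intersection of an
   assembly-based (Assemblytics-style BED) and a read-based (VCF)
   callset under the 40%-"either" overlap rule
   max(ov/len<sub>a</sub>, ov/len<sub>b</sub>), genic/coding annotation,
   novelty classification against reference callsets, and size spectra.
4. **Population frequencies** — superpopulation allele frequencies from
   a genotype VCF after allele-count (≤ 2) and multiallelic filters.
5. **Repeat landscapes** — Kimura 2-parameter divergence
   *K* = −½ ln[(1−2*p*−*q*)√(1−2*q*)] of repeat copies to consensus,
   binned into class × divergence landscapes and compared between
   assemblies.

## Worked example

Simulate a flow-sorted chromosome 1 experiment at the default study
conditions (8-fold target enrichment on a scaled diploid-male genome,
Alu-like 300 bp insertion component, 2:1 deletion bias, 1000-Genomes-
like superpopulation frequencies), then analyze it:

```r
library(chromsort)

cfg <- sim_config(seed = 42, total_mapped_bases = 5e7,
                  n_true_svs = 2500, n_samples = 500)

## enrichment
m   <- gen_mappings(cfg)
enr <- enrichment_folds(summarize_mappings(m$records, cfg$genome),
                        cfg$genome, "chr1")
enr
#> enrichment_report: chr1 at 7.94-fold (66.3% of aligned bases); mean off-target fold 0.35

## SV harmonization
sv    <- gen_svsets(cfg)
zones <- exclusion_zones(cfg$genome, cfg$exclusion_flank)
A     <- filter_calls(sv$callset_a, zones)
B     <- filter_calls(sv$callset_b, zones, require_precise = TRUE)
isec  <- intersect_callsets(A, B)
spec  <- size_spectrum(rbind(A, B), bin_width = 50, range = c(0, 1000))
#> A: 2207 calls, B: 1751 calls, matches: 1276 (27.1% unique to B)
#> modal size bin center: 325 bp, DEL:INS ratio 1.89

## superpopulation allele frequencies
pop <- gen_population(sv$truth, cfg)
fr  <- superpop_frequencies(filter_variants(pop$table))
fr$summary
#>   superpop mean_af_pct median_af_pct n_samples
#> 1      AFR        9.95             9       100
#> 2      AMR       18.35            18       100
#> 3      EAS       20.64            20       100
#> 4      EUR       14.79            14       100
#> 5      SAS       18.50            18       100
```

Reading the output: the estimated 7.94-fold enrichment recovers the
generator's ground-truth fold of 8 (the target chromosome holds 66% of
aligned bases versus 8.3% expected under random sampling, while every
other chromosome is depleted to ~0.35-fold); the SV size spectrum peaks
in the 300–350 bp bin, the mobile-element signature planted by the
size mixture; and the recovered superpopulation means sit within ±1
point of the configured 20.5 / 18.8 / 18.4 / 14.7 / 9.8 percent.

`run_demo(seed = 1, out_dir = "demo")` chains every stage — simulation,
enrichment, assembly statistics, SV merging, novelty, population
frequencies, landscapes — and writes all input files, ground-truth
manifests and a single `report.json`; identical seeds give
byte-identical reports.

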