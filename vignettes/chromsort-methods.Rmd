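---
title: "Methods: analysis of flow-sorted single-chromosome sequencing"
author: "chromsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysis of flow-sorted single-chromosome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromsort)
```

## The problem

Flow sorting (flow karyotyping) physically isolates one chromosome type
from a cell line by flow cytometry, so that long-read sequencing of the
sorted material is strongly enriched for the target chromosome. The
downstream questions this package answers are: how enriched is the
sequencing, how contiguous and complete is the resulting single-
chromosome assembly, which structural variants (SVs) do an
assembly-based and a read-based caller agree on, which of those are
novel relative to population resources and at what allele frequencies
known ones segregate, and whether the assembly resolves the repeat
landscape as well as the reference does.

All stages run equally on real caller/aligner outputs (PAF,
`show-coords`, VCF, Assemblytics-style BED, RepeatMasker `.out`) and on
the package's own synthetic data, which carries known ground truth.

## Enrichment model

The sampling null is "a base drawn uniformly at random from a diploid
male genome": chromosome $c$ with length $L_c$ and copy number $k_c$
(autosomes 2, X and Y 1) is expected to contribute the fraction

$$e_c = \frac{L_c k_c}{\sum_j L_j k_j}.$$

Given a coverage summary, the enrichment fold of chromosome $c$ is
$f_c = o_c / e_c$ where $o_c$ is its observed fraction of aligned
bases. By construction $\sum_c e_c f_c = \sum_c o_c = 1$; this
conservation identity is property-tested on every report. Folds above 1
indicate enrichment (the sorting target), folds below 1 depletion.

Aligned bases are accounted as the *target span* of each primary
alignment (`end − start`), not column-matched bases. Span accounting is
robust across input dialects (PAF column 11 vs CIGAR-derived BAM dumps)
and matches "Gb mapped" style reporting. Note that published per-
chromosome Gb and mean-depth figures for such experiments are not
always mutually consistent under any single accounting convention; this
package does not attempt to reconcile them and reports folds from
fractions of *mapped* bases. The off-target depletion summary is
reported both as an unweighted chromosome mean and as an
aligned-base-weighted mean, since the choice of summary is a genuine
free parameter.

Coordinates are 0-based half-open everywhere internally; BED is native,
VCF/GFF positions are shifted by −1 on read and restored on write.
Telomeres are modeled as the chromosome ends (positions 0 and $L$), so
"within 2 Mb of a telomere" means the first and last 2 Mb; no separate
telomere track is consumed. Exclusion zones are the union of the two
telomere flanks and the centromere interval padded by the same flank,
clipped and merged per chromosome.

## Assembly evaluation

* `nx_statistic` uses the standard descending-cumulative rule; ties at
  exactly x% include the boundary contig, matching common assembler
  reporting.
* `mutual_coverage` merges overlapping alignment blocks before summing,
  so it is invariant to splitting blocks; when the reference carries
  unresolved N-gaps the caller should pass the resolved (non-N) length
  as the denominator.
* `boundary_feature_test` formalizes the observation that contig
  boundaries concentrate in segmental duplications and satellites: each
  contig's outermost aligned reference coordinates are its projected
  boundaries; the statistic is the fraction of boundaries within a
  window of a feature, and the null redraws the same number of points
  uniformly over the aligned portion of the reference. The empirical
  p-value uses the add-one estimator $(1 + \#\{null \ge obs\})/(1 +
  n_{perm})$, which never returns 0. Contigs with no alignments are
  excluded from the statistic and counted separately.

## SV harmonization

Calls are normalized to a common table (`id`, `chrom`, `start`, `end`,
`svtype`, `length`, `precise`, `source`); insertions have `end ==
start` and are anchored at their breakpoint. Assemblytics-style types
map onto the caller-comparable vocabulary (expansions to INS,
contractions to DEL); breakpoint-type records are out of scope.

Filters mirror standard practice for this kind of experiment: a 2 Mb
centromere/telomere exclusion flank, the read-based caller's "precise"
flag, and the 50 bp SV size definition. Filtering is idempotent, and a
call starting exactly at a zone's half-open end is retained.

The overlap score between two span-type calls is the "either" rule
$\max(ov/len_a, ov/len_b)$ with threshold 0.4 ("over 40% in either");
the same rule and threshold are reused for the caller-vs-caller
intersection, which keeps a single coherent metric across comparisons.
Insertions have no reference span, so INS pairs score
$\min(len)/\max(len)$ when their breakpoints lie within a 500 bp
window — the standard merging heuristic for long-read insertion calls.
Both the threshold and the window are exposed as arguments.

Intersection is one-to-one and deterministic. Pairs are seeded greedily
by descending score (ties: smaller breakpoint distance, then
lexicographic ids) and then completed to a maximum-cardinality matching
by augmenting paths. The augmentation step exists because pure
score-greedy matching can strand a matchable call on dense instances
(two calls competing for one partner while another partner goes
unused); with augmentation the match count is a well-defined quantity —
the maximum-cardinality one-to-one matching — and is verified in the
tests against an exhaustive brute-force search on small random
instances. Novelty classification deliberately does *not* use
one-to-one matching: a call is "known" in a reference set if any
compatible call exceeds the score threshold, since a reference set may
legitimately describe one locus with several records.

Uniqueness percentages are reported in both directions
(`pct_unique_a`, `pct_unique_b` = percent of each callset outside the
matching); published asymmetric summaries of this kind cannot always be
reproduced from the printed set sizes in both directions, so no attempt
is made to force agreement beyond the arithmetic itself.

## Population frequencies

Genotypes are alt-allele dosages in {0, 1, 2, missing}. The filters
drop variants with global allele count ≤ 2 (computed over non-missing
genotypes) and multiallelic records. Per superpopulation, a variant's
allele frequency is the dosage sum over twice the non-missing sample
count; missing genotypes leave the denominator rather than being
imputed. The single-number-per-superpopulation summary is the
unweighted mean over variants, in percent — whether published figures
of this kind are means or medians is typically unstated, so the median
is emitted alongside.

## Repeat landscapes

Divergence of a repeat copy to its consensus uses the Kimura
2-parameter estimator
$K = -\tfrac12 \ln\!\big[(1-2p-q)\sqrt{1-2q}\big]$ on the transition
($p$) and transversion ($q$) proportions. $K$ is monotone in both
arguments and saturates when $1-2p-q \le 0$ or $1-2q \le 0$; saturated
hits are excluded from landscapes with a warning. The CpG-adjusted
variant of the estimator is intentionally not implemented — plain K2P
only. Landscapes bin each hit's divergence at 1% width over 0–50% with
an overflow bin, accumulating hit length over a caller-supplied
assembly denominator; total landscape mass equals total non-saturated
hit length over the denominator, exactly. When a RepeatMasker `.out`
file supplies a precomputed divergence column, it is binned directly;
$p$/$q$ pairs come from the simplified TSV dialect.

Landscape comparison reports, per repeat class, the annotated
proportion in each assembly and their ratio (the repeat-resolution
measure), plus a cosine similarity over the flattened class × bin
matrices.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions of a flow-sorted
chromosome 1 experiment on a diploid male:

| parameter | default | rationale |
|---|---|---|
| target fold | 8 | realized enrichment of the sorting target |
| read lengths | log-normal, mean = sd = 7 kb, min 500 bp | long-tailed ONT-like distribution |
| total mapped bases | 1.4 Gb (≈200,000 reads) | recovery-test scale |
| SV size mixture | 0.4·N(300, 30) + 0.3·N(100, 40) + 0.3·N(1200, 800), min 50 bp | Alu-like 300 bp component over a broad background |
| DEL:INS ratio | 2 | deletion bias of nanopore callsets |
| caller sensitivities | 0.8 / 0.7, independent | plausible assembly-based vs read-based recall |
| breakpoint jitter | N(0, 20 bp), read-based calls only | read-based breakpoint uncertainty |
| precise flag | P = 0.9 | exercise the precision filter |
| false positives | 10% of detections per caller | exercise intersection and novelty |
| superpop mean AF | EAS .205, SAS .188, AMR .184, EUR .147, AFR .098 | continental stratification of shared SVs |
| AF spread | Beta, concentration 30 | between-variant frequency variation |
| repeat classes | 5 classes, 3–22% mean divergence | distinct landscape modes per class |

The default genome is the GRCh38-like preset scaled to 10% (relative
chromosome sizes, copy numbers and centromere positions preserved),
with the exclusion flank scaled identically, so simulations complete in
seconds. Chromosome sampling probabilities multiply the expected
fraction by a boost on the target; the boost realizing a requested fold
$F$ is $b = F(1-e_t)/(1-Fe_t)$, which also caps the feasible fold at
$1/e_t$.

Deliberately *not* modeled: sequence-level reads (no FASTQ, no error
model), flow-cytometry physics, basecalling/assembly engines, linkage
between variants, genotype missingness, non-uniform SV placement within
allowed regions, and correlation between the two callers' errors.
Passing recovery tests therefore demonstrates that the *analysis* code
measures what it claims on data with known truth — not that real
sorting experiments will match these numbers.

All generators are pure functions of (config, seed). Each draws from
its own stream via a stable string hash of (master seed, stream name),
so enlarging one dataset never perturbs another. Every bundle is
written alongside JSON/TSV ground-truth manifests and round-trips
through the package's readers losslessly.

## Numerical choices

* K2P inversion (generator): divergences are rounded to 0.01% and
  solved by `uniroot` per unique value at a fixed 2:1
  transition:transversion ratio, to tolerance 1e-12.
* Nx ties include the boundary contig; N100 is the minimum length.
* Empty inputs: an empty PAF is a valid empty mapping set, but
  enrichment on zero aligned bases is an error ("no aligned bases");
  an empty repeat class set yields a valid header-only `.out` file.
* Chromosomes with zero expected fraction but observed bases are
  reported with an infinite fold and a warning rather than an error.
* The permutation null seeds its RNG explicitly and restores the
  caller's RNG state afterwards, as do all generators.

## Problem sizes

The shipped tests and the acceptance script use: ~200,000 simulated
reads for enrichment recovery, 2,500 true SVs (~4,000 calls) for the
size-spectrum mode, 1,000 samples × 400 variants for allele-frequency
recovery, and ≤ 15-call instances for exhaustive matching
verification — sizes at which every stochastic recovery target sits
well inside its tolerance.

## Known limitations

* The enrichment estimate is fraction-of-mapped-bases based; it cannot
  measure absolute yield or unmapped contamination.
* `boundary_feature_test` projects each contig to its single most
  frequent target sequence; split alignments across references
  contribute only their main target.
* The Assemblytics reader maps expansion/contraction types onto
  INS/DEL; information distinguishing tandem from dispersed events is
  not retained.
* The genotype VCF writer emits biallelic-style GT strings even for
  records flagged multiallelic (dosage semantics are preserved; allele
  identity is not).
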