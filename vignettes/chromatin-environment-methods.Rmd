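---
title: "Chromatin-state dynamics and environment analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state dynamics and environment analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdyn)
```

chromdyn integrates histone-mark chromatin states with gene regulation
across male germ cell differentiation stages (germline stem cells, GSC;
primary spermatocytes, SCI; round spermatids, RS). Its components mirror a
complete epigenomic study: chromatin-state segmentation from binarized
histone-mark tracks, ChIP-seq peak annotation and cross-stage dynamics,
enhancer classification and gene linking, promoter chromatin-environment
assignment, spike-in-anchored differential expression, heterologous
spike-in scaling for CUT&Tag, and region-overlap permutation tests. A
synthetic-data generator with planted ground truth stands behind the test
suite, so every claim the package makes about itself is checked against a
known truth.

This vignette records the models, the parameters that matter, the
numerical choices, and the design decisions taken where the design was
genuinely open.

## Coordinate conventions

All user-facing tables use 0-based half-open intervals (the BED
convention); GTF input (1-based inclusive) is converted on read. The TSS
of a minus-strand gene at `[start, end)` is `end - 1`. Peak strand is
ignored throughout — ChIP peaks are unstranded. Windows that extend past a
chromosome end are clipped rather than rejected, so promoters near
telomeres stay in the analysis with their actual (shorter) window length
as the denominator of coverage fractions.

## The chromatin-state hidden Markov model

`fit_state_model()` learns a hidden Markov model over fixed 200 bp bins in
which each hidden state emits the six histone marks (H3K4me1, H3K4me3,
H3K27ac, H3K27me3, H3K36me3, H3K9me3) independently Bernoulli given the
state — the emission model of the widely used chromatin-state discovery
tools. Chromosomes are independent sequences sharing one transition matrix
and one initial distribution.

Assumptions worth stating: mark calls are conditionally independent given
the state (violated in real data where marks co-occur within a bin for
technical reasons; the state vocabulary absorbs most of this), bin-level
binarization is adequate (200 bp matches nucleosome-scale resolution of
the marks), and state runs are geometric in length (a first-order Markov
property; real domains are burstier, which mostly affects rare short
states).

* **Binarization** (`binarize_track()`): a bin is called present when the
  upper-tail Poisson probability `P(X >= count | lambda = global_rate)` is
  at most `1e-4`. The threshold is the conventional background-significance
  cutoff for this step; it is exposed as `p_threshold`.
* **Fitting**: Baum–Welch EM with scaled forward–backward recursions
  (compiled code; log-emissions are computed per bin with emission
  probabilities clipped to `[1e-12, 1 - 1e-12]` so deterministic 0/1
  emission models remain decodable). The log-likelihood is non-decreasing
  by construction and fitting stops at a relative change below `tol`
  (default `1e-4`) or `max_iter = 200`.
* **Initialization**: emissions start from randomly drawn observed mark
  patterns, blended toward 0.5 and jittered; transitions start sticky
  (0.9 self). Five seeded restarts are fitted and the best likelihood
  kept. EM on this model has local optima; restarts are the standard
  insurance. Results are bit-reproducible given `seed`.
* **Decoding** (`decode_segmentation()`): per-bin argmax of the posterior
  (forward–backward), not Viterbi, matching the segmentation behaviour of
  the established tools; ties (numerically exact equal posteriors) resolve
  to the lower state index.
* **One-state edge case**: with `n_states = 1` the MLE is closed-form (the
  empirical mark frequencies) and is returned exactly.
* **State names**: learned states are numbered `S1..Sn`. Mnemonic labels
  (TSSA, TxWk, EnhA, ...) are a biological interpretation of the emission
  rows, so they are supplied by the user (or by a labelled
  `state_model()`), never guessed by the fitter. The package supports
  learning across several concatenated track sets but makes no claim of
  reproducing any published model's state numbering.

`pool_states()` collapses the 18-state vocabulary to 13 (TSS-flanking
states to TSSFlnk, the two genic-enhancer states to EnhG, the two polycomb
states to ReprPC, the three quiescent states to Quies), merging adjacent
runs that acquire the same label. `categorize_state()` maps the 13 labels
to six categories: active (TSSA, Tx, EnhG, EnhA), weak (TSSFlnk, TxWk,
EnhW), heterochromatin (ZNF/Rpts, Het), bivalent (TssBiv, EnhBiv),
polycomb (ReprPC), quiescent (Quies).

Parameter recovery is validated by simulation: a 3-state, 6-mark model
with self-transition 0.95 on 50,000 bins is re-fitted from its own
emissions; the test suite requires emission recovery within 0.05 after
best state matching and posterior-decoding accuracy of at least 90%.

## Peak annotation and cross-stage dynamics

`annotate_peaks()` assigns each peak one of four categories with a fixed
priority — promoter (overlap with TSS ± 3 kb, strand-aware anchor) >
intragenic (gene-body overlap) > downstream (within 3 kb past the 3' end)
> distal intergenic. The upstream tools collapse richer annotations into
these four without stating a precedence rule; an explicit priority makes
the collapse deterministic, and the 3 kb downstream window mirrors the TSS
window. Both windows are arguments.

`classify_stage_dynamics()` union-merges all stages' peaks into maximal
regions (book-ended intervals merge — the BEDtools merge convention),
scores presence per stage as ≥ 1 bp overlap (`min_overlap`), and names the
class from the presence pattern: all stages → `common`, one stage →
`<stage>-spe`, otherwise the joined stage names (`GSC-SCI`, `GSC-RS`,
...). All seven patterns of a three-stage design are reported, so either
reading of "common" (all three stages versus pairwise chains) is
recoverable from the output. Classes with at most 100 regions are flagged
`minor` rather than dropped, mirroring the usual alluvial-plot filter
while keeping the information.

`chromosome_peak_density()` reports peaks per Mb per chromosome;
`ratio_between_stages()` forms per-chromosome fold changes with the
conventions ratio = `Inf` when only the second stage has peaks and missing
when both are empty.

`tss_profile()` builds meta-gene profiles: an upstream flank at native bin
resolution, the gene body rescaled to 100 meta-bins, a downstream flank;
minus-strand genes are flipped so positions run 5' to 3'; genes are
grouped into expression deciles computed within the sample. Genes shorter
than two signal bins are excluded and counted. Flank width (1.5 kb) and
body meta-bin count are arguments; the defaults are desk-scale choices,
not biological constants.

## Chromatin environment, enhancers and gene linking

`assign_region_state()` implements the predominant-state rule: the state
covering the most bp of a region wins, with its coverage fraction
reported. Exact ties are broken by a fixed priority — category order
active > bivalent > polycomb > weak > heterochromatin > quiescent, then
lexicographic — because coverage ties, though rare, must resolve
deterministically. The runner-up state and fraction are reported as the
ambiguity check; in practice the second fraction is far below the first.
Uncovered bp never outvote annotated states; a region is `"unannotated"`
only when nothing covers it. `gene_promoter_environment()` applies this to
TSS ± 3 kb windows.

Enhancers are the maximal runs of the four enhancer states (EnhA, EnhG,
EnhW, EnhBiv). H3K79me2 status is binary: a region is `+` from ≥ 1 bp of
peak overlap (`min_overlap` exposed); no coverage-fraction threshold is
imposed because none is established for this mark.

`link_enhancer_genes()` measures distance boundary-to-boundary (0 for
overlap) and links within 100 kb inclusive, either to the nearest gene
(exact ties reported and flagged) or to all genes in range. The distance
anchor ("within 100 kb from each side") is interpreted as the gap from the
nearer enhancer boundary; gene-body overlap is distance zero. For genic
enhancers the host gene is linked only by distance like any other — an
alternative convention would force the host gene into the link set, and
the output makes it easy to impose that downstream.

`enhancer_expression()` averages linked-gene cpm per enhancer and
contrasts `+` versus `-` enhancers within each class by a two-sided
Wilcoxon rank-sum test with continuity correction, BH-adjusted across the
four classes. Fully tied inputs (a degenerate case) report p = 1. Groups
below two enhancers report a missing p rather than a meaningless one.

`h3k79_gene_category()` classifies genes as GB (body peak), ENH (any
linked mark-positive enhancer), GB-ENH, or none — a partition by
construction — and, given DE classes, tests the category-by-class
contingency (chi-square, or a simulated-p Fisher test when expected counts
fall below 5).

## Spike-in differential expression

The expression module follows the spike-in design: ERCC rows are carried
through filtering, anchor the normalization, and are excluded from library
sizes so that depth normalization and spike-in information do not collide.

* **Filtering**: genes need cpm ≥ 1 in ≥ 2 samples; controls always pass.
* **Unwanted variation** (`ruv_control_normalize()`): the control-gene
  construction — row-centred log counts (pseudocount 0.5) of the ERCC
  rows, first `k` right singular vectors as the per-sample factors W
  (orthonormal), W regressed out of every gene. `k = 1` by default; the
  appropriate `k` is a study-level choice and the function accepts any
  `k` below the control-matrix rank.
* **The threshold test** (`de_threshold_test()`): each gene is a
  negative-binomial GLM with log link under design (intercept, genotype,
  optional W), fitted by IRLS (batched across genes in compiled code).
  Gene-wise dispersions maximize a Cox–Reid adjusted profile likelihood on
  a log-spaced grid with parabolic refinement; the common dispersion
  maximizes the summed profile; the working dispersion blends the two on
  the log scale with weight 0.25 gene / 0.75 common. The null hypothesis
  is |fold change| ≤ 1.5, tested by refitting with the genotype
  coefficient pinned at the two boundaries ± log(1.5) and converting the
  likelihood-ratio statistics to boundary z-scores. The default
  `null = "interval"` composition averages the rejection probability over
  the interval of null fold changes (the TREAT interval formulation, with
  its published calibration constant 1.470402); `null = "worst.case"` sums
  the two boundary tails and is more conservative. BH across genes;
  `up`/`down` requires FDR < 0.05.

Exact numerical agreement with any particular reference implementation is
not claimed; the test suite instead checks operating characteristics
(false-positive control under a 3 vs 3 null at dispersion 0.1 across 50
simulations; sensitivity ≥ 0.8 for planted four-fold effects) and, as an
independent cross-check, ≥ 90% agreement of called sets with edgeR's
glmTreat on a shared fixture.

`feature_enrichment()` contrasts up (and down) genes against
not-deregulated genes over gene-length deciles (computed over the tested
genes), the six biotype groups (IG-TR, protein_coding, pseudogene, lncRNA,
mtRNA, snoRNA; unmapped biotypes become `other` and are counted), and
chromosomes, by chi-square with a simulated-p Fisher fallback, BH across
contrasts.

## CUT&Tag spike-in scaling

`spike_scale_factors()` converts heterologous (Drosophila nuclei) spike
read counts to multiplicative factors `reference / spike_reads`. The
reference defaults to the minimum spike count over samples, which keeps
every factor at or below 1 — scaling signal down rather than inflating
noise in shallow samples. Factors are comparable only within one
reference. `class_tss_profiles()` scales per-sample tracks, averages
within genotype, and profiles TSS ± 3 kb per DE class with strand
flipping. The package scales tracks; a per-peak variant is a trivial
application of the same factors to per-peak scores.

## Region-overlap permutation tests

`permutation_association()` measures the number of query regions
overlapping a subject set (a total-bp statistic is available) against a
randomization null:

* `circular` (default): one random rotation per chromosome, wrapping
  around the end. This preserves the per-chromosome region count, length
  multiset and inter-region spacing — the right null when the query set is
  clustered.
* `random_regions`: uniform re-placement preserving lengths, with an
  optional mask (rejection sampling, capped); appropriate for sparse sets.

The empirical p carries the +1 correction, `p = (1 + #{perm >= obs}) /
(n_perm + 1)`, bounded below by `1/(n_perm + 1)`; `z = (obs - mean)/sd`
over permutations, and the normalized z-score `nz = z / sqrt(|A|)` makes
cells of a multi-set matrix comparable across query sizes.
`association_matrix()` computes all ordered pairs under a seed stream and
BH-adjusts the matrix. Significance is reported at p < 0.05; a fixed nz
reporting cutoff is deliberately not imposed — nz and p are both returned
and thresholding is left to the user.

Permutation overlap counting uses a sorted-boundary vectorized kernel
(`findInterval` on merged subject boundaries); its equivalence to the
generic interval-tree route is itself a test.

## The synthetic-data generator

The generator exists so that every pipeline property can be checked
against planted truth. The default scenario (`simulate_scenario()`) is a
toy-scale mirror of the real study design:

* genome: chr1 and chr2 at 5 Mb, chrX at 3 Mb, chrY at 1 Mb; 2,000
  non-overlapping genes on random strands with log-normal lengths
  (meanlog log 2000, sdlog 0.8 — a realistic mammalian shape at 1/10
  scale);
* a 13-state segmentation sampled from a plausible emission/transition
  model (`default_state_model()`: conventional mark combinatorics, sticky
  transitions, quiescent-heavy);
* three stage-resolved H3K79me2 peak sets with planted presence patterns
  (common / pairwise / stage-specific) and a 10x RS-specific rate excess
  on chrX;
* planted deregulation tied to the chromatin environment: upregulated
  genes are drawn from repressed/bivalent promoters and coupled to
  H3K79me2-positive enhancers within 100 kb (with mark peaks kept off
  their bodies), downregulated genes from active promoters with
  H3K79me2-covered bodies;
* a 3 vs 3 negative-binomial count matrix (dispersion 0.1, baseline
  meanlog log 100) with 92 ERCC rows and a planted unwanted sample factor
  loading on every gene including the controls;
* CUT&Tag-like signal tracks for H3K27ac/H3K27me3 with per-sample depths
  captured by spike read counts, and a 3x H3K27me3 excess at upregulated
  promoters in CTL versus KO.

The planted unwanted factor is drawn orthogonal to the genotype contrast.
With three samples per group a fully random factor occasionally aligns
with genotype by chance, and in that draw the normalization-recovery
question is unanswerable by any method — the two sources are the same
direction. Technical variation is therefore modelled as
genotype-independent, which is also what it is physically.

What the generator does not emulate — and hence what passing tests do not
show about real data: read-level noise and mappability, GC and
fragment-length biases, peak-caller artefacts, correlated mark emissions
within a bin, non-geometric domain lengths, cell-type mixtures within a
sorted fraction, and library-preparation effects beyond a single linear
factor. Conclusions about the package's statistical machinery transfer;
conclusions about any particular biological dataset do not.

Problem sizes used in validation were chosen for desk-scale runs: 50,000
bins for model recovery, 2,000 genes x 50 simulations for the null
false-positive sweep, 1,000 permutations and 200 seeded runs for the null
uniformity of the permutation p, and the full default scenario (run twice)
for end-to-end determinism.

## Numerical choices and degenerate inputs

* Pseudocount 0.5 before logs of counts; emission probabilities clipped at
  `1e-12` for decoding and `1e-6` inside EM; dispersions floored at
  `1e-6`.
* IRLS linear predictors are clamped to ±30 (natural log scale) to keep
  exponentiation finite; all-zero genes are flagged, given p = 1 and fold
  change 0 rather than fitted.
* Ties: predominant-state ties break by the documented priority list;
  nearest-gene ties report all tied genes with a flag; posterior-decoding
  ties take the lower state index.
* Degenerate tracks (a mark never observed) fit to the clipped emission
  floor and are listed in the fit report.
* `fisher.test` fallbacks use simulated p-values (B = 10,000), which draw
  from the RNG; `run_pipeline()` therefore seeds the RNG for the whole
  run, making reruns byte-identical.
* Permutation `perm_sd = 0` (constant statistic) reports z and nz as
  missing rather than infinite.

## Running the pipeline

`run_pipeline(pipeline_config(seed = 1))` executes every stage on the
default synthetic scenario and writes plain-text tables, the resolved
configuration, a log, and a summary of planted-structure recovery into the
output directory. The configuration defaults are the analysis parameters
of the germ-cell study design: 200 bp bins, TSS window ± 3 kb, 100 kb enhancer linking, cpm
filter (1 cpm, 2 samples), fold-change threshold 1.5 at FDR 0.05, 10,000
permutations (the per-stage association matrix caps its own permutation
count at 1,000 to keep the end-to-end run short), one unwanted-variation
factor. A config with a fold-change threshold at or below 1 is rejected:
the threshold test is undefined there.

The package exposes each stage as an ordinary function over plain-text
standard formats (BED, GTF, TSV), so any stage can be fed externally
produced files — an external segmentation BED, real peak calls, a real
count matrix — in place of the synthetic ones.

## Known limitations

* The HMM learns per supplied track set; no multi-condition concatenated
  state model with shared emission labelling across many cell types is
  attempted, and learned state numbers are not comparable across runs
  without matching.
* The threshold test covers a two-genotype design with optional
  continuous covariates; multi-factor designs (genotype x cell type
  interactions) are out of scope.
* Enhancer-gene linking is purely distance-based; no contact (Hi-C) or
  activity-correlation evidence is used.
* The permutation framework randomizes the query set only; conditional
  nulls (e.g. matched GC or gene-density strata) are not implemented.
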