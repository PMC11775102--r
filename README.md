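# chromdyn

Integrative analysis of histone-mark chromatin states and gene regulation
across male germ cell differentiation.

During spermatogenesis, germ cells pass through sharply different
chromatin regimes — germline stem cells (GSC), meiotic spermatocytes
(SCI/SCII, with sex-chromosome silencing), and haploid round spermatids
(RS) — while DOT1L-deposited H3K79me2 redistributes over gene bodies and
regulatory elements. Asking what H3K79me2 does to gene expression requires
joining several kinds of evidence: where the mark's peaks sit and how they
move between stages, which chromatin state (from the combinatorics of six
histone marks) surrounds each promoter and enhancer, which genes each
enhancer plausibly regulates, and which genes actually change expression
when the writer is knocked out — measured against spike-in controls so
that global shifts are not normalized away.

chromdyn implements that whole analysis as a tested R package, for
epigenomics researchers who have peak calls, segmentations or count
matrices (their own or deposited ones) and want the integration steps to
be explicit, deterministic and validated. Every component is exercised
end-to-end on synthetic data with planted structure, so the operating
characteristics quoted below are properties the test suite actually
measures.

## What is inside

| Component | Core idea |
|---|---|
| `fit_state_model()`, `decode_segmentation()` | Hidden Markov model over 200 bp bins; state *k* emits mark *m* as Bernoulli(*p<sub>km</sub>*); Baum–Welch EM with restarts, posterior decoding; 18→13 state pooling (`pool_states()`) |
| `annotate_peaks()`, `classify_stage_dynamics()` | Four-category annotation (promoter ± 3 kb > intragenic > downstream > distal); merge-then-intersect presence patterns across stages (common / pairwise / stage-specific) |
| `gene_promoter_environment()`, `classify_enhancers()`, `link_enhancer_genes()` | Predominant state of TSS ± 3 kb by coverage; EnhA/EnhG/EnhW/EnhBiv runs split into H3K79me2+/− ; genes linked within 100 kb (nearest or all), Wilcoxon contrasts of linked-gene expression |
| `ruv_control_normalize()`, `de_threshold_test()` | Control-gene (ERCC) unwanted-variation removal via SVD of centred log controls; negative-binomial GLM test of H₀: \|fold change\| ≤ 1.5 (TREAT-style boundary LRT, Cox–Reid grid dispersions shrunk 0.25/0.75 toward common), BH at FDR 5% |
| `spike_scale_factors()`, `class_tss_profiles()` | Heterologous (Drosophila) spike scaling, factor = reference/spike reads; DE-class TSS profiles per genotype |
| `permutation_association()`, `association_matrix()` | Region-overlap permutation tests (circular or random placement), p with +1 correction, z and normalized z = z/√\|A\| |
| `simulate_scenario()`, `run_pipeline()` | Synthetic study with planted truth at every level; one-call deterministic end-to-end run |

The key statistics, in the field's notation: the threshold test evaluates
H₀: |β| ≤ log 1.5 for the genotype coefficient β of a NB-GLM
log μ = β₀ + β·KO + W·α + log N (library size N over non-control genes),
with p from boundary likelihood-ratio z-scores under the TREAT interval
null; the permutation z is (obs − mean)/sd over randomizations of the
query set, and nz = z/√|A| makes multi-set matrices comparable.

## Worked example

Build the default synthetic study (2,000 genes on a 14 Mb toy genome,
three H3K79me2 stages, spike-in counts with 100 planted up- and
100 down-regulated genes tied to promoter chromatin state), then run the
spike-in DE analysis and two integration steps:

```r
library(chromdyn)
sc <- simulate_scenario(seed = 1)

filtered <- filter_expressed(sc$counts, sc$control)
ruv <- ruv_control_normalize(filtered, attr(filtered, "control"), k = 1)
de <- de_threshold_test(filtered, sc$group, W = ruv$W,
                        control = attr(filtered, "control"))
table(de$status[!de$control])
#> down  not   up
#>   90 1819   91
```

Of the 181 called genes, almost all are planted ones (F1 ≈ 0.93 against
`sc$truth`). The promoter chromatin environment of the recovered
upregulated genes shows the planted repressed/bivalent states:

```r
seg <- decode_segmentation(sc$model, sc$tracks, sc$assembly)
env <- gene_promoter_environment(sc$genes, seg, assembly = sc$assembly)
head(env[env$gene_id %in% sc$truth$up, 1:3], 4)
#>      gene_id predominant_state coverage_fraction
#> 103 gene0524            EnhBiv         0.5332445
#> 106 gene0208            EnhBiv         0.9018497
#> 134 gene0864            ReprPC         0.4247625
#> 172 gene1317            TssBiv         0.4707549
```

Cross-stage peak dynamics and a stage-association test:

```r
dyn <- classify_stage_dynamics(sc$peaks)
table(dyn$class)
#>  common  GSC-RS GSC-SCI GSC-spe  RS-spe  SCI-RS SCI-spe
#>      94      13      21      45     105      20      48

permutation_association(sc$peaks$GSC, sc$peaks$SCI, sc$assembly,
                        n_perm = 1000, seed = 1)
#> Region-overlap permutation test (circular, 1000 permutations)
#> observed: 115  null: 5.12 +/- 2.62
#> z: 41.946  nz: 3.1891  p: 0.000999 ( greater )
```

The 115 observed co-occurring regions against a null of ~5 give the
minimal attainable p at 1,000 permutations (0.000999 = 1/1001) — the two
stage sets share their planted common regions. `run_pipeline(
pipeline_config(seed = 1))` executes all stages and writes every table,
a resolved config, a log and a planted-structure recovery summary to the
output directory; reruns with the same seed are byte-identical.

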