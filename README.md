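# ampbench

Benchmarking 16S rRNA amplicon sequence inference as microbial biomass
decreases.

Low-biomass samples (urinary tract, lung mucosa, blood, built
environments) carry so little template DNA that reagent and laboratory
contamination becomes a major fraction of what is sequenced. Whether a
community-profiling workflow holds up in that regime depends on the
sequence inference step: OTU clustering groups reads within a fixed
similarity radius (typically 3%), while amplicon sequence variant (ASV)
denoisers model sequencer error and abundance jointly. `ampbench` is for
methodologists and pipeline builders who want a controlled, fully
synthetic testbed for that comparison: it simulates a mock-community
dilution series with a fixed-mass contaminant pool, runs six desk-scale
implementations of de novo inference strategies, classifies every inferred
feature against the known truth, and summarizes accuracy and diversity
along the dilution axis.

## What it computes

**Simulation.** An `S`-strain uniform mock community is serially diluted
`fold`-fold over `n` samples (defaults: 8 strains, 3-fold, 9 samples,
ending at 1/6561). A contaminant pool of fixed mass `C` joins every
sample, so the expected contaminant read fraction at step `k` is

    f(k) = C / (C + T * fold^-(k-1))

— strictly increasing as the template mass `T * fold^-(k-1)` shrinks.
Paired 2 x 251 bp reads get per-cycle quality-dependent substitution
errors (`P(error) = 10^(-q/10)`) and optional PCR bimeras; ground-truth
origin tags ride along for evaluation.

**Inference.** Six strategies behind one interface (`infer_features()`):
greedy abundance-sorted OTU clustering at 97% identity (`uclust`); the
same with a stringent prefilter and inline two-parent chimera checks
(`uparse`); abundance-skew denoising with
`beta(d) = 1/2^(alpha*d + 1)`, alpha = 2 (`unoise`); positional error
subtraction over Hamming neighborhoods up to d = 11 (`deblur`); an
iterative error-model denoiser with a Poisson abundance p-value and
threshold 1e-40 (`dada`); and minimum entropy decomposition with a 0.02%
dataset-relative abundance floor (`med`).

**Evaluation.** Every feature is classified by precedence — `Reference`
(exact allele match), `RefNoisy` (within 10 nt of a more abundant
Reference feature), `Contaminant` (exact contaminant match),
`ContamNoisy` (within 10 nt of a Contaminant feature), `Other` — and
summarized as strain-level recall, overall precision (all non-Reference
features are false positives), technical precision (only RefNoisy
counts), reference read fractions, and Shannon / inverse Simpson / Fisher
alpha diversity against design expectations.

## Worked example

```r
library(ampbench)

cfg <- run_config(seed = 1,
                  design = list(n_samples = 9, depth_per_sample = 5000),
                  methods = c("uclust", "unoise", "dada"))
res <- run_all(cfg)
subset(res$report, sample %in% c("sample_1", "sample_7"))
```

```
   sample method total_features reference contaminant recall overall_precision
 sample_1 uclust             15         8           5    100                53
 sample_7 uclust             41         8          30    100                20
 sample_1 unoise             16         8           5    100                50
 sample_7 unoise             43         8          30    100                19
 sample_1   dada             13         8           5    100                62
 sample_7   dada             38         8          30    100                21
 technical_precision reference_read_pct  shannon
                 100               99.8 2.091643
                 100               58.3 3.182321
                 100               99.8 2.092695
                 100               58.4 3.184700
                 100               99.9 2.087903
                 100               58.4 3.177902
```

Reading the output: in the undiluted sample (`sample_1`) every method
recovers all 8 strains (recall 100) and well over 99% of reads map to the
known community. By the seventh 3-fold dilution (`sample_7`, relative
concentration 1/729) the fixed-mass contaminant pool dominates: all 30
simulated contaminants are detected, the share of reads from the real
community drops below 60%, overall precision falls to ~20%, and Shannon
diversity is inflated past the design expectation of ln 8 = 2.08. The
trend table tracks this along the whole series:

```r
attr(res$trends, "spearman")   # contaminant features vs dilution step
#> uclust unoise   dada
#>  0.957  0.957  0.957
```

`compare_scopes(cfg)` re-runs inference with samples pooled versus
processed individually; only the `dada` strategy is invariant to pooling
(it processes samples one at a time), while dataset-relative filters such
as the `med` abundance floor make results depend on what is processed
together.

A thin command-line wrapper with `run-all`, `simulate` and
`compare-scopes` subcommands is installed at
`system.file("cli", "ampbench.R", package = "ampbench")`.

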