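# gameteMEI

Single-read detection and characterization of de novo Alu insertions in
gamete long-read sequencing data.

## What this is for

Deep PacBio HiFi sequencing of bulk sperm samples one gamete per read, so a
de novo mobile element insertion (MEI) can be observed directly in a single
read carrying the element and its genomic context — no pedigree needed. At
single-read support, everything conventional SV pipelines lean on
(read-depth consensus, multi-read support) is unavailable, and the analysis
instead rests on read-level evidence and on the molecular hallmarks of
target-primed reverse transcription (TPRT): a target site duplication (TSD)
flanking the element, a 3' poly(A) tail, sense/antisense orientation against
a subfamily consensus, and the 5'-TT/AAAA-3' endonuclease motif at the
reconstructed pre-insertion junction.

`gameteMEI` implements the computational toolchain for this regime, aimed at
developers and analysts of low-allele-fraction SV pipelines:

* **Simulation with truth** — a mini-genome generator (background at 41% GC,
  dead repeats, segmental-duplication pairs) and a read-level spiker that
  plants single-read Alu insertions with TSD and poly(A) hallmarks, emitting
  a machine-readable truth table (blinded read names, single seed).
* **Benchmarking** — single-read TP/FP/FN definitions (a TP is one call,
  one spiked read, at the origin position), FP categorization into mapping
  errors vs multi-read (chimeric) calls, and regional FP stratification
  with enrichment ratios.
* **Annotation** — insertion sequence extraction, an internal consensus
  aligner (or RepeatMasker `.out` import) for subfamily / divergence /
  orientation, GFF/BED feature intersection, GC content of the surrounding
  10 kb.
* **Refinement** — supporting vs non-supporting read partitioning, a
  [0,1] confidence score penalizing low MAPQ and excess soft-clipping
  (zero without primary support), and the ordered filter cascade
  (SVLEN <= 10 kb, chr 1-22/X/Y, 40-80x site depth, Alu >= 300 bp,
  divergence <= 3%, primary support, non-centromeric).
* **TPRT features** — exact TSD detection (oracle-verified), score-based
  poly(A) tail calling with impurity fraction, 5' truncation, breakpoint
  context windows, positional adenosine profiles.
* **Rate models** — the closed-form gamete-sampling model (reads/cell,
  singleton meioses), per-gamete rates with exact Poisson intervals, age
  regression, and a cohort outlier z-test.

The statistic at the core: with each read sampling one gamete, the
per-sample insertion rate is `events / fold-coverage`, and the number of
daughter cells sampled per meiosis is Binomial(n = 4, p = Ncells/Nspecimen),
so at p = 0.0125 a fraction P(X=1) = 4p(1-p)^3 = 0.0481 of meioses
contribute exactly one cell — 96% of sampled cells are singletons, which is
what licenses the read = gamete identification.

## Worked example

```r
library(gameteMEI)

lib    <- synthetic_consensus_library()
genome <- generate_mini_genome(seed = 11)
cfg    <- sim_config(seed = 12, n_reads = 500, n_spiked = 20, base_error_rate = 0)
sim    <- simulate_dataset(genome, cfg)

calls <- truth_to_calls(sim$truth, sim$spike_aux)   # truth-preserving aligner stub
classify_calls(calls, sim$truth)
#> <bench_result> TP=20 FP=0 FN=0 precision=1.0000 recall=1.0000
#>   FP categories: mapping_error=0 multiread_nova_majority=0 multiread_nova_minority=0

tr <- sim$truth[1, ]
alu_features(calls[[1]], sim$reads[[tr$read_name]], tr$read_start, lib)
#> <alu_call> ctg2:50104 AluYk12 antisense TSD=13nt polyA=25nt (impurity 0.00) trunc5p=0
```

With error rate 0 and truth-preserving placement, precision and recall are
1 by construction — that verifies the classifier's bookkeeping, not a real
aligner. The feature line reads: the call at `ctg2:50104` is an antisense
AluYk12 with a 13-nt target site duplication and a pure 25-nt poly(A) tail,
matching the simulator's truth row for that read.

```r
model <- gamete_model()   # study-scale defaults: 2.5e6/2e8 cells, 50x, 18 kb
singleton_probability(model)
#> P(singleton) = 0.048148; 2407417 singleton meioses (96.3% of cells)
reads_per_cell(model)
#> 3.56 reads/cell from 8.89e+06 reads

per_gamete_rate(4, 54, sample_id = "donor07", age = 41, group = "healthy")
#> rate = 0.074 events/gamete (95% CI 0.020-0.190)
```

Four events at 54x coverage is 0.074 insertions per gamete, with an exact
Poisson 95% interval of 0.020-0.190.

A command-line entry point wraps the same modules
(`inst/cli/toolkit <simulate|bench|annotate|refine|features|rates|gamete-model>`),
e.g. `Rscript inst/cli/toolkit gamete-model` prints the model quantities
above.

## Layout

```
R/                  implementation (intervals, formats, simulator, bench,
                    annotate, refine, features, rates, cli)
tests/testthat/     unit + property tests; test-acceptance.R holds the
                    acceptance criteria
scripts/acceptance.R
vignettes/gameteMEI-methods.Rmd   the methods vignette (models, defaults,
                    design decisions, limitations)
inst/extdata/       bundled published insertion feature table (TSV)
inst/cli/toolkit    command-line wrapper
```
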