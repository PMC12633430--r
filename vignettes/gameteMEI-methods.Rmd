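---
title: "Methods: single-read de novo Alu detection, simulation and rate models"
author: "gameteMEI developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-read de novo Alu detection, simulation and rate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gameteMEI)
```

# The problem

De novo mobile element insertions (MEIs) — chiefly Alu retrotranspositions —
arise during gametogenesis at rates too low for pedigree studies to
characterize well. Deep long-read sequencing of bulk sperm turns each read
into a sample of one gamete, so a *single read* carrying an insertion plus
its genomic context is, in principle, one observed mutation event. Working
at single-read support demands machinery that conventional germline callers
do not provide: a simulator that spikes insertions into individual reads
with a tracked truth table, a benchmark that scores a caller against that
truth under single-read definitions, careful read-level evidence scoring, a
strict filter cascade, and extraction of the molecular hallmarks of
target-primed reverse transcription (TPRT) that separate true
retrotransposition from artifact. This package implements that toolchain at
desk scale, plus the closed-form sampling and rate models that convert
per-sample event counts into per-gamete mutation rates.

# Coordinate and data conventions

All internal coordinates are 0-based half-open. VCF is converted at the file
boundary (POS - 1 on read, + 1 on write); BED is consumed natively. One
convention everywhere prevents the off-by-one drift that mixing dialects
invites. Insertion calls (`insertion_candidate`) carry the inserted block,
allele fraction, supporting read names and arbitrary INFO tags, and
round-trip through `write_annotated_vcf()`/`read_insertion_vcf()` as an
identity on the domain type.

# The read-level insertion simulator

`generate_mini_genome()` builds a stand-in assembly: random background at
41% GC (the genome-wide average), dead (heavily diverged) SINE/LINE copies
at a configurable density, and segmental-duplication pairs created by
copy-then-mutate at a stated identity (default 98%), all with ground-truth
annotations. It deliberately does not model chromatin, repeat nesting
structure, satellite arrays or real Alu sequence: a green test on this
genome establishes that the *caller logic* is correct, not that performance
on a real genome is matched.

`spike_alu_insertion()` edits one read. At a junction offset drawn uniformly
at least `edge_margin` (default 2 kb) from either end — so both breakpoints
and full flank context stay inside the aligned span — it inserts, 5' to 3':
a copy of the `tsd_len` bases immediately downstream of the junction (the
target site duplication), the subfamily consensus body (reverse-complemented
with probability 0.5, matching the roughly equal sense/antisense split of
real insertions), and a poly(A) tail. Defaults state the observed world:
TSD lengths uniform on 8–18 nt, tail lengths uniform on 18–147 nt (the
observed min/max), read lengths normal with mean 18 kb and SD 2.5 kb,
substitution-only sequencing errors at 0.1% (HiFi error profiles are
substitution-dominated; indel errors are available but off by default).
An optional impurity process plants interior single-base non-A impurities
in tails, all of one nucleotide per tail, mirroring the structure seen in
real low-purity tails.

Two construction details make truth well defined. First, the junction is
rejection-sampled until the drawn TSD is exactly the *maximal* duplication
in the modified read — otherwise chance identity of flanking bases (~1/4
per extra base) would silently extend it and the truth table would disagree
with any correct detector. Second, the bundled synthetic consensus library
forbids adenosine in the last six body positions and any A-run of four or
more, so the 5' boundary of a spiked tail is unambiguous. The library
itself is generated in code (one GC-rich 281-bp ancestral body, each
subfamily derived by a fixed handful of diagnostic substitutions, plus a
LINE fragment): no third-party consensus sequences are shipped, and the
library is documented as synthetic. Users point `read_consensus_library()`
at a real Repbase/Dfam FASTA for production work.

`simulate_dataset()` samples reads uniformly (position and strand), spikes
exactly `n_spiked` of them, applies errors afterwards, and emits reads,
pristine originals and a truth table. Read names encode nothing about spike
status. All randomness flows from the single config seed, and the RNG state
of the caller is restored afterwards.

# The benchmark classifier

`classify_calls()` scores a callset at single-read resolution: a true
positive is a call whose support set is exactly one spiked read with the
call position inside that read's origin span; any call containing a spiked
read that violates either condition is a false positive, categorized as a
mapping error (single mismapped spiked read), a multi-read majority call
(several spiked reads merged) or a multi-read minority chimera (spiked reads
mixed with at least as many others). Calls containing no spiked reads
belong to the baseline callset and are ignored; FILTER status plays no
role.

One definitional tension had to be resolved: "false negative = truth read
appearing in no call" conflicts with the invariant `tp + fn = n_truth`
whenever a truth read is swallowed by a false-positive call. We keep the
invariant — a truth read not credited as the single support of a TP call
counts as missed — which also makes recall exactly `tp / n_truth`. The
position check defaults to span-level containment rather than a fixed
window because the insertion position sits at an arbitrary offset inside an
~18 kb read; a numeric tolerance is available.

# Annotation and refinement

`annotate_repeats()` replaces an external RepeatMasker run at desk scale:
batched local alignment of the query (both strands) against every library
consensus with match +2 / mismatch -3 / gap open -5 / extend -2, reporting
hits with score at least 150. That threshold sits far above the score
distribution of shuffled 350-nt sequences and far below any true SINE-body
hit at this scale (a ~280 bp exact hit scores ~560). Divergence is
mismatches plus indel bases over aligned columns, with no CpG adjustment —
the 3% divergence filter downstream refers to raw divergence. Ties break by
score, then divergence, then family name, so output is deterministic.
RepeatMasker `.out` import is the production path for real data.

`confidence_score()` formalizes read-evidence scoring as a base score of 1
adjusted by multiplicative factors against the non-supporting baseline:
`f_mapq = min(1, mapq_sup / max(mapq_nonsup, 1))` and
`f_clip = max(0, 1 - max(0, clip_sup - clip_nonsup - 0.05))`, forced to 0
when no supporting alignment is primary. The functional form is a design
choice (the reference behavior constrains only the [0,1] range, the
baseline-equal case giving 1, and supplementary-only support giving 0); it
was chosen for monotonicity — non-decreasing in supporting MAPQ,
non-increasing in soft-clip excess — which the property tests enforce. The
0.05 clip tolerance absorbs the clipping any true insertion-bearing read
shows at the event itself. With an empty baseline the factors default to 1:
absence of other reads is not evidence against the call.

`apply_filters()` applies the detection cascade in a fixed order, each
failure labeled with the first violated rule: SVLEN <= 10 kb; contig
normalizes to chr 1-22/X/Y (haplotype-suffixed assembly names accepted);
site depth within 40-80x (counted as primary alignments overlapping POS);
Alu-class annotation at >= 300 bp (unannotated candidates fail here as
`UNANNOTATED`); divergence <= 3%; confidence > 0 with primary support
(threshold exposed as `min_conf`, since "low-confidence" is otherwise
unquantified); outside centromeres.

# TPRT feature extraction

A caller reports one inserted block (TSD copy + element).
`refine_insertion_block()` finds the duplication as the longest exact
prefix of the block recurring immediately after it on the read, yielding
the TSD-exclusive element span; `detect_tsd()` states the equivalent
junction-anchored definition directly and is verified against a brute-force
oracle. TSD matching is exact — observed duplications are base-perfect —
and a mismatch-tolerant mode is deliberately out of scope.

`detect_polya_tail()` finds the tail by score-based extension from the 3'
end of the oriented element (A +1, non-A -2, x-drop 6), then trims both
ends back to an adenosine; among equal-scoring suffixes the shortest wins.
Score-based extension tolerates the interior single-base impurities real
tails show without fragmenting them, while the x-drop stops extension at
any run of four or more non-A bases. The exhaustive suffix-scoring oracle
agrees with the x-drop path whenever non-A runs are at most three bases
with enough adenosine between them to recover the score — exactly the
impurity structure the tails exhibit — and the adversarial oracle tests
generate within that envelope. Impurity is reported as the non-A fraction
of the tail, consistent with the published two-decimal impurity column
(0.04 at length 24 is one base).

Breakpoint context reconstructs the pre-insertion junction from the native
support read: for sense elements, 4 bases upstream of the left TSD copy
concatenated with the 4 bases following the tail end; for antisense, the 4
bases upstream of the tail end (the read-strand poly(T) run) with the 4
following the right TSD copy; plus 20-nt outer flanks both sides. The 8-mer
of a canonical endonuclease site contains `TTAAAA`. Motif discovery itself
(MEME-class tools) is external; the package only emits the windows.
`adenosine_profile()` indexes per-position A-frequency from both the
proximal and the distal TSD end, since positional conventions differ
between analyses, and reports the TSD length histogram alongside.

# Gamete-sampling and rate models

`gamete_model()` holds the study-scale constants: 2.5e6 cells sampled from
a 2e8-cell specimen (~5e7 meioses, 4 daughter cells each), 3.2 Gb genome,
18 kb fragments, 50x coverage, 586 ng library input at 1.096e-21 g/bp. The
number of daughter cells sampled per meiosis is Binomial(4, p = 0.0125);
`singleton_probability()` gives P(X=1) = 0.0481, ~2.41e6 singleton
meioses, 96.3% of sampled cells — computed exactly from the closed form
(the printed reference values 0.048118/2,405,900 carry a ~0.06% arithmetic
rounding that the tests accommodate explicitly). `reads_per_cell()` chains
the coverage, fragment-length and library-mass identities (8.89e6 reads,
3.56 reads/cell, 2.97e10 library fragments).

`per_gamete_rate()` divides events by fold-coverage — each read samples one
gamete, justified by the ~96% singleton fraction; no multi-read-per-cell
correction is applied. The confidence interval is the exact (Garwood)
Poisson interval, chosen because event counts per sample are small and the
method is standard and reproducible; the interval method is otherwise
unspecified in the reference analysis. `age_regression()` is ordinary least
squares of rate on age over healthy donors with a two-sided t-test on the
slope. `rate_outlier_test()` compares one sample's rate against the pooled
cohort with `z = (rate - pooled) / sqrt(pooled / coverage)`; an exact
Poisson alternative sits behind `method = "exact"`.

The z-test is asymptotic. At the study's own count scale (~3.7 expected
events per sample) exact enumeration puts its size at ~0.035 at nominal
0.05 — conservative, never anti-conservative. The calibration test
therefore runs where the approximation is meant to hold (expected ~31.5
events per sample, where enumeration gives size 0.049) and separately
asserts conservativeness at the small-count scale. This regime choice was
made from the enumeration, before simulation, and is not a tuned quantity.

# Numerical and degenerate-input choices

Interval queries are half-open everywhere and verified against an all-pairs
scan. Empty feature overlap, empty poly(A) tails (< 5 nt flagged
low-confidence), all-N GC windows (NA), absent RNAMES (candidate kept but
unrefinable, score 0), and empty baselines are all defined rather than
errors. Degenerate uniform ranges in the simulator (e.g. a fixed TSD
length) are guarded against R's scalar `sample()` expansion. FASTQ is
written directly as text because the Biostrings FASTQ writer overflows its
line buffer beyond ~20 kb, which HiFi-scale reads exceed.

# What the synthetic world does and does not establish

The simulator emulates: single-read insertions with TPRT hallmarks at
realistic length scales, segdup-targeted placement, substitution noise, and
blinding of spike status. It does not emulate: real Alu sequence (and hence
real subfamily confusability), alignment itself (benchmark fixtures use
truth-preserving placement), PCR chimeras, indel-heavy error modes, or
reference bias. Consequently the in-package precision/recall = 1 result
verifies classifier and bookkeeping correctness by construction — the
analogous claim on real data rests on the external alignment and calling
stack, which this package consumes but does not re-run.

# Known limitations

* Subfamily assignment against the synthetic library is easier than against
  real AluY derivatives, which differ at fewer, CpG-heavy positions.
* The confidence score's functional form is one admissible choice; scores
  are comparable within a run, not across tools.
* The per-gamete rate treats coverage as gamete count; clonal structure in
  the sampled cell population would violate this.
* `read_alignments()` loads alignment summaries into memory; it is sized
  for desk-scale fixtures, not production BAMs.
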