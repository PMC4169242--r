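---
title: "Methods: signal processing, overlap statistics and Boolean circuit models in regloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal processing, overlap statistics and Boolean circuit models in regloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regloop)
```

# Scope and design

`regloop` re-implements, as a tested and reusable pipeline, the
computational core of a regulatory-circuit analysis built around the
forkhead transcription factor dFOXO and the antagonistic ETS factors AOP
and PNT in *Drosophila*: tiling-array ChIP-chip signal processing and peak
calling, peak-to-gene annotation with randomization-based enrichment
statistics, block-bootstrap significance of binding overlap between two
factors, FDR-based differential-expression selection, and synchronous
Boolean network models of the dFOXO–AOP–PNT–lifespan circuit. Raw array
data are replaced throughout by a seeded synthetic-data generator, so every
stage can be validated against a known planted truth without any download.

All intervals live in `GenomicRanges` containers using the Bioconductor
1-based closed convention; BED (0-based half-open) and GFF3 (1-based
closed) are converted at the I/O boundary by `rtracklayer`, so on-disk
coordinates are always in each format's native convention. Peak sets are
sorted and internally disjoint; overlapping records in an input BED are
merged on read, with a warning, because the downstream statistics assume
disjointness. Strand is carried but ignored by all overlap arithmetic,
except for the strand-aware upstream/downstream feature classification.

# ChIP-chip signal model

The signal representation is a `signal_track`: one log2 IP/input value per
probe of a tiling-array probe map with centres approximately every 300 bp.
Processing follows the classic tiling-array chain:

1. **Median centring** of each track (location adjustment). The original
   arrays were loess-normalized within each array on raw two-channel
   intensities; those intensities are out of scope here, and on a log-ratio
   track the defensible reduction of a within-array normalization is a
   location shift. This is a deliberate, documented deviation.
2. **Quantile normalization between arrays** (`limma::normalizeQuantiles`,
   ties by average rank), applied within the ChIP replicate group and
   within the mock group separately — the two experiments have genuinely
   different signal distributions, and forcing an enriched ChIP track onto
   a flat mock distribution (or vice versa) would corrupt both.
3. **Replicate pooling** by the per-probe median; the median of an even
   number of replicates is the mean of the central pair.
4. **Running-median smoothing** along each chromosome with a 3-probe window
   (5 for noisier factors). The window never crosses a chromosome boundary
   and shrinks at chromosome edges; this shrink-at-edges rule and the
   mean-of-central-pair tie convention are conventions this package fixes
   explicitly, since upstream tools leave them unstated.
5. **Mock subtraction**: direct per-probe subtraction of the processed mock
   control, removing nonspecific enrichment shared between ChIP and mock.
   Whether subtraction happens before or after smoothing is ambiguous in
   the original description; the default subtracts after smoothing both
   tracks, and `subtract_first = TRUE` flips the order.

With zero simulated noise this chain returns exactly the planted amplitude
inside peaks and zero elsewhere — an invariant the test suite asserts.

# Peak calling

`call_peaks` is a threshold-and-merge caller. A probe qualifies when its
smoothed, mock-subtracted value reaches the threshold; the default 0.97 is
interpreted as an absolute value on the log2 scale (the y0-threshold
semantics of cher-style callers). Because the original description does not
disambiguate whether 0.97 was an absolute value or a null-derived bound, a
`quantile` mode is also shipped. A peak is a maximal run of consecutive
qualifying probes broken by any intervening sub-threshold probe or by a
centre-to-centre gap above `max_gap` (default 600 bp), and must contain at
least `min_probes` probes (default 3, the conventional caller default; the
source description is silent). The peak spans first to last probe centre —
probe extents on a custom array are unknown, so centres are the honest
boundary — and its score is the maximum probe value in the run. The caller
is verified against a brute-force run-enumeration oracle, and its
recovery operating point (recall and precision both above 95%) is measured
on synthetic tracks at amplitude 2.0 and noise SD 0.3 log2 units, three
replicates — a signal-to-noise regime typical of a well-behaved tiling
ChIP.

# Annotation and feature enrichment

Genes are associated to peaks when any gene feature lies within 1 kb of the
peak; the gap between half-open intervals `[a,b)` and `[c,d)` with `b <= c`
is `c - b`, and "within 1 kb" means gap <= 1000 (the boundary inequality is
a choice this package fixes). Feature classification counts each peak
toward every category it touches — gene bodies, strand-aware 1 kb upstream
and downstream flanks, or intergenic — non-exclusively, since the
categories are reported independently.

Enrichment is judged against a random-placement null: `n_sim` (default
1000) random peak sets with the identical per-chromosome peak counts and
identical length multisets, starts uniform along each chromosome. Random
peaks may overlap one another — the null preserves size, length and
chromosomal distribution, not disjointness — with a `disjoint` rejection
mode available. Per category the Z-score is `(obs - mean)/sd` over the
null draws and the empirical p is `(1 + #extreme)/(n_sim + 1)`, one-sided
in the direction of the observed deviation; the `+1` floor means p can
never be 0 (minimum `1/(n_sim+1)`, i.e. `p < 10^-3` at 1000 draws). A
category whose null has zero variance is flagged degenerate and given z = 0.

# Block-bootstrap overlap significance

The significance of the basepair overlap between two factors' peak sets is
assessed by a tiled block bootstrap: the second set is rebuilt chromosome
by chromosome from destination slots of `block_length` bp (default 100 kb —
much longer than any peak, much shorter than a chromosome), each filled
from a uniformly drawn source block, with intervals clipped at slot edges.
This preserves interval lengths and short-range clustering while destroying
long-range alignment with the fixed first set. Several variants of the
block bootstrap exist (segmented, circular); the tiled variant implemented
here is a documented choice, not a claim about the original study's exact
variant. Which set is resampled is a parameter of the orientation: `b`, the
second argument, is resampled with `a` fixed. Reported are the Z-score, the
one-sided empirical p with the `+1` floor, and a normal-approximation p.
The inner loop uses plain vectorized interval arithmetic (merge by
cumulative maximum, overlap by inclusion–exclusion), cross-checked in the
tests against the `GenomicRanges` intersection.

For gene-set overlap the test is the hypergeometric upper tail
`P(X >= overlap)`, delegated to `stats::phyper` and verified against
exhaustive enumeration for small universes.

# Differential expression

Expression analysis reproduces a selection logic, not a specific moderated
statistic: presence filtering (intensity floor, default the matrix-wide
25th percentile, reached in at least `min_samples` samples — a simple
stand-in for present/absent calls), per-gene ordinary least squares of
log2 intensity on condition plus fixed-effect batch indicators, two-sided
t-tests on the condition coefficient, and conversion of a target FDR into a
p-value cutoff by the Benjamini–Hochberg step-up rule. Empirical-Bayes
variance moderation is deliberately not re-implemented; this changes
small-sample power, so all quantitative claims about this module are made
against its own OLS model on synthetic data, never against gene counts
obtained with a moderated statistic. At the reference simulation setting
(log2 effect 1.0, noise SD 0.25, 4 vs 4 samples, 2000 genes of which 100
differentially expressed) the ordinary t with 6 residual degrees of freedom
has a BH fixed-point power of about 0.59 — a known-variance z-test would
have 0.996 — so recall at this setting sits near 60% while the realized
false-discovery proportion stays controlled at or below the nominal 5–10%.
When a simulation contains no batch variance the analysis design contains
no batch term: batch indicators with nothing to explain only consume
residual degrees of freedom. Batch handling is validated separately at
batch SD 1.0, where effect estimates remain unbiased.

# Boolean circuit models

The circuit engine is a synchronous Boolean network: named nodes in {0,1},
per-node update rules over the operators AND, OR, NOT, NAND, a clamp set
fixing nodes to constants (modelling constitutive activation), and free
nodes — nodes with neither rule nor clamp — which hold their initial value.
The free-node convention matters: dFOXO's own regulation is outside the
circuit, and holding its uniformly drawn initial value is what makes
"clamping PNT alone" a meaningful perturbation. Two wirings are built in:

* **feed-forward**: AOP' = dFOXO; PNT' = NOT AOP; lifespan' =
  NAND(dFOXO, PNT) — only the combined activity of dFOXO and PNT is
  detrimental;
* **linear**: as above but lifespan' = NOT PNT, a pure cascade.

The linear wiring is reconstructed from a figure-level description (a grey
chain through AOP and PNT with NOT gates); rules are overridable through
the text format parsed by `parse_network`, so alternative wirings can be
tested without code changes.

Simulations initialise unclamped nodes uniformly at random, run 1000
synchronous transitions, and report the probability the lifespan node is
active. Exact mode enumerates all initial states (the default for these
4-node circuits); Monte-Carlo mode samples seeded initial states and is
used as a cross-check. These networks are deterministic, so every
trajectory enters a cycle within at most 2^4 steps; the state at step 1000
is computed by cycle detection rather than literal iteration, and the tests
assert the step-1000 probability equals any post-transient horizon. The
derived exact probabilities (for the feed-forward model: 1 with dFOXO
clamped, 0.5 with PNT alone — the free dFOXO's uniform initial value — and
0 with both) are this package's own ground truth; the qualitative
discrimination they support is that only the feed-forward wiring shows
synergy, defined as P(both clamped) strictly below both single-clamp
probabilities.

# Synthetic data: what it emulates, and what it does not

The generators produce: multi-chromosome genomes with uniformly placed,
non-overlapping, randomly stranded gene models; probe maps on a grid of
`spacing/2 + k*spacing` with optional Gaussian placement jitter (clipped at
half the spacing to keep centres strictly increasing — the source material
only says "approximately every 300 bp", so the grid is this package's
choice); ChIP replicate tracks equal to amplitude inside planted peaks plus
homoscedastic Gaussian noise on the log2 scale, with an optional mock
track sharing planted artifact regions (to demonstrate that mock
subtraction removes them) and optional per-replicate scale factors (to
exercise quantile normalization); and two-condition expression matrices
with per-gene baselines, planted log2 effects, shared within-batch offsets
and Gaussian noise. Every generator is a pure function of its arguments
including the seed, and returns its planted truth so downstream tests can
compute recall and precision directly.

None of this models probe GC/affinity bias, fragment-size convolution of
ChIP signal, spatial array artifacts, or heavy-tailed intensity noise.
Passing tests therefore demonstrate correctness of the algorithms under a
clean statistical model, not robustness to every artifact of real arrays.

# Numerical conventions and problem sizes

Empirical p-values always carry the `+1` correction and are never 0. The
BH cutoff returns 0 (and selects nothing) when no ordered p-value
qualifies. Genes with numerically zero residual variance and a nonzero
effect receive the machine-minimum positive p and a degenerate flag.
Chromosome-edge flanks are trimmed; zero-width candidates are dropped.
Pipeline stages derive child seeds from one global seed via a documented
splitting scheme (`derive_seeds`), so stages can be rerun in isolation and
two runs with one seed produce byte-identical artifacts.

Validation problem sizes are chosen to represent the study scale while
keeping a full run comfortable on a laptop: peak recovery uses a 2 x 5 Mb
genome with 50 planted 1–3 kb peaks over 10 seeds; bootstrap calibration
uses 200 trials of 500 iterations on a 5 Mb chromosome with 50 peaks of
1–2 kb (about 1.5% genome coverage, matching the density of roughly 1400
peaks of 1–2 kb on a 120 Mb genome); enrichment calibration uses 100
trials at 200 random sets each; the demo pipeline uses a 2 x 2 Mb genome.
The bundled demo (`run_demo`) exercises every stage end to end.

# Known limitations

* The peak caller reports probe-centre extents; deposited peak coordinates
  from hybridization platforms may use probe extents, a systematic
  half-probe-width difference.
* The block bootstrap's tiled variant clips transplanted intervals at slot
  boundaries; its null preserves per-chromosome coverage to within 2% in
  expectation (asserted in tests) but the lost coverage slightly depresses
  the null mean, making the one-sided test mildly anti-conservative — at
  the reference density the empirical rejection rate at nominal 5% sits
  around 5–9% depending on the random draw. Calibration is verified
  empirically rather than guaranteed analytically; for borderline findings
  prefer the empirical p at many iterations over the normal approximation.
* The DE module's OLS t is honest but low-powered at small n; it is not a
  substitute for moderated statistics when analysing real arrays with few
  replicates.
* Boolean modelling here is synchronous and deterministic; asynchronous
  update schemes and probabilistic Boolean networks are out of scope.
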