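# regloop

Analysis of transcription-factor regulatory circuits from tiling-array
ChIP-chip and expression microarray data, built around the dFOXO–AOP–PNT
circuit in *Drosophila*: how a forkhead activator and an antagonistic pair
of ETS factors jointly regulate downstream targets and lifespan.

`regloop` is aimed at computational biologists who need the classic
tiling-array / gene-set toolchain as reusable, tested building blocks:

* **ChIP-chip signal processing** — quantile normalization between arrays
  (`limma`), replicate pooling by per-probe median, running-median smoothing
  along chromosomes, mock-control subtraction;
* **peak calling** — threshold-and-merge on the smoothed log2 enrichment
  (y0 threshold 0.97, 600 bp distance cutoff, >= 3 probes by default);
* **annotation and enrichment** — peak-to-gene association within 1 kb,
  genomic-feature classification, and Z-scores against a null of random
  peak sets with identical size, length and chromosomal distribution;
* **overlap statistics** — hypergeometric tests for gene-set overlap and a
  tiled block bootstrap (default 10000 iterations, 100 kb blocks) for the
  basepair overlap of two factors' binding sites;
* **differential expression** — presence filtering, per-gene OLS with batch
  covariates, and conversion of a target FDR into a p-value cutoff by the
  Benjamini–Hochberg step-up rule;
* **Boolean circuit models** — synchronous Boolean networks with node
  clamping; built-in linear and feed-forward wirings of
  dFOXO → AOP ⊣ PNT with lifespan read out through NOT or NAND logic;
* **synthetic data** — seeded generators for genomes, gene models, probe
  maps (~300 bp spacing), planted-peak ChIP/mock tracks and two-condition
  expression matrices with batch structure, returning their planted truth.

The statistical model at the core of the circuit comparison: nodes take
values in {0,1}; each scenario clamps dFOXO, PNT or both to 1, initialises
the remaining nodes uniformly, runs 1000 synchronous transitions, and
reports P(lifespan = 1). A wiring shows *synergy* when
P(both) < min(P(dFOXO), P(PNT)) — the feed-forward NAND circuit does
(P = 1, 0.5, 0 for dFOXO, PNT, both), a linear cascade cannot
(P(PNT) = P(both) = 0).

## Worked example

```r
library(regloop)

# a synthetic study: 2 x 2 Mb genome, 120 genes, 30 planted peaks,
# three ChIP replicates at amplitude 2, noise SD 0.3
gen    <- generate_genome(n_chrom = 2, chrom_length = 2e6, n_genes = 120, seed = 1)
probes <- generate_probe_map(gen$genome, spacing = 300, jitter_sd = 30, seed = 2)
truth  <- plant_peaks(gen$genome, n_peaks = 30, seed = 3)
sim    <- generate_chip_tracks(probes, chip_sim_truth(truth, amplitude = 2,
                                                      noise_sd = 0.3, seed = 3))

track <- process_chip_tracks(sim$chip, sim$mock, window = 3)
peaks <- call_peaks(track, threshold = 0.97, max_gap = 600, min_probes = 3,
                    genome = gen$genome)
length(peaks)
#> [1] 30
directional_peak_overlap_counts(peaks, truth)$frac_b
#> [1] 1

# overlap significance of the called peaks against the planted truth
block_bootstrap_overlap(peaks, truth, gen$genome,
                        n_iterations = 500, block_length = 1e5, seed = 5)
#> block-bootstrap basepair overlap
#>   observed: 45447 bp; null 587.6 +/- 817.2 (500 iterations, block 100000 bp)
#>   Z = 54.89, empirical p = 0.002

# Boolean circuit comparison
compare_models()
#>         model dFOXO PNT both synergy
#> 1 feedforward     1 0.5    0    TRUE
#> 2      linear     1 0.0    0   FALSE
```

All 30 planted peaks are recovered exactly; the bootstrap Z of 54.9 with
the empirical p at its floor (1/501) says the called peaks and the planted
truth share far more basepairs than random placement of equally sized peaks
would give; and only the feed-forward wiring reproduces the synergistic
lifespan effect of activating both transcription factors.

A complete end-to-end demonstration (`run_demo("out", seed = 1)`) writes
peaks BED, association/enrichment/overlap/DE TSV tables, the Boolean
probability table, and a manifest with artifact checksums; reruns with the
same seed are byte-identical. A thin CLI over the same functions is in
`inst/scripts/regloop.R` (subcommands `demo`, `chip`, `overlap`,
`boolnet`).

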