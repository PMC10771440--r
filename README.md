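# sigrekin

Sigma-factor regulon inference from expression kinetics and promoter motifs.

Alternative sigma factors — in particular the small, stress-responsive ECF
(extracytoplasmic function) family of bacteria such as *Streptomyces
coelicolor* — redirect RNA polymerase to their own promoter repertoire. After
a ChIP experiment has produced a list of binding sites, two questions remain
for the computational analyst: *does the sigma factor actually drive (or,
surprisingly, repress) the expression of the associated genes?* and *do the
bound regions carry the expected bipartite -35/-10 promoter signature?*
`sigrekin` implements a tested, reusable pipeline for both, together with a
synthetic-data generator with known ground truth so that every stage can be
validated end to end without any external download.

## What it computes

**Kinetic model.** Target expression `z(t)` driven by regulator profiles
`y_i(t)` follows

```
dz/dt = k1 * sigmoid(b + sum_i w_i * y_i(t)) - k2 * z
```

with maximal synthesis rate `k1`, first-order mRNA decay `k2`, bias `b` and
signed regulatory weights `w`. The model is integrated by forward Euler and
fitted by simulated annealing restarted 256 times from random initial
parameters; the minimum-SSE model is kept. A fit below the normalized-SSE
threshold makes the regulation "possible"; the sign of `w` separates
stimulation (`w > 0`) from repression (`w < 0`). Profiles are preprocessed
the way single-replicate microarray time courses require: exponentiation
from log2, Savitzky–Golay smoothing, and resampling to a uniform 24-minute
grid, then classified against the two regulators (alternative sigma factor
vs. housekeeping HrdB vs. flat) by Pearson correlation and a
coefficient-of-variation flatness test.

**Promoter motifs.** From peak-summit windows the pipeline discovers the -10
half-site with a zero-or-one-occurrence-per-sequence EM, searches a fixed
upstream window for the -35 half-site, joins the two across spacers of
16–19 bp into composite motifs, and scans both strands with exact PWM
p-values computed by dynamic programming over the discretized score
distribution (no sampling, no approximation). Retention rules (best hit per
sequence, wildcard-pattern rescue such as `--TA---T--`), overlap pruning and
spacer tallies follow.

**Set statistics.** Hypergeometric (upper-tail) functional-class enrichment,
fold enrichment against a genome-wide incidence, and regulon overlap
arithmetic.

## Worked example

Simulate a 26-gene cohort (9 sigma-E-activated, 3 sigma-E-repressed, 8
HrdB-driven, 6 flat) at realistic noise, classify it, and refit one of the
planted repressed genes:

```r
library(sigrekin)

cfg <- simulation_config(master_seed = 11, noise_sd_log2 = 0.1)
coh <- simulate_expression_cohort(cfg, n_activated = 9, n_repressed = 3,
                                  n_hrdb = 8, n_flat = 6)
cl <- classify_cohort(coh$targets, coh$sigE, coh$hrdB)
table(cl$group)
#> A_sigE B_hrdB C_flat  other
#>      9      8      6      3

fit <- fit_single_regulator(preprocess_profile(coh$targets[["G0010"]]),
                            preprocess_profile(coh$sigE),
                            n_restarts = 256, master_seed = 1)
fit
#> <kinetic_fit> G0010: sse=3.283 (normalized 0.01481), regulation_possible, w=(-2.835)
```

The three repressed genes land in `other` (they anti-correlate with the
sigma factor), and the kinetic fit recovers the repression: the fitted
weight is negative with a normalized SSE of 1.5%, i.e. the model explains
98.5% of the profile's variance. Regulon arithmetic is one call:

```r
regulon_overlap(gene_set("study", ids_a), gene_set("published", ids_b))
#> $n_a 132  $n_b 137  $n_intersection 57  $n_union 212
```

`run_pipeline(pipeline_config(master_seed = 11), "out/")` executes the whole
chain — simulate (or ingest), preprocess, classify, fit, discover and scan
motifs, tally spacers, test enrichment — and writes per-stage TSVs plus a
machine-readable `summary.json`.

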