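---
title: "Methods: kinetic regulon inference and bipartite motif scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic regulon inference and bipartite motif scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrekin)
```

## The question the package answers

A ChIP experiment for a sigma factor yields binding sites; it does not say
whether the factor activates the downstream genes, represses them, or binds
without consequence under the assayed conditions. `sigrekin` addresses this
with three independent lines of evidence: (i) a kinetic model that asks
whether the regulator's expression time course can *generate* the target's
time course, and with what sign of regulatory weight; (ii) a bipartite
promoter-motif analysis of the bound sequences; (iii) functional-class
enrichment of the associated genes. Each stage is exercised on synthetic
data with known ground truth, which is what the test suite and the
acceptance script measure.

## The kinetic model

Target expression $z(t)$ under regulators $y_i(t)$ follows

$$\frac{dz}{dt} = k_1\,\sigma\!\Big(b + \sum_i w_i\,y_i(t)\Big) - k_2\,z,
\qquad \sigma(x) = \frac{1}{1+e^{-x}},$$

a sigmoidal synthesis term with first-order mRNA decay. The parameters, with
units and default plausibility bounds:

| parameter | meaning | units | bounds (default) |
|---|---|---|---|
| $k_1$ | maximal synthesis rate | expression units / h | $(0,\ 10\,\max(x_t)]$ |
| $k_2$ | mRNA degradation rate | 1 / h | $[0.1,\ 5]$ |
| $b$ | regulation bias | — | $[-10, 10]$ |
| $w_i$ | regulatory weight | — | $[-10, 10]$ |
| $z_0$ | initial expression | expression units | fixed to first observation |

The weight bound $\pm 10$ is effectively unconstrained because the sigmoid
saturates far earlier; the $k_1$ cap keeps fitted steady states within an
order of magnitude of the observed dynamic range at moderate decay rates
(box constraints cannot couple $k_1$ and $k_2$, so the cap is deliberately
generous at the small-$k_2$ corner). Fixing $z_0$ to the first observed
value removes one poorly identified degree of freedom.

**Integration.** Forward Euler at the 24-minute step of the resampled
observation grid, regulators linearly interpolated. The suite verifies
first-order convergence against an adaptive Runge–Kutta reference
(`deSolve::ode`, method `ode45`), which serves only as an oracle.
Positivity of the trajectory requires $k_2\,dt < 1$, satisfied across the
whole $k_2$ box at the default step.

**Optimization.** Simulated annealing over the box: uniform random start,
Gaussian proposals with standard deviation 0.1 of each box width clipped to
the bounds, Metropolis acceptance, geometric cooling ($T \leftarrow 0.97\,T$
per iteration, 500 iterations), initial temperature calibrated per gene to
the standard deviation of the objective over 24 random points. The fit is
restarted 256 times (seed of restart $i$ derived from the master seed by a
counter hash, so results are independent of how many other genes are fitted)
and the minimum-SSE model is kept; exact ties keep the lowest restart index.
The annealer exists twice — a reference implementation in R (`anneal()`) and
a compiled inner loop — written to consume random draws in the same order,
and a test asserts bit-identical output of the two on the kinetic objective.

**Verdict.** "Regulation possible" when SSE divided by the target's total
sum of squares falls below 0.2 (configurable); this normalized criterion is
scale-free across genes. Nothing in the data dictates this constant; 0.2
("model explains at least 80% of profile variance") is the package's
recorded choice. The sign of the fitted $w$ then separates stimulation from
repression, the package's core readout.

## Preprocessing and classification

Published log2 single-replicate values are exponentiated back to linear
reads, smoothed with a Savitzky–Golay filter, and resampled by linear
interpolation to a uniform 24-minute grid (the 20–60 h, 32-point hour grid
yields 101 points). The filter window (9 points) and order (3) are not
dictated by the data either; they preserve cubic trends exactly — verified
to machine precision in the tests — while suppressing single-replicate
noise, and are exposed as arguments.

Classification into the three groups uses Pearson correlation of the
preprocessed linear-scale profiles against each regulator: flat if the
coefficient of variation is below 0.1, group A if $r_{\sigma}\ge 0.7$ and
$\ge r_{\mathrm{HrdB}}$, group B if $r_{\mathrm{HrdB}}\ge 0.7$, otherwise
"other". The thresholds 0.7 / 0.1 reproduce a qualitative tri-partition,
not any particular gene count. Two consequences are intentional: the signed
correlation sends *repressed* targets (anti-correlated with their
regulator) to "other", where the kinetic fit subsequently identifies them
by a negative weight; and correlation is computed on smoothed profiles, the
same objects the ODE is fitted to.

## Synthetic data: what it emulates, and what it does not

The generator is a pure function of a configuration and a master seed;
per-entity seeds are derived by a counter scheme so enlarging a cohort
never changes existing genes.

* **Expression.** Regulators are smooth positive curves (a transient pulse
  for the stress sigma factor, a logistic ramp for the housekeeping one).
  Targets are forward-integrated from the ODE and observed through additive
  Gaussian noise on the log2 scale (equivalently multiplicative log-normal
  noise on reads), the natural model for single-replicate microarray data.
  The default `noise_sd_log2 = 0.2` is a tunable, not a claim about any
  particular dataset. Flat genes receive a quarter of the cohort noise,
  emulating the empirically much lower within-profile variability of the
  flat cluster. Driven genes draw $k_1 \sim U(1,6)$, $k_2 \sim U(0.5,2)$,
  $|w| \sim U(2,6)$, with the bias centred so the sigmoid traverses its
  responsive range — a regulator whose effect never leaves saturation is
  biologically a constitutive promoter and statistically unidentifiable.
* **Dual-regulator battery.** The activator-plus-repressor recovery study
  uses a ramp that plateaus around 30 h and a repressor pulse at 46 h, with
  the operating point placed just above the sigmoid midpoint after the
  ramp. This is the identifiable version of combined regulation: the
  repressor carves a visible dip into an otherwise-sustained profile. When
  instead the pulse acts while the activator still holds the promoter off,
  the data contain no trace of the repressor and no optimizer can recover
  its sign — a limitation of the *experiment*, not of the fit, and the
  reason the battery pins these phases.
* **Promoters.** Background sequence is 0-order i.i.d. at configurable GC
  content (default 0.72, symmetric A=T/C=G); no dinucleotide structure is
  modelled. A configurable fraction of sequences receives exactly one
  bipartite site — bases sampled from the PWM columns (so scanner score
  distributions are exercised) or set to consensus for exact-recovery
  checks — at a uniform position and strand, with the spacer drawn from the
  configured distribution (defaults 9/11/59/21% for 16/17/18/19 bp). The
  built-in family has an ECF-type `GGAACTT` -35 and a more conserved
  `CGTCTAA` -10 (consensus probabilities 0.8 and 0.9), mirroring the
  asymmetry real sigma-factor promoters show.

Passing tests on these data therefore demonstrate correctness of the
machinery under a known generative model — they do not certify performance
on real arrays with batch structure, probe effects, or peaks containing
multiple promoters.

## Motif discovery, scanning and exact p-values

Discovery is a two-stage zero-or-one-occurrence-per-sequence EM: the best
ungapped motif in the summit windows is taken as the -10 element; a fixed
segment upstream of each -10 site is then searched for the -35 element. An
ungapped motif discovered on both strands is strand-ambiguous, so both
orientations of the -10 are tried and the one whose upstream segments yield
the higher per-segment -35 likelihood is kept — only the true orientation
has a conserved element on its upstream side. The default segment starts
`width35 + max(spacer)` bp upstream with length 10, which contains the full
-35 element for every allowed spacer; `extract_upstream_segments()` itself
defaults to the conventional 23 bp offset. The EM maximises a
pseudocount-regularised objective whose trace is checked for monotonicity;
it is a stand-in validated on planted motifs, not a re-implementation of
any particular discovery tool's objective.

Scanning scores every offset on both strands with log-odds against a
complement-symmetric 0-order background estimated from the scanned set
(A=T, C=G — this symmetrisation makes the hit set exactly invariant under
reverse-complementing the input, a property the suite asserts). P-values
are exact: per-column scores are discretized at 0.01 bits and convolved
into the full score distribution, from which upper tails are read; the
suite proves equality with exhaustive $4^w$ enumeration at small widths.
Spacer columns of a composite motif sit at background frequencies and
contribute exactly zero score, so the four spacer variants share their
half-site columns and differ only in geometry. Degenerate inputs are
handled explicitly: non-ACGT bases score zero (background substitution,
with a warning); an uninformative motif gives every word $p = 1$.

Retention mirrors promoter practice: the lowest-p hit per sequence, plus
any hit matching a wildcard core pattern (e.g. `--TA---T--` for
housekeeping-promoter rescue); overlapping hits across spacer variants are
clustered transitively and only the most significant survives. All ties
break deterministically (leftmost offset, then plus strand), making output
independent of input order.

## Enrichment

Upper-tail hypergeometric tests per functional class (no depletion test),
fold enrichment against the genome-wide incidence, and integer-rounded
percentages. No multiple-testing correction is applied by default, matching
the single-class reporting convention of regulon studies; a
Benjamini–Hochberg column is available by flag.

## Problem sizes and determinism

The validation suites use 50 genes per noise level for the recovery
batteries (64 annealing restarts there; the pipeline default is 256), 1000
planted sequences for spacer tallies, and ~16,000 scanned positions for the
calibration check — sizes at which the binomial/multinomial acceptance
bands are meaningful while the whole suite runs in about a minute. Every
stage is a pure function of its configuration and a master seed; the
pipeline writes its effective configuration next to its outputs and a rerun
is byte-identical.

## Known limitations

* The ODE treats the regulator's *expression* profile as the active-protein
  profile; post-translational control (anti-sigma factors) is invisible.
* Box plausibility bounds are rectangular; the $k_1$/$k_2$ corner admits
  steady states beyond ten times the observed range.
* The ZOOPS-EM can lock onto a shifted register of a planted motif when the
  flanks carry signal; the multi-start strategy mitigates but does not
  eliminate this.
* No E-value/q-value layer over scan hits (raw p-value thresholding only),
  and no genome-wide scanning outside the supplied regions.
* Confidence intervals on fitted kinetic parameters are not computed; the
  verdict is a point decision at the normalized-SSE threshold.
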