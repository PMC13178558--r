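---
title: "Methods: from smFISH spot intensities to transcriptional burst parameters"
author: "burstfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from smFISH spot intensities to transcriptional burst parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstfish)
```

## The problem

Single-molecule RNA FISH (smFISH) renders individual transcripts as
diffraction-limited fluorescent spots, so a microscope field yields, per
cell, a set of spot intensities rather than a count. Turning those spots
into per-cell mRNA copy numbers, and those copy numbers into a mechanistic
description of transcription — how often a promoter fires, how many mRNAs
each firing produces, and what fraction of cells is locked off entirely —
is the analysis this package implements. The motivating system is
expression of a biosynthetic operon (e.g. *trpE* of the tryptophan operon)
across a ladder of external metabolite concentrations, where regulation by
repression and/or attenuation reshapes both the mean and the cell-to-cell
distribution of transcripts.

## Spot quantification

Three steps convert a spot table into counts, each deliberately simple and
fully deterministic:

1. **False-positive exclusion.** Spots are also detected in a deletion
   strain carrying no target transcript; their intensities define the
   nonspecific background. The threshold is the 99.9th percentile of the
   control intensities, computed with the linear-interpolation percentile
   convention (sorted 0-based position $(n-1)q$, `stats::quantile` type 7).
   The convention is stated because different software disagrees at the
   third decimal and we want bit-reproducible thresholds. The threshold is
   applied to the integrated spot intensity; peak height is carried as
   metadata only.
2. **Unit-intensity calibration.** In a low-expressing calibration strain
   the spot-intensity distribution is quantal: Gaussian components sit near
   integer multiples of the intensity of one mRNA. A Gaussian mixture is
   fitted by maximum likelihood (EM, unequal variances, delegated to
   `mclust`, whose model-based hierarchical initialization makes the fit
   deterministic), components are sorted by mean, and the lowest mean is
   the single-molecule unit intensity. Component means are left free rather
   than constrained to integer multiples; with free means the first
   component is an estimate, not an assumption. The component count
   defaults to 3 and is configurable; on synthetic tables produced by this
   package's generator one component suffices, because the generator emits
   exactly one spot per molecule.
3. **Counting.** Per cell, surviving spot intensities are summed, divided
   by the unit intensity, and rounded to the nearest integer (floored at
   0). Rounding rather than truncation is used because copy numbers are
   integers and symmetric rounding is unbiased under symmetric intensity
   noise. Cells with no surviving spots count 0.

The pipeline's recovery guarantee is quantitative: with per-spot intensity
CV at or below 10% and a control population below half a unit intensity,
the true count is recovered exactly for at least 99% of cells (the
probability of a rounding error on a cell with $k$ spots is
$2\Phi(-0.5/(\mathrm{cv}\sqrt{k}))$, negligible for the copy numbers these
operons produce).

## Population statistics

Per strain and condition the package reports mean $\mu$, sample standard
deviation $\sigma$ (with the $n-1$ denominator, stated so results are
reproducible to the last digit), noise $CV^2 = \sigma^2/\mu^2$, burstiness
$F = \sigma^2/\mu$ (Fano factor; 1 for a Poisson process, above 1 for
bursty transcription), and the fractions of silent (count 0) and
transcriptionally on (count $\ge 1$) cells. When $\mu = 0$ both ratios are
undefined and flagged `NA` rather than returned as 0/0.

Two inferential tools accompany the summaries:

* **Exact Spearman test.** Condition ladders have only a handful of
  points, where the usual asymptotic p-values are meaningless. For
  $n \le 8$ the two-sided p-value is computed by full enumeration of all
  $n!$ rank permutations with the $\ge$ tail convention; for perfectly
  monotone data at $n = 4$ this gives $p = 2/24 = 0.083$, printed as 0.08.
  Beyond $n = 8$ the $t$ approximation is used and a notice is emitted.
* **One-phase exponential decay.** The dependence of $CV^2$ and $F$ on mean
  expression is summarized by least-squares fits of
  $y(x) = (y_0 - \text{plateau})e^{-kx} + \text{plateau}$ with $k \ge 0$
  (Levenberg–Marquardt via `minpack.lm`). Starting values are
  $\text{plateau}_0 = \min y$, $y_{0,0} = \max y$ and $k_0$ from a
  log-linear regression of $y - \text{plateau}_0$, with $k_0$ clamped to
  $[0.2, 20]/\mathrm{range}(x)$ — outside that window one of the Jacobian
  columns degenerates numerically; two fallback starts cover rising or
  non-monotone data. $R^2 = 1 - SS_{res}/SS_{tot}$, defined as 1 for
  constant data (zero total sum of squares).

## The burst model and its inference

Per-cell copy numbers are modelled as zero-inflated negative binomial
(ZINB): with probability $\omega$ a cell is transcriptionally repressed and
contributes a structural zero; otherwise its count follows
$\mathrm{NB}(r, p)$ with

$$P(k) = \binom{k+r-1}{k} p^k (1-p)^r,$$

so $P(0) = \omega + (1-\omega)(1-p)^r$. The NB arises as the stationary law
of a gene producing geometric bursts of mean size $b = p/(1-p)$ at rate
$r$ per mRNA lifetime, which fixes the reported burst parameters: burst
size $b = p/(1-p)$, burst frequency $f = r$ (dimensionless, per mRNA
lifetime), repression $\omega$. The pmf convention matters — under the
alternative convention ($p \leftrightarrow 1-p$) the burst size inverts —
so it is stated once here and used everywhere, including in the mapping of
`stats::dnbinom(size = r, prob = 1 - p)` used by the sampling routine.

Priors are Uniform(0, 1) on $\omega$ and $p$ and half-normal
($\mu = 0$, $\sigma = 20$, positively truncated) on $r$. Inference is by
random-walk Metropolis–Hastings with a diagonal Gaussian proposal whose
per-coordinate standard deviation is 5% of the current parameter value.
The production protocol runs 500,000 iterations, discards 100,000 as
burn-in and thins by 100, retaining 4,000 draws; the point estimate is the
retained draw with maximal log posterior (a reproducible MAP needing no
kernel bandwidth choice) and uncertainty is the equal-tailed 2.5–97.5%
posterior interval of each derived quantity, computed after mapping each
draw to $(\omega, b, f)$.

Design choices where the procedure was genuinely open:

* **Hastings correction.** A proposal scale tied to the current state makes
  the kernel asymmetric; detailed balance then requires the ratio
  $q(\theta|\theta')/q(\theta'|\theta)$ in the acceptance probability. The
  correction is on by default — the grid-posterior validation below shows
  the corrected chain reproduces the exact posterior — and can be switched
  off (`hastings_correction = FALSE`) to mimic a plain Metropolis rule.
* **Proposal floor.** The per-coordinate proposal SD is
  $\max(0.05\,|\theta_j|, 10^{-4})$; without the floor a coordinate
  approaching 0 freezes the chain.
* **Initialization.** Method of moments: $\hat p = 1 - \mu/v$,
  $\hat r = \mu^2/(v-\mu)$ from the sample mean and variance, and
  $\hat\omega$ as the observed zero fraction minus the NB-predicted zeros,
  clipped to $[0.01, 0.99]$; fallback $(0.5, 1, 0.5)$ when the moments are
  inconsistent (e.g. under-dispersed or all-zero data). An all-zero dataset
  is valid input; the posterior concentrates at $\omega \to 1$.
* **Single chain.** One chain per dataset, as in the protocol above;
  determinism is guaranteed by seeding, and the validation suite compares
  chains across seeds instead of relying on within-run diagnostics.
* **Speed.** The iteration loop and the ZINB log-pmf (log-gamma form) are
  implemented in C++ (Rcpp) over the tabulated count histogram, using R's
  RNG so `set.seed()` reproduces chains exactly. A 50,000-iteration chain
  on 2,000 cells runs in about a quarter of a second.

## The synthetic-data generator

All tests run on synthetic data; the generator defines the study
conditions rather than adapting to them.

* **Counts.** `sample_zinb()` draws from the ZINB above.
  `default_synthetic_design()` fixes one strain across the metabolite
  ladder 0/5/50/100 µM (0, 1×, 10×, 20×) with repression rising
  ($\omega = 0.1 \to 0.8$) and burst size falling ($p = 0.75 \to 0.5$) as
  concentration increases — the qualitative signature of
  attenuation-mediated shutoff — at 300 cells per condition, a typical
  per-condition segmentation yield for one imaging session.
* **Mechanistic oracle.** `simulate_telegraph()` is an exact Gillespie
  simulation of the two-state promoter (OFF↔ON, transcription while ON,
  first-order decay), started at zero mRNA with the promoter state drawn
  from its stationary switching law. It provides model-independent checks:
  the always-ON limit must give Fano = 1, and the bursty limit
  ($k_{off} \gg k_{on}$, $k_{tx} \gg k_{off}$) must give mean
  $(k_{on}/k_{deg})(k_{tx}/k_{off})$ and an NB-like law whose fitted burst
  size matches $k_{tx}/k_{off}$.
* **Spots.** `generate_spot_table()` emits one spot per molecule with
  intensity $\mathcal N(u, \mathrm{cv}\cdot u)$ truncated at 0 (default
  unit $u = 100$ a.u., cv = 0.05, matching well-focused bacterial smFISH),
  plus a half-normal control population (default scale $0.15u$, putting the
  99.9th control percentile near $0.5u$ — clearly separated from real
  spots). Only control quantiles matter downstream, so the half-normal
  family choice is free. Co-localized multi-molecule spots are represented
  through intensity, not spot multiplicity; real data additionally contain
  segmentation errors, out-of-focus loss and probe-binding variability that
  the generator deliberately omits, so passing tests certify the analysis
  chain, not microscope performance.

## Validation design and numerical conventions

The test suite checks every operation against an independent route:
the ZINB pmf against `stats::dnbinom`, the log posterior against a
term-by-term R summation, the permutation test against `e1071`'s
permutation enumerator, moments against closed forms and brute-force pmf
summation, and the sampler against a brute-force grid evaluation of the
posterior.

Two validation choices deserve explanation:

* **Grid comparison.** On a 20-cell dataset the retained-sample histograms
  of $\omega$ and $p$ (bin width 0.02) are compared with the
  grid-integrated posterior ($r$ integrated on a 0.02 grid up to 60, where
  the half-normal prior leaves negligible mass) by total variation
  distance, with a 0.08 bound at three seeds. The bounded parameters are
  the ones compared because an empirical histogram of any realistic number
  of retained draws cannot approach a fine-grained density on the unbounded
  $r$ axis to that tolerance; the $r$ mode is covered separately by the
  grid-argmax MAP comparison, whose tolerance is two posterior standard
  deviations (the Monte Carlo precision of an argmax over retained draws).
* **Coverage study.** Fifty datasets of 1,000 cells with parameters drawn
  from the priors, chains of 150,000 iterations (30,000 burn-in, thin 50):
  each 95% interval must cover its truth in at least 90% of runs. The
  chain length is three tenths of the production protocol; shorter chains
  (30,000 iterations) measurably undercover in slow-mixing corners of the
  prior (tiny means, $r$ in the prior's far tail), which is a mixing
  limitation of state-scaled random-walk proposals worth knowing about
  when reducing the protocol.

Problem sizes used throughout the suite — $10^5$ draws for moment checks,
20,000 Gillespie cells for the telegraph limits, 2,000 cells × 20
replicates for parameter recovery — were chosen as the smallest sizes at
which the quantities under test are statistically stable at the stated
tolerances.

## Limitations

* The ZINB is phenomenological: it cannot distinguish structural zeros
  ($\omega$) from deep NB zeros when the mean is very low, and the
  $\omega$–$(1-p)^r$ ridge makes joint identifiability poor below a few
  mRNA per cell. Credible intervals widen accordingly; the coverage study
  confirms they widen honestly.
* Burst frequency is reported per mRNA lifetime ($f = r$), not per unit
  time; converting requires an independent estimate of the degradation
  rate.
* The quantification rule assumes intensity scales linearly with molecule
  number within a spot, and starts from detected spots — segmentation and
  spot detection are upstream of this package.
* The exact Spearman test is limited to $n \le 8$ by factorial growth;
  ladders in practice have 4 conditions.
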