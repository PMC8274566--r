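---
title: "Methods: two-stage genomic selection for early-stage testcross trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage genomic selection for early-stage testcross trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlygs)
```

`earlygs` models the decision problem of an early-stage hybrid breeding
program: thousands of new doubled-haploid (DH) lines per year, testcrossed
to a common tester and evaluated in well-watered (WW) and managed
water-stress (WS) trials, with genomic prediction offered as a partial
replacement for the first year of field testing. This vignette documents
the statistical models, the simulator that stands in for unreleased field
data, the numerical choices, and the limits of what the package's tests can
show.

## Stage 1: phenotypic analysis

Each year × management slice is analysed per trait with the linear mixed
model

$$y_{ijrk} = \mu + L_j + R_{r}(L_j) + B_k[R_r(L_j)] + G_i + GL_{ij} +
\varepsilon_{ijrk},$$

where $L_j$ (trial), $R_r(L_j)$ (replicate within trial), $G_i$ (genotype)
and $GL_{ij}$ are fixed and the incomplete block $B_k$ and residual are
random. Two fits are made per slice, the convention of standard
multi-environment-trial software:

* **genotype fixed** — gives the genotype BLUEs by generalized least
  squares at the REML variance estimates (sum-to-zero contrasts on the
  design factors, so each genotype coefficient is its adjusted mean at the
  average trial/replicate);
* **genotype (and genotype × trial) random** — gives the variance
  components $\sigma^2_G$, $\sigma^2_T$, $\sigma^2_{GT}$,
  $\sigma^2_{B}$, $\sigma^2_\varepsilon$ used for reporting.

Both fits are REML fits delegated to `lme4::lmer`; this is a standard
mixed-model computation, and a dense-matrix GLS oracle in the test suite
verifies that the extracted BLUEs equal the explicit
$(X'V^{-1}X)^{-1}X'V^{-1}y$ solution at the fitted variances. Missing plot
values are dropped record-wise; aliased genotype levels are dropped with a
logged warning.

Entry-mean broad-sense heritability is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{gl}/l +
\sigma^2_\varepsilon/(lr)},$$

with $l$ the number of trials in the slice and $r$ the replicate count.
Taking $l$ as the trial count (rather than a location count) is the
convention that reproduces the published per-year heritabilities from their
printed variance components; WS slices are single trials ($l = 1$).
The slice summaries also report CV $= 100\sqrt{\sigma^2_\varepsilon}/\bar y$
and LSD $= t_{0.975,\nu}\sqrt{2\sigma^2_\varepsilon/(lr)}$. Both are
reporting conventions — published CV values for such trials are not exactly
recoverable from printed components, so CV/LSD are deliberately excluded
from any exact cross-check.

## Marker quality control and the genomic relationship matrix

Dominant presence/absence markers carry one observable frequency, the
presence frequency $p$; the minor allele frequency is $\min(p, 1-p)$.
`filter_markers()` removes markers with MAF below the threshold (default
0.05, boundary inclusive — a marker at exactly 0.05 is kept, matching a
"remove MAF < 0.05" rule).

`build_grm()` computes $G = WW'/m$ with columns of the marker matrix
centered and scaled to unit *population* variance (denominator $n$). This
choice makes $\mathrm{trace}(G)/n = 1$ an exact identity (tested to
machine precision), gives a stable scale for variance components, and makes
$G$ invariant to the arbitrary 0/1 orientation of a dominant marker. A
ridge of $10^{-6}$ is added to the diagonal before any solve.

## Stage 2: reaction-norm GBLUP

Line × environment BLUEs are modelled as

$$y_{ij} = \mu + E_i + g_j + gE_{ij} + \varepsilon_{ij}$$

with $E_i \sim N(0, \sigma^2_E)$,
$g \sim N(0, \sigma^2_g G)$, and
$gE \sim N(0, \sigma^2_{gE} (Z_g G Z_g') \circ (Z_E Z_E'))$, where $\circ$
is the Hadamard product and $Z_g, Z_E$ are the record-to-line and
record-to-environment incidence matrices. The default environment
definition is year × management; the fits used by the cross-validation
engine are per management, so the environment factor is the year.
Single-environment input automatically drops $E$ and $gE$, reducing to
plain GBLUP. The two-stage analysis is unweighted (no propagation of BLUE
standard errors into stage 2); a weighting option is a possible extension
but is not implemented, because the scheme being emulated feeds unweighted
adjusted means forward.

**REML.** The variance components of the three kernels plus residual are
maximized by average-information (AI) updates with two safeguards: every
step is accepted only if the restricted likelihood does not decrease
(step-halving toward the current iterate), and when the AI step fails the
fitter falls back to the monotone fixed-point update
$\sigma^2_k \leftarrow \sigma^2_k\,(y'PK_kPy)/\mathrm{tr}(PK_k)$.
Components decaying to zero may be pinned at the lower bound
($10^{-10}\times$ the response variance) when doing so does not lower the
likelihood. Convergence is declared at a relative log-likelihood change
below $10^{-6}$ (cap 200 iterations); the non-decreasing likelihood
trajectory is itself a tested invariant. When $\sigma^2_{gE}$ and
$\sigma^2_\varepsilon$ are nearly aliased — for instance when most lines
are observed in a single environment — the likelihood has a flat ridge and
an occasional fit stops at the iteration cap; the cross-validation engine
counts such fits and reports the tally rather than failing, since the
fitted values on the ridge are indistinguishable.

**Gibbs.** A sampler is provided for fidelity to Bayesian GBLUP practice:
each random term is reparameterized through the eigendecomposition of its
kernel, $u_k = Q_k\alpha_k$, making the full conditionals diagonal;
variances get scaled-inverse-$\chi^2$ priors (df 5, scale set from the
phenotypic variance split evenly across terms). Defaults are 12,000
iterations, 2,000 burn-in, thinning 5, fixed seed. The test suite checks
that posterior-mean GEBVs agree with REML GEBVs (Pearson $r \ge 0.98$) on
a fixture; REML is the default because it is deterministic and
oracle-checkable.

**Prediction.** GEBVs for all lines in $G$ — including unphenotyped ones —
come from $\hat g = \sigma^2_g\, G Z_g' P y$, which the tests verify to be
algebraically identical to the reduced-form propagation
$\hat g_{TST} = G_{TST,TRN} G_{TRN,TRN}^{-1} \hat g_{TRN}$ and, on
$G = WW'/m$, to marker-effect ridge regression with
$\lambda = m\sigma^2_\varepsilon/\sigma^2_g$.

## Forward cross-validation

A scenario is (training years, testing year, conversion fraction $f$,
replications, management, trait). Each replication partitions the
testing-year lines into a converted subset of size $\mathrm{round}(f\,n)$
(ties to even) that joins the training records, and a predicted remainder;
accuracy is the Pearson correlation between GEBVs and the held-out
testing-year BLUEs. "Accuracy" is therefore on the predictive-ability
scale (no division by $\sqrt{H^2}$), matching how such programs report it.
Design rules enforced by construction and asserted by tests:

* converted and predicted sets are disjoint and exhaustive;
* no testing-year phenotype outside the converted subset enters a fit
  (a poisoning probe verifies GEBVs are unchanged);
* lines present in both a training year and the testing year are assigned
  to the testing year and removed from training;
* per-replication seeds derive from a stable hash of the scenario
  descriptor and the master seed, so adding scenarios to a grid never
  perturbs existing random streams.

The replicated-random-partition scheme (20 replications by default) is the
primary design; a conventional within-year k-fold mode is provided as an
auxiliary (`kfold_within_year()`), reflecting that both appear in practice.

## The simulator

`simulate_breeding_program()` generates the data structure the analysis
assumes, with ground truth retained for parameter-recovery tests:

* **Genomes.** A founder pool (binary dominant markers, per-marker presence
  frequency uniform on a configurable range) is crossed into biparental
  populations; each DH line is one recombinant gamete (markers on a single
  synthetic map, constant adjacent-marker recombination fraction, default
  0.05), chromosome-doubled — so the dominant score equals the gamete
  allele and every DH value is one of its two parents' values. The linkage
  creates the within-population LD that makes genomic prediction work.
* **Genetic values.** Additive QTL models per trait (default 200 loci;
  anthesis date and plant height share half their loci with grain yield).
  QTL effects are compound-symmetrically correlated across environments
  (`gxe_corr`, default 0.7), then scaled so each management hits its target
  genetic variance — the simplest structure that produces the
  genotype-by-environment covariance the reaction-norm model estimates.
* **Trials.** Within a year each line is evaluated in one trial per
  management, with a small set of shared checks in every trial connecting
  the design, two replicates, and incomplete blocks randomized anew per
  replicate (alpha-lattice-like structure; the lattice's efficiency
  properties are not reproduced, only its model terms). Year, trial and
  block effects are Gaussian with configurable scales.
* **Stress.** WS reduces the grain-yield and plant-height means by
  configurable fractions (defaults 0.57 and 0.135, the midpoints of the
  published three-year ranges) and shifts anthesis date by +2 days.
* **Heritability targets.** `target_h2_*` are *entry-mean* heritabilities
  on the single-trial design ($l = 1$, $r$ = replicates); the residual
  variance is back-solved from them. The entry-mean scale (rather than
  plot-level) is used because it is the scale the stage-1 fit estimates and
  the scale on which recovery tests are phrased. Defaults take the
  published per-year ranges (e.g. grain yield ≈ 0.75 WW, ≈ 0.30 WS).
* **Cohorts.** Lines are assigned to first-evaluation years with weights
  proportional to the published cohort sizes; an overlap fraction (default
  0) optionally re-evaluates lines the following year, reflecting the
  limited connectivity typical of historical breeding data.

Default scale parameters mirror the motivating program (54 populations ×
57 lines ≈ 3,078 DH lines, 9,155 markers, trial counts 14/34/17 WW and 1 WS
per year). The published line count appears as both 3,068 and 3,086 in
different places of the source material; the generator's default of ~3,078
treats this as a rounding/typo issue and does not attempt to resolve it.

**What the simulator does not emulate:** tester genomes and testcross
dominance (the testcross value is folded into the line's
environment-specific genetic value), selection and advancement between
years, spatial field trends, disease traits, and non-Gaussian error. Tests
passing on this generator therefore demonstrate internal statistical
correctness and qualitative design behaviour — not that real-data
accuracies will match any particular value.

## Problem sizes and numerical tolerances

The test suite runs scaled-down programs chosen to exercise every code path
at interactive speed: oracle identities on 20–50-line fixtures (BLUP vs
closed form to $10^{-6}$; REML vs brute-force Nelder–Mead on the restricted
likelihood to ~3 decimals), variance-component recovery at 400 lines × 4
environments over 10 seeds (±25%), stage-1 recovery at 300–500 lines over
10 seeds (±15% / ±0.1 on $H^2$), and a three-year forward-prediction
experiment at 960 lines × 2,000 markers with 20 replications comparing
$f = 0.3$ against $f = 0$ (paired one-sided t-test). The full-scale
defaults (~3,000 lines, ~9,000 markers) are practical for the simulator and
stage 1, while dense REML at that scale is the known computational limit
(the engine holds $n \times n$ kernels; records beyond a few thousand call
for sparse or eigendecomposition-based approaches, which are out of scope).

## Known limitations

* Stage-2 REML is dense ($O(n^3)$ per iteration in the record count).
* $\sigma^2_{GT}$ is weakly identified when lines are nested in trials —
  it is reported as estimated, and exact heritability checks use published
  variance components, not simulated multi-trial recovery.
* The Gibbs sampler reports posterior means only (no full chain export).
* No marker imputation: marker input must be complete 0/1.
* No training-set optimization, sparse-testing designs, or multi-trait
  models; these are deliberate non-goals of the current scope.
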