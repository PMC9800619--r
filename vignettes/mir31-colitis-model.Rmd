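---
title: "Modelling MIR31-balanced inflammation and epithelial regeneration in DSS colitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MIR31-balanced inflammation and epithelial regeneration in DSS colitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mir31colitis)
```

## The biological question

Dextran sulfate sodium (DSS) in drinking water injures the colonic
epithelium, lets luminal antigens reach the lamina propria, and triggers an
acute inflammatory response — the standard mouse model of ulcerative colitis.
MicroRNA-31 (MIR31) sits at the centre of this response with two opposing
jobs: it *inhibits inflammation* by repressing the cytokine receptors Gp130
and IL17RA, and it *promotes epithelial regeneration* by repressing Axin1 and
Lats1/2, the negative regulators of WNT/β-catenin and Hippo/Yap signalling.
Because one pool of MIR31 serves both functions, the two compete: which
function dominates, and when, depends on the DSS dose and on time.

`mir31colitis` implements a phenomenological ordinary-differential-equation
model of this network, together with the analyses that interrogate it:
wild-type versus MIR31-knockout simulation, calibration to time-course data,
parameter-scaling sensitivity analysis of the proliferative cell number, and
the binding-probability/action-strength competition analysis.

## The model

Fourteen species evolve on a time axis measured in days: the cytokines TNFα,
IL1β, IL6 and IL17; the active transcription factors p-p65 (NF-κB) and
p-STAT3; the receptors Gp130 and IL17RA; MIR31 itself; the WNT/Hippo
regulators Axin1 and Lats1/2 with their transducers β-catenin and Yap; and
the proliferative epithelial cell number $N$ (cells per crypt, in arbitrary
units before normalization).

Every interaction uses Hill kinetics.  An activating edge contributes a
production term

$$ k \, \frac{Y^n}{l^n + Y^n}, $$

and an inhibitory edge multiplies the affected production term by the
complementary repressive factor $l^n/(l^n + Y^n)$.  Every species carries
first-order degradation.  Both choices are deliberate: a pure sum of
saturating production terms can only accumulate, whereas the measured
responses show *adaptation* — a transient rise followed by return to the
pre-treatment baseline — which requires removal terms, and the repressive
form keeps inhibitory edges inside the same Hill framework.  The Hill
coefficient defaults to a single shared $n = 2$ (a modest cooperativity
typical of transcriptional regulation; the value is exposed per parameter
set).

The wild-type network wires four processes:

1. **DSS-induced cytokine production.**  The effective DSS concentration
   $D(t)$ is the drinking-water concentration during treatment and decays
   exponentially (default washout 1/day) after withdrawal — residual DSS
   persists in the gut, so the forcing is not a hard step.  $D$ drives TNFα,
   IL1β and IL6 production (the immune-cell compartment is folded into these
   lumped production terms).  TNFα activates p-p65; p-p65 feeds back on IL1β
   and IL6; IL6 activates p-STAT3 through Gp130, with a weak additional IL1β
   route; p-STAT3 drives IL17 secretion, and IL17 acting through IL17RA
   re-activates p-p65 — the positive feedback loop that sustains
   inflammation.
2. **MIR31 induction** by both p-p65 (rate `kMIRp65`) and p-STAT3
   (`kMIRpST`).
3. **MIR31-mediated repression** of Gp130, IL17RA, Axin1 and Lats1/2.  Each
   inhibition strength is a dimensionless multiplier $\gamma_i$ on MIR31
   inside the repressive factor $l^n/(l^n + (\gamma_i M)^n)$, so scaling
   $\gamma_i$ by a factor $\lambda$ acts multiplicatively.  Each target also
   has a MIR31-insensitive basal synthesis fraction: microRNA repression of a
   transcript is partial, not a hard off-switch.
4. **Epithelial regeneration.**  Axin1 represses β-catenin and Lats1/2
   represses Yap, so MIR31 (by repressing the repressors) raises both
   transducers.  The cell number obeys
   $$ \dot N = k_\mathrm{prolif}\,H^+(\beta\text{-cat})\,H^+(\mathrm{Yap})\,(1 - N/N_\mathrm{max}) - k_\mathrm{damage}\,H^+(\mathrm{IL1\beta})\,N - d_N (N - N_\mathrm{base}), $$
   the simplest form with logistic-capped proliferation driven by the two
   transducers, inflammation-driven loss, and homeostatic turnover.

Two structural additions go beyond the qualitative network diagram and are
worth flagging.  First, p-p65 and p-STAT3 carry small basal activation rates:
day-0 animals show small but nonzero levels of all observables, so the
untreated steady state must not be identically zero.  Second, the basal
(non-repressible) synthesis fractions of the four MIR31 targets differ, and
this is what reproduces the observed sensitivity structure — Gp130's input to
STAT3 operates near saturation and retains a large basal fraction, so even
complete repression of its repressible fraction barely moves STAT3, whereas
IL17RA gates the inflammatory feedback loop with a small basal floor, so its
repression strength has real leverage over the cell number.

In the MIR31-knockout variant, MIR31 production and all four repression
terms are removed; MIR31 is identically zero and regeneration proceeds by
intrinsic proliferation only.  The knockout is exactly the six-coupling zero
limit of the wild type (`gamma* = kMIRp65 = kMIRpST = 0`), which the test
suite asserts by direct pairwise simulation.

## Default parameterization

The supplementary parameter table of the original study is not available, so
the package ships its own calibrated defaults.  Rates were first placed in
typical biological ranges (rates $10^{-3}$–$10^2$/day, half-saturations
$10^{-2}$–$10$ a.u., strengths $10^{-2}$–$10^2$) with species scaled to
order-one peak concentrations, then adjusted against the reference waveforms
(`reference_waveforms()`) and the published qualitative findings until the
model reproduces, under the standard 3.5% wt/vol, 5-day protocol:
the adaptation of MIR31, p-p65 and p-STAT3 with peaks near withdrawal; the
dip-and-recovery of the proliferative cell number; the knockout orderings
(amplified p-p65/p-STAT3 peaks, deeper and slower-recovering cell-number
dip); the dominance ranking of `gammaI17RMIR`, `kMIRp65`, `kMIRpST` over
`gammaGpMIR`, `gammaAxiMIR`, `gammaLatMIR` in the day-5 change ratio; and
the competition landmarks (probability crossings near days 3 and 10, an
intersection-onset threshold near 1.1% wt/vol, a function switch near 3%
wt/vol, maximal action strength near day 5).  These defaults play the role
of the study's fitted parameter set; they are a calibration product of this
package, not transcribed values.

```{r params}
colitis_params()
```

## Simulation

`simulate_colitis()` integrates the stiff system with `deSolve::lsoda`
(relative tolerance `1e-8`, absolute `1e-10`), splitting the integration at
the protocol's switch points so the discontinuous forcing never crosses an
adaptive step.  Initial conditions are the genotype's untreated steady state,
found by integrating the DSS-free system from unit concentrations until the
maximum relative derivative falls below `1e-8` (capped at 500 days) — day-0
animals are at homeostasis.  States that dip below `-1e-9` abort the run;
values in `[-1e-9, 0)` are clamped to zero with a warning, a numerical guard
that does not mask model errors.  The default output grid has 0.01-day
spacing, the resolution at which probability-curve intersections are
localized.

```{r simulate, eval = FALSE}
traj <- simulate_colitis(colitis_params(), dose_protocol(3.5))
observables(traj)   # max-normalized MIR31, p-p65, p-STAT3, N
autoplot(traj)
```

## Synthetic observations

`generate_observations()` stands in for the mouse measurements: it samples
the wild-type observables at discrete days (default
`{0, 1, 3, 5, 6, 8, 10, 13}`, bracketing treatment, withdrawal and
recovery), applies multiplicative Gaussian noise `value * (1 + eps)`
truncated at zero, and normalizes each observable by the maximum of its
replicate means — the same convention as the published summary bars, which
are scaled to their maximum.  Defaults are 3 replicates (the
immunostaining panels; the MIR31 qRT-PCR panel used 4) and a 10% coefficient
of variation, consistent with the published error bars; the true replicate
variances are not recoverable from the figures, so these are explicit
stand-ins.  The generator emulates the *statistical structure* of the
experiments (normalized means over few replicates on a sparse day grid), not
their measurement physics: staining, imaging and segmentation artefacts are
out of scope, noise is uncorrelated across days, and replicate animals are
exchangeable.  Passing tests therefore demonstrate correct recovery under
the stated noise model, not robustness to systematic experimental error.

## Calibration

`fit_colitis()` reproduces the study's fitting strategy: bounded multi-start
optimization minimizing the sum of squared deviations between normalized
model observables and normalized replicate means, equally weighted across
the four observables (max-normalization puts them on a comparable scale).
Starting points are drawn log-uniformly within the bounds — rate-like
parameters span orders of magnitude — and refined with bounded quasi-Newton
minimization (`nlminb`) in log-parameter space; everything is deterministic
given the seed.  By default only the six MIR31 couplings are free: they are
what the downstream knockout and sensitivity analyses depend on, and the
remaining kinetic constants are not identifiable from four max-normalized
curves.  The recovery tests assert twofold agreement only for the three
*sensitive* parameters (`gammaI17RMIR`, `kMIRp65`, `kMIRpST`); the three
insensitive strengths barely influence the fitted curves, so demanding their
recovery would be dishonest about identifiability.

Even the sensitive set is identifiable only up to a gauge: because every
observable is max-normalized, the absolute MIR31 scale is unobservable, and
scaling both induction rates by a constant while dividing `gammaI17RMIR` by
the same constant leaves all four normalized curves essentially unchanged
(the residual signal, through the weakly-coupled Axin1/Lats1/2 arms, sits
below a 5% replicate noise floor).  Recovery studies on synthetic data make
this concrete: for some noise realizations the global optimum lies far from
the generating values along this valley yet fits the data better than the
truth does.  Users calibrating to real data should therefore interpret the
identified quantity as the product of MIR31 level and coupling strength, or
fix one gauge parameter externally.

## Sensitivity analysis

`sensitivity_scan()` multiplies one coupling at a time by a factor
$\lambda \in [0.01, 100]$ (default 25 log-spaced points) and records the
change ratio $\delta_i(t) = |N_{\lambda_i}(t) - N(t)|/N(t)$ of the
proliferative cell number.  Perturbed runs start from the *unperturbed*
wild-type baseline: the scan emulates an acute intervention on a healthy
animal at day 0, not an organism that developed under the altered parameter.
Every scan cell is reproducible by two stand-alone simulations, which the
test suite checks to $10^{-9}$ relative.

## Competition analysis

The competition bookkeeping apportions MIR31 across its four targets plus a
resting pool.  Binding weights are mass-action-style propensities
$w_i = \gamma_i [\mathrm{Target}_i]$ with a constant resting weight $w_0$ —
the minimal choice consistent with "probability of binding to" each target;
the original study does not specify the weight functional (its value of
$w_0$ is likewise unknown; the default puts the resting share near 0.1 at
baseline).  Probabilities are the normalized weights, so
$\sum_i p_i(t) = 1$ exactly; action strengths are
$F_0 = M p_0$, $F_1 = M(p_1+p_2)$, $F_2 = M(p_3+p_4)$ with
$F_0 + F_1 + F_2 = M$ pointwise.  Intersections of $p_1+p_2$ and $p_3+p_4$
are localized by linear interpolation on the 0.01-day grid; more than two
crossings are reported with a warning, with the first and last returned.

Two dose thresholds are found by bisection (tolerance 0.01% wt/vol) over the
treatment concentration: the onset of any intersection, and the switch of
MIR31's major function.  The switch is evaluated, by default, by comparing
the inflammation-inhibition probability at the time its action strength
$F_1$ peaks with the regeneration-promotion probability at the time $F_2$
peaks — the two maximal-action-strength working points of the dose-response
analysis.  A stricter alternative (both probabilities at the single time of
maximal total $F$) is available via `criterion = "total_f_max"`; under that
reading the switch threshold nearly coincides with the intersection-onset
threshold, because near the onset dose the marginal crossing occurs close to
the time of maximal action strength.

## Problem sizes in the test suite

The test and acceptance suites are sized to run comfortably on one CPU:
qualitative trajectory checks use a 0.05-day grid (the intersection analyses
keep 0.01 days); the sensitivity ranking is asserted at the λ-grid extremes;
Monte-Carlo checks of the noise model use 1,000–10,000 replicates at a few
time points; and the parameter-recovery study uses the three sensitive
parameters free, a handful of multi-starts, and a few seeds.  These sizes
are the package's choices for routine verification; all analyses accept
larger grids, start counts and seed sets through their arguments.

## Known limitations

* The model is phenomenological and spatially lumped: no crypt geometry, no
  explicit immune-cell populations, no stochastic (SSA) simulation.
* The exact equations and fitted constants of the original study are not
  public; this package's defaults reproduce its qualitative and headline
  quantitative findings but are an independent calibration, and individual
  rate constants should not be read as measured quantities.
* The binding-weight law and the function-switch criterion are declared
  stand-ins for quantities the original study defines only verbally.
* Only one-at-a-time parameter scaling is implemented; no global
  (variance-based) sensitivity analysis.
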