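# mir31colitis

Dynamic modelling of how microRNA-31 (MIR31) balances inflammation and
epithelial regeneration in DSS-induced mouse colitis.

## The problem

Dextran sulfate sodium (DSS) in drinking water injures the colonic
epithelium and triggers acute, ulcerative-colitis-like inflammation in mice.
MIR31 is strongly induced in the inflamed epithelium and plays two opposing
roles with one molecular budget: it **inhibits inflammation** by repressing
the cytokine receptors Gp130 and IL17RA, and it **promotes regeneration** by
repressing Axin1 and Lats1/2, thereby de-repressing WNT/β-catenin and
Hippo/Yap signalling.  This package implements a phenomenological
Hill-kinetics ODE model of that network for researchers who want to simulate
wild-type and MIR31-knockout colitis time courses, calibrate the model to
time-course data, and quantify the competition between MIR31's two functions
across DSS doses.

## The model in brief

Fourteen species (cytokines TNFα/IL1β/IL6/IL17, active p-p65 and p-STAT3,
receptors Gp130/IL17RA, MIR31, Axin1/Lats1/2, β-catenin/Yap, and the
proliferative cell number *N*) evolve by Hill-type production and
first-order decay:

    dY_i/dt = Σ_j k_ij · Y_j^n / (l_ij^n + Y_j^n)  −  d_i · Y_i

with inhibitory edges entering as repressive factors `l^n / (l^n + (γ·MIR31)^n)`
on the affected production terms.  The proliferative cell number follows
logistic-capped proliferation driven by β-catenin and Yap, inflammation-driven
loss gated by IL1β, and homeostatic turnover.

The competition analysis apportions MIR31 across its four targets with
mass-action binding weights `w_i = γ_i · [Target_i]` plus a resting weight
`w0`.  Binding probabilities `p_i = w_i / Σ w_j` split into an
inflammation-inhibition share `p1 + p2` and a regeneration-promotion share
`p3 + p4`; action strengths are `F1 = [MIR31]·(p1+p2)`,
`F2 = [MIR31]·(p3+p4)`, `F0 = [MIR31]·p0`, with `F0+F1+F2 = [MIR31]`
exactly.  The analysis reports the intersection times D1/D2 of the two
probability curves, and two dose thresholds: the lowest DSS concentration at
which the curves intersect at all, and the concentration above which MIR31's
major function (measured at its maximal action strengths) switches from
regeneration promotion to inflammation inhibition.

## Worked example

```r
library(mir31colitis)

params <- colitis_params()        # calibrated defaults
protocol <- dose_protocol(3.5)    # 3.5% wt/vol DSS, days 0-5, 15-day horizon

# wild-type simulation and the four normalized observables
traj <- simulate_colitis(params, protocol)
prof <- competition_profile(params, protocol, traj = traj)
prof

# knockout comparison
ko_comparison(params, protocol)$metrics

# dose thresholds
threshold_no_intersection(params, protocol)
threshold_function_switch(params, protocol)
```

Output:

```
<competition_profile> 3.50% DSS: D1 = 2.94 d, D2 = 8.64 d, F max at day 5.47
# A tibble: 2 × 6
  genotype peak_pP65 peak_pSTAT3 min_N baseline_N recovery_time
  <chr>        <dbl>       <dbl> <dbl>      <dbl>         <dbl>
1 WT           0.888        1.06 0.613       1.11          9.89
2 KO           1.01         1.12 0.539       1.11         11.4
threshold_no_intersection: 1.557617
threshold_function_switch: 1.59668
```

Reading the numbers: under the standard protocol the inflammation-inhibition
binding probability overtakes the regeneration-promotion probability on day
2.9 and hands dominance back on day 8.6, so MIR31 acts mainly as an
inflammation brake while DSS injury is active and as a regeneration promoter
otherwise; its total action strength peaks just after DSS withdrawal (day
5.5).  Knocking MIR31 out raises the p-p65 and p-STAT3 peaks (here by 14%
and 6% relative to wild type), deepens the proliferative-cell trough (0.54
vs 0.61 of baseline) and delays recovery to 90% of baseline by a day and a
half — MIR31 both restrains inflammation and accelerates epithelial
recovery.  The two dose thresholds mark where the probability curves first
intersect at all and where inflammation inhibition becomes the major
function at the action-strength peaks.

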