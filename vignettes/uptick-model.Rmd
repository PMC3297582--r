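---
title: "The comK uptick model: assumptions, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The comK uptick model: assumptions, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uptick)
```

## The biological problem

Competence for DNA uptake in *Bacillus subtilis* is a bimodal cell fate: only
10–20% of a clonal population switches ON, by crossing a threshold of the
master regulator ComK. The switching probability is not constant in time. The
basal firing rate of the *comK* promoter rises transiently as the culture
approaches stationary phase and then falls — the "uptick" — and this window
defines when transitions can happen. This package implements a stochastic
model of the uptick built from three ingredients:

1. **A global core-promoter activity** `g(t)`: even promoters stripped to
   their −35/−10 motifs rise and fall around the entry into stationary phase
   (time `t0`). We treat this as an extrinsic, dimensionless multiplier of
   every transcription propensity.
2. **Rok**, a constitutively present repressor that binds an AT-rich region
   overlapping the activation site A2 (K_D ≈ 15 nM) and an auxiliary site
   (residual K_D ≈ 50 nM). Its pool size does not change over the experiment.
3. **Spo0A~P (OA~P)**, which accumulates steadily after the entry into
   stationary phase and acts twice on the promoter: first as an
   *anti-repressor* of Rok and direct activator through sites A1–A3
   (K_D ≈ 50 nM), later as a *repressor* through the weaker operator sites
   R1–R2 (K_D ≈ 125 nM). The affinity ordering K_D(A) < K_D(R) is what makes
   activation precede repression as OA~P rises.

The model deliberately excludes the ComK positive-feedback loop, downstream
competence genes and the phosphorelay that generates OA~P: the question it
answers is whether Rok and OA~P acting on the basal promoter are *sufficient*
to produce the uptick and the observed mutant amplitudes.

## The transcription propensity

Each promoter copy carries sites A1, A2, A3, R1, R2 (OA~P) and the two Rok
sites; A2 is competed for by OA~P and Rok. Given an occupancy state, the
transcription propensity is

```
k_tx_base * g(t) * alpha^nA * rho_rok^nRok * rho_R^nR
```

with `nA` the number of OA~P-occupied A sites, `nRok` the number of
Rok-occupied sites and `nR` the OA~P-occupied R sites. Two design choices are
folded into this form:

* **Non-displacing anti-repression.** OA~P bound at A sites raises
  transcription multiplicatively even while Rok remains bound at the
  auxiliary site. This mirrors the behaviour reported for ComK-type
  anti-repression, which antagonizes Rok without removing it from the DNA.
  Competition is direct only at A2, where the two proteins exclude each
  other.
* **Multiplicative repression.** Each Rok site contributes `rho_rok` and each
  occupied R site `rho_R`. The product makes joint repression by Rok and
  OA~P stronger than either alone, which is what lets the wild type shut the
  window abruptly while single mutants develop a shoulder.

An alternative activation rule (`activation_mode = "all_or_none"`, boosting
only the fully A-occupied promoter) is exposed for comparison; the default is
per-site because the single-site mutants A1 and A3 each collapse activation
in the experiments, implying the sites act additively rather than as an
all-or-nothing unit being necessary for any boost.

## Drives

`g(t)` is a Gaussian rise to exactly 1 at `t0 = 2.25 h` (the growth-curve
inflection) followed by a two-exponential decline (`tau_fast = 0.4 h`,
`tau_slow = 3 h`, shoulder weight 0.25, late floor 0.05). Any smooth unimodal
curve with a late shoulder satisfies the constraints the data put on this
function; this closed form was chosen for its small parameter count and is
shared (same compiled code) between the stochastic engine and the
deterministic oracle. The spo0A drive `h(t)` rises like `g` but is held at
its maximum afterwards, so the OA~P pool keeps accumulating — the
developmental clock. Phosphorylation is not modelled separately: all newly
produced Spo0A counts as OA~P, reflecting how quickly the phosphorelay
processes new protein.

A cell volume of 1.66 fL makes 1 nM equal one molecule per cell, so gel-shift
K_Ds can be read directly as molecule counts.

## What is measured and what is calibrated

The binding side of the model is pinned by gel-shift measurements: 50 nM for
the A sites, 125 nM for R1/R2, 15 nM for Rok at A2 and 50 nM for the residual
Rok interaction. The kinetic side is not measured; only equilibria are. We
therefore set a single fast on-rate (`k_on = 100` per molecule per hour, so
site occupancy is in quasi-equilibrium on the time scale of the drives) and
calibrate the remaining free coefficients against the printed comparative
amplitudes, using `calibrate_defaults()`:

* wild type / Δspo0A peak ratio ≈ 9,
* Δrok / wild type ≈ 5,
* ΔrokΔspo0A / Δrok ≈ 0.6,
* ≈ 30% peak decrease when spo0A is deleted in the A123 site mutant,
* ≈ 1 transcript per cell at the wild-type peak,

plus the qualitative orderings Δrok > A2 > wt > A123 > Δspo0A and the faster
wild-type shutdown. Scoring uses a deterministic mean-field evaluation: site
occupancies in quasi-equilibrium with the deterministic OA~P trajectory, and
the expected propensity computed exactly as the product of per-site factors.
The winner maximizes the worst constraint margin; `k_tx_base` is then set so
the wild-type peak mean mRNA is 1. The shipped defaults are the output of
this calibration (`alpha = 2.8`, `rho_rok = 0.05`, `rho_R = 0.25`,
`rok_copies = 120`, `oap_rate0 = 1550 /h`, `oap_decay = 0.12 /h`,
`k_tx_base = 19.185 /h`, `k_deg_mrna = 10 /h`). They are a documented
stand-in for rate tables that are not reproduced here, not measured values.

Two calibration findings are worth recording. First, with `alpha` forced to
1 (pure anti-repression, no direct activation) no parameter combination can
push the ΔrokΔspo0A peak *below* the Δrok peak: in a Rok-less background
OA~P would only repress. Reproducing the ~60% recovery therefore requires
OA~P to be a direct activator as well — the calibration selects `alpha > 1`.
Second, the constraint set is tight: the ~9-fold spo0A effect pushes toward
complete displacement of Rok from A2 at the wild-type peak, while the
requirement that the A2 point mutant *exceed* the wild type requires that
displacement stay incomplete. The default set sits where every constraint
holds inside its ×1.5 band, with the double-mutant recovery (≈45% rather
than 60%) and the two site-mutant orderings being the binding constraints.

**Mutated boxes retain residual affinity.** Site mutations in the
experiments leave 2/7 consensus bases and demonstrably do not abolish
binding. Mutant presets therefore scale a site's affinity by 0.135 rather
than deleting it; the A2 (and A123) presets additionally remove the
high-affinity Rok interaction at A2, whose loss is seen directly in gel
shifts, while the residual ~50 nM Rok binding is carried by the separate
auxiliary site. With the A sites fully destroyed instead, deleting spo0A in
the A123 mutant could only *increase* the amplitude (OA~P would act purely
at R1/R2), contradicting the observed ~30% decrease; the residual affinity
is what lets a weak activating role survive in that strain.

## The stochastic engine

Networks are simulated with Gillespie's algorithm in compiled code. The two
time-dependent drives are handled by capping each exponential waiting time at
`dt_max = 0.01 h`: if the drawn time exceeds the cap, the clock advances and
propensities are refreshed without firing. Because `g` and `h` vary on ~1 h
scales, the residual bias is far below sampling noise; the suite checks that
halving the cap moves ensemble means by less than 1%. On autonomous networks
the algorithm is exact, verified against the analytic immigration–death
moments and the master-equation solution of the two-state telegraph model.
Snapshots are recorded on a 0.05 h grid (≥ 20 points across the ~1 h uptick);
ensembles run with seeds `base_seed + run index`, so any run can be
reproduced in isolation, and keep only streamed reductions (mean counts,
per-run mRNA snapshots, transcription event times).

Ensemble sizes in the tests and the acceptance script are 1000 runs per
strain (2000 for the dual-promoter correlation). The amplitude ratios are
ratios of smoothed peak means and are already stable at a few hundred runs;
the suite checks directly that 250-run subsets move the headline ratios by
less than 15%.

## Observables

The luciferase observable of the experiments reports the transcription
*rate*, so the model's primary output is the ensemble-mean transcription
event rate in 0.1 h bins (`mean_rate_curve`), not the mRNA level; mean mRNA
is carried alongside for the transcripts-per-cell calibration. "Amplitude"
is the maximum of the rate curve after a centered 3-bin moving average
(suppressing bin noise; ties broken at the earliest time), and the decay
half-time is the interpolated first crossing of half the peak, computed on
the raw curve so that exact geometric cases (e.g. a triangular pulse) give
exact answers.

## Noise decomposition

Two identical promoter copies in one simulated cell share the OA~P and Rok
pools and the global drive. The Pearson correlation of their transcript
counts across the ensemble at a fixed time then measures the extrinsic share
of the noise. Under the calibrated defaults the correlation stays near zero
(the OA~P pool is ~10²–10³ molecules, so its relative fluctuations are a few
percent), reproducing the reported conclusion that competence-determining
noise is intrinsic to the promoter. The suite also demonstrates the
mechanism the other way: with a deliberately small OA~P pool (~10 molecules,
K_Ds scaled to match) the correlation becomes clearly positive, and freezing
the pool at its mean removes it.

## Single-cell cytometry pipeline

The pipeline starts from per-cell mean CFP/YFP intensities (image
segmentation is out of scope). Threshold calibration takes a late reference
population in which a ComK-dependent reporter separates ON cells above a
50 a.u. cutoff, measures the ON fraction, and places the CFP threshold at
the nearest-rank `(1 − fraction)` quantile of the early CFP distribution
(the `floor(n(1−f))`-th order statistic); classification uses strict
inequality. Both conventions are fixed for bit-reproducibility. The YFP
boundary for the proportion comparison is analyst-supplied, as in the
original analysis, and the "two-tailed t-test" quoted for two proportions is
implemented as the standard two-proportion z-test with pooled variance (a
t-test is not well defined for two binomial proportions); Fisher's exact
test is computed as a cross-check whenever any cell of the 2×2 table is
below 5.

## The synthetic cell generator

`generate_cells()` emulates the statistical structure the pipeline assumes:
uniform 12–16 a.u. autofluorescence in both channels, a log-normal YFP
signal for the OA~P reporter, a raised-cosine "window" of competence
probability over an intermediate YFP range (rescaled to hit the target ON
fraction, 13.3% by default), ON-cell CFP from a log-normal truncated above
the planted 36 a.u. threshold and OFF-cell CFP kept strictly below it.
These distribution families are modelling choices; only the qualitative
structure (background floor, bimodal CFP, window-shaped dependence on the
OA~P reporter) is constrained by the data. Because ON and OFF cells are
separated exactly at the planted threshold, passing recovery tests shows the
pipeline arithmetic is right — it does not show robustness to overlapping
populations, which real data may have. `generate_null_cells()` keeps the
marginals but makes competence independent of YFP, for calibrating the
type-I error of the boundary test.

## Known limitations

* The rate coefficients are calibrated, not measured; other parameter sets
  inside the ×1.5 bands exist, and conclusions should rest on the ratios and
  orderings, not on absolute propensities.
* The double-mutant recovery calibrates to ≈ 45% against the printed ≈ 60%;
  the structural analysis above explains why these constraints trade off.
* OA~P accumulation is deterministic in shape (its stochasticity is only
  copy-number noise); bursts in spo0A expression are not modelled.
* The model stops at basal transcription: no ComK protein, no positive
  feedback, no comG reporter, so the simulated mRNA distributions describe
  the OFF-state population only.
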