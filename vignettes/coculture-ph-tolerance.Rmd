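---
title: "Modeling pH-mediated lag and antibiotic tolerance in Lactobacillus-Acetobacter co-cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pH-mediated lag and antibiotic tolerance in Lactobacillus-Acetobacter co-cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocultol)
```

# The system

*Lactobacillus plantarum* (Lp) ferments glucose to lactate and acidifies its
medium from a starting pH near 6.75 down to roughly 3.7, at which point its
own growth arrests. *Acetobacter* species (here generically "Ax"; *A.
pomorum* is the efficient reference partner) consume that lactate, raising
the pH back toward neutrality late in the culture. This cross-feeding loop
has two measurable physiological consequences for Lp: inocula taken from
co-cultures (neutral-pH history) exit stationary phase with a much shorter
lag than inocula from acidified monocultures, and the same pH history
changes how fast the population is killed by bactericidal antibiotics —
faster killing of acid-adapted cells by rifampin, slower killing by
erythromycin — without any change in the MIC. That combination (unchanged
MIC, longer time to kill) is *tolerance*, as opposed to resistance.

`cocultol` implements the full quantitative pipeline around these
observations — growth-curve kinetics, interaction scoring, ratiometric pH
inference, MIC and time-kill analysis, single-cell classification, and the
statistical comparisons — together with a mechanistic generator that
produces every input the pipeline consumes, with known ground truth.

# The generative model

## Community dynamics

`simulateCommunity()` integrates a deterministic consumer-resource system
per culture condition. State variables: Lp biomass $B_{Lp}$ and Ax biomass
$B_{Ax}$ (OD-equivalent units), glucose $G$ and lactate $L$ (mM), and the
Baranyi physiological state $q$ of Lp.

$$
\begin{aligned}
\mu_{Lp} &= \mu^{max}_{Lp}\,\frac{G}{G+K_G}\,\gamma_{Lp}(\mathrm{pH})\,\frac{q}{1+q},
&\dot B_{Lp} &= \mu_{Lp} B_{Lp}, \qquad \dot q = \mu^{max}_{Lp}\gamma_{Lp}(\mathrm{pH})\,q,\\
\dot G &= -\mu_{Lp} B_{Lp}/Y_G,
&\dot L &= y_{LG}(-\dot G) - v_A B_{Ax} \frac{L}{L+K_L},\\
\dot B_{Ax} &= \mu^{max}_{Ax}\,\frac{L}{L+K_L}\,\gamma_{Ax}(\mathrm{pH})\,B_{Ax},
&\mathrm{pH} &= \mathrm{pH}_0 - \Delta\mathrm{pH}_{max}\frac{L}{L+K_{buf}}.
\end{aligned}
$$

$\gamma$ is the Rosso cardinal-pH factor (`cardinalPh()`), equal to 1 at
the optimum and 0 outside $(\mathrm{pH}_{min}, \mathrm{pH}_{max})$. Three
deliberate simplifications:

* **pH is algebraic, not dynamic.** The saturating buffering map makes pH
  the instantaneous image of accumulated lactate. This keeps the map
  invertible and testable; it ignores acetate production and CO2 chemistry
  (out of scope).
* **Lag is carried entirely by one scalar.** The inoculum's Baranyi state
  is set by its parent culture's final pH through a monotone logistic
  `historyState()` with midpoint halfway between 3.77 and 7. A neutral-pH
  parent gives $q_0 \approx 2$ (lag well under an hour); an acidified 48-h
  parent gives $q_0 \approx 0.04$ (a multi-hour lag). No molecular
  mechanism is claimed — one state suffices to reproduce the
  history-dependence of lag.
* **Less efficient lactate consumers** (the *A. orientalis* /
  *A. aceti*-like partners) are modeled purely by a smaller uptake preset
  `vA`; the design of the experiment does not change.

The solver is deSolve's adaptive `lsoda` at `rtol = 1e-8` with dense output
on the plate-reader grid (8.3-min spacing). An adaptive stiff-capable
integrator was chosen over an explicit Runge-Kutta because the late-culture
regime (lactate rundown under strong uptake) is mildly stiff; the contract
is refinement stability — halving the tolerance moves no state by more than
$10^{-6}$ relative — which the test suite checks.

## Frozen default parameters

The study's medium composition (glucose content, buffering capacity) is not
measured anywhere in the source data, so the defaults in
`communityParams()` are presets tuned once against four qualitative
anchors and then frozen:

* Lp monoculture ends near the observed common final pH of ~3.7 (the
  default run ends at pH 3.700 with $\mu_{Lp} < 10^{-3}$/h);
* co-culture lactate at 48 h is below 2 mM (the default run fully clears
  it);
* co-culture pH reaches its minimum before 48 h and then rises;
* co-culture final Lp biomass is at least the monoculture's (2.00 vs 1.30
  OD in the default run, since the monoculture arrests on pH with ~28 mM
  glucose unconsumed).

They are presets of the artifact, not facts about the organisms; anyone
fitting real plates should re-estimate them.

## Observation layers

`observePlate()` adds the optics: OD600 is biomass plus a blank offset
with Gaussian noise ($\sigma$ = 0.003 OD); the BCECF channels are generated
from the trajectory pH through the forward sigmoid
$R(\mathrm{pH}) = R_{min} + (R_{max}-R_{min})/(1+10^{n_H(pK'_a-\mathrm{pH})})$
(defaults $R \in [0.5, 3.5]$, $pK'_a = 6.98$, $n_H = 1$) split into a
440-excited channel (intensity scale + background) and a 490-excited
channel (scale × ratio + background). Dye-free control wells emit
background only. All generators are pure functions of (params, design,
seed).

`simulateDoseResponse()` emulates a 24-h endpoint MIC plate over a two-fold
ladder: a Hill factor with midpoint at $\mathrm{MIC}/\sqrt{2}$ (between the
ladder point below the MIC and the MIC itself) and slope 40 suppresses the
carrying capacity essentially completely at and above the true MIC. The
default plate design — four replicate wells per concentration and a
twelve-well media-blank row — was chosen so the two-standard-deviation
blank rule is statistically well calibrated at the plate noise level;
sparser designs make the empirical blank SD unstable and the rule
occasionally mis-calls by one dilution step.

`simulateKillExperiment()` draws CFU tables under the delayed exponential
killing model $S(t) = e^{-k\max(0, t-d)}$ with the acid-adaptation state
$s \in [0,1]$ (from the parent culture's final pH) coupled into the rate:
$k = k_0(1+\theta s)$ for rifampin ($\theta > 0$: acid-adapted die faster)
and $k = k_0(1-\theta s)$ for erythromycin (acid-adapted are protected).
Plating picks the serial dilution whose expected colony count lands in the
countable 3–300 band and draws Poisson colonies; zero-colony spots are
below the limit of detection, $\mathrm{LOD} = 1/(\text{volume}\times
\text{dilution})$.

`simulateCellTracks()` draws birth length and width per cell from the
observed morphology (Lp 2.46 ± 0.78 µm by 0.72 ± 0.12 µm; Ap 1.66 ± 0.38 µm
by 0.90 ± 0.09 µm) as a *correlated* bivariate normal — correlations 0.54
(Lp) and 0.04 (Ap) chosen so the implied aspect-ratio SDs match the
observed 0.91 and 0.46. Independent marginals would inflate the ratio
spread and overstate classifier error. Cells then elongate exponentially
after a condition-dependent lag, with multiplicative per-frame measurement
noise.

# The analysis pipeline

## Growth curves

ln-fold curves $y(t) = \ln\frac{OD(t)-\text{blank}}{OD(0)-\text{blank}}$
(sub-blank points are masked, never clipped) are smoothed with a window-5
centered mean filter — edges use a symmetrically shrinking window, which
preserves series length and linear trends — then differentiated centrally
for instantaneous rates and fitted to the modified (Zwietering) Gompertz
model

$$ y(t) = A\,\exp\!\left(-\exp\!\left(\frac{\mu_{max}e}{A}(\lambda - t) + 1\right)\right). $$

Initialization is deterministic (steepest-slope heuristics) with up to ten
jittered restarts; curves never exceeding 0.05 ln-fold — below the plate
noise floor — are declared degenerate ($\mu_{max} = 0$, no lag) rather than
given a meaningless $\lambda$. Whether to blank-subtract before
ln-normalizing is a genuine open choice; the default subtracts (the
`blank` argument of `fitGrowthCurves()` makes it explicit). Every converged
fit satisfies the model's analytic identities ($y(\infty) = A$; maximum
slope $\mu_{max}$ at $t^* = \lambda + A/(\mu_{max}e)$; tangent at $t^*$
crossing zero at $\lambda$), which the tests verify.

## Interaction score

$\alpha = (OD_{co} - (OD_{Lp} + OD_A))/(OD_{Lp}\,OD_A)$, with synergy
($\alpha > 0$) and antagonism ($\alpha < 0$) called by a two-sided
one-sample t-test against zero at a Bonferroni-corrected level. Because
the score scales as $1/c$ when all ODs are multiplied by $c$, endpoint
reads taken after dilution (the 1:30 PBS read used for saturated cultures)
must be rescaled to undiluted OD first — `scoreReplicates(dilution = 1/30)`
does this. Replicates are paired by index, the simplest reproducible rule
consistent with per-condition SD reporting.

## pH inference

Background-corrected 490/440 ratios are inverted through a four-parameter
log-logistic calibration fitted to standards. Inversion is closed-form and
*censored* outside the range where the ratio is at least 2% of the span
away from either plateau: a BCECF-type dye with $pK'_a \approx 6.98$ is
simply uninformative near pH 3.7, so points there are flagged
`below_range` rather than extrapolated — silent clipping would fabricate
values in exactly the region the acidification argument cares about.
pHluorin emission ratios (475/405 excitation) go through the same ratio
contract but are reported as a monotone intracellular-pH proxy only; no
intracellular calibration exists.

## MIC, kill curves, and the tolerance call

The MIC rule: a concentration is "no growth" iff its mean endpoint OD is
within two standard deviations (population SD — the blanks are the
complete set of media controls, and this makes the call invariant to
duplicated blank wells) of the media-blank mean; the MIC is the lowest
no-growth rung, with non-monotone plates flagged and censoring reported as
`> max` / `<= min` rather than a number.

Survival is normalized to $t = 0$; below-LOD records become upper bounds,
never zeros, and never enter least squares. `fitKillCurve()` fits
$\log S$ to the delayed exponential model; the delay is profiled on a
0.05-h grid and kept only if an F-test at 0.05 says it earns its degree of
freedom, so clean log-linear kill data reduce exactly to no-intercept
regression. MDK99 — the minimum duration to kill 99% — is
$d + \ln(100)/k$. `classifyResponse()` then encodes the taxonomy:
MIC ratio ≥ 4 (two two-fold steps) is resistance; MIC ratio < 4 with
MDK99 ratio ≥ 2 is tolerance; both thresholds are conservative against
dilution-ladder granularity, since no numeric cutoffs are standard.

## Single-cell classification

Tracks are filtered (raw length ever > 6 µm, or ≤ 15 timepoints, removed),
lengths and widths smoothed with the window-5 filter, and each frame scored
by $\log_{10}(\text{length}/\text{width})$ against the 0.375 threshold
(ties count as above; the comparison carries a $10^{-12}$ guard against
floating-point round-off). A cell is Lp if ≥ 90% of frames are above, Ap
if ≥ 90% are below, and *ambiguous* otherwise — ambiguous cells are
excluded from elongation-rate summaries rather than force-classified.
Whether widths should also be smoothed is unstated in the underlying
protocol; they are smoothed by default (`smoothWidth = FALSE` reverts).
On tracks drawn from the observed morphology the confident-call error is
~8–9%, consistent with the ~13% analytic per-frame overlap bound of the
two ratio distributions and with the ~10% error measured for
fluorescently tagged strains.

## Statistics

`ttestTwoSample()` is the pooled-variance Student's test (Welch behind a
flag; "Student's" is read literally), with star tiers at the
Bonferroni-corrected levels $0.05/n$, $0.01/n$, $0.001/n$ where $n$ counts
the comparisons actually performed in the family (per panel, as printed in
legend conventions). Display thresholds round to one significant figure
(0.05/12 → 4 × 10⁻³); exact values are always stored.

# Worked example

```{r example}
params <- communityParams()
design <- experimentDesign(list(
  list(name = "neutral", species = "Lp", parentPh = 7),
  list(name = "acid", species = "Lp", parentPh = 3.77)),
  duration = 24, replicates = 3)
trajs <- simulateCommunity(params, design)
plate <- observePlate(trajs, params, design, seed = 1)
fits <- fitGrowthCurves(plate)
aggregate(lag ~ condition, fits, mean)
```

A neutral-pH parent history yields a lag well under an hour; the acidified
history yields close to three hours — the ordering the single-scalar
history state was built to produce, recovered here through the full
observation-plus-fitting pipeline.

# Problem sizes and what the tests show

The test suite and `scripts/acceptance.R` run on deliberately modest
problem sizes — 48-h plates at 8.3-min spacing (347 points), 25–50 seeded
replicates for noise studies, 40 seeds for the end-to-end direction checks,
10,000 simulated families for the type-I calibration, 400 cells per species
for the classifier — sizes a desktop analysis of one experiment would use.

Passing tests demonstrate internal consistency: the pipeline recovers the
generator's ground truth under the generator's noise model. They do not
validate the ODE presets against real MRS cultures, and the generator
deliberately omits features of real data — acetate chemistry, oxygen
limitation, dye bleaching and leakage, segmentation artifacts beyond the
length cutoff, biological replicate-to-replicate variability beyond
observation noise. Known limitations worth restating: pH below ~5.3 is
outside the BCECF calibration's valid range and is censored (real
experiments reporting such values must have extrapolated); the kill model
is single-exponential and cannot represent persister subpopulations
(biphasic decomposition is explicitly out of scope); and interaction
scores are only comparable across experiments on a common OD scale.
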