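---
title: "The S-TOL block-design fNIRS pipeline: models, design choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The S-TOL block-design fNIRS pipeline: models, design choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stolfnirs)
```

## The task and its combinatorics

The S-TOL presents a start and a goal board — three pegs of capacities
3, 2 and 1 holding three distinct colored balls — and asks on every trial
whether the goal can be reached in exactly two moves. Only the top ball
of a peg moves, and a peg never holds more balls than its capacity. Under
these rules the state space has exactly 36 configurations (six feasible
occupancy patterns of the capacity-(3,2,1) pegs times the 3! assignments
of distinct balls), every state has at least two legal moves, and the
state graph is connected with diameter 8.

```{r states}
length(enumerate_states())
problem_spec(tol_state(c("red", "green", "blue")),
             tol_state(c("red"), c("green"), c("blue")))
```

Two derived problem attributes matter for stimulus design:

* **Search depth** — a problem *requires an intermediate move* iff every
  optimal solution places some ball on a peg that is not that ball's goal
  peg. We quantify over *all* optimal paths (enumerated over the layered
  shortest-path DAG) because a single direct path means the solver can
  avoid interdependent planning.
* **Goal-hierarchy ambiguity** — operationalized as the number of
  distinct optimal move sequences; 1 means the order of moves is fully
  forced. The task's problems are generated unambiguous by default
  (`require_unambiguous = TRUE`), which is satisfiable for both two- and
  three-move problems, and three-move problems are balanced between the
  two search-depth classes (both classes exist among unambiguous
  three-move problems; the generator verifies this at build time).

The session is fixed by the design: twelve 60-s blocks of six 10-s trials
(7-s study + 3-s response), alternating multiple-move and zero-move
blocks starting with MM, separated by 30-s rests — 1050 s in total, all
marker times exact multiples of the 500-ms sampling interval. MM blocks
mix two- and three-move problems 3 + 3 by default; the ratio is a
parameter because the original design states a mixture without fixing it.

## Behavioral scoring

Accuracy is percent correct per trial type with omitted responses scored
incorrect (denominators are per trial). The 90% criterion that splits
high- from low-accuracy subjects is applied to MM (pooled) and ZM
accuracy and is *inclusive* (exactly 90% passes); strictness was not
specified, and the inclusive reading keeps the boundary subject in the
group its rounding suggests. The MM-vs-ZM error comparison uses the
paired Wilcoxon signed-rank statistic with the tie-corrected normal
approximation, dropping zero differences — the common convention. Two
notes on deliberate choices:

* The effect size is r = z/√N with N configurable as all pairs (default)
  or non-zero pairs; both conventions are in circulation and the default
  is documented rather than silently assumed.
* A degenerate input (all differences zero) raises an error instead of
  returning z = 0: a signed-rank test on an empty set of ranks has no
  sampling distribution, and silently returning a "null" result would
  hide a data problem.

## Preprocessing

**Conversion.** The modified Beer–Lambert law maps optical-density
changes at 730 and 850 nm to oxy/deoxy-hemoglobin changes by inverting
the 2×2 extinction system scaled by source–detector distance × DPF.
Extinction coefficients default to standard published hemoglobin-spectrum
values (in 1/(mM·cm): 0.390/1.1022 at 730 nm, 1.058/0.69132 at 850 nm
for oxy/deoxy) and, like distance (2.5 cm) and DPF (6), are exposed as
arguments — instrument software normally hides these constants, so they
must be configurable here. The ΔOD reference is the whole-recording mean
by default: because the conversion is linear in ΔOD, any constant
reference shift cancels exactly under the per-block local-baseline
referencing applied downstream, so this choice is immaterial for the
analysis while keeping the conversion stateless.

**Filtering.** A linear-phase FIR low-pass of order 20 with 0.1-Hz
cutoff at 2-Hz sampling (Hamming design via `signal::fir1`, coefficients
renormalized to exact unit DC gain) is applied forward and backward, so
the net phase is zero and block timing is not shifted; the effective
magnitude response is the squared design response, which the tests verify
against an independently computed frequency response. Edges are handled
by odd-reflection padding of three filter lengths; output length equals
input length.

**Motion rejection.** The sliding-window detector scores 10-s windows
(5-s hop) by their SD and their largest sample-to-sample jump, converts
both to robust z-scores (median/MAD across windows) and masks windows
exceeding z = 5 on either metric. The thresholds and window length are
design decisions calibrated on the synthetic generator — the original
instrument-side detector's internals are not public — and were chosen
once so that clean Gaussian series are essentially never masked while
planted spikes of the generator's magnitude are caught with sensitivity
above 0.9. Detection runs on the *unfiltered* hemoglobin series: the
0.1-Hz low-pass smears a spike across ten seconds and below the jump
detector's reach.

**Segmentation.** Each 60-s block contributes 120 samples per channel,
referenced by subtracting the mean of that block's first 10 s
(20 samples); rest periods are excluded and the effect code is ZM = −1,
MM = +1, starting +1. Masked samples are simply absent from the output
(unbalanced fits are supported downstream). If an entire baseline window
is masked the block/channel segment is dropped and logged rather than
erroring: this mirrors segment-rejection practice and keeps one unlucky
artifact from aborting a cohort run. Time is 0-based seconds; windows are
half-open.

## The multilevel model

Channel-wise inference uses the random-intercept model on the segmented
rows, condition effect-coded so that twice the coefficient is the MM−ZM
mean difference. Estimation is restricted maximum likelihood, profiled
down to the single variance ratio λ = σ²_u/σ²_ε: with a random intercept
per subject, Woodbury reduces everything to group-level sufficient
statistics, so each criterion evaluation is O(subjects) and a fit costs
little more than one pass over the rows. This matters because the
calibration and recovery suites run thousands of fits. The tests verify
the fitter against a dense-matrix restricted-likelihood oracle (to 1e−6)
and against `nlme::lme` on balanced and unbalanced fixtures, and verify
the exact effect-code contract (2·b equals the raw condition mean
difference to 1e−9 on balanced data). Noiseless fixtures drive σ²_ε to
the boundary; the optimizer works on log λ over [−30, 15] with the
boundary flagged, and coefficients remain exact there because the GLS
solution is λ-insensitive on balanced data.

Degrees of freedom follow the between-within partition: coefficients that
vary within subjects get N − n − k₁ df (k₁ = number of level-1
coefficients), subject-constant coefficients get n − 1 − k₂. For the
condition contrast this is N − n − 1; for the moderation model the
level-1 terms get N − n − 2 and the trait main effect n − 2 — the df
patterns the published channel tables show. A model description stating
both "random intercepts" and an "unstructured covariance matrix" cannot
hold literally at this data scale; the random-intercept reading matches
the reported df magnitudes and is the contract here, with an AR(1)
residual option (`ar1 = TRUE`, via `nlme`) exposed because temporal
autocorrelation is the stated motivation for conservatism.

Channel-wise p-values are Benjamini–Hochberg adjusted across the fitted
channels (step-up with monotonicity, order preserved); a channel is
labelled activated/deactivated only below the adjusted 0.05 threshold.
Per-channel fitting failures become flagged rows, never silent drops.

The moderation model centers the deliberation T-score at the sample mean
of the analyzed subjects (listwise deletion on missing scores), forms the
cross-level interaction, and probes simple slopes at mean ± 1 SD; the
simple-slope identity (slope at D* = γ10 + γ11·D*) and centering
invariance of γ11 are asserted in the tests.

## The synthetic generator

`simulate_cohort` produces the full study structure from one seed:
38 subjects by default, 16 channels at 2 Hz over the fixed 1050-s
schedule, per-trial behavior, and trait T-scores ~ Normal(50, 10).
Signal per channel is

> subject-by-channel tonic level × (all-block response) +
> channel amplitude × (MM-block response) + 1/f noise +
> physiological sinusoids + white noise + planted artifacts,

with responses formed by convolving condition boxcars with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, kernel normalized to unit
plateau). Design constants are computed deterministically from this
model: the local-baseline attenuation factors (how much of a sustained
response survives subtraction of the block's first 10 s, computed on the
*filtered* regressors because the low-pass reshapes the onset rise) scale
the preset amplitudes so fitted coefficients land near the preset's
nominal values, and scale the tonic SD so the realized intraclass
correlation hits its target.

Chosen-once emulation values, with rationale:

* **Effect maps.** Presets `"table4"`, `"table5"`, `"table6"` encode the
  sign pattern and rough magnitude ordering of the reported all-subject,
  high-accuracy and low-accuracy channel contrasts (coefficients of a few
  hundredths of a µM; the implausible order-of-magnitude outlier in the
  first channel of the all-subject table is treated as a misprint and one
  weak borderline channel as null). They do not chase exact printed
  values.
* **Noise.** White 0.35 µM, 1/f 0.08 µM, cardiac 0.9 Hz × 0.15 µM,
  respiratory 0.25 Hz × 0.10 µM, Mayer 0.10 Hz × 0.03 µM. The
  spectrum was set so the channel-wise contrast attains coefficient
  sampling precision on the scale the study itself reports (SEs of order
  0.003 µM at 38 subjects): a generator so noisy that the emulated
  effects became undetectable would not emulate a study that detected
  them.
* **Between-subject structure.** Tonic levels are drawn per subject *and
  channel*, targeting ICC 0.15 (mid-range of the reported 0.03–0.28).
  Channel-specific draws reflect that real between-subject variance
  differs markedly by channel (coupling, regional physiology) and make
  the 16-channel average ICC self-averaging rather than hostage to one
  38-draw sample.
* **Artifacts.** Poisson 0.5 events per channel series, 1–3 samples,
  ±8 broadband-SD spikes, positions recorded in provenance so detector
  sensitivity is computable exactly.
* **Behavior.** Accuracy probabilities 0.889/0.892/0.975 (two-move /
  three-move / zero-move) as reported, with a 1% omission rate.
  Response-time means for MM trials follow the reported values
  (896 ± 155, 1018 ± 206 ms); the reported zero-move mean RT is
  internally implausible (its SD exceeds the mean sixfold), so the
  generator uses 600 ± 150 ms truncated to the 3-s window as its own
  choice.
* **Moderation.** The `"moderation"` preset encodes the crossing
  pattern — high-deliberation subjects tonically elevated in both
  conditions, condition-responsive only at low deliberation — by scaling
  the ROI amplitude with the subject's *cohort-standardized* trait score.
  Standardizing within the cohort (not against the population) makes the
  condition effect vanish exactly at the +1 SD probe point the analysis
  uses; with population scaling, probe-point mismatch of order 1/√n would
  masquerade as a real slope at these row counts.

Seeds: every stream (per-subject signal, behavior, traits) derives from
the master seed; identical seeds give identical cohorts, and signal and
behavior can be varied independently.

## What the synthetic validation does and does not show

Two generators serve two different questions, and conflating them would
produce dishonest greens:

* The **full fNIRS generator** exercises the whole pipeline — forward
  Beer–Lambert optics, filtering, motion masking, segmentation — and
  validates *recovery*: signed channels are recovered in direction and
  FDR significance, the ICC target is hit, behavioral probabilities are
  recovered. Its filtered noise is, deliberately, temporally
  autocorrelated; an independence-assuming random-intercept test applied
  to it yields inflated t statistics (as it arguably does on real
  recordings). Nominal significance levels are therefore *not* calibrated
  on this path, and the suite does not pretend they are.
* The **model-consistent generators** (`simulate_null_long`,
  `simulate_moderation_long`) generate data under exactly the assumptions
  the estimator makes (white within-subject noise, random intercepts,
  balanced effect codes) at reduced length. They validate *calibration*:
  the per-channel test's type-I error at α = 0.05 lands in [0.03, 0.07]
  over 500 replicates, FDR keeps the mean significant-channel proportion
  at or below 0.05 under the global null, and the moderation probe one SD
  above the mean is non-significant in ≥ 90% of replicates while the low
  probe and the negative interaction are recovered.

Neither establishes anything about real tissue: no systemic blood
pressure, no scalp coupling physics, no deoxy dynamics beyond a fixed
−1/3 coupling, no spatial correlation between channels.

## Problem sizes and numerical choices

The validation suites run at the study's size where the property is about
the study design (38 subjects for recovery, 100 full-pipeline
replicates for sign recovery) and at reduced series length where the
property is about the estimator (500 null replicates at 24 rows/subject,
the moderation recovery at 400 rows/subject); these sizes are the
package's own choice of desk-scale precision. Other numerical choices:
BFS neighbor expansion is in deterministic move order (ascending source,
then destination) so path enumeration is reproducible, though only
lengths and counts are contractual; the zero-move problem counts one
(empty) optimal path by convention; REML uses `optimize` with tolerance
1e−10 on log λ; the BH adjustment delegates to `p.adjust`'s step-up with
the from-definition oracle in the tests; marker files carry 3-decimal
seconds; all windows are half-open.

## Known limitations

Channel-wise t statistics on the full synthetic path (and plausibly on
real data analyzed the same way) are anticonservative because residual
autocorrelation is ignored; the AR(1) option mitigates but does not
remove this, and fully honest inference would model the filtered noise
spectrum. The board solver supports any pair of the 36 states but the
task generator only emits 0/2/3-move problems, as designed. The
channel-grid heatmap is a schematic 4×4 layout, not anatomical
topography. The Wilcoxon effect-size denominator and the MM2/MM3 block
ratio remain conventions exposed as arguments rather than fixed facts.
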