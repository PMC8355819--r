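---
title: "Regional expiratory time constants from dynamic 4DCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional expiratory time constants from dynamic 4DCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtau)
```

## The problem

During pressure-controlled mechanical ventilation, exhalation is passive:
airway pressure steps from the inspiratory level (P_insp) down to PEEP and
each lung region deflates at its own pace. Regions that lose aeration
quickly and extensively — typically the poorly aerated, dependent (dorsal)
lung in injury — are the regions most at risk of cyclic collapse and
reopening (atelectrauma). Quantifying *how much* aeration a region loses
during exhalation and *how fast* it loses it therefore matters for choosing
lung-protective ventilator settings, in particular short expiratory times.

Dynamic (respiratory-gated) 4DCT provides one 3D HU volume per breath
phase without interrupting ventilation. After deformable registration to a
common end-inspiratory reference phase, a voxel indexes the same tissue at
every phase, and its time-varying CT density becomes a per-region record of
deaeration. This package implements the voxel-wise analysis of such
registered sequences, together with a synthetic phantom generator that
makes the whole pipeline testable without animal data.

## The exhalation model

Each voxel's expiratory density is modelled as a single-exponential
approach to equilibrium following the pressure step:

$$\hat I(t_n) = D_0 + (D_\infty - D_0)\,\bigl(1 - e^{-t_n/\tau_D}\bigr)$$

with $D_0$ the initial (= end-inspiratory) density, $D_\infty$ the
equilibrium density that would be reached after infinite exhalation, and
$\tau_D$ the density time constant. The elapsed expiratory time of phase
$n$ is $t_n = n / f_s$ with sampling frequency
$f_s = n_\text{phases} \cdot \text{rate} / 60$ (7 Hz for 21 phases at
20 min⁻¹). The end-expiratory density
$D_{EE} = \hat I(t_\text{exp})$ is a *derived* quantity: with a 1:2 I:E
ratio the exhalation lasts $t_\text{exp} = \tfrac{2}{3}$ of the breath
period, and when $\tau_D$ is not small compared with $t_\text{exp}$,
$D_{EE}$ falls short of $D_\infty$. The *nonequilibrated change*
$D_\infty - D_{EE} = (D_\infty - D_0)\,e^{-t_\text{exp}/\tau_D}$
quantifies that shortfall; at $\tau_D = t_\text{exp}/5$ it is
$e^{-5} \approx 0.674\%$ of the total expected change.

Three practical conventions:

* **Exhalation only.** Inspiratory phases never enter the regression; the
  end-inspiratory sample anchors $t = 0$ and is included.
* **End-inspiration detection.** The reference phase is found
  automatically as the phase with the *minimum* within-mask mean HU, i.e.
  the phase of maximal aeration — the gas-filled lung is least dense at
  end-inspiration, which is what visual inspection of time-varying
  intensity histograms identifies. Ties break to the lowest index, a flat
  sequence raises an error instructing a manual override.
* **Fractional phase counts.** When $n_\text{phases} \cdot \tfrac{2}{3}$
  is not an integer, the number of expiratory intervals is rounded to the
  nearest integer with ties resolved toward more expiratory phases, which
  maximizes the number of regression samples.

## Estimation

For fixed $\tau$, the model is linear in $(D_\infty, A)$ with
$A = D_0 - D_\infty$, so the least-squares problem is solved by *variable
projection*: the profiled SSE is evaluated on a lattice of
$\log_{10}\tau$ (0.01 decades over $[10^{-3}, 10^{2}]$ s), the linear
subproblem being solved exactly at every candidate, and the per-voxel
optimum is then refined by golden-section search. The procedure is
deterministic (no starting values, no randomness), vectorized across all
voxels simultaneously, and bounded: estimates ending at the $\tau$ lattice
bounds are flagged `at_bound`; exactly constant series return
$D_0 = D_\infty$ with $\tau$ undefined. Series are mean-centred before
fitting so the SSE arithmetic is well conditioned at lung HU magnitudes.

**Noise mitigation by downsampling.** Before regression, sequences are
block-mean downsampled (default factor 2, e.g. 0.6 mm to 1.2 mm), which
divides the HU noise SD by $\sqrt{8}$; the mask follows by majority vote.
This is the method's primary defence against reconstruction noise and is
what makes time-constant recovery accurate at realistic noise levels (see
below).

**Significance filtering.** Each voxel's regression is tested against the
mean-only model with
$F = \dfrac{(SSE_\text{mean} - SSE_\text{model})/2}{SSE_\text{model}/(n-3)}$
referred to $F(2, n-3)$; voxels with $p > 0.05$ are excluded from all
regional analyses (no multiple-testing correction; the threshold is
per-voxel and configurable). Because $\tau$ is a *profiled nonlinear*
parameter, this reference distribution is approximate: on simulated null
(constant + noise) voxels at $n = 15$ samples the realized rejection rate
is about 3.4%, i.e. the filter is mildly conservative relative to its
nominal 5% level. The alternative convention of counting only one
numerator degree of freedom is badly anti-conservative (~12%) and is not
used. Exclusion errs toward dropping voxels, which matches the filter's
screening purpose.

## Gas-volume dynamics (SACJ)

CT density conflates tissue and gas. The specific air volume change by
corrected Jacobian isolates the gas compartment under the two-compartment
assumption (gas −1000 HU, tissue 0 HU):

$$\mathrm{SACJ}_n = J_{n\to 0}\,\frac{I_n}{I_0} - 1$$

where $J_{n\to 0} = V_n / V_0$ is the Jacobian determinant of the
registration transform (the ratiometric voxel volume change). SACJ is 0 at
the reference phase by construction, negative where gas volume is lost,
and bounded below by −1. Intensities are clamped to $[-1000, 0]$ HU before
use; voxels with no gas at reference ($I_0 \ge 0$) are excluded and
counted. Fitting the same exponential model to the SACJ series (initial
value estimated freely, not pinned to its definitional 0 — the regression
treats SACJ exactly as it treats density) yields gas-volume time constants
$\tau_{SACJ}$. Under tissue conservation,
$J_{n\to 0} = (I_0 + 1000)/(I_n + 1000)$, and the composed SACJ trajectory
of a deflating voxel relaxes *faster* than its density, so
$\tau_{SACJ} < \tau_D$ voxel-wise — the package reproduces this ordering
exactly on noiseless phantoms.

Jacobians may be supplied directly or computed from displacement fields by
central differences (one-sided at the grid boundary), a second-order
scheme that is exact on affine fields; nonpositive determinants inside the
mask (folding) raise a warning with a voxel count.

## Regional analyses

* **Aeration classes** at standard thresholds: hyper-aerated < −900 HU,
  normally aerated [−900, −500), poorly aerated [−500, −100), non-aerated
  ≥ −100 HU (lower-edge-inclusive, a convention the thresholds' prose
  leaves open).
* **Height profiles**: voxels are binned by relative height along the
  user-declared dorsal-ventral axis (0 = dorsal-most masked extent,
  1 = ventral-most; normalization over the whole-lung mask bounding range,
  10 bins by default), reporting per-bin median/IQR of $D_{EI}$, $D_{EE}$,
  intratidal change and $\tau_D$.
* **Parametric response map**: a 2D probability histogram over
  ($D_{EI}$, $D_\infty$) — the predicted equilibrium density stands in for
  the quasi-static end-expiratory density of conventional PRMs — with
  25 HU bins over [−1000, 100] HU, averaged across subjects. Median
  $\tau_D$ and median nonequilibrated change are overlaid only in cells
  where at least half the subjects contribute at least 5 voxels.
* **Normalized convergence**: per voxel, $\tau_D/t_\text{exp}$ against
  $(D_\infty - D_{EE})/(D_\infty - D_0)$, compared with the theoretical
  curve $f(x) = e^{-1/x}$; voxels with $|D_\infty - D_0| < 5$ HU are
  omitted from this normalization to avoid division blow-up.
* **Whole-lung mechanics**: the same exponential model fitted to the
  exhaled-volume waveform (200 Hz) over the first complete expiratory
  window gives the overall mechanical time constant; driving pressure
  (P_insp − PEEP) over tidal volume gives dynamic elastance.
* **Density–SACJ correlation**: per-subject Spearman rank correlation of
  paired significant time constants (rank-based because the joint
  distribution is skewed and the identity-line comparison is ordinal in
  nature; the choice between Pearson and rank statistics was open).

## The phantom generator

The generator emulates the statistical structure the analysis assumes, so
every downstream stage can be validated against analytic ground truth:

* **Geometry**: an ellipsoidal lung interior minus a cylindrical airway
  channel, 48³ voxels at 1.2 mm by default (~36 000 masked voxels — large
  enough for height-decile statistics at desk scale).
* **Equilibrium density**: a gravity-dominated latent field
  (dorsal = denser), quantile-mapped so that aeration-class quotas at
  $D_\infty$ hold exactly (baseline 5/70/20/5% hyper/normal/poor/non;
  injured 3/45/35/17%). The smooth perturbation fields are demeaned within
  each height slab, so the gravitational profile is exactly the designed
  monotone one.
* **Intratidal amplitudes** concentrate where real lungs concentrate them:
  normally aerated 70–180 HU, poorly aerated 90–250 HU (injured patches
  120–300 HU), while hyper- and non-aerated voxels are 80% exactly static
  (airway/vessel/atelectasis analogues for the exclusion logic) and
  otherwise weak (20–60 HU). A 2% paradoxical fraction *loses* density
  during exhalation (30–80 HU), exercising sign handling and the
  above-identity PRM region. These choices follow an a priori power
  analysis: at the study noise level (15 HU SD) and 15 expiratory samples,
  amplitudes of this size keep the post-downsampling F-filter power near 1
  and median τ recovery error under 10%, while the static fraction
  supplies realistic excluded voxels.
* **Time constants**: 0.15–1.0 s, dorsal-fast/ventral-slow. The upper end
  keeps $e^{-t_\text{exp}/\tau} \lesssim 0.2$ at the 2 s exhalation,
  consistent with near-equilibration of most voxels within the breath.
* **Noise**: i.i.d. Gaussian HU noise, default SD 15 HU — a free parameter
  of the phantom, not a claim about any scanner; it is chosen to stress
  but not break the significance filter at 13–21 phases.
* **Deformation**: the analytic-Jacobian mode emits the tissue-conserving
  $J = (I_0+1000)/(I_n+1000)$ from noiseless intensities; the displacement
  mode emits a uniform per-phase axial compression whose Jacobian has a
  closed form, stored alongside for verification.
* **Ventilator trace**: 200 Hz square pressure wave with exhaled volume
  rising as $V_T(1 - e^{-t/\tau_V})$ ($\tau_V$ = 0.35 s baseline, 0.25 s
  injured — faster than the density time constants, as gas-volume dynamics
  should be), P_insp/PEEP/V_T defaults at typical pressure-controlled
  settings for a ~10 kg animal.
* **Inspiratory phases** are a linear re-inflation placeholder: they exist
  so end-inspiration detection has a full cycle to scan, and are never
  fitted.

What the phantom does *not* emulate — CT texture and beam hardening,
cardiac-motion asynchrony, breath-to-breath variability, registration
error in the Jacobians — bounds what passing tests show: they validate the
estimator and analysis chain, not robustness to real-scanner artifacts.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 11)                 # 48^3, 21 phases, 15 HU noise
truth <- generate_parameter_fields(spec)
seq4d <- render_sequence(truth, spec)

grid <- build_phase_grid(spec$n_phases, spec$respiratory_rate_per_min,
                         spec$ie_ratio, detect_end_inspiration(seq4d))
fits <- fit_all_voxels(block_downsample(seq4d, 2), grid)

summary(fits$tau_s[fits$significant])
group_tau_by_class(fits, classify_aeration(fits$d_ee))
```

Or end to end, writing NIfTI maps, TSV summaries and a checksummed
manifest:

```{r pipeline, eval = FALSE}
run_pipeline(list(out_dir = "lungtau_demo", seed = 1))
```

## Numerical choices and limitations

* τ lattice $[10^{-3}, 10^{2}]$ s at 0.01 decades plus golden-section
  refinement: resolves τ far beyond the data's information content while
  preventing overflow on near-constant voxels; bound hits are flagged.
* Downsampling truncates axes to multiples of the factor; the phase grid
  is untouched.
* The problem sizes used throughout the test suite (24³–48³ phantoms,
  10⁴-voxel null panels, 200-voxel oracle comparisons) were chosen as the
  smallest sizes at which the relevant statistics are stable.
* Exact-zero SACJ at the reference phase is enforced structurally rather
  than recomputed, so the invariant holds to equality, not just tolerance.
* The F-filter's reference distribution is approximate under profiling
  (see above); its realized type-I error is conservative (~3.4% at
  nominal 5%, n = 15).
* "Subject" at phantom scale means one generated sequence (one seed);
  aggregate analyses (PRM, correlations) accept lists of fit tables.
* Whether the source workflow evaluated SACJ at full or downsampled
  resolution is not recorded; the package downsamples intensities and
  Jacobians identically before fitting, keeping both regressions on the
  same grid.
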