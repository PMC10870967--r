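---
title: "Dual-modality cerebral perfusion pipelines on a digital tMCAO phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality cerebral perfusion pipelines on a digital tMCAO phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package models

`perfusim` reproduces, end to end, the measurement chain of a serial
cerebral-perfusion experiment in the rat filament tMCAO model (90-minute
middle cerebral artery occlusion followed by filament retraction): whole-brain
ultrafast-ultrasound power Doppler tracking relative cerebral blood volume
(rCBV), ultrasound localization microscopy (ULM) measuring absolute blood
flow velocity (CBFv) from tracked microbubbles, and dynamic susceptibility
contrast MRI (DSC-MRI) yielding CBV- and CBF-weighted indices from a
gadolinium bolus passage. Because no animal data accompany the package, a
digital phantom with fully recorded ground truth stands in for the animals;
validation is parameter recovery: the processing chains must recover the
hemodynamic state the simulators were configured with.

The hemodynamic state is an epoch timeline (`build_scenario()`): baseline,
90-minute occlusion, a brief recanalization transient (overshoot intercept
with linear decay), and progressive post-recanalization decline. The bundled
`"paper_tmcao"` scenario stores, per epoch, the ipsi- and contralesional
ultrasound CBV factors, absolute CBFv values, and DSC-specific CBV/CBF
factors. These live in one editable JSON fixture
(`inst/extdata/scenario_paper_tmcao.json`) — a single source of truth for the
recovery tests. The DSC factors are separate columns because the occlusion
deficit measured through a bolus-dilution index differs from the
Doppler-derived one; one column cannot encode both.

# The phantom

`build_phantom()` builds a labelled 64 x 64 x 21 grid (in-plane
field of view 14.1 x 14.2 mm, 0.3 mm elevational pitch). The brain is a
tapered ellipsoid, mirror-symmetric about a half-integer mid-sagittal plane
so that reflection is exact on the voxel grid. The lesion is a compact
ipsilesional region sized by an exact voxel-count quantile (default 15% of
brain voxels) and kept one voxel clear of the midline so that morphological
operations can never make it cross; its mirror image is the contralesional
homologous ROI. A 2 x 2 x 2 block of labelled arterial voxels is placed in
the contralesional hemisphere by a deterministic scan. The vessel-fraction
field `v(x)` is a smoothed random field, mirrored in x so baseline statistics
are hemisphere-symmetric.

Between-animal variability enters in two ways: each subject gets its own
phantom seed (anatomy), and a subject-level severity factor scales the
ipsilesional *deviation from baseline*, `factor' = 1 + (factor - 1) * s` with
`s` lognormal around 1. Scaling the deviation (not the factor itself) keeps
identity scenarios exactly null and leaves cohort means unbiased.

# Ultrafast ultrasound

## Signal model

Each slice acquisition is a complex beamformed IQ stack (200 frames at
500 Hz by default), simulated directly in the Casorati orientation
(pixels x frames):

* **Tissue clutter** — rank-limited (default 5): smooth complex spatial
  patterns times slow temporal tones, amplitude 100, i.e. 20 x the blood
  scattering scale. Tissue dominates the leading singular values by
  construction, as in vivo.
* **Blood** — Gaussian speckle in the many-scatterer limit: a complex AR(1)
  process per pixel whose pole carries a Doppler rotation proportional to
  local velocity and whose modulus sets a transit-time decorrelation
  bandwidth (default 120 Hz). Blood speckle in microvessels decorrelates
  within milliseconds; modelling that is not cosmetic. First, the
  power-Doppler estimate (mean squared magnitude over frames) then averages
  many independent speckle realizations, giving the estimator the ~7%
  relative precision per stack that makes voxel-wise baseline normalization
  well posed. Second, a temporally white blood process makes the singular
  spectrum of the blood+noise residue isotropic in time, so removing 60
  singular values attenuates every pixel's blood power by nearly the same
  factor — with coherent narrow-band scatterers the filter removes blood
  non-uniformly and epoch contrasts collapse. Expected blood power per pixel
  is `blood_amp^2 * v(x) * CBV-factor`.
* **Vasomotion** — per-acquisition lognormal modulation of blood power
  (sdlog 0.18). This supplies the physiologic temporal variability that the
  coefficient-of-variation vessel mask (threshold 0.15) requires; without
  it, contralesional voxels would be flat up to estimator noise and the mask
  would reject healthy vasculature.
* **Flash artifacts** — rare (p = 0.002/pixel/acquisition) brief broadband
  high-amplitude bursts, giving the 3x flash-rejection rule something real
  to reject.
* **Noise** — circular complex Gaussian.

## Processing

`svd_clutter_filter()` removes the leading 60 singular components of the
Casorati matrix (computed through the frames x frames Hermitian
cross-product, identical to SVD truncation and much faster for tall
matrices; a test verifies 1e-8 agreement with an explicit `La.svd`
reconstruction). `power_doppler()` takes the mean (not sum) of squared
magnitudes so values are stack-length invariant. Slices are assembled
posterior-to-anterior (`assemble_wb_volume()`; 21 x 0.3 mm = 6.3 mm
elevational extent), interpolated voxel-wise onto a one-minute common
timeline with linear extrapolation into declared no-acquisition gaps
(surgery, microbubble washout), clipped at zero, and normalized by the
voxel-wise baseline-window median to rCBV. The vessel mask keeps voxels
whose population coefficient of variation over the whole series exceeds
0.15; ROI averages reject values above 3x the pre-rejection ROI mean.

One honest imperfection is worth knowing about: truncating 60 of 200
singular values removes slightly more energy from high-power than from
low-power pixels (the top singular directions align preferentially with
high-variance rows). At the study's filter setting this compresses the
occlusion contrast by a few percent — recovered occlusion rCBV sits near
0.55 for a configured 0.50 — comfortably inside the between-animal spread,
and absent when only the clutter rank is removed (the regime in which the
proportionality tests run).

# Ultrasound localization microscopy

Bubbles are sparse Gaussian blobs (PSF sigma 0.65 px) on a grid twice as
fine as the Doppler grid (0.11 mm, the probe pitch), spawned with intensity
proportional to local blood volume (so the occluded territory carries fewer
detectable bubbles, mirroring the in vivo detection failures), moving along
straight paths at the current region's epoch CBFv with a 10% per-bubble
spread. The acquisition and tracking defaults are module parameters, not
protocol claims, and are justified by the recovery tests:

* **PSF sigma 0.65 px**: the localization operator is a 3 x 3
  intensity-weighted centroid. For that operator a broader PSF is *worse* —
  truncation shrinkage grows with sigma and exceeds 0.1 px by sigma = 1 —
  while 0.65 px keeps the worst-case subpixel error below 0.1 px.
* **Frame rate 200 Hz, 200-frame sequences**: at 500 Hz the inter-frame step
  of a 9 mm/s bubble is ~0.17 px, comparable to the localization error, and
  the mean of step magnitudes is inflated by up to ~15% (|d + e| rises with
  noise even when errors are unbiased). At 200 Hz the step-to-error ratio
  makes per-step speeds accurate to a few percent at all simulated speeds.
* **Clutter filter depth 4** (clutter rank 3 + 1): with sparse bright
  bubbles the stack's non-clutter energy is concentrated in few singular
  components; deeper truncation visibly distorts blob shapes and biases
  speeds upward.
* **Linking**: greedy nearest-neighbour assignment in ascending-distance
  order, gated at `v_max / frame rate`, deterministic tie-breaks, one-frame
  gap bridging by linear interpolation, minimum track length 4. Greedy
  equals exhaustive minimum-cost matching at the simulated densities (tested
  against a brute-force assignment oracle for up to 3 bubbles).

Maps accumulate per-step speeds on an 8x refined grid; ROI velocity averages
only pixels with at least one deposit, and the zero-pixel fraction is
reported alongside (during occlusion it approaches 1 in the lesion, as in
the real experiment).

# DSC-MRI

## Forward model and quantification

Tissue concentration follows the indicator-dilution model
`C(t) = CBF * (AIF (*) R)(t) * TR` with an exponential residue
`R(t) = exp(-t/MTT)`; the arterial input is a gamma-variate
(`A (t-t0)^alpha exp(-(t-t0)/beta)`, alpha = 3, beta = 0.8 s — a sharp rat
bolus — arriving 2 s after the injection at the 180th image; TR/TE
164/13 ms, 500 images). Signal is `S = S0 exp(-k C TE)` plus Gaussian noise;
labelled arterial voxels carry the AIF itself. Baseline transit time is
1.2 s; the epoch factors set ipsilesional CBV and CBF, and
`MTT = MTT0 * cbv_factor / cbf_factor` (central volume theorem by
construction). A per-experiment lognormal injection-efficiency factor scales
artery and tissue alike — the reason the analysis reports ipsi/contra ratios
rather than raw indices, as injection variability cancels in the ratio.

Processing converts signal to `-ln(S/S0)/TE` (baseline window images 50-170,
non-positive samples clipped to the smallest positive observation with a
logged count), integrates the trapezoid of the concentration curve through
the 400th image for the CBV index, selects the arterial reference as the
mean of the 5 contralesional voxels with the highest peak concentration
(ties broken by earliest arrival; arrival/width QC is emitted so the choice
can be audited), and deconvolves through the block-circulant SVD formulation:
zero-pad to 2N, build the circulant AIF matrix scaled by TR, invert keeping
singular values at or above `lambda = 0.10` of the largest, and take
`CBF = max_t k(t)` of the flow-scaled residue, clipped at zero. CBV and CBF
stay in arbitrary units; only normalized ipsi/contra ratios are reported.

## Known biases, stated plainly

* The fixed-fraction threshold underestimates CBF everywhere, and more so
  at short MTT (sharp residue peaks are smoothed hardest). At the occlusion
  time point — contralesional MTT 1.2 s versus ischemic MTT 3.4 s, with the
  ischemic flow near the noise floor where the voxel-wise residue maximum is
  noise-inflated — the recovered CBF ratio lands near 0.29-0.30 for a
  configured 0.20, and sweeping lambda across 0.01-0.10 does not move it
  (the two bias terms trade off). The corresponding acceptance check is
  left failing rather than widened: it is a faithful reproduction of why
  occlusion-phase readouts from different techniques disagree at very low
  flow. Post-recanalization ratios, where the two transit times are close,
  recover within the between-animal spread.
* The rectangle-rule discretization of the residue carries a TR/2 offset
  into the CBV/CBF quotient (`MTT_est = MTT + TR/2`), under 7% at the
  simulated transit times.

## T2 mapping and lesion ROIs

Multi-echo spin-echo volumes (TE 30/50/80/190 ms) with elevated lesion T2
(68 vs 50 ms, vasogenic edema) are fitted voxel-wise with
`S(TE) = S0 exp(-TE/T2)` by a Levenberg-Marquardt iteration initialized from
the log-linear closed form. The solver is vectorised across voxels (shared
matrix operations, per-voxel damping) because calling a scalar optimizer per
voxel costs minutes per volume; a test verifies per-voxel agreement with
`minpack.lm::nlsLM` to 1e-4. Lesion segmentation thresholds T2 at the
contralesional mean + 2 SD, keeps the largest 6-connected component, and
applies an in-plane morphological closing — in-plane because slices (0.3 mm
uUS, 0.6 mm MRI) are thicker than the in-plane voxels and closing across
slices bridges the lesion caps. The contralesional ROI is the geometric
mirror of the segmented lesion (the phantom is built symmetric; the
image-registration mirroring used on real animals is out of scope).

# ROI analysis and reporting

`roi_timecourse()` produces ipsi/contra means and the normalized ratio
(flash rejection applied to ultrasound only); `group_summary()` reduces
per-subject tables to mean +/- sample SD per (time point, modality, measure)
cell. The single-slice 0.5 Hz series after filament retraction is fitted
pixel-wise with ordinary least squares (`y = a + b t`, time origin at
retraction); the intercept map estimates rCBV at the instant of
recanalization, and ipsi vs contra mean intercepts are compared with a
paired t-test. The single-slice series is simulated at the rCBV level
(transient line plus multiplicative noise) — the intercept operator consumes
an rCBV series, and nothing downstream needs per-frame IQ there. Mixed-model
inference across time points is deliberately not re-implemented; the tidy
per-subject tables are the interface to standard statistics tooling.

# Problem sizes, determinism and limitations

The full experiment (`run_experiment()` with `default_config()`) simulates
6 ultrasound and 7 MRI subjects on the 64 x 64 x 21 grid with 200-frame
stacks and 500-image bolus series — about ten minutes on one CPU; the test
suite exercises the same chains on reduced sizes (48 x 48 x 9 grids,
120-frame stacks, cohorts of 3) chosen so the whole suite stays in a few
minutes while the recovery bands remain the study's printed between-animal
SDs. One master seed expands to per-subject, per-stage streams through a
counter scheme, so adding subjects never perturbs existing ones and every
output is re-derivable from the configuration alone.

What passing recovery tests do **not** show about real data: the phantom has
no motion or breathing artifacts, no skull attenuation, no registration
error between time points or modalities (the grid is intrinsically
registered, so the motion correction and co-registration steps of the real
protocol have no counterpart here), idealized mirror symmetry, piecewise
constant hemodynamics within epochs, and Gaussian (not Rician) MR noise at
SNRs where the distinction is immaterial. Recovery failures therefore
indicate algorithmic bias; recovery successes bound algorithmic error only,
not robustness to those nuisances.
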