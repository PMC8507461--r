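---
title: "Monte-Carlo reconstruction of staff Hp(10) in interventional radiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte-Carlo reconstruction of staff Hp(10) in interventional radiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`irscatter` reconstructs the personal dose equivalent Hp(10) received by
an operator during an interventional procedure from two machine-side data
streams: the per-event exposure log of the angiography system (one row
per fluoroscopy run or image acquisition, with tube voltage, Cu
filtration, C-arm angulation, collimated field size, kerma-area product
P~KA~, reference-point air kerma K~air~ and a timestamp) and a
timestamped 3D trace of the operator's position in the room frame.

The chain per event is

1. **Spectrum.** A Kramers-type bremsstrahlung photon fluence,
   Φ(E) ∝ (kVp − E)/E in 1 keV bins from 10 keV, with tungsten
   K-characteristic lines added above the 69.5 keV K edge, hardened by a
   target self-absorption term, the inherent tube filtration and the
   logged added Cu. This semi-empirical class of model reproduces beam
   quality (mean energy, first HVL) at the few-percent level, which is
   sufficient because the absolute output is not taken from the spectrum
   at all — it is normalised away (step 4).
2. **Transport.** Photons are sampled on the square collimated aperture,
   attenuated by an Al-equivalent table slab, and transported analog
   through the patient phantom. Interaction physics: photoelectric
   absorption, free-electron Klein–Nishina Compton sampling
   (composition–rejection), and coherent scattering with the tabulated
   partial coefficient and a Thomson-shaped angular kernel. Photons below
   10 keV are absorbed on the spot.
3. **Scoring.** The operator is *not* modelled as a body. At every
   interaction a next-event (point-detector) estimate adds, to each point
   of interest, the probability per steradian of scattering toward the
   point times the attenuation along the exit path (phantom chord,
   optional ceiling shield) divided by r². The result is an
   energy-binned fluence spectrum per source photon at each point. The
   same run accumulates the simulated P~KA~ and K~air~ per source photon
   (free-in-air, upstream of the table, so they correspond to what the
   machine reports).
4. **Dose.** The fluence spectrum is folded with ICRU-slab
   Hp(10)-per-fluence coefficients at normal incidence; operator
   backscatter is implicit in the slab definition of the operational
   quantity. The relative dose is scaled by the event's logged output:
   Hp(10) = Hp(10)~rel~ · P~KA~/P~KA~^sim^ (or the K~air~ analogue).
5. **Position.** The operator position is the last valid trace sample at
   or before the event start (hold-last-value, not interpolation): the
   operator is assumed not to move within an event. For acquisitions
   where this assumption fails, the event can be subdivided into
   equal-duration frames, each taking the trace position at its own start
   and 1/n of the event output.

## Key parameters

| parameter | default | unit | notes |
|---|---|---|---|
| `d_source_iso` | 0.75 | m | focal spot–isocenter; standard C-arm value, config-overridable |
| `d_iso_detector` | 0.35 | m | isocenter–receptor |
| `d_iso_reference` | 0.15 | m | interventional reference point, toward the tube |
| inherent filtration | 2.5 Al + 0.1 Cu | mm | tube assembly; vendor value is rarely logged, so it is configuration |
| anode angle | 12 | degrees | scales the target self-absorption term |
| table | 1.5 | mm Al eq. | crossed by the primary beam only (under-table tube) |
| energy cutoff | 10 | keV | negligible penetration at ≥ 0.5 m in air/tissue; conversion tables bottom out here |
| `max_gap` | 5 | s | oldest usable position sample; staler events are position-unknown |
| `u_norm_rel` | 0.10 (k = 2) | – | output-normalisation uncertainty attached to every event |
| history floor | 1e4 | – | per event; budget otherwise proportional to P~KA~ so variance sits where dose is |

The patient is a 10-bottle BOMAB-type segment set (head ellipsoid; neck,
chest, gut, pelvis elliptical cylinders; arms, thighs, calves as circular
cylinders) of water-equivalent soft tissue at 1.04 g/cm³, supine along
+y with the abdomen at the isocenter, per-axis scalable; a prism phantom
is available for slab-like set-ups. The room frame is right-handed,
origin at the isocenter, x = patient left, y = cranial, z = up; +RAO
primary angulation rotates about y. The frame convention and RAO sign are
fixed here because event logs print only "(+RAO/−LAO)" without a frame.

## Physics constants

Partial linear attenuation coefficients for air, water, soft tissue,
aluminium, copper and lead (10–150 keV, lead with a split node at the
88 keV K edge), the air mass energy-absorption coefficient and the
ICRU-slab Hp(10)/Φ coefficients ship as plain-text tables under
`inst/extdata/` (provenance headers in the files; generation script in
`data-raw/`). The Compton part is the exact free-electron Klein–Nishina
cross-section times electron density; the coherent part a Z~eff~
power law anchored on water; the photoelectric part the residual against
standard total-attenuation anchor values, so the three partials sum to
the stored total exactly. All lookups interpolate log-log and are exact
at the nodes; log-log linear interpolation is monotone between nodes by
construction, so conversion coefficients never overshoot.

## Numerical choices

- **Estimator.** Next-event estimation was chosen as the variance
  reduction because desk-scale history counts (1e4–1e6) then resolve
  µSv-level doses at metre distances. Its unbiasedness is checked against
  closed forms (vacuum 1/(4πr²), inverse-square) and against an
  independent analog track-length estimator on a water-slab benchmark in
  the test suite.
- **Uncertainty.** Histories run in batches (default 20); every reported
  statistical uncertainty is the batch-mean spread. Folding to Hp(10) is
  done per batch before the variance is formed, because bins of one
  history are correlated. The reported expanded uncertainty combines MC
  statistics with the 10 % (k = 2) normalisation term in quadrature;
  geometry and positioning errors are intentionally *not* quantified and
  are listed in reports as such.
- **Reproducibility.** Each event draws from an RNG stream seeded by a
  hash of (seed, event id), so results are independent of event order
  and of which other events are simulated; reruns are bit-identical.
  Russian roulette (threshold 1e-3, survival ×10) guards any weighted
  extension; in the default analog mode weights stay at 1.
- **Degenerate inputs.** Events with zero P~KA~ and K~air~ are kept,
  contribute zero dose and are counted; a zero simulated normalisation
  quantity is an error (nothing to scale by); empty logs produce a
  zero-total report; equal timestamps sort stably by event id;
  subdivision falls back (with a warning) when the trace has fewer
  samples than requested frames while conserving the event output
  exactly.

## The synthetic generator

No clinical logs or traces are distributed, so `generate_case()` emulates
four reference scenarios spanning the realistic envelope: a single-event
experimental set-up (79 kVp, 0.3 mm Cu, 835 cm², ~4 Gy·cm²), a long
shielded abdominal case (115 events, 163 Gy·cm²), a short low-dose
extremity case (19 events, 0.06 Gy·cm²) and a long renal case (186
events, 10.5 Gy·cm²) with an operator who walks about and leaves the
room. Per-event outputs are log-normal shapes rescaled to the exact case
total, with a 40/60 fluoroscopy/acquisition output split (acquisitions
dominate output in practice); traces are deterministic waypoint scripts
with 3 cm Gaussian jitter at 5 Hz, short dropout gaps, and invalid
stretches when the operator is out of camera view. Operator distances not
printed in the scenario descriptions default to 0.7 m ("close to the
patient").

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about clinical data: real RDSR vendor quirks and unit
variants, isocenter/table motion during a procedure, posture (arms
shielding the dosemeter), the second operator, movable-shield tracking,
and camera-calibration error in the trace.

## Known limitations

- Free-electron Compton (no incoherent scattering function, no Doppler
  broadening) and a Thomson-shaped coherent kernel: a few-percent effect
  on scatter at these energies.
- Normal-incidence slab conversion coefficients; angular dependence of
  Hp(10) in the broad scattered field is ignored.
- Scattered photons are not attenuated by the table or air, only by the
  phantom and shield; the table hardens the primary beam only.
- Binary DICOM RDSR is not parsed; irradiation events are ingested via
  the documented CSV/JSON dialect (export upstream, units normalised at
  the boundary: Gy·cm², mGy).
- The operator body is a point in air; organ doses, Hp(0.07) and eye-lens
  quantities are out of scope.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` use 2e3–2e5 histories per run
(seeded, deterministic): enough for ~1–3 % statistical precision at the
chest point, which is well below the 10 % normalisation floor that
dominates the reported uncertainty in any case.
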