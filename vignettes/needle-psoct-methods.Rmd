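---
title: "Methods: simulating and tracking a PS-OCT needle probe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and tracking a PS-OCT needle probe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoctrack)
```

## The measurement problem

An unscanned, forward-viewing OCT needle probe produces one depth profile
(A-line) per laser sweep along a single axis. Structural intensity alone
is hard to interpret in layered tissue; polarization-sensitive (PS)
processing adds two contrasts that track tissue organization: cumulative
phase retardation (how much organized birefringent material the beam has
crossed) and optic-axis orientation (which way its fibers point). Because
the probe never scans laterally, a spatial picture can only be assembled
by knowing where the needle tip is at every instant. The package couples
the PS contrasts with Doppler phase-shift odometry of the tip and a
reference-frame remapping, so that M-mode data become a
surface-referenced visualization of the traversed tissue column.

Everything here runs on simulated data: no public dataset exists for
this probe class, so the package ships a fringe-level simulator whose
ground truth (tip trajectory, layer structure, Jones response) is known
exactly, making every downstream stage testable.

## Phantom and fringe model

A phantom is an ordered stack of homogeneous layers, each a linear
retarder with birefringence $\Delta n$, axis $\theta$, mean scatterer
reflectivity, and an amplitude attenuation coefficient. Scattering is
modeled by discrete reflectors on a jittered grid (mean spacing 5 µm,
log-normal amplitudes): dense enough for realistic speckle, yet giving an
exact per-scatterer phase oracle. Layer interfaces carry small specular
reflectors; a *void* layer (the epidural-space archetype) is entered
through a strong interface and is weakly scattering inside — residual
fat content keeps a usable Doppler signal, while its intensity sits
~22 dB below tissue.

Three presets encode the standard archetypes: `salmon` (five
birefringent muscle sheets alternating with four non-birefringent
connective layers — retardation contrast), `shrimp` (three equally
birefringent layers with axes −50°, +10°, +60° — axis contrast), and
`spine` (skin, subcutaneous fat, three ligament layers, void).

Fringes are synthesized in wavenumber space, per A-line, as the real
part of the coherent sum over visible scatterers. Key modeling choices:

* **Sampling.** `k_samples` (default 1024) span the wavenumber range
  whose FFT pixel pitch is 1.87 µm in tissue (n = 1.37). With the default
  sampling the reconstructed window is `k_samples/2` pixels, i.e. about
  0.96 mm of tissue below the tip; the nominal 4.7 mm allocation acts as
  an upper bound. Only the shallow window matters for tracking (the
  Doppler mean uses 86 µm below the tip), so simulations use
  `k_samples = 128` (≈ 0.22 mm window) unless the full polarimetry depth
  is under study.
* **Source envelope.** Gaussian in k, with bandwidth back-calculated
  from the 10.6 µm axial resolution (in air); the spectrum occupies
  roughly a quarter of the sampled range, as in a real swept source.
* **Sweep direction.** k is sampled in descending order so that needle
  insertion (tissue delay shrinking) produces a *positive* same-state
  phase difference, matching the sign convention of the displacement
  formula.
* **Polarization.** Launch states alternate between horizontal and 45°
  linear every sweep. Each scatterer at depth $z$ carries the round-trip
  Jones matrix $J^{\mathsf T} J$ of the layers between the tip position
  $p(t)$ and $z$ (tissue above the tip has been displaced by the needle).
  An optional static unitary models the fiber lead (identity by default
  in tests); the tip reflection itself is polarization-neutral.
* **Beam divergence** is reduced to a Lorentzian-like amplitude roll-off
  with depth (no lateral dimension exists). Scatterers fade in/out over a
  few pixels at the window edges to avoid popping artifacts.
* **Noise.** Common-mode laser phase jitter (per-A-line glitches of
  > 2.5 rad with configurable probability), slow common-mode phase
  drift, and additive detector noise. Jitter and drift multiply whole
  fringes, so they are exactly common-mode across depth — which is what
  the tip-reference correction exploits.

## Reconstruction and polarimetry

Each fringe is apodized, FFT'd, and the positive-delay half kept; a
linear phase recentres the carrier on the source center so that the
phase at a reflector's pixel is $-2 k_c z_{\mathrm{opt}}$. Spectral
binning splits the occupied band into five 50%-overlapping Hann
sub-bands; per-bin estimates are combined by circular means on doubled
angles. With a single simulated source (no polarization-mode dispersion)
binning mostly trades depth resolution for redundancy; it is retained
because five bins is the standard configuration for this system class
and the bin-combination rule is isolated behind `combine_bins()`.

Polarimetry follows the Stokes/Poincaré formulation for two alternating
launch states: at every depth the pair of measured Stokes vectors is
compared with the pair at the needle-tip pixel, and the rotation carrying
the tip pair to the depth pair is estimated in closed form (two-step
axis/angle construction composed as quaternions). The rotation angle,
folded to $[0, \pi]$, is the cumulative round-trip retardation referenced
to the tip; half the rotation-axis azimuth in the QU plane is the
apparent optic-axis orientation in $[-90°, 90°)$. Retardation is
invariant under any static fiber transformation; the axis is reported as
*relative* orientation only. Columns with a degenerate reference pair
and pixels below the intensity floor (+5 dB margin) or with retardation
under 0.15 rad are masked rather than reported.

The tip-referenced rotation is validated against an independent oracle:
the analytic Jones round-trip `jones_roundtrip_between()`, whose rotation
angle and axis are extracted directly from the SU(2) matrix.

## Doppler odometry

For one launch state the per-depth phase difference between consecutive
same-state A-lines (T = 40 µs at the 50 kHz sweep rate) feeds the chain,
in this exact order:

1. **Jitter gate** — $|\Delta\varphi| > 2.5$ rad (apparent motion faster
   than $v = \lambda_c \Delta\varphi / 4\pi n T \approx 4.7$ mm/s, faster
   than a hand-held needle moves) is set to exactly zero. Gating is on
   magnitude: retraction produces legitimate negative phase.
2. **Causal sliding median**, 72 intervals (2.88 ms), per depth pixel,
   always over the *past* 72 samples; start-up uses the available
   prefix. The median absorbs the gate's zeros.
3. **Tip-reference subtraction** — the tip reflection sits at constant
   delay, so its phase difference is pure common-mode drift; it is
   subtracted from every depth at or below the tip.
4. **Depth mean** over 46 pixels (86 µm) below the tip surface. The
   averaging span starts `guard_px` (default 8) pixels below the
   tip-reflection *peak*: at 10.6 µm resolution the static tip response
   spreads over several pixels, and averaging inside it would bias the
   velocity toward zero. "Below the surface of the tip" is read as
   "below the tip response".
5. **Conversion** $v = \lambda_c \Delta\varphi / (4\pi n T)$,
   $d = vT$, and cumulative summation to the tip depth $p(t)$ with
   $p(0)=0$.

$n$ is fixed at 1.37 for all tissue; with the documented near-infrared
adipose index of 1.44 the induced displacement error is
$|1.44-1.37|/1.37 \approx 5\%$ (≤ 7% across the 1.44–1.47 literature
range when referenced to the reported displacement), and it cancels upon
retraction.

Two intrinsic error mechanisms are worth knowing. *Speckle
decorrelation*: as tissue slides through the fixed point-spread
function, per-pixel phase estimates acquire zero-mean noise that
integrates into a slow random walk (sub-micrometre over a 4 mm traverse
at full rate). *Median lag*: the causal median lags a velocity sign
reversal by about half its window, costing roughly
$72 \cdot v \cdot T$ of position at a triangle apex (≈ 1.8 µm at
0.6 mm/s and T = 40 µs). Both scale with the same-state period, which is
why the displacement-recovery check runs at the full 50 kHz rate while
stationary and archetype runs use 5–8× decimated sweeps (the decimation
leaves their physics unchanged and keeps runtimes in seconds).

## Visualization

The needle-referenced map is the verbatim concatenation of profiles
(time × needle-relative depth). The surface-referenced canvas re-places
each profile at absolute depth using the tracked tip row
$r(t) = \mathrm{round}(p(t)/\mathrm{pitch})$ (nearest-row quantization;
no interpolation): rows at or below the tip are rewritten from the
current A-line, rows above the tip are frozen at their last-written
values. On retraction, rows re-exposed *below* the tip resume updating
while rows above the shallower tip stay frozen — this keeps the
traversed-tissue record stable. Each canvas column is a snapshot of this
evolving record, so dwell time widens a band along the time axis
(an implicit confidence cue) and the tip-boundary slope encodes the
Doppler velocity. Rendered frames mirror the image about the needle's
center line purely for visual symmetry and draw the tip boundary as a
thick dark line; color maps (grayscale dB, sequential retardation,
cyclic axis hue) are display choices and configurable.

## Problem sizes and numerical choices

* Displacement recovery: spine phantom, 4 mm triangle over 13 s at the
  full 50 kHz sweep rate (~325k same-state intervals, `k_samples = 128`);
  recovered RMSE is well under 2 µm and the closure error under 0.5% of
  the peak depth.
* Stationary jitter/drift immunity: 10 s at 5× decimation with 5%
  glitch probability and 0.5 rad/s drift; the tracked position stays
  within ~0.1 µm.
* Polarimetry oracle: single 1400 µm layer ($\Delta n = 6.8\times10^{-4}$,
  axis 30°), 512 k-samples, slow 0.6 mm/s insertion to refresh speckle;
  retardation agrees with the Jones oracle to well under 1% of π and the
  axis is depth-consistent to under 3° (exact up to a global offset under
  a random fiber).
* Archetypes: insertion-only runs at 8× (salmon/shrimp) and 5× (spine)
  decimation; layer classification thresholds the below-tip retardation
  slope at the midpoint of its low/high quantiles, axis boundaries are
  circular-mean jumps across a ±250 µm split window, and void entry is
  the co-occurrence of a ≥8 dB tip-intensity spike with collapse of the
  below-tip axis coherence (resultant length < 0.6).

Degenerate inputs are handled explicitly: parallel launch states at the
reference are flagged, not thrown; retardation near 0 or π makes the
axis undefined (masked); median windows shorter than 72 samples at
start-up use all available history so tracking begins at t = 0.

## What the simulation does and does not show

The simulator reproduces the *mechanisms* the processing relies on —
speckle from discrete scatterers, alternating launch states, common-mode
jitter/drift, layer birefringence, the static tip reflection, the void
intensity spike — so passing tests show the pipeline is internally
consistent and recovers known ground truth under realistic noise. It
does not model tissue deformation or needle-tissue mechanics (tissue is
rigid; real insertion compresses and relaxes tissue), the SNR asymmetry
from hole closure after retraction, polarization-mode dispersion (so
spectral binning is exercised but not stressed), lateral beam structure,
or physiological motion. Quantitative figures (e.g. the sub-2 µm
tracking RMSE) are therefore statements about the method under the
stated model, not about in-vivo accuracy.
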