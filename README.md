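# psoctrack

Simulation and processing toolkit for **Doppler-tracked,
polarization-sensitive OCT needle guidance**.

Unscanned, forward-viewing OCT needle probes — a bare single-mode fiber
embedded in a needle — are cheap enough to be disposable, but their
one-dimensional structural signal is hard to interpret. Two additions
make the signal readable in layered tissue: polarization-sensitive (PS)
processing, which adds cumulative phase retardation and optic-axis
orientation as tissue contrasts, and Doppler phase tracking of the
needle tip, which turns the time axis into an absolute depth axis. The
package is aimed at researchers developing or evaluating such probes
(e.g. for epidural space identification during nerve-block placement):
it provides a fringe-level simulator of the whole measurement with exact
ground truth, the full reconstruction/tracking pipeline, and the
needle-to-surface reference-frame transform for visualization.

## The method

A 1310 nm swept source (50 kHz) alternates two launch polarization
states between successive A-lines. Per A-line, spectrally binned
processing (five 50%-overlapping sub-bands) yields intensity, and —
from the Poincaré-sphere rotation carrying the needle-tip Stokes pair to
the depth-z pair — cumulative round-trip phase retardation in [0, π]
and apparent optic-axis orientation in [−90°, 90°).

The tip is tracked from the same-state phase differences Δφ at the
fixed same-state period T = 40 µs:

* gate: |Δφ| > 2.5 rad (apparent motion faster than ≈ 4.7 mm/s) is laser
  phase jitter and is zeroed;
* causal 72-interval sliding median per depth pixel (2.88 ms);
* subtraction of the phase difference at the needle-tip pixel (constant
  delay ⇒ pure common-mode drift);
* mean over 46 pixels (86 µm) below the tip response;
* conversion by the Doppler relations

  v = λ_c Δφ / (4 π n T),  d = λ_c Δφ / (4 π n),  n = 1.37,

  and cumulative summation to the tip depth p(t).

Needle-referenced M-mode maps are then re-plotted at absolute depth
using p(t); rows above the tip freeze once traversed, so the canvas
keeps a stable record of the tissue column, and dwell time widens bands
along the time axis.

## Worked example

A mock epidural insertion: the spine phantom (skin, subcutaneous fat,
three ligament layers, then the epidural void) is traversed over 6.5 s
to 3.4 mm with realistic noise, at a 5× decimated sweep rate to keep the
example light.

```r
library(psoctrack)

sys     <- system_spec(k_samples = 128, sweep_rate = 50e3 / 5)
phantom <- build_phantom("spine", seed = 1)
motion  <- make_motion("custom", breakpoints = cbind(c(0, 6.5), c(0, 3400)))
seq     <- synthesize_sequence(phantom, motion, sys, noise_spec(seed = 1))

tom      <- reconstruct_tomogram(seq, bins = 5)
profiles <- compute_polarimetry(tom)
tr       <- track(tom, doppler_params_for(sys))
tr
#> <tip_track> 32500 intervals, peak depth 3348.0 um, final 3348.01 um, gate hits 1.97%

track_report(tr, seq$truth)
#> <track_report> RMSE 10.415 um | final error -51.985 um | peak 3348.0 um (err -51.985 um) | 32500 intervals
#>   boundary crossings (um, s):
#>  depth_um t_true_s t_recovered_s    dt_s
#>       700   1.3384        1.3370 -0.0014
#>      1500   2.8678        2.8692  0.0014
#>      2000   3.8236        3.8262  0.0026
#>      2400   4.5884        4.5922  0.0038
#>      3000   5.7354        5.7502  0.0148

vd <- detect_void_entry(profiles)
sprintf("void entry detected at t = %.3f s (truth %.3f s)",
        vd$t_void, seq$truth$void_entry_time_s)
#> "void entry detected at t = 5.735 s (truth 5.735 s)"

canvas <- build_surface_canvas(profiles, tr, stride = 200)
canvas
#> <surface_canvas> 1846 rows x 163 snapshots, pitch 1.87 um, max tip row 1786
```

Reading the numbers: every tissue-layer boundary crossing is recovered
to within 15 ms, and the epidural void is identified at the truth time
by the co-occurrence of the tip-intensity spike with the collapse of
optic-axis coherence. The ~50 µm (1.5%) position deficit accrues in the
weakly scattering void at this decimated rate, where the per-interval
phase step is large and SNR low; at the full 50 kHz rate the same
trajectory is recovered with micrometre-level error (see the acceptance
script below). `render_frame()` / `export_frames()` turn the canvas
into the mirrored video frames with the black tip-boundary line.

A command-line wrapper with `simulate`, `run` (with `--stop-after`) and
`report` subcommands is installed at
`system.file("cli", "psoctrack", package = "psoctrack")`.

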