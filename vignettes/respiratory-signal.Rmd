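---
title: "Recovering a respiratory signal from cine CT with a frame-mounted wire device"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering a respiratory signal from cine CT with a frame-mounted wire device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resp4d)
```

## The measurement principle

Respiration-correlated (4D) CT needs a respiratory signal to sort images
into breathing phases. Dedicated surrogate systems (pressure belts,
camera-tracked markers) are costly and not universally available. An
alternative is to embed the surrogate *in the images themselves*: a simple
add-on to a stereotactic body frame couples an abdominal "central piece" to
four rigid bars that pivot at the frame sidewalls. Each bar carries a
copper wire along its axis, so every axial CT slice shows two bright wire
cross-sections whose vertical position follows the patient's abdominal
motion, demagnified by the lever arm.

Three relations define the method. With image Y increasing toward the
table (origin in the upper-left image corner), each wire is referenced to
its own *exhale extreme* — the frame where it sits closest to the table —
and the per-frame wire amplitude at a slice is the two-wire mean

$$A_z(t) = \frac{(y_{1,\max} - y_1(t)) + (y_{2,\max} - y_2(t))}{2},$$

converted to mm by the pixel spacing. The lever arm maps it to the central
piece at longitudinal coordinate $Z_0$, given the pivot coordinate $Z_p$
and the slice coordinate $Z$:

$$A_0(t) = A_z(t)\,\frac{Z_0 - Z_p}{Z - Z_p},$$

and the resulting trace is fitted with

$$y(t) = y_0 + A \sin\!\left(\frac{2\pi (t - t_c)}{T}\right),$$

whose amplitude $A$ and cycle time $T$ are compared with the motion preset
on a dynamic phantom. Because the trace is exhale-referenced (its minimum
is 0), a preset of $\pm A$ mm appears as a fit with amplitude $\approx A$
and baseline $y_0 \approx A$.

Averaging the two wires makes $A_z$ robust to a common-mode reading error;
the measure is also exactly invariant to adding a constant to both wires'
Y series. The observed maximum only shifts the baseline of the trace, so
the finite sampling of the exhale extreme does not bias the fitted
amplitude or period — a property the test suite checks explicitly.

## Scope of the simulator, and what passing tests mean

`simulate_cine_study()` renders synthetic cine studies with known ground
truth. It emulates the acquisition geometry and sampling of the cine
protocol — slabs of 8 × 3 mm slices imaged for 16 s at one frame every
0.8 s, 500 mm FOV on a 768 × 768 matrix (0.651 mm pixels) — and the image
formation that matters to the method: anti-aliased 2 mm wire discs at
sub-pixel positions (area-weighted coverage by 16 × 16 supersampling,
centroid fidelity well below 0.1 px), a soft-tissue body outline with lung
fields, additive Gaussian noise in HU, and integer-HU quantisation with the
scanner's −1024 HU air floor.

It does **not** model CT physics: no sinogram reconstruction, beam
hardening, metal or motion artifacts (frames are instantaneous samples by
default; an optional flag averages sub-samples across the 0.5 s exposure),
no couch or frame hardware in the image, and no irregular patient
breathing (periods and amplitudes are constant within a study). Passing
the end-to-end accuracy tests therefore demonstrates that the *processing
chain* — detection, tracking, the amplitude and lever-arm relations, and
the fit — is unbiased and precise under the stated acquisition geometry
and noise; it does not certify performance against scanner artifacts or
irregular breathing, which only a physical phantom can probe.

Intensity presets are fixed for reproducibility: background −1000 HU, body
40 HU, lung −700 HU, wire 3000 HU (copper saturates clinical scales; any
value far above soft tissue behaves identically under the 1500 HU
threshold).

### The shark-fin waveform

Motion phantoms ship an asymmetric "shark fin" pattern (long exhale dwell,
sharp inhale peak) whose factory curve is proprietary. The package uses a
single configurable stand-in with the same qualitative shape,

$$y(t) = y_0 + A\,(2u(t) - 1), \qquad
  u(t) = \left|\sin\frac{\pi (t - t_c)}{T}\right|^{\,p},$$

with $p = 4$ by default: it is $T$-periodic with half peak-to-peak $A$,
spends well under half the cycle above mid-level, and — as expected for
this pattern — fits a sinusoid with a visibly lower adjusted $R^2$ than a
sine of equal amplitude (a property test asserts the strict ordering).

## Geometry defaults

The lever relation needs $Z_0$ and $Z_p$, which are read from a scout
(helical) scan in practice and are free configuration values here. The
defaults place the central piece at stereotactic $Z_0 = 580$ mm (the
phantom-centre coordinate of the reference setup) and the pivot at
$Z_p = 180$ mm, giving a 400 mm lever span within the 470 mm bars, and
putting the standard evaluation slice — 200 mm from the central piece — at
$Z = 380$ mm with lever ratio exactly 0.5. Rod rotation is treated as pure
vertical translation per slice; at ≤ 10 mm displacement over a ≥ 200 mm
lever the small-angle error is below 0.1 mm. Bar tips also translate
longitudinally by a comparable second-order amount; this is not modelled.

## Detection and tracking choices

* **Threshold 1500 HU**: midway between tissue and wire, so ±20 HU noise
  can neither promote background nor demote wire pixels. The original
  workflow windowed images interactively; a fixed default keeps the
  pipeline non-interactive and is exposed in configuration.
* **8-connected components with area bounds** (default 3–200 px) replace
  interactive binary filtering; with 0.651 mm pixels the 2 mm wire spans
  ~7 px.
* **Sub-pixel centroids** are intensity-weighted over a small window
  around each component after subtracting the local background (median of
  the window border). Because pixel values are background + coverage ×
  contrast, the weighted centroid recovers the true disc centre; binary
  centroids would quantise at ~0.2 px, too coarse for the 0.4 mm
  amplitude bound at this pixel pitch.
* **Identity linking** orders the two detections by image X
  (left < right always) and checks frame-to-frame continuity (default
  jump bound 40 px). Failed or ambiguous frames are flagged invalid and
  excluded; a track under 50% valid frames is rejected as unusable. If a
  third component comes within 10% of the second's area the frame is
  declared ambiguous rather than guessed.

## Fitting choices

The sinusoid is fitted by bounded Levenberg–Marquardt (`minpack.lm`) with
$T \in [2, 20]$ s and $A \in [0, 50]$ mm — the physiological range, which
also suppresses period-doubled local minima. The initial period comes from
a least-squares spectrum on a 600-point frequency grid (valid for
non-uniform timestamps, which are used as-is; no resampling), the phase
from a linear sine/cosine fit at that period. If the first start fails,
three quarter-period phase shifts are tried in deterministic order; the
lowest residual sum of squares wins, and the fit never ends worse than its
initial guess. Results are canonicalised to $A \ge 0$, $t_c \in [0, T)$.

"SD extracted from the residuals" can be read as the parameter standard
error or as the residual SD; both are reported (`sd_A`, `sd_T` from the
least-squares covariance are the headline values; `residual_sd` is the
other reading). Adjusted $R^2$ uses an $n - 4$ denominator for the four
parameters. A trace with excursion below twice the noise floor (default
0.05 mm) returns a degenerate $A = 0$ fit flagged unconverged instead of
an error.

## Phase sorting choices

Phase is the fraction of the fitted cycle with phase 0 at the upward
zero-crossing $t = t_c$ (a flag re-references to peak inhale). Amplitude
binning uses the *measured* trace, not the fitted model, so irregular
signals degrade gracefully; `amplitude+velocity` mode splits each
amplitude bin by the sign of the model derivative. The representative
frame per (bin, slice) is the one closest to the bin centre, ties broken
by earliest time. Empty (bin, slice) cells are reported, never
interpolated — with 20 frames covering 2⅔ cycles full 10-bin coverage is
not guaranteed, and fabricating slices would be silent data invention. The
bin count (default 10) and the nearest-to-centre rule are this package's
choices; the upstream method stops at the trace itself.

## Numerical and degenerate-input behaviour

* Lever scaling rejects slices at the pivot ($Z = Z_p$, division by zero /
  no wire motion) and outside $(Z_p, Z_0]$; forward/inverse round-trip is
  exact to 1e−12.
* Studies are bit-reproducible for a fixed seed; pixel data are integer HU
  and round-trip exactly through the 16-bit TIFF + JSON store.
* All-background frames raise a typed "wires not found" condition that
  tracking converts into a flagged gap.
* Captures shorter than two nominal cycles warn that the exhale reference
  may not reach true exhale.

## Problem sizes used by the checks

The package's standard accuracy benchmark (`benchmark_sine_sweep()`) runs
the full chain on 50 studies — amplitudes {1, 2, 3, 6, 10} mm × 10 seeds,
6 s cycle, 20 frames per slice, 20 HU noise, full 768 × 768 matrix,
evaluation slice at lever ratio 0.5 — about a minute of compute. Unit and
property tests use compact fields of view at the same 0.651 mm pixel pitch
(96–184 px matrices) so sub-pixel behaviour is identical while rendering
stays fast; counts-and-layout tests use a 32 px matrix. These sizes are
the package's testing choices and are stated here so they can be scaled
up when more compute is available.

## Known limitations

* The shark-fin curve is a stand-in, not the proprietary phantom curve.
* Surrogate-to-target correlation is assumed, as in any external-surrogate
  method; the optional target sphere exists only to demonstrate sorting.
* DICOM I/O is not provided; studies persist as TIFF + JSON. Slab timing
  assumes sequential acquisition with a configurable (default zero) gap.
* Only periodic waveforms are generated; fitting irregular breathing is
  outside the model by design (the sine is fitted to everything,
  including the shark fin — deliberately, to quantify the mismatch).
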