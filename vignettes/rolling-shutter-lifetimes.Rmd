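---
title: "Rolling-shutter time-gated luminescence: model, estimators, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rolling-shutter time-gated luminescence: model, estimators, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shutterlum)
```

## The measurement principle

A rolling-shutter CMOS sensor starts each row's exposure one `line_time`
after the previous row, so an image is a stack of time windows marching
down the frame. Excitation pulsed faster than the frame traversal writes
its on/off cycle into the image as horizontal bands; emitters with
lifetimes comparable to the strobe period keep glowing into the "off"
bands, where their exponential decay is spread across consecutive rows.
The row index is therefore a time axis with resolution `line_time`
(10 µs by default here), and a single photograph yields strobe frequency,
duty cycle, and emissive lifetimes.

## Forward model and its assumptions

**Excitation.** An ideal square wave (instantaneous edges). Real LED
drivers have finite rise/fall times; a 50% duty square wave mitigates
their effect, and we model none of it. Steady illumination is available
as `constant_excitation()` for control conditions.

**Emitters.** Single-exponential only. "Fast" emitters (conventional
fluorescence, τ below a nanosecond) are treated as instantaneous:
emission is `brightness · x(t)`. Slow emitters follow
`dE/dt = b·x(t) − E/τ` and are evaluated in periodic steady state — the
strobe is assumed to have run for many lifetimes before the capture,
which holds for any practical capture sequence. The closed form is exact;
tests verify it against an adaptive ODE solver to 1e-6 relative across
`τ/period` from 0.01 to 10, and its cycle average equals `b·τ·duty`
(energy balance) to 1e-8.

**Sensor.** Row `r` integrates over `[r·line_time, r·line_time +
exposure_time]`; integrals of the piecewise-exponential radiance are
analytic per on/off segment, so the noise-free image contains no
quadrature error. Noise is the standard CMOS model — Poisson shot noise
on expected photoelectrons, additive Gaussian read noise (3 e⁻ RMS
default), clipping at `full_well`, quantisation to 8 or 16 bits. The
response is linear: real phone pipelines apply tone curves and white
balance, so analysis of real captures needs a linearisation step that is
out of scope here (the analyzer operates on whatever codes it is given;
all its estimates are invariant to a global intensity scale, which
removes the first-order effect).

**Geometry.** Bands are parallel to rows (no tilt), row 0 is the earliest
time (a `readout_reversed` flag flips this), and the sensor `line_time`
must be supplied — camera apps do not report it. With a strobe of known
frequency it can be calibrated from the band period:
`line_time = 1/(frequency · period_rows)`.

A useful non-obvious consequence of box-window sampling: band contrast of
a fast emitter falls as `exposure_time/period` grows, vanishes exactly
when the exposure spans an integer number of periods (every window then
integrates the same number of full cycles), and *reappears* for
fractional multiples beyond one period — e.g. at 1.3 periods the
fractional 0.3-period remainder still bands with contrast 0.3/1.3.

## Inverse pipeline

**Profiles and segmentation.** Channels are analysed separately; a
profile is the per-row mean over a column range (middle 50% by default).
The on/off threshold is the midpoint of the robust 5th/95th percentiles —
Otsu-style histogram splitting is unreliable on a 1-D profile whose "off"
level is not flat but carries a decaying slow-emitter tail. Runs shorter
than 3 rows are merged. A profile whose robust contrast
`(p95−p5)/(p95+p5)` is below 0.05 raises a flat-profile error, which *is*
the steady-illumination verdict: constant light produces no bands and
cannot reveal lifetimes, so authentication and analysis refuse rather
than report.

**Strobe.** Band edges are refined to sub-row precision by linear
interpolation of the threshold crossing. Because the profile value of a
row is attributed to its window centre, the 50% crossing of the ramp sits
exactly at the true edge for a square source. The period in rows is the
mean spacing of like edges (rising and falling pooled; at least two
complete cycles required), duty the mean on-width over the period, and
standard errors come from edge-spacing scatter. First and last, possibly
partial, bands never contribute widths.

**Decay fits.** Each interior off band is fit with
`I(t) = A·e^(−t/τ) + b` by Levenberg–Marquardt (minpack.lm), initialised
from a log-linear regression with the trailing-rows median as baseline
guess. Time is `row · line_time` relative to the interpolated falling
edge, which makes amplitudes comparable across bands. Rows whose exposure
window straddles a band edge are excluded on both sides
(`ceiling(exposure_time/line_time)` = 2 rows at the defaults); the
window-centre convention then leaves the sampled decay *exactly*
exponential, so noise-free fits recover τ to numerical precision.

**Band-phase refinement.** When the channel used for strobe estimation
itself carries slow emission (a TADF-only scene, say), its threshold
crossings are systematically late — the period and duty stay unbiased but
the phase shifts, and off-band windows would leak into the next rise.
`estimate_lifetime()` therefore re-locates the rising edge from the
analyte profile folded at the estimated period: the folded profile's
largest circular jump marks the edge for square and sawtooth shapes
alike. This is on by default and is a no-op when the strobe channel was
already clean.

**QC and aggregation.** A band fit is rejected if it fails to converge,
if `se(τ) > 0.6·τ`, if `τ` exceeds ten off-band durations, or if a nested
F-test (p > 0.01) cannot distinguish the exponential from a straight
line — the last gate is what flags `τ ≫ period` captures, whose off-band
decline is a few percent and whose "lifetime" would otherwise be a noise
artifact with a deceptively small standard error. Accepted bands are
combined by inverse-variance weights with a between-band variance
component (DerSimonian–Laird): when band scatter exceeds the nominal fit
SEs, the weights flatten toward equality. Plain `1/se²` weights are
biased low here because a band whose τ fluctuates low also reports a
smaller SE; the random-effects component removes most of that
correlation-induced bias (from about −10% to about −3% at the hardest
grid point, `τ/period = 1`, peak SNR 20). If no band survives QC the
result is a no-lifetime error, never a silent number.

**Identification and authentication.** A measured lifetime matches a
library entry if within its relative tolerance; zero matches is
"unknown", several is an ambiguity error. Tag authentication estimates
the strobe from a fast region, then requires each slow region's
aggregated lifetime to match its reference and each fast region to band
with the strobe while yielding *no* off-band lifetime.

## Sensing calibrations

Oxygen/pressure quenching uses the Stern–Volmer relation
`obs₀/obs = 1 + K_SV·P` with ambient pressure as the quencher variable
(vacuum as oxygen proxy; no conversion to %O₂ is attempted). The
intensity and lifetime forms share the same `K_SV` — and linearity of
the decay *rate* `1/τ` in `P` is algebraically the same statement, so no
separate parameterisation is needed. Fits require at least three
pressures including a near-zero anchor for the unquenched level.

Temperature response uses a single-barrier thermal-quenching form
`τ(T) = τ_ref/(1 + c·e^(−a/T))` (kelvin internally), fit with a small
multi-start over activation scales; the fitted curve must be strictly
decreasing over the calibrated range. Wald intervals are reported on the
natural scale except for the prefactor `c`, whose interval is built on
the log scale — the natural-scale Wald interval for this strongly
right-skewed parameter undercovers badly.

Both calibrations invert in closed form, refuse observables outside the
calibrated response range, and propagate the fit residual scale to a
condition-scale interval by the delta method. The package's core claim
about robustness is encoded as a pair of properties: lifetime-based
prediction is invariant to a global intensity rescaling of the capture
(viewing angle, distance, ambient light), intensity-based prediction is
not.

## The synthetic-scene generators

`make_fixture()` builds the study scenarios: a bare pulsed-LED
reflection; fast + slow emitters co-deposited on a solid support (fast
blue polymer dye, Eu complex at τ = 500 µs emitting red); the same pair
homogeneously dissolved in a vial (fast yellow/green perylene dye), with
a steady-illumination variant as the negative control; a three-ink
security tag (fast yellow/green ink, red Eu at 500 µs, green Tb at
800 µs) with its matching template; a pressure series (TADF dye,
τ₀ = 300 µs, `K_SV = 0.01 mbar⁻¹`, six pressures from 0 to 300 mbar —
the range of the vacuum-gauge setup being emulated — with fixed
brightness so intensity and lifetime quench by the same factor); and a
temperature series (Eu complex, τ_ref = 600 µs, c = 3×10⁴, a = 3500 K,
six temperatures spanning 248–373 K, i.e. −25 °C to +100 °C, under dark
and ambient lighting). Defaults follow the emulated experiments: 3000
rows, 10 µs line time, 14 µs exposure (≈ 1/71429 s), strobe 600.08 Hz at
50% duty — about 166.6 rows per cycle, 18 cycles per frame. The slow-dye
lifetimes sit in the µs range characteristic of these material classes;
λ-dependence is reduced to fixed RGB weight vectors per dye.

Sensing scenes include a modest LED-reflectance term (the strobed LED
reflecting off the substrate), which is both realistic and what gives a
clean square-wave channel for strobe estimation when the only emitter is
slow.

Noise is anchored by a peak SNR: the gain is solved so that the brightest
pixel of the analyte channel satisfies `N/sqrt(N + B + σ_r²) = SNR`
(N peak signal electrons, B ambient background electrons per exposure).
Ambient lighting is a background fraction of that peak (25% in the
temperature scenario's ambient arm).

What the generator deliberately does **not** emulate: phone ISP
nonlinearity (tone curves, white balance, compression), demosaicing,
lens vignetting, band tilt from sensor rotation, LED slew, and
multi-exponential decays. Passing tests therefore demonstrate estimator
correctness under the stated physics and noise model — not robustness to
ISP processing, which real-image work must address with a linearisation
step upstream.

## Numerical choices

- `expm1` throughout the periodic-steady-state algebra, so `τ ≫ period`
  does not cancel catastrophically.
- Decay fits bound `A ≥ 0` and `τ ≥ line_time/10`; non-convergence,
  `se(τ) > τ`, or a constant profile raise classed errors rather than
  returning garbage.
- Sub-row edges fall back to the interval boundary minus half a row if no
  bracketing threshold crossing is found within ±3 rows.
- Degenerate inputs (empty column ranges, out-of-range rows, mismatched
  scene/sensor shapes, grayscale input to channel splitting, empty
  species libraries) raise classed input errors; every QC refusal carries
  the reason in its message.
- All randomness flows through one integer seed per capture
  (`withr::with_seed`), so captures are bit-reproducible and the global
  RNG stream is left untouched.

## Problem sizes used by the test suite

Deterministic round trips run at the full 3000-row geometry. The
stochastic recovery studies use reduced captures chosen for comfortable
margins at modest cost: the lifetime-recovery grid
(`τ/period ∈ {0.1, 0.3, 0.5, 1.0}`, peak SNR 20, 100 seeds each) uses
3000×128-pixel captures, the end-to-end quenching study (6 pressures,
50 seeds) 1500×64, and the ambient/dark comparison 1500×96. Column count
matters because profiles average across columns: at 128 columns the
profile SNR is ~8× the per-pixel SNR. These sizes are the package's
choices; the tolerances quoted in the tests are stated per fixture, not
per resolution.

## Known limitations

- `τ/period` near or above ~2 is not resolvable within a single off band;
  the QC refuses it (by design) rather than extrapolating. Slower dyes
  need a slower strobe.
- The weighted lifetime aggregate retains a small negative bias (~3% at
  `τ/period = 1`, SNR 20) from the nonlinearity of per-band fits; it
  vanishes for better-resolved decays.
- Duty-cycle estimates from a channel dominated by slow emission are
  biased (edge crossings are late); strobe estimation should use a fast
  or reflection channel, as the fixtures do.
- Real-image use requires knowing `line_time` (or calibrating it from a
  known strobe) and linearising the ISP response; neither is blindly
  estimable from a single banded image.
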