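---
title: "Generating bio-inspired extracellular benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating bio-inspired extracellular benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikebench)
```

## The model

Evaluating spike sorters, event detectors or closed-loop hardware requires
recordings in which every event is known. spikebench builds such ground-truth
datasets as the per-electrode sum of three components,

$$ s_e(n) = x(n) + w(n) + a(n), $$

where $x(n)$ is spike activity (action potentials of nearby neurons plus the
background formed by distant ones), $w(n)$ is the non-stationary
slow-oscillation component (< 300 Hz), and $a(n)$ are injected artefacts.
Each component is generated separately, fully annotated, and summed linearly,
so every downstream quantity — spike times, per-channel spike amplitudes,
artefact intervals — is known exactly.

## Virtual tissue and spike activity

Neurons are placed uniformly at random in a virtual volume (a 1.5 mm³ cube by
default, or a stack of layers with independent densities and rate laws). Unit
counts are deterministic — `round(density × sub-volume)`, half away from zero
so counts do not depend on parity — which makes population structure exactly
testable: the default 300,000 neurons/mm³ cube holds 450,000 units, and a
1 × 1 mm × 55 µm stratum-pyramidale slab at 272,400/mm³ holds exactly 14,982.
Cell types follow exact proportional rounding (80 % pyramidal by default)
rather than Bernoulli draws, again so the configured ratio holds
deterministically. Firing rates come from a configurable law — uniform
bounds for the awake (0.5–12 Hz) and anaesthetised (0.5–5 Hz) presets,
generalised Pareto for heavy-tailed populations, logistic for the multilayer
preset — with interneuron rates drawn from the same law scaled by a factor of
five.

Spike trains are renewal processes with a hard dead time: each inter-spike
interval is the 2 ms refractory period plus an exponential whose mean is
chosen so the train's mean rate equals the configured rate. This reading of
"irregular intervals bounded by a rate range with a refractory period" keeps
firing Poisson-like while making the refractory constraint exact, and it is
the property the tests assert.

Each unit's spikes are rendered onto every channel by scaling a normalized
template with a clamped point-source law,

$$ \mathrm{scale}(d) = A_\mathrm{ref} \, d_\mathrm{ref} / \max(d,
d_\mathrm{min}), $$

anchored at 50 µV at 50 µm and clamped below 10 µm. A declared monotone law
was chosen over a compartmental line-source computation: it preserves the
properties that matter for benchmark construction (amplitudes sort by
distance; a unit equidistant from all tetrode sites renders identically on
them) while remaining cheap and exactly testable. Templates themselves are
parametric biphasic/triphasic shapes with cell-type-dependent widths
(interneurons 0.6–0.9 ms, pyramidal cells 1.2–1.8 ms), peak-normalized, and
exactly zero at both ends.

Units whose nearest site is beyond the 100 µm `noise_radius` are treated as
unresolvable background. They can be rendered mechanistically (their
superposed low-amplitude spikes *are* the background), but the scenario
default replaces them with a Gaussian surrogate of 10 µV RMS: none of the
annotated quantities depend on the microstructure of the background, and the
surrogate keeps multi-seed studies cheap. The 10 s awake preset renders
roughly 600–700 resolvable units this way.

## Slow oscillations

The $w(n)$ component is either extracted from a supplied recording or
synthesized. Both paths share the same filter: a 10th-order low-pass
Butterworth at 300 Hz applied forward and backward for zero phase
distortion. Two numerical choices matter here. First, at a 300 Hz cutoff
against a 20 kHz sampling rate the expanded polynomial form of a 10th-order
filter is ill-conditioned (its clustered poles lose several decimal digits in
direct-form filtering), so the design stays in pole-zero space and is applied
as a cascade of second-order sections, each normalized to exact unit DC gain.
Second, reflection padding must cover the filter's startup transient
(~1700 samples for this design, the time its slowest pole takes to decay to
1e-13), not merely a multiple of the filter order; shorter signals are
constant-extended. With both choices the filter meets its analytic contract
to float precision: DC gain 1, amplitude exactly 0.5 at the cutoff after the
two passes, and output symmetric for symmetric input.

The synthetic generator produces pink (1/f) noise shared across channels
plus a smaller independent per-channel term, an amplitude-modulated
condition-specific oscillation (8 Hz theta for awake, 1.5 Hz slow-wave for
anaesthetised), low-passed and scaled to 100 µV RMS (awake) or 200 µV
(anaesthetised). These RMS values and the spectral exponent are declared
defaults, not measurements. `contamination_check()` verifies that spike
waveforms leak negligibly below the cutoff; the pass threshold of 5 % of the
slow-band power is likewise a design choice standing in for an unquantified
"negligible".

## Artefacts

Three documented classes are synthesized parametrically:

* **Mechanical shocks** — 1142 µs damped oscillations (285 µs quiet
  pre-threshold segment; 32 samples at the 28 kHz of the reference library)
  with carrier drawn uniformly in 1000–2000 Hz and peak-to-peak amplitude
  from Normal(136.1064, 62.0262) µV truncated above 10 µV. Truncation lifts
  the realized mean to ≈ 139 µV, within ~2.3 % of the nominal mean.
* **Mastication** — Hann-enveloped noise bursts whose cycle intervals are
  drawn around 162.5 ms and whose sequence durations centre on 3.3 s,
  yielding ≈ 6.2–6.3 bursts/s (the documented 6.17/s is consistent with the
  cycle duration: 1/0.1625 ≈ 6.15).
* **Grooming** — broadband large-amplitude segments with durations uniform
  in 0.4–28 s and ordered phase annotations (phases 1–4, each present with
  probability 0.7, never reordered).

Event counts follow `N = round(a_rate × duration)`; onsets are uniform over
the feasible range with pairwise-disjoint placement enforced by rejection
sampling (overlap is physically plausible but would blur the annotations).
Injection adds the template sample-wise and splices one transition sample at
each boundary whose added value is half the template's boundary sample — the
linear midpoint between "nothing added" and the template edge — so injection
is exactly invertible. The scenario presets inject shocks only: 100 shocks of
1142 µs in 10 s cover 1.15 % of samples (awake, nominal ~1 %) and 10 cover
0.115 % (anaesthetised, nominal ~0.1 %); mastication and grooming sequences
(0.4–28 s) cannot fit those fractions in a 10 s recording and are instead
available for explicit injection.

Detection mirrors the extraction criterion used for real libraries: an
artefact is declared when at least 80 % of channels cross their amplitude
threshold within a 300 µs window (rounded up to samples), with detections
closer than one window merged. The planted-recording fixtures
(`make_planted()`) give the detector known truth with ≥ 3× margins between
plant amplitude, threshold and noise, so the coincidence-fraction and
window-width boundaries are tested without flakiness.

## Validation statistics

`bartlett_psd()` implements the averaged periodogram: K non-overlapping
rectangular segments (10 × 1 s for the default benchmarks), per-segment
periodograms normalized as $|\mathrm{DFT}|^2 / (N f_s)$ (one-sided, interior
bins doubled), averaged, with the per-frequency SEM as segment standard
deviation over $\sqrt{K}$. Each segment satisfies Parseval to 1e-9 relative,
and averaging reduces white-noise periodogram variance by ≈ 1/K.
`smooth_local()` is the classic tri-cube weighted local polynomial smoother
(degree 2, 1 % span; "2n degree" is read as degree 2). `compare_psd()`
reports per-band mean log10 power ratios with delta-method SEMs — the
operational form of the visual spectral comparisons this class of generator
is validated with. On equal contamination, the 1–3 kHz band rises in both
conditions and rises more in the anaesthetised preset, where neural power is
lower.

## Reproducibility and problem sizes

Every stochastic function takes a seed; `run_scenario()` derives per-stage
seeds from one master seed by fixed offsets, so datasets are bit-reproducible
while stages stay independently re-runnable. R's default Mersenne–Twister
supplies the uniform variates. The shipped test suite exercises the full
10 s, 20 kHz, 16-channel awake benchmark across 20 seeds for the
contamination statistic and uses reduced sizes elsewhere (e.g. 2 kHz
white-noise PSDs, 2 s contamination comparisons, 1000-unit populations) —
sizes chosen to make sampling error a small fraction of each tolerance.

What passing tests show — and what they do not: the generator reproduces its
*configured* statistics (counts, rates, amplitudes, spectral bands) and the
analytic contracts of its operators. Synthetic slow oscillations and
parametric templates do not capture state transitions, bursting units,
electrode drift, or the full diversity of real waveforms; comparisons against
real recordings remain the user's task, for which the PSD stack is provided.

## Known limitations

* No bursting units; trains are renewal processes.
* The attenuation law is isotropic; no anisotropic tissue conductivity.
* Artefact libraries extracted from real data can be dropped in via the JSON
  container, but the package does not extract them from raw recordings.
* No NWB export; the interleaved int16 `.dat` + JSON layout is the only
  on-disk format (gain 0.195 µV/bit by default, clipping detected at
  export).
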