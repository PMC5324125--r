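# spikebench

Fully annotated, parameterisable benchmark datasets of extracellular
multi-unit recordings — for evaluating spike sorters, artefact detectors,
denoising methods and closed-loop neural hardware, where progress is gated by
the scarcity of ground-truth data.

Each dataset is built per electrode as the sum of three components,

```
s_e(n) = x(n) + w(n) + a(n)
```

* **x(n)** — spike activity: neurons placed uniformly in a virtual tissue
  volume (single 1.5 mm³ cube or stacked layers), 80/20
  pyramidal/interneuron, renewal spike trains with a 2 ms refractory period,
  rendered through a clamped point-source attenuation law onto arbitrary
  probe geometries (tetrode, 32-site polytrode, custom), plus background
  from unresolvable distant units.
* **w(n)** — non-stationary slow oscillations (< 300 Hz): synthesized pink
  noise with condition-specific theta / slow-wave components, or extracted
  from a real recording by a zero-phase 10th-order Butterworth low-pass.
* **a(n)** — artefacts of three documented classes: mechanical shocks
  (1142 µs, peak band 1–2 kHz, peak-to-peak 136.1 ± 62.0 µV), mastication
  bursts (6.17 bursts/s, 162.5 ms cycles), and grooming sequences
  (0.4–28 s, ordered phases); scheduled uniformly, injected with
  boundary-smoothing transition samples, and detectable by the 80 %
  cross-channel coincidence rule within 300 µs.

Every spike time, per-channel amplitude scale and artefact interval is
recorded in the ground truth, and a Bartlett averaged-periodogram stack
(per-frequency SEM, 1 %-span local polynomial smoothing, band-wise
comparison) quantifies how contamination reshapes the spectrum.

## Worked example

```r
library(spikebench)

ds <- run_scenario(scenario_preset("awake"), seed = 1)
summary(ds)
#> <benchmark_dataset> 16 channels x 200000 samples @ 20000 Hz (10 s)
#>   ground truth: 83910 spikes from 667 resolvable units
#>   artefacts: 100 events (1.15% of samples)
#>   signal RMS 104 uV, range [-546, 386.5] uV
```

A 10 s awake hippocampal benchmark on a 16-site probe: 100 mechanical shocks
(10 artefacts/s) cover 1.15 % of samples — the awake contamination regime —
and 667 units within 100 µm of a site contribute resolvable, annotated
spikes. How much did the artefacts distort the spectrum?

```r
clean <- ds$components$x$traces[, 1] + ds$components$w$traces[, 1]
compare_psd(bartlett_psd(clean, ds$fs),
            bartlett_psd(ds$signal[, 1], ds$fs),
            bands = list(c(1, 300), c(1000, 3000)))
#>     lo   hi n_bins  log10_ratio         sem
#> 1    1  300    299 0.0009321845 0.011101438
#> 2 1000 3000   2000 0.0149311655 0.004118899
```

Contamination leaves the slow band untouched (log-ratio ≈ 0) but raises the
1–3 kHz band — the region where sharp artefacts overlap spike energy — by
0.015 decades (~3.5 %). Datasets export to interleaved int16 `.dat` with
JSON annotations via `export_benchmark()`, and a command-line front end
lives in `inst/cli/spikebench`:

```sh
Rscript inst/cli/spikebench generate --scenario awake --duration 10 --seed 1 --out bench/
```

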