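name: anaesthetised
duration: 10
sampling_rate: 20000
tissue:
  volume_mm3: 1.5
  density_per_mm3: 300000
  active_fraction: 0.04
  pyramidal_fraction: 0.8
  rate_model:
    kind: uniform_bounds
    min_rate: 0.5
    max_rate: 5
interneuron_factor: 5
refractory_ms: 2
probe: {}
n_templates: 20
attenuation:
  reference_distance: 50
  reference_amplitude: 50
  minimum_distance: 10
  noise_radius: 100
background:
  mode: gaussian
  noise_rms: 10
lfp:
  condition: anaesthetised
  amplitude_rms: 200
artefacts:
  a_rate: 1
  classes: [mechanical_shock]
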