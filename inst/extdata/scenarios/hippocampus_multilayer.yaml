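name: hippocampus_multilayer
duration: 10
sampling_rate: 20000
tissue:
  dimensions_um: [1000, 1000, 415]
  layers:
    - name: stratum oriens
      thickness_um: 120
      density_per_mm3: 11300
      active_fraction: 0.10
      pyramidal_fraction: 0.05
      rate_model: {kind: logistic, location: 0.6, scale: 0.06}
    - name: stratum pyramidale
      thickness_um: 55
      density_per_mm3: 272400
      active_fraction: 0.10
      pyramidal_fraction: 0.8
      rate_model: {kind: logistic, location: 0.4, scale: 0.04}
    - name: stratum radiatum
      thickness_um: 240
      density_per_mm3: 1900
      active_fraction: 0.10
      pyramidal_fraction: 0.05
      rate_model: {kind: logistic, location: 0.2, scale: 0.02}
interneuron_factor: 1
refractory_ms: 2
probe:
  preset: polytrode_8x4
  center_um: [500, 500, 160]
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
  condition: awake
  amplitude_rms: 100
artefacts:
  a_rate: 1
  classes: [mechanical_shock]
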