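# Shared in-code fixtures: tiny populations, quiet renders, filter helpers.

# A hand-placed population inside a small cubic volume, bypassing random
# placement so geometry-sensitive render tests are fully deterministic.
tiny_pop <- function(positions, cell_type = "pyramidal", rate = 5,
                     side = 400) {
  vol <- tissue_volume(rep(side, 3),
                       list(layer_spec("block", thickness = side, density = 0,
                                       rate_model = firing_rate_model(
                                         "uniform_bounds",
                                         min_rate = 0.5, max_rate = 12))))
  n <- nrow(positions)
  pop <- data.frame(x = positions[, 1], y = positions[, 2],
                    z = positions[, 3], layer_id = 1L, layer_name = "block",
                    active = TRUE,
                    cell_type = rep_len(cell_type, n),
                    rate = rep_len(rate, n))
  structure(pop, volume = vol, class = c("neuron_population", "data.frame"))
}

# One-template bank with a known deterministic waveform.
one_template_bank <- function(fs = 20000, seed = 7) {
  synth_template_bank(1, cell_type_mix = 1, fs = fs, seed = seed)
}

# Single-channel rendered signal from a plain vector.
as_signal <- function(x, fs = 20000) {
  rendered_signal(matrix(x, ncol = 1), fs)
}

# Amplitude of a sinusoid estimated away from the edges.
mid_amplitude <- function(y) {
  n <- length(y)
  max(abs(y[floor(n * 0.4):ceiling(n * 0.6)]))
}

awake_rate_model <- function() {
  firing_rate_model("uniform_bounds", min_rate = 0.5, max_rate = 12)
}

# Seeded draws from a rate model (internal sampler).
with_seed_draws <- function(model, n, factor = 1, seed = 99) {
  set.seed(seed)
  spikebench:::draw_rates(model, n, factor)
}
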