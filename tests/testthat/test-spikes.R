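test_that("template banks are peak-normalized, zero-ended and well mixed", {
  bank <- synth_template_bank(100, cell_type_mix = 0.8, seed = 1)
  ct <- vapply(bank, `[[`, "", "cell_type")
  expect_equal(sum(ct == "pyramidal"), 80)
  for (tp in bank[c(1, 50, 100)]) {
    w <- tp$waveform
    expect_equal(max(abs(w)), 1)
    expect_identical(w[1], 0)
    expect_identical(w[length(w)], 0)
    expect_lte(length(w) / tp$fs, 3e-3)  # finite duration <= 3 ms
  }
  # interneuron templates are strictly narrower than pyramidal ones
  wid <- vapply(bank, `[[`, 0, "width_ms")
  expect_lt(max(wid[ct == "interneuron"]), min(wid[ct == "pyramidal"]))
  one <- synth_template_bank(1, cell_type_mix = 1, seed = 2)
  expect_equal(max(abs(one[[1]]$waveform)), 1)
  expect_error(synth_template_bank(0), class = "spikebench_validation_error")
})

test_that("spike trains respect the refractory period and target rate", {
  tr <- gen_spike_train(5, 10, refractory = 0.002, seed = 1)
  expect_gte(min(diff(tr$times)), 0.002)
  expect_true(all(tr$times >= 0 & tr$times < 10))
  # ~50 spikes expected at 5 Hz x 10 s
  expect_gt(length(tr$times), 25)
  expect_lt(length(tr$times), 80)
  expect_length(gen_spike_train(5, 0, seed = 1)$times, 0)
  expect_error(gen_spike_train(rate = 600, duration = 1, refractory = 0.002),
               class = "spikebench_configuration_error")
})

test_that("renewal count matches the dead-time model within 3 sigma", {
  # ISI = refractory + Exp(1/rate - refractory): mean 1/rate,
  # sd (1/rate - refractory); renewal CLT: var N ~ duration * sd^2 / mean^3
  rate <- 1; dur <- 1000; refr <- 0.002
  sd_isi <- 1 / rate - refr
  sigma_n <- sqrt(dur * sd_isi^2 / (1 / rate)^3)
  for (seed in 1:5) {
    n <- length(gen_spike_train(rate, dur, refr, seed = seed)$times)
    expect_lt(abs(n - rate * dur), 3 * sigma_n)
  }
})

test_that("trains hit their configured rate within 3 sigma across rates", {
  for (rate in c(2, 10, 40)) {
    tr <- gen_spike_train(rate, 20, seed = rate)
    sd_isi <- 1 / rate - 0.002
    sigma_n <- sqrt(20 * sd_isi^2 / (1 / rate)^3)
    expect_lt(abs(length(tr$times) - rate * 20), 3 * sigma_n + 2)
  }
})

test_that("the attenuation law anchors, decays as 1/d, and clamps", {
  m <- attenuation_model(reference_distance = 50, reference_amplitude = 50,
                         minimum_distance = 10)
  expect_equal(attenuate(m, 50), 50)
  expect_equal(attenuate(m, 100), 25)
  expect_equal(attenuate(m, 5), attenuate(m, 10))
  d <- seq(10, 500, by = 5)
  expect_true(all(diff(attenuate(m, d)) < 0))  # strictly decreasing
  expect_error(attenuate(m, -1), class = "spikebench_validation_error")
})

test_that("a single spike renders as the scaled template at its sample", {
  fs <- 20000
  bank <- one_template_bank(fs)
  probe <- build_probe("custom", coords = matrix(c(0, 0, 0), 1))
  atten <- attenuation_model()
  pop <- tiny_pop(matrix(c(100, 0, 0), 1))  # 100 um from the site
  tr <- list(structure(list(unit_id = 1L, times = 0.01),
                       class = "spike_train"))
  sig <- render_spikes(pop, tr, bank, probe, atten, fs = fs, duration = 0.1,
                       background = "none")
  w <- bank[[1]]$waveform
  i0 <- round(0.01 * fs) + 1
  scale <- attenuate(atten, 100)
  expect_equal(sig$traces[i0:(i0 + length(w) - 1), 1], scale * w)
  expect_true(all(sig$traces[seq_len(i0 - 1), 1] == 0))
})

test_that("rendering is linear over unions of trains", {
  fs <- 20000
  bank <- one_template_bank(fs)
  probe <- build_probe("tetrode")
  atten <- attenuation_model()
  pop <- tiny_pop(rbind(c(30, 0, 0), c(0, 40, 0)))
  trA <- list(structure(list(unit_id = 1L, times = c(0.01, 0.05)),
                        class = "spike_train"))
  trB <- list(structure(list(unit_id = 2L, times = c(0.02, 0.07)),
                        class = "spike_train"))
  both <- render_spikes(pop, c(trA, trB), bank, probe, atten, fs = fs,
                        duration = 0.1, background = "none")
  a <- render_spikes(pop, trA, bank, probe, atten, fs = fs, duration = 0.1,
                     background = "none")
  b <- render_spikes(pop, trB, bank, probe, atten, fs = fs, duration = 0.1,
                     background = "none")
  expect_equal(both$traces, a$traces + b$traces)
  # two coincident spikes superpose to twice one spike
  tr1 <- list(structure(list(unit_id = 1L, times = 0.03),
                        class = "spike_train"))
  tr2 <- list(structure(list(unit_id = 1L, times = c(0.03, 0.03)),
                        class = "spike_train"))
  one <- render_spikes(pop, tr1, bank, probe, atten, fs = fs, duration = 0.1,
                       background = "none")
  two <- render_spikes(pop, tr2, bank, probe, atten, fs = fs, duration = 0.1,
                       background = "none")
  expect_equal(two$traces, 2 * one$traces)
})

test_that("a unit equidistant from all tetrode sites renders identically", {
  fs <- 20000
  bank <- one_template_bank(fs)
  probe <- build_probe("tetrode")   # regular tetrahedron centred at origin
  atten <- attenuation_model()
  pop <- tiny_pop(matrix(c(0, 0, 0), 1))  # the centroid
  tr <- list(structure(list(unit_id = 1L, times = 0.02),
                       class = "spike_train"))
  sig <- render_spikes(pop, tr, bank, probe, atten, fs = fs, duration = 0.05,
                       background = "none")
  for (ch in 2:4) expect_equal(sig$traces[, ch], sig$traces[, 1])
})

test_that("channel peak amplitudes sort by distance to the unit", {
  fs <- 20000
  bank <- one_template_bank(fs)
  coords <- cbind(c(20, 60, 120, 240), 0, 0)
  probe <- build_probe("custom", coords = coords)
  atten <- attenuation_model(noise_radius = 1000)
  pop <- tiny_pop(matrix(c(0, 0, 0), 1))
  tr <- list(structure(list(unit_id = 1L, times = 0.02),
                       class = "spike_train"))
  sig <- render_spikes(pop, tr, bank, probe, atten, fs = fs, duration = 0.05,
                       background = "none")
  peaks <- apply(abs(sig$traces), 2, max)
  expect_true(all(diff(peaks) < 0))
})

test_that("annotated spikes mark local extrema on the nearest channel", {
  fs <- 20000
  bank <- synth_template_bank(4, seed = 3)
  probe <- build_probe("tetrode")
  atten <- attenuation_model()
  noise_rms <- 5
  pop <- tiny_pop(rbind(c(25, 0, 0), c(0, 0, 30)), rate = 2)
  trains <- lapply(1:2, function(u) gen_spike_train(2, 1, seed = u,
                                                    unit_id = u))
  sig <- render_spikes(pop, trains, bank, probe, atten, fs = fs, duration = 1,
                       background = "gaussian", noise_rms = noise_rms,
                       seed = 5)
  gt <- attr(sig, "ground_truth")
  half_ms <- round(0.5e-3 * fs)
  for (i in seq_len(nrow(gt$spikes))) {
    u <- gt$spikes$unit[i]
    urow <- gt$units[gt$units$unit == u, ]
    if (urow$peak_scale <= 3 * noise_rms) next
    pos <- as.numeric(pop[u, c("x", "y", "z")])
    d <- sqrt(colSums((t(probe$sites) - pos)^2))
    ch <- which.min(d)
    s0 <- gt$spikes$sample[i]
    win <- max(1, s0 - half_ms):min(nrow(sig$traces), s0 + half_ms)
    expect_gte(max(abs(sig$traces[win, ch])), 3 * noise_rms)
  }
})

test_that("band-limited resampling preserves template shape", {
  tp <- one_template_bank(fs = 28000)[[1]]
  tp2 <- resample_template(tp, 20000)
  expect_equal(tp2$fs, 20000)
  expect_equal(max(abs(tp2$waveform)), 1)
  # durations agree to one sample
  expect_equal((length(tp2$waveform) - 1) / 20000,
               (length(tp$waveform) - 1) / 28000, tolerance = 1 / 20000)
})
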