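test_that("artefact counts integrate the rate over the duration", {
  expect_identical(count_artefacts(1, 10), 10L)
  expect_identical(count_artefacts(10, 10), 100L)
  expect_identical(count_artefacts(0, 10), 0L)
  expect_error(count_artefacts(-1, 10), class = "spikebench_validation_error")
})

test_that("shock templates carry the documented band, length and amplitude", {
  fs <- 28000
  tp <- gen_shock(fs = fs, seed = 3)
  expect_equal(length(tp$waveform), 32)          # 1142 us at 28 kHz
  # spectral peak inside the 1000-2000 Hz band
  w <- c(tp$waveform, rep(0, 1024 - length(tp$waveform)))
  p <- Mod(stats::fft(w))^2
  f <- (seq_along(w) - 1) * fs / length(w)
  sel <- f > 0 & f <= fs / 2
  fpk <- f[sel][which.max(p[sel])]
  expect_gte(fpk, 900); expect_lte(fpk, 2100)
  # degenerate spread pins the peak-to-peak exactly
  par0 <- artefact_class_params()$shock
  par0$p2p_sd <- 0
  tp0 <- gen_shock(par0, fs = fs, seed = 1)
  expect_equal(diff(range(tp0$waveform)), 136.1064)
  expect_error(gen_shock(fs = 3000), class = "spikebench_validation_error")
})

test_that("shock amplitudes recover the truncated-normal mean over draws", {
  p2p <- vapply(1:1000, function(i) {
    diff(range(gen_shock(seed = i)$waveform))
  }, 0)
  expect_equal(mean(p2p), 136.1064, tolerance = 0.05)
})

test_that("mastication sequences recover cycle and burst-rate statistics", {
  seqs <- lapply(1:100, function(i) gen_mastication(seed = i))
  cycles <- unlist(lapply(seqs, function(s) diff(s$annotations$burst_onsets)))
  expect_equal(mean(cycles), 0.1625, tolerance = 0.05)
  rates <- vapply(seqs, function(s) {
    length(s$annotations$burst_onsets) / s$duration
  }, 0)
  expect_equal(mean(rates), 6.17, tolerance = 0.05)
  durs <- vapply(seqs, `[[`, 0, "duration")
  expect_equal(mean(durs), 3.3, tolerance = 0.1)
  # zero jitter collapses every cycle to exactly 162.5 ms
  par0 <- artefact_class_params()$mastication
  par0$cycle_sd <- 0
  s0 <- gen_mastication(par0, seed = 5)
  expect_true(all(abs(diff(s0$annotations$burst_onsets) - 0.1625) < 1e-12))
})

test_that("grooming durations stay in range with ordered phase labels", {
  durs <- vapply(1:200, function(i) gen_grooming(fs = 2048, seed = i)$duration, 0)
  expect_gte(min(durs), 0.4)
  expect_lte(max(durs), 28)
  g <- gen_grooming(fs = 2048, seed = 11)
  ph <- g$annotations$phases
  expect_true(all(diff(ph$phase) > 0))   # phases in order, possibly skipped
  expect_true(all(diff(ph$onset) >= 0))
  par5 <- artefact_class_params()$grooming
  par5$duration_range <- c(5, 5)
  expect_equal(gen_grooming(par5, fs = 2048, seed = 2)$duration, 5)
})

test_that("scheduling places disjoint events uniformly and reproducibly", {
  on <- schedule_artefacts(10, 10, 0.05, seed = 1)
  expect_length(on, 10)
  expect_true(all(on >= 0 & on + 0.05 <= 10))
  o <- order(on)
  expect_true(all(diff(on[o]) >= 0.05))  # pairwise disjoint
  expect_identical(on, schedule_artefacts(10, 10, 0.05, seed = 1))
  # single event exactly filling the recording is forced to onset 0
  expect_equal(schedule_artefacts(1, 2, 2, seed = 1), 0)
  # infeasible packing raises a scheduling error carrying the achieved count
  err <- tryCatch(schedule_artefacts(3, 1, 0.5, seed = 1),
                  error = function(e) e)
  expect_s3_class(err, "spikebench_scheduling_error")
})

test_that("injection is additive in the interior with midpoint transitions", {
  fs <- 20000
  tp <- gen_shock(fs = fs, seed = 2)
  w <- tp$waveform
  base <- rendered_signal(matrix(0, 1000, 2), fs)
  ev <- artefact_event(onset = 100 / fs, template = tp)
  out <- inject_artefact(base, ev)
  i0 <- 101
  expect_equal(out$traces[i0:(i0 + length(w) - 1), 1], w)
  expect_equal(out$traces[i0 - 1, 1], w[1] / 2)
  expect_equal(out$traces[i0 + length(w), 1], w[length(w)] / 2)
  expect_true(all(out$traces[seq_len(i0 - 2), ] == 0))
  # the transition value is the linear midpoint between 0 added and the
  # template's first sample
  tp30 <- tp; tp30$waveform[1] <- -30
  out30 <- inject_artefact(base, artefact_event(100 / fs, tp30))
  expect_equal(out30$traces[i0 - 1, 1], -15)
  # invertibility on a non-trivial carrier signal
  set.seed(9)
  carrier <- rendered_signal(matrix(rnorm(2000), 1000, 2), fs)
  inj <- inject_artefact(carrier, ev)
  rec <- inj$traces
  rec[i0:(i0 + length(w) - 1), ] <- rec[i0:(i0 + length(w) - 1), ] - w
  rec[i0 - 1, ] <- rec[i0 - 1, ] - w[1] / 2
  rec[i0 + length(w), ] <- rec[i0 + length(w), ] - w[length(w)] / 2
  expect_equal(rec, carrier$traces)
  # out-of-bounds events are rejected
  expect_error(inject_artefact(base, artefact_event(0.9999, tp)),
               class = "spikebench_validation_error")
})

test_that("detection requires the coincidence fraction within the window", {
  fs <- 20000
  rule <- detection_rule(thresholds = 30)
  # 16 of 20 channels within the window: exactly the 80% requirement
  pr16 <- make_planted(20, fs, 0.5,
                       events = list(list(onset = 0.2, channels = 1:16)),
                       seed = 1)
  expect_equal(nrow(detect_artefacts(pr16$signal, rule)), 1)
  # 15 of 20 (75%) falls short
  pr15 <- make_planted(20, fs, 0.5,
                       events = list(list(onset = 0.2, channels = 1:15)),
                       seed = 2)
  expect_equal(nrow(detect_artefacts(pr15$signal, rule)), 0)
  # 16 channels spread over 1 ms exceed the 300 us window
  spread <- make_planted(20, fs, 0.5,
                         events = list(list(onset = 0.2, channels = 1:16,
                                            spread = 1e-3)),
                         seed = 3)
  expect_equal(nrow(detect_artefacts(spread$signal, rule)), 0)
  # empty signal: empty result
  empty <- rendered_signal(matrix(0, 0, 4), fs)
  expect_equal(nrow(detect_artefacts(empty, rule)), 0)
})

test_that("detected onsets match the planted times", {
  fs <- 20000
  pr <- make_planted(20, fs, 1,
                     events = list(list(onset = 0.25, channels = 1:20),
                                   list(onset = 0.75, channels = 1:18)),
                     seed = 4)
  ev <- detect_artefacts(pr$signal, detection_rule(30))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$onset, c(0.25, 0.75), tolerance = 1e-3)
})

test_that("injected shocks are recalled fully with no spurious detections", {
  fs <- 20000
  base <- rendered_signal(matrix(rnorm(fs * 2 * 8, 0, 5), fs * 2, 8), fs)
  par <- artefact_class_params()$shock
  par$p2p_sd <- 0   # uniform amplitude: thresholds at half peak are 6.8x RMS
  tmpls <- lapply(1:10, function(i) gen_shock(par, fs = fs, seed = 100 + i))
  durs <- vapply(tmpls, function(tp) length(tp$waveform) / fs, 0)
  onsets <- schedule_artefacts(10, 2, durs, seed = 6)
  contaminated <- base
  for (i in 1:10) {
    contaminated <- inject_artefact(contaminated,
                                    artefact_event(onsets[i], tmpls[[i]]))
  }
  peaks <- vapply(tmpls, function(tp) max(abs(tp$waveform)), 0)
  rule <- detection_rule(thresholds = min(peaks) * 0.5)
  found <- detect_artefacts(contaminated, rule)
  # every injected event recovered (allowing window-level merges)
  matched <- vapply(onsets, function(o) {
    any(abs(found$onset - o) < max(durs)) }, TRUE)
  expect_true(all(matched))
  # no detections on the artefact-free render at 6 x background RMS
  clean_rule <- detection_rule(thresholds = 6 * 5)
  expect_equal(nrow(detect_artefacts(base, clean_rule)), 0)
})

test_that("artefact libraries round-trip through the JSON container", {
  tmpls <- list(gen_shock(seed = 1), gen_mastication(seed = 2),
                gen_grooming(fs = 2048, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_artefact_library(tmpls, path)
  back <- read_artefact_library(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$waveform, tmpls[[i]]$waveform)
    expect_equal(back[[i]]$class, tmpls[[i]]$class)
    expect_equal(back[[i]]$fs, tmpls[[i]]$fs)
  }
  expect_equal(back[[2]]$annotations$burst_onsets,
               tmpls[[2]]$annotations$burst_onsets)
  expect_equal(back[[3]]$annotations$phases$phase,
               tmpls[[3]]$annotations$phases$phase)
})
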