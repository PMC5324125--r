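#' Compose a benchmark dataset from its three components
#'
#' The per-electrode composite is the exact sample-wise sum
#' \code{s_e(n) = x(n) + w(n) + a(n)}: spike activity plus background,
#' slow oscillations, and artefacts. Components may optionally be retained so
#' the decomposition stays available for downstream scoring.
#'
#' @param x spike-activity component (\code{rendered_signal}).
#' @param w slow-oscillation component (\code{slow_oscillation} or
#'   \code{rendered_signal}), or \code{NULL} for none.
#' @param a artefact component (\code{rendered_signal}), or \code{NULL}.
#' @param keep_components store the three traces in the result (default
#'   TRUE).
#' @param ground_truth optional list of annotations to attach.
#' @return an object of class \code{benchmark_dataset}: list with
#'   \code{signal} (samples x channels, uV), \code{fs}, \code{duration},
#'   \code{components} and \code{ground_truth}.
#' @export
compose_benchmark <- function(x, w = NULL, a = NULL, keep_components = TRUE,
                              ground_truth = NULL) {
  stopifnot(inherits(x, "rendered_signal"))
  zero <- function() rendered_signal(matrix(0, nrow(x$traces), ncol(x$traces)),
                                     x$fs)
  w <- w %||% zero(); a <- a %||% zero()
  for (comp in list(w, a)) {
    if (!identical(dim(comp$traces), dim(x$traces))) {
      stop_validation("component shapes differ (channels x samples must match)")
    }
    if (!isTRUE(all.equal(comp$fs, x$fs))) {
      stop_validation("component sampling rates differ")
    }
  }
  structure(list(signal = x$traces + w$traces + a$traces,
                 fs = x$fs, duration = nrow(x$traces) / x$fs,
                 components = if (keep_components) list(x = x, w = w, a = a),
                 ground_truth = ground_truth),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("<benchmark_dataset> %d channels x %d samples @ %g Hz (%.3g s)\n",
              ncol(x$signal), nrow(x$signal), x$fs, x$duration))
  gt <- x$ground_truth
  if (!is.null(gt)) {
    if (!is.null(gt$spikes)) {
      cat(sprintf("  ground truth: %d spikes from %d resolvable units\n",
                  nrow(gt$spikes), length(unique(gt$spikes$unit))))
    }
    if (!is.null(gt$artefacts) && nrow(gt$artefacts)) {
      cat(sprintf("  artefacts: %d events (%.3g%% of samples)\n",
                  nrow(gt$artefacts),
                  100 * sum(gt$artefacts$n_samples) / length(x$signal) *
                    ncol(x$signal)))
    }
  }
  invisible(x)
}

#' @export
summary.benchmark_dataset <- function(object, ...) {
  print(object)
  cat(sprintf("  signal RMS %.3g uV, range [%.4g, %.4g] uV\n",
              stats::sd(object$signal), min(object$signal),
              max(object$signal)))
  invisible(object)
}

#' @export
plot.benchmark_dataset <- function(x, channels = seq_len(min(4, ncol(x$signal))),
                                   t_max = min(1, x$duration), ...) {
  n <- min(nrow(x$signal), round(t_max * x$fs))
  tt <- (seq_len(n) - 1) / x$fs
  offset <- 3 * stats::sd(x$signal[seq_len(n), channels])
  graphics::plot(NULL, xlim = c(0, tt[n]),
                 ylim = c(-offset, offset * length(channels)),
                 xlab = "time (s)", ylab = "channel", yaxt = "n", ...)
  for (i in seq_along(channels)) {
    graphics::lines(tt, x$signal[seq_len(n), channels[i]] + (i - 1) * offset)
  }
  graphics::axis(2, at = (seq_along(channels) - 1) * offset,
                 labels = channels)
  invisible(x)
}

#' Scenario presets
#'
#' Loads one of the shipped scenario configurations:
#' \describe{
#'   \item{awake}{1.5 mm^3 cube, 300,000 neurons/mm^3, 80/20
#'     pyramidal/interneuron, 10\% active, uniform rates 0.5–12 Hz
#'     (interneurons x5), 16-site probe, 10 artefacts/s (~1\% of samples).}
#'   \item{anaesthetised}{as awake but 4\% active, rates 0.5–5 Hz,
#'     1 artefact/s (~0.1\% of samples).}
#'   \item{hippocampus_multilayer}{stratum oriens / pyramidale / radiatum
#'     slabs (120 / 55 / 240 um; 11,300 / 272,400 / 1,900 neurons/mm^3)
#'     under a 32-site polytrode, logistic layer rates centred on
#'     0.6 / 0.4 / 0.2 Hz.}
#' }
#'
#' @param name preset name.
#' @return a configuration list accepted by \code{\link{run_scenario}}.
#' @export
scenario_preset <- function(name = c("awake", "anaesthetised",
                                     "hippocampus_multilayer")) {
  name <- match.arg(name)
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "spikebench", mustWork = TRUE)
  yaml::read_yaml(path)
}

config_rate_model <- function(cfg) {
  do.call(firing_rate_model, c(list(kind = cfg$kind),
                               cfg[setdiff(names(cfg), "kind")]))
}

config_volume <- function(cfg) {
  if (!is.null(cfg$volume_mm3)) {
    tissue_cube(volume_mm3 = cfg$volume_mm3, density = cfg$density_per_mm3,
                rate_model = config_rate_model(cfg$rate_model),
                active_fraction = cfg$active_fraction,
                pyramidal_fraction = cfg$pyramidal_fraction)
  } else {
    layers <- lapply(cfg$layers, function(ly) {
      layer_spec(ly$name, thickness = ly$thickness_um,
                 density = ly$density_per_mm3,
                 rate_model = config_rate_model(ly$rate_model),
                 active_fraction = ly$active_fraction,
                 pyramidal_fraction = ly$pyramidal_fraction)
    })
    tissue_volume(unlist(cfg$dimensions_um), layers)
  }
}

config_probe <- function(cfg, volume) {
  probe <- if (!is.null(cfg$preset) && cfg$preset != "custom") {
    build_probe(cfg$preset)
  } else if (!is.null(cfg$sites)) {
    build_probe("custom",
                coords = matrix(unlist(cfg$sites), ncol = 3, byrow = TRUE))
  } else {
    # default scenario probe: 4 stacked tetrodes, 150 um apart (16 sites)
    base <- build_probe("tetrode")$sites
    build_probe("custom",
                coords = do.call(rbind, lapply(0:3, function(k) {
                  sweep(base, 2, c(0, 0, k * 150), "+")
                })),
                name = "tetrode_x4")
  }
  position_probe(probe, volume,
                 at = if (!is.null(cfg$center_um)) unlist(cfg$center_um))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_with("spikebench_stage_error",
              sprintf("[stage %s] %s", stage, conditionMessage(e)),
              stage = stage)
  })
}

#' Run an end-to-end benchmark scenario
#'
#' Executes the full pipeline — tissue placement, type/rate assignment,
#' template synthesis, spike-train generation and rendering, slow-oscillation
#' synthesis, artefact scheduling and injection, composition — from a single
#' configuration and master seed. Per-stage seeds are derived from the master
#' seed by fixed offsets, so the same configuration and seed reproduce the
#' dataset bit for bit while stages stay independently re-runnable.
#'
#' @param config a configuration list (see \code{\link{scenario_preset}}).
#' @param seed master seed.
#' @param duration override the configured duration, s.
#' @param keep_components retain x/w/a traces (default TRUE).
#' @return a \code{\link{compose_benchmark}} dataset; \code{ground_truth}
#'   carries the spike table, unit table, artefact events, configuration
#'   snapshot and all derived seeds.
#' @examples
#' \donttest{
#' ds <- run_scenario(scenario_preset("awake"), seed = 1, duration = 1)
#' ds
#' }
#' @export
run_scenario <- function(config, seed = 1L, duration = NULL,
                         keep_components = TRUE) {
  duration <- duration %||% config$duration
  fs <- config$sampling_rate
  seeds <- list(tissue = derive_seed(seed, 1), types = derive_seed(seed, 2),
                rates = derive_seed(seed, 3), templates = derive_seed(seed, 4),
                trains = derive_seed(seed, 5), lfp = derive_seed(seed, 6),
                artefacts = derive_seed(seed, 7), render = derive_seed(seed, 8))

  volume <- run_stage("tissue", config_volume(config$tissue))
  pop <- run_stage("tissue", {
    p <- place_neurons(volume, seed = seeds$tissue)
    p <- assign_types(p, seed = seeds$types)
    assign_rates(p, interneuron_factor = config$interneuron_factor %||% 5,
                 seed = seeds$rates)
  })
  probe <- run_stage("tissue", config_probe(config$probe %||% list(), volume))

  atten <- do.call(attenuation_model, config$attenuation %||% list())
  bg <- config$background %||% list(mode = "gaussian", noise_rms = 10)

  x <- run_stage("spikes", {
    bank <- synth_template_bank(config$n_templates %||% 20,
                                fs = fs, seed = seeds$templates)
    # units to realise as trains: active units near enough to matter
    act <- which(pop$active)
    d_act <- distance_to_probe(pop, probe, rows = act)
    sel <- act[d_act <= atten$noise_radius]
    if (identical(bg$mode, "mechanistic")) sel <- act
    refr <- (config$refractory_ms %||% 2) / 1000
    trains <- lapply(sel, function(u) {
      gen_spike_train(pop$rate[u], duration, refractory = refr,
                      seed = derive_seed(seeds$trains, u), unit_id = u)
    })
    render_spikes(pop, trains, bank, probe, atten, fs = fs,
                  duration = duration, background = bg$mode %||% "gaussian",
                  noise_rms = bg$noise_rms %||% 10, seed = seeds$render)
  })

  w <- run_stage("lfp", {
    lf <- config$lfp %||% list(condition = "awake")
    synth_slow(lf$condition, channels = nrow(probe$sites), fs = fs,
               duration = duration, seed = seeds$lfp,
               amplitude_rms = lf$amplitude_rms)
  })

  a <- run_stage("artefacts", {
    acfg <- config$artefacts %||% list(a_rate = 0)
    n_art <- count_artefacts(acfg$a_rate %||% 0, duration)
    azero <- rendered_signal(matrix(0, nrow(x$traces), ncol(x$traces)), fs)
    if (n_art > 0) {
      classes <- acfg$classes %||% "mechanical_shock"
      tmpls <- lapply(seq_len(n_art), function(i) {
        cls <- classes[1L + (i - 1L) %% length(classes)]
        gen <- switch(cls, mechanical_shock = gen_shock,
                      mastication = gen_mastication, grooming = gen_grooming)
        gen(fs = fs, seed = derive_seed(seeds$artefacts, i))
      })
      durs <- vapply(tmpls, function(tp) length(tp$waveform) / fs, 0)
      onsets <- schedule_artefacts(n_art, duration, durs,
                                   seed = derive_seed(seeds$artefacts, 0))
      inj <- inject_events(azero$traces, fs, tmpls, onsets)
      azero$traces <- inj$traces
      attr(azero, "artefact_log") <- inj$log
    }
    azero
  })

  gt_x <- attr(x, "ground_truth")
  gt <- list(spikes = gt_x$spikes, units = gt_x$units,
             unit_scales = gt_x$unit_scales,
             artefacts = attr(a, "artefact_log") %||%
               data.frame(onset = numeric(), duration = numeric(),
                          class = character(), n_samples = integer()),
             config = config, seed = seed, seeds = seeds,
             duration = duration)
  compose_benchmark(x, w, a, keep_components = keep_components,
                    ground_truth = gt)
}

# distance (um) from each unit (optionally a row subset) to its nearest site
distance_to_probe <- function(pop, probe, rows = NULL) {
  xyz <- if (is.null(rows)) as.matrix(pop[, c("x", "y", "z")]) else
    cbind(pop$x[rows], pop$y[rows], pop$z[rows])
  d2min <- rep(Inf, nrow(xyz))
  for (s in seq_len(nrow(probe$sites))) {
    d2 <- (xyz[, 1] - probe$sites[s, 1])^2 +
      (xyz[, 2] - probe$sites[s, 2])^2 +
      (xyz[, 3] - probe$sites[s, 3])^2
    d2min <- pmin(d2min, d2)
  }
  sqrt(d2min)
}

#' Fraction of samples covered by artefact events
#'
#' Convenience accessor over the ground-truth annotations.
#'
#' @param ds a \code{benchmark_dataset} from \code{\link{run_scenario}}.
#' @return fraction in [0, 1] of samples inside injected artefact events.
#' @export
artefact_sample_fraction <- function(ds) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  art <- ds$ground_truth$artefacts
  if (is.null(art) || !nrow(art)) return(0)
  sum(art$n_samples) / nrow(ds$signal)
}

#' Export / load a benchmark dataset
#'
#' Writes the composite signal as interleaved int16 binary (\code{signal.dat},
#' channel-major frames: channels 1..E at sample 1, then sample 2, ...) with
#' a declared uV-per-bit gain, the ground-truth annotations as
#' \code{annotations.json}, and the configuration snapshot as
#' \code{config.yaml}. \code{load_benchmark} inverts the export up to int16
#' quantization (max error gain/2 per sample).
#'
#' @param ds a \code{benchmark_dataset}.
#' @param dir output directory (created if needed).
#' @param gain uV per bit (default 0.195, a common acquisition convention).
#' @return \code{export_benchmark} returns \code{dir} invisibly;
#'   \code{load_benchmark} returns a \code{benchmark_dataset} (components not
#'   retained).
#' @export
export_benchmark <- function(ds, dir, gain = 0.195) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  if (length(ds$signal) && max(abs(ds$signal)) > gain * 32767) {
    stop_export(sprintf("signal exceeds int16 range at gain %g uV/bit", gain))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- as.integer(round_half_away(t(ds$signal) / gain))  # channel-major frames
  writeBin(q, file.path(dir, "signal.dat"), size = 2L, endian = "little")
  gt <- ds$ground_truth %||% list()
  ann <- list(
    sampling_rate = ds$fs, n_channels = ncol(ds$signal),
    n_samples = nrow(ds$signal), gain_uv_per_bit = gain,
    units = gt$units, spikes = gt$spikes,
    artefacts = if (!is.null(gt$artefacts) && nrow(gt$artefacts)) {
      data.frame(onset = gt$artefacts$onset,
                 duration = gt$artefacts$duration,
                 class = gt$artefacts$class,
                 n_samples = gt$artefacts$n_samples)
    },
    seed = gt$seed, seeds = gt$seeds)
  jsonlite::write_json(ann, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(gt$config)) {
    yaml::write_yaml(gt$config, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname export_benchmark
#' @export
load_benchmark <- function(dir) {
  ann <- jsonlite::read_json(file.path(dir, "annotations.json"),
                             simplifyVector = TRUE)
  n_val <- ann$n_channels * ann$n_samples
  raw <- readBin(file.path(dir, "signal.dat"), "integer", n = n_val,
                 size = 2L, signed = TRUE, endian = "little")
  sig <- t(matrix(raw * ann$gain_uv_per_bit, nrow = ann$n_channels))
  cfg_path <- file.path(dir, "config.yaml")
  gt <- list(units = ann$units, spikes = ann$spikes, artefacts = ann$artefacts,
             seed = ann$seed, seeds = ann$seeds,
             config = if (file.exists(cfg_path)) yaml::read_yaml(cfg_path))
  structure(list(signal = sig, fs = ann$sampling_rate,
                 duration = ann$n_samples / ann$sampling_rate,
                 components = NULL, ground_truth = gt),
            class = "benchmark_dataset")
}
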