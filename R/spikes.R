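#' Synthesize a parametric spike-template bank
#'
#' Generates biphasic/triphasic extracellular action-potential templates with
#' cell-type-dependent widths: interneuron spikes are narrower (total width
#' drawn in 0.6–0.9 ms) than pyramidal spikes (1.2–1.8 ms). Each template is
#' a negative main deflection followed by a slower positive after-wave,
#' tapered so the first and last samples are exactly zero, and peak-normalized
#' (max |amplitude| = 1); physical amplitude comes from the attenuation law at
#' render time.
#'
#' @param n_templates number of templates (>= 1).
#' @param cell_type_mix proportion of pyramidal templates (exact proportional
#'   rounding; default 0.8).
#' @param fs template sampling rate, Hz (default 20000).
#' @param seed RNG seed.
#' @return an object of class \code{template_bank}: a list of
#'   \code{spike_template} objects, each with \code{waveform} (unit peak),
#'   \code{fs}, \code{cell_type}, \code{width_ms} and \code{polarity} (-1,
#'   negative-going main deflection).
#' @export
synth_template_bank <- function(n_templates, cell_type_mix = 0.8, fs = 20000,
                                seed = NULL) {
  if (!is_scalar_num(n_templates) || n_templates < 1) {
    stop_validation("'n_templates' must be >= 1")
  }
  check_fraction(cell_type_mix, "cell_type_mix")
  n_templates <- as.integer(n_templates)
  n_pyr <- as.integer(round_half_away(cell_type_mix * n_templates))
  types <- c(rep("pyramidal", n_pyr),
             rep("interneuron", n_templates - n_pyr))
  with_seed(seed, {
    bank <- lapply(types, function(ct) synth_template(ct, fs))
    structure(bank, class = "template_bank")
  })
}

# One random template of the given cell type. Shape: negative Gaussian trough
# + delayed positive after-wave (+ optional small initial bump -> triphasic),
# edge-tapered to exact zeros.
synth_template <- function(cell_type, fs) {
  width_ms <- if (cell_type == "interneuron") stats::runif(1, 0.6, 0.9) else
    stats::runif(1, 1.2, 1.8)
  n <- max(5L, as.integer(round(width_ms * 1e-3 * fs)))
  t <- seq(0, width_ms * 1e-3, length.out = n)
  tp <- width_ms * 1e-3 * 0.35              # trough position
  s1 <- width_ms * 1e-3 * stats::runif(1, 0.06, 0.09)
  s2 <- s1 * stats::runif(1, 1.8, 2.6)      # broader after-wave
  amp2 <- stats::runif(1, 0.25, 0.5)
  w <- -exp(-(t - tp)^2 / (2 * s1^2)) + amp2 * exp(-(t - tp - 2.5 * s1)^2 / (2 * s2^2))
  if (stats::runif(1) < 0.5) {              # triphasic: small leading bump
    w <- w + stats::runif(1, 0.1, 0.2) * exp(-(t - tp + 2.2 * s1)^2 / (2 * s1^2))
  }
  # taper 15% at each edge (cosine) so endpoints are exactly zero
  w <- w * taper_window(n, 0.15)
  w <- w / max(abs(w))
  w[c(1L, n)] <- 0
  structure(list(waveform = w, fs = fs, cell_type = cell_type,
                 width_ms = width_ms, polarity = -1),
            class = "spike_template")
}

# Tukey-style taper: cosine ramps over `frac` of each edge, exactly 0 at ends.
taper_window <- function(n, frac) {
  k <- max(2L, as.integer(ceiling(frac * n)))
  ramp <- (1 - cos(pi * seq(0, 1, length.out = k))) / 2
  c(ramp, rep(1, max(0L, n - 2L * k)), rev(ramp))[seq_len(n)]
}

#' Resample a spike template to a new sampling rate
#'
#' Band-limited (windowed-sinc) interpolation of the template waveform.
#'
#' @param template a \code{spike_template}.
#' @param fs target sampling rate, Hz.
#' @return the template resampled to \code{fs}.
#' @export
resample_template <- function(template, fs) {
  stopifnot(inherits(template, "spike_template"))
  if (fs == template$fs) return(template)
  n_old <- length(template$waveform)
  dur <- (n_old - 1) / template$fs
  t_new <- seq(0, dur, by = 1 / fs)
  k <- outer(t_new * template$fs, seq_len(n_old) - 1, "-")
  w <- as.numeric((sinc(k) * lanczos(k, 8)) %*% template$waveform)
  w[c(1L, length(w))] <- 0
  template$waveform <- w / max(abs(w))
  template$fs <- fs
  template
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
lanczos <- function(x, a) ifelse(abs(x) < a, sinc(x / a), 0)

#' @export
print.template_bank <- function(x, ...) {
  ct <- vapply(x, `[[`, "", "cell_type")
  cat(sprintf("<template_bank> %d templates (%d pyramidal, %d interneuron)\n",
              length(x), sum(ct == "pyramidal"), sum(ct == "interneuron")))
  invisible(x)
}

#' Generate a spike train with refractoriness
#'
#' Stationary renewal process with a hard dead time: inter-spike intervals are
#' \code{refractory + Exponential(mean = 1/rate - refractory)}, so the mean
#' rate equals \code{rate} while no interval is shorter than the refractory
#' period (2 ms by default, the standard hippocampal setting).
#'
#' @param rate target mean firing rate, Hz (> 0).
#' @param duration train duration, s.
#' @param refractory refractory period, s (default 0.002). Must be smaller
#'   than \code{1/rate}, otherwise the rate is unattainable.
#' @param seed RNG seed.
#' @param unit_id optional identifier stored on the train.
#' @return an object of class \code{spike_train}: list with \code{unit_id}
#'   and \code{times} (s, sorted, all in \code{[0, duration)}).
#' @examples
#' tr <- gen_spike_train(5, 10, seed = 1)
#' min(diff(tr$times)) >= 0.002
#' @export
gen_spike_train <- function(rate, duration, refractory = 0.002, seed = NULL,
                            unit_id = NA_integer_) {
  if (!is_scalar_num(rate) || rate <= 0) stop_validation("'rate' must be > 0")
  if (!is_scalar_num(duration) || duration < 0) {
    stop_validation("'duration' must be >= 0")
  }
  if (!is_scalar_num(refractory) || refractory < 0) {
    stop_validation("'refractory' must be >= 0")
  }
  if (refractory >= 1 / rate) {
    stop_configuration(sprintf(
      "rate %g Hz unattainable with refractory %g s (needs refractory < 1/rate)",
      rate, refractory))
  }
  with_seed(seed, {
    times <- numeric(0)
    if (duration > 0) {
      mean_exp <- 1 / rate - refractory
      # draw ISIs in chunks until the train passes `duration`
      t_last <- stats::runif(1, 0, 1 / rate)  # random phase start
      times <- t_last
      while (t_last < duration) {
        k <- max(16L, ceiling((duration - t_last) * rate * 1.5))
        isi <- refractory + stats::rexp(k, 1 / mean_exp)
        new <- t_last + cumsum(isi)
        times <- c(times, new)
        t_last <- new[length(new)]
      }
      times <- times[times < duration]
    }
    structure(list(unit_id = unit_id, times = times), class = "spike_train")
  })
}

#' Distance-attenuation model for extracellular amplitude
#'
#' Declares how a unit's normalized spike template scales with distance from
#' a recording site: a clamped point-source law
#' \code{scale(d) = reference_amplitude * reference_distance / max(d,
#' minimum_distance)} (uV per unit template peak). Beyond \code{noise_radius}
#' units are treated as unresolvable background rather than sortable spikes.
#'
#' @param reference_distance anchor distance, um (default 50).
#' @param reference_amplitude amplitude at the anchor, uV (default 50).
#' @param minimum_distance clamp distance, um (default 10): sites closer than
#'   this see the same amplitude as at \code{minimum_distance}.
#' @param noise_radius background cutoff, um (default 100).
#' @return an object of class \code{attenuation_model}.
#' @export
attenuation_model <- function(reference_distance = 50, reference_amplitude = 50,
                              minimum_distance = 10, noise_radius = 100) {
  stopifnot(is_scalar_num(reference_distance), reference_distance > 0,
            is_scalar_num(reference_amplitude), reference_amplitude > 0,
            is_scalar_num(minimum_distance), minimum_distance > 0,
            is_scalar_num(noise_radius), noise_radius > 0)
  structure(list(reference_distance = reference_distance,
                 reference_amplitude = reference_amplitude,
                 minimum_distance = minimum_distance,
                 noise_radius = noise_radius),
            class = "attenuation_model")
}

#' @rdname attenuation_model
#' @param model an \code{attenuation_model}.
#' @param distance distance(s) in um (>= 0; clamped below
#'   \code{minimum_distance}).
#' @return \code{attenuate} returns the scale factor(s) in uV per normalized
#'   template peak.
#' @export
attenuate <- function(model, distance) {
  stopifnot(inherits(model, "attenuation_model"))
  if (any(distance < 0)) stop_validation("'distance' must be >= 0")
  model$reference_amplitude * model$reference_distance /
    pmax(distance, model$minimum_distance)
}

#' Render spike activity onto a probe
#'
#' Builds the spike-activity component x(n): for every unit and channel the
#' unit's template, scaled by the attenuation law at the unit-to-site
#' distance, is added at each (sample-quantized) spike time — pure linear
#' superposition. Units whose nearest site lies within
#' \code{atten$noise_radius} are "resolvable" and annotated in the ground
#' truth; more distant units form the background, either rendered
#' mechanistically from their own superposed low-amplitude spikes
#' (\code{background = "mechanistic"}) or replaced by a Gaussian surrogate of
#' matched purpose (\code{"gaussian"}, default \code{noise_rms} 10 uV) for
#' speed, or omitted (\code{"none"}).
#'
#' @param pop a \code{neuron_population} with types and rates (only units
#'   with a train entry are rendered).
#' @param trains list of \code{spike_train} objects; names (or
#'   \code{unit_id}) index rows of \code{pop}.
#' @param templates a \code{\link{synth_template_bank}} bank.
#' @param probe a \code{\link{build_probe}} geometry.
#' @param atten an \code{\link{attenuation_model}}.
#' @param fs sampling rate, Hz (default 20000).
#' @param duration render duration, s (default 10).
#' @param background \code{"gaussian"}, \code{"mechanistic"} or \code{"none"}.
#' @param noise_rms RMS of the Gaussian background surrogate, uV.
#' @param seed RNG seed (template assignment and background noise).
#' @return an object of class \code{rendered_signal}: list with
#'   \code{traces} (samples x channels matrix, uV), \code{fs},
#'   \code{duration}; ground truth is attached as attribute
#'   \code{ground_truth} (spike table, unit table with per-channel peak
#'   scales).
#' @export
render_spikes <- function(pop, trains, templates, probe, atten,
                          fs = 20000, duration = 10,
                          background = c("gaussian", "mechanistic", "none"),
                          noise_rms = 10, seed = NULL) {
  background <- match.arg(background)
  stopifnot(inherits(probe, "probe_geometry"),
            inherits(atten, "attenuation_model"),
            inherits(templates, "template_bank"))
  if (!is_scalar_num(fs) || fs <= 0) stop_validation("'fs' must be > 0")
  n_samp <- as.integer(round(duration * fs))
  n_ch <- nrow(probe$sites)
  traces <- matrix(0, n_samp, n_ch)

  unit_rows <- vapply(seq_along(trains), function(i) {
    id <- trains[[i]]$unit_id
    if (is.na(id)) i else as.integer(id)
  }, 0L)
  for (tr in trains) {
    if (length(tr$times) && max(tr$times) >= duration) {
      stop_validation("spike trains must lie within the render duration")
    }
  }

  with_seed(seed, {
    ct <- vapply(templates, `[[`, "", "cell_type")
    waves <- lapply(templates, function(tp) resample_template(tp, fs)$waveform)

    spikes <- list(); units <- list()
    scales_all <- matrix(NA_real_, length(trains), n_ch)
    for (k in seq_along(trains)) {
      row <- unit_rows[k]
      pos <- as.numeric(pop[row, c("x", "y", "z")])
      d <- sqrt(colSums((t(probe$sites) - pos)^2))
      sc <- attenuate(atten, d)
      scales_all[k, ] <- sc
      cell <- pop$cell_type[row] %||% "pyramidal"
      cand <- which(ct == cell)
      if (!length(cand)) cand <- seq_along(templates)
      tmpl_id <- cand[1L + (k - 1L) %% length(cand)]
      resolvable <- min(d) <= atten$noise_radius
      if (!resolvable && background != "mechanistic") next
      w <- waves[[tmpl_id]]
      samp <- as.integer(round(trains[[k]]$times * fs)) + 1L
      samp <- samp[samp >= 1L & samp <= n_samp]
      if (length(samp)) {
        # sparse superposition: collapse overlapping template windows once,
        # then add the unit's footprint to every channel with its scale
        idx <- as.vector(outer(samp, seq_along(w) - 1L, "+"))
        val <- rep(w, each = length(samp))
        keep <- idx <= n_samp
        agg <- rowsum(val[keep], idx[keep])
        uidx <- as.integer(rownames(agg))
        for (c in seq_len(n_ch)) {
          traces[uidx, c] <- traces[uidx, c] + sc[c] * agg[, 1]
        }
      }
      if (resolvable) {
        if (length(trains[[k]]$times)) {
          spikes[[length(spikes) + 1L]] <- data.frame(
            unit = row, time = trains[[k]]$times,
            sample = as.integer(round(trains[[k]]$times * fs)) + 1L)
        }
        units[[length(units) + 1L]] <- data.frame(
          unit = row, cell_type = cell, template = tmpl_id,
          nearest_um = min(d), peak_scale = max(sc))
      }
    }
    if (background == "gaussian" && noise_rms > 0) {
      traces <- traces + matrix(stats::rnorm(n_samp * n_ch, 0, noise_rms),
                                n_samp, n_ch)
    }
    gt <- list(
      spikes = if (length(spikes)) do.call(rbind, spikes) else
        data.frame(unit = integer(), time = numeric(), sample = integer()),
      units = if (length(units)) do.call(rbind, units) else NULL,
      unit_scales = scales_all,
      background = background, noise_rms = noise_rms)
    structure(list(traces = traces, fs = fs, duration = duration),
              class = "rendered_signal", ground_truth = gt)
  })
}

#' Construct a rendered-signal container
#'
#' @param traces samples x channels numeric matrix, uV.
#' @param fs sampling rate, Hz.
#' @return a \code{rendered_signal}.
#' @export
rendered_signal <- function(traces, fs) {
  traces <- as.matrix(traces)
  if (!is_scalar_num(fs) || fs <= 0) stop_validation("'fs' must be > 0")
  structure(list(traces = traces, fs = fs, duration = nrow(traces) / fs),
            class = "rendered_signal")
}

#' @export
print.rendered_signal <- function(x, ...) {
  cat(sprintf("<rendered_signal> %d channels x %d samples @ %g Hz (%.3g s)\n",
              ncol(x$traces), nrow(x$traces), x$fs, x$duration))
  invisible(x)
}
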