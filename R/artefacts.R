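#' Default artefact class parameters
#'
#' Statistics of the three documented artefact classes, as characterised from
#' in-vivo rodent recordings: mechanical shocks (head collisions, electronic
#' interference) with peak-to-peak amplitude 136.1064 +/- 62.0262 uV and a
#' spectral peak in the 1000–2000 Hz band, 1142 us long with a 285 us
#' pre-threshold segment; mastication (chewing) bursts at a mean rate of
#' 6.17 bursts/s, mean sequence duration 3.3 s, mean chewing cycle 162.5 ms;
#' grooming sequences with heterogeneous durations of 0.4–28 s carrying
#' ordered phase annotations (1–4).
#'
#' @return a named list with components \code{shock}, \code{mastication},
#'   \code{grooming}; each is a parameter list that the corresponding
#'   generator accepts.
#' @export
artefact_class_params <- function() {
  list(
    shock = list(p2p_mean = 136.1064, p2p_sd = 62.0262, p2p_min = 10,
                 peak_band = c(1000, 2000), duration = 1142e-6,
                 pre_threshold = 285e-6),
    mastication = list(burst_rate_mean = 6.17, cycle_mean = 0.1625,
                       cycle_sd = 0.015, sequence_duration_mean = 3.3,
                       sequence_duration_sd = 0.8, burst_duration = 0.08,
                       burst_amplitude = 120),
    grooming = list(duration_range = c(0.4, 28), phases = 1:4,
                    phase_prob = 0.7, amplitude = 150))
}

#' Number of artefacts to inject
#'
#' \code{N = round(a_rate x duration)}: the injected event count is the
#' average artefact rate integrated over the recording.
#'
#' @param a_rate average artefacts per second (>= 0).
#' @param duration recording duration, s (> 0).
#' @return integer count.
#' @examples
#' count_artefacts(10, 10)  # 100
#' @export
count_artefacts <- function(a_rate, duration) {
  if (!is_scalar_num(a_rate) || a_rate < 0) {
    stop_validation("'a_rate' must be >= 0")
  }
  if (!is_scalar_num(duration) || duration <= 0) {
    stop_validation("'duration' must be > 0")
  }
  as.integer(round_half_away(a_rate * duration))
}

new_artefact_template <- function(waveform, class, fs, duration, annotations) {
  structure(list(waveform = waveform, class = class, fs = fs,
                 duration = duration, annotations = annotations),
            class = "artefact_template")
}

#' @export
print.artefact_template <- function(x, ...) {
  cat(sprintf("<artefact_template> %s: %.4g s @ %g Hz, p2p %.4g uV\n",
              x$class, x$duration, x$fs,
              diff(range(x$waveform))))
  invisible(x)
}

#' Synthesize a mechanical-shock artefact template
#'
#' A damped oscillation whose carrier frequency is drawn uniformly from the
#' class peak band (1000–2000 Hz) and whose realized peak-to-peak amplitude
#' is drawn from Normal(136.1064, 62.0262) uV truncated above 10 uV. The
#' template spans 1142 us with a quiet 285 us pre-threshold segment before
#' the sharp onset (32 samples at the native 28 kHz of the reference library;
#' scaled to \code{fs}).
#'
#' @param params shock parameter list (see
#'   \code{\link{artefact_class_params}}).
#' @param fs sampling rate, Hz; must exceed 4000 Hz so the 2 kHz carrier is
#'   representable.
#' @param seed RNG seed.
#' @return an \code{artefact_template} of class tag
#'   \code{"mechanical_shock"}; \code{annotations$carrier_hz} records the
#'   drawn carrier.
#' @export
gen_shock <- function(params = artefact_class_params()$shock, fs = 20000,
                      seed = NULL) {
  if (!is_scalar_num(fs) || fs <= 4000) {
    stop_validation("'fs' must exceed 4000 Hz to represent the 1-2 kHz peak band")
  }
  with_seed(seed, {
    n <- max(4L, as.integer(round(params$duration * fs)))
    n_pre <- as.integer(round(params$pre_threshold * fs))
    carrier <- stats::runif(1, params$peak_band[1], params$peak_band[2])
    p2p <- if (params$p2p_sd == 0) params$p2p_mean else {
      repeat {
        a <- stats::rnorm(1, params$p2p_mean, params$p2p_sd)
        if (a > params$p2p_min) break
      }
      a
    }
    t <- (seq_len(n) - 1) / fs
    t_on <- n_pre / fs
    tau <- (params$duration - params$pre_threshold) / 3
    w <- ifelse(t < t_on, 0,
                exp(-(t - t_on) / tau) * sin(2 * pi * carrier * (t - t_on)))
    w <- w * taper_window(n, 0.08)
    w <- w / diff(range(w)) * p2p
    new_artefact_template(w, "mechanical_shock", fs, params$duration,
                          list(carrier_hz = carrier, p2p_uv = p2p,
                               pre_threshold_s = params$pre_threshold))
  })
}

#' Synthesize a mastication artefact sequence
#'
#' A train of enveloped noise bursts: burst-to-burst (chewing cycle)
#' intervals are drawn around 162.5 ms, the sequence duration around 3.3 s,
#' giving the documented ~6.17 bursts/s. Burst onsets are annotated.
#'
#' @param params mastication parameter list.
#' @param fs sampling rate, Hz (> 2000).
#' @param seed RNG seed.
#' @return an \code{artefact_template} of class tag \code{"mastication"};
#'   \code{annotations$burst_onsets} holds onset times (s, within the
#'   sequence).
#' @export
gen_mastication <- function(params = artefact_class_params()$mastication,
                            fs = 20000, seed = NULL) {
  if (!is_scalar_num(fs) || fs <= 2000) stop_validation("'fs' must exceed 2 kHz")
  with_seed(seed, {
    dur <- max(0.5, stats::rnorm(1, params$sequence_duration_mean,
                                 params$sequence_duration_sd))
    onsets <- 0
    repeat {
      cyc <- if (params$cycle_sd == 0) params$cycle_mean else
        max(0.05, stats::rnorm(1, params$cycle_mean, params$cycle_sd))
      nxt <- onsets[length(onsets)] + cyc
      if (nxt >= dur) break
      onsets <- c(onsets, nxt)
    }
    n <- as.integer(round(dur * fs))
    w <- numeric(n)
    nb <- as.integer(round(params$burst_duration * fs))
    env <- (1 - cos(2 * pi * seq(0, 1, length.out = nb))) / 2  # Hann burst
    for (on in onsets) {
      i0 <- as.integer(round(on * fs)) + 1L
      idx <- i0:min(i0 + nb - 1L, n)
      amp <- params$burst_amplitude * stats::runif(1, 0.7, 1.3)
      w[idx] <- w[idx] + amp * env[seq_along(idx)] *
        stats::rnorm(length(idx))
    }
    new_artefact_template(w, "mastication", fs, dur,
                          list(burst_onsets = onsets))
  })
}

#' Synthesize a grooming artefact sequence
#'
#' A broadband, large-amplitude segment with duration drawn uniformly in the
#' documented 0.4–28 s range. The sequence is split into an ordered subset of
#' the four stereotyped grooming phases (phases may be skipped, never
#' reordered); phase onsets are annotated.
#'
#' @param params grooming parameter list.
#' @param fs sampling rate, Hz (> 2000).
#' @param seed RNG seed.
#' @return an \code{artefact_template} of class tag \code{"grooming"};
#'   \code{annotations$phases} is a data frame of (phase, onset s).
#' @export
gen_grooming <- function(params = artefact_class_params()$grooming,
                         fs = 20000, seed = NULL) {
  if (!is_scalar_num(fs) || fs <= 2000) stop_validation("'fs' must exceed 2 kHz")
  with_seed(seed, {
    dur <- stats::runif(1, params$duration_range[1], params$duration_range[2])
    present <- params$phases[stats::runif(length(params$phases)) <
                             params$phase_prob]
    if (!length(present)) present <- sample(params$phases, 1)
    k <- length(present)
    bounds <- if (k > 1) sort(stats::runif(k - 1, 0, dur)) else numeric(0)
    onsets <- c(0, bounds)
    n <- as.integer(round(dur * fs))
    # per-phase amplitude modulation over broadband noise
    amp <- numeric(n)
    edges <- c(onsets, dur)
    for (i in seq_len(k)) {
      idx <- seq(as.integer(round(edges[i] * fs)) + 1L,
                 max(as.integer(round(edges[i + 1] * fs)), 1L))
      idx <- idx[idx >= 1L & idx <= n]
      amp[idx] <- params$amplitude * stats::runif(1, 0.6, 1.4)
    }
    w <- amp * stats::rnorm(n) * taper_window(n, 0.02)
    new_artefact_template(w, "grooming", fs, dur,
                          list(phases = data.frame(phase = present,
                                                   onset = onsets)))
  })
}

#' Schedule artefact onsets inside a recording
#'
#' Onsets are drawn uniformly over the feasible range (Mersenne–Twister
#' uniforms, R's default RNG); events are kept pairwise disjoint by rejection
#' sampling (up to \code{max_attempts} draws per event). When the packing is
#' infeasible a scheduling error carries the count achieved in its
#' \code{achieved} field.
#'
#' @param n number of events.
#' @param duration recording duration, s.
#' @param artefact_durations per-event durations, s (recycled to length
#'   \code{n}).
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling cap per event (default 1000).
#' @return numeric vector of onsets (s), in draw order.
#' @export
schedule_artefacts <- function(n, duration, artefact_durations, seed = NULL,
                               max_attempts = 1000L) {
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  durs <- rep_len(artefact_durations, n)
  if (sum(durs) >= duration && !isTRUE(all.equal(sum(durs), duration))) {
    stop_scheduling("total artefact time exceeds the recording duration",
                    achieved = 0L)
  }
  with_seed(seed, {
    onsets <- numeric(0); ends <- numeric(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (k in seq_len(max_attempts)) {
        o <- stats::runif(1, 0, duration - durs[i])
        if (!any(o < ends & (o + durs[i]) > onsets)) {
          onsets <- c(onsets, o); ends <- c(ends, o + durs[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_scheduling(sprintf(
          "could not place event %d of %d after %d attempts", i, n,
          max_attempts), achieved = i - 1L)
      }
    }
    onsets
  })
}

#' Describe an artefact injection
#'
#' @param onset onset time, s.
#' @param template an \code{artefact_template}.
#' @param channels affected channel indices (\code{NULL} = all channels).
#' @param channel_gains optional per-channel multipliers (recycled).
#' @return an object of class \code{artefact_event}.
#' @export
artefact_event <- function(onset, template, channels = NULL,
                           channel_gains = 1) {
  stopifnot(inherits(template, "artefact_template"))
  if (!is_scalar_num(onset) || onset < 0) stop_validation("'onset' must be >= 0")
  structure(list(onset = onset, template = template, channels = channels,
                 channel_gains = channel_gains),
            class = "artefact_event")
}

#' Inject an artefact event into a rendered signal
#'
#' The template is added sample-wise on the masked channels. To splice the
#' waveform smoothly into the composite, one transition sample is inserted
#' immediately before the onset and after the offset, whose added value is
#' the linear interpolant between the untouched signal (0 added) and the
#' template's first (resp. last) sample — i.e. half the boundary sample,
#' anchored at the preceding composite value. The operation is exactly
#' invertible: subtracting the template and the two transition values
#' restores the input.
#'
#' @param signal a \code{rendered_signal}.
#' @param event an \code{\link{artefact_event}}; template sampling rate must
#'   match the signal's.
#' @return the signal with the event added; the event record is appended to
#'   attribute \code{artefact_log} (onset, duration, class, channels).
#' @export
inject_artefact <- function(signal, event) {
  stopifnot(inherits(signal, "rendered_signal"),
            inherits(event, "artefact_event"))
  tmpl <- event$template
  if (!isTRUE(all.equal(tmpl$fs, signal$fs))) {
    stop_validation("template and signal sampling rates differ")
  }
  n <- nrow(signal$traces)
  w <- tmpl$waveform
  i0 <- as.integer(round(event$onset * signal$fs)) + 1L
  i1 <- i0 + length(w) - 1L
  if (i0 < 1L || i1 > n) {
    stop_validation("artefact event exceeds the signal bounds")
  }
  ch <- event$channels %||% seq_len(ncol(signal$traces))
  gains <- rep_len(event$channel_gains, length(ch))
  for (k in seq_along(ch)) {
    g <- gains[k]; c_i <- ch[k]
    signal$traces[i0:i1, c_i] <- signal$traces[i0:i1, c_i] + g * w
    if (i0 > 1L) {
      signal$traces[i0 - 1L, c_i] <- signal$traces[i0 - 1L, c_i] + g * w[1] / 2
    }
    if (i1 < n) {
      signal$traces[i1 + 1L, c_i] <- signal$traces[i1 + 1L, c_i] +
        g * w[length(w)] / 2
    }
  }
  log <- attr(signal, "artefact_log") %||%
    data.frame(onset = numeric(), duration = numeric(), class = character(),
               n_samples = integer(), channels = I(list()))
  rec <- data.frame(onset = event$onset, duration = length(w) / signal$fs,
                    class = tmpl$class, n_samples = length(w))
  rec$channels <- I(list(ch))
  attr(signal, "artefact_log") <- rbind(log, rec)
  signal
}

# Internal batch form of inject_artefact: one traces allocation for many
# full-probe events (the per-event public API copies the matrix every call).
inject_events <- function(traces, fs, templates, onsets) {
  n <- nrow(traces)
  log <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    w <- templates[[i]]$waveform
    i0 <- as.integer(round(onsets[i] * fs)) + 1L
    i1 <- i0 + length(w) - 1L
    if (i0 < 1L || i1 > n) {
      stop_validation("artefact event exceeds the signal bounds")
    }
    for (ch in seq_len(ncol(traces))) {
      traces[i0:i1, ch] <- traces[i0:i1, ch] + w
      if (i0 > 1L) traces[i0 - 1L, ch] <- traces[i0 - 1L, ch] + w[1] / 2
      if (i1 < n) traces[i1 + 1L, ch] <- traces[i1 + 1L, ch] + w[length(w)] / 2
    }
    log[[i]] <- data.frame(onset = onsets[i], duration = length(w) / fs,
                           class = templates[[i]]$class,
                           n_samples = length(w))
  }
  list(traces = traces, log = do.call(rbind, log))
}

#' Cross-channel coincidence rule for artefact detection
#'
#' An artefact is declared when the signal crosses the per-channel amplitude
#' threshold on at least \code{coincidence_fraction} of the channels
#' simultaneously — within a sliding window of \code{window} seconds (300 us
#' by default, converted to samples by rounding up).
#'
#' @param thresholds per-channel absolute thresholds, uV (recycled to the
#'   channel count at detection time).
#' @param coincidence_fraction required fraction of channels in (0, 1]
#'   (default 0.8).
#' @param window coincidence window, s (default 300e-6).
#' @return an object of class \code{detection_rule}.
#' @export
detection_rule <- function(thresholds, coincidence_fraction = 0.8,
                           window = 300e-6) {
  if (!is.numeric(thresholds) || !length(thresholds) || any(thresholds <= 0)) {
    stop_validation("'thresholds' must be positive (uV)")
  }
  if (!is_scalar_num(coincidence_fraction) || coincidence_fraction <= 0 ||
      coincidence_fraction > 1) {
    stop_validation("'coincidence_fraction' must be in (0, 1]")
  }
  if (!is_scalar_num(window) || window <= 0) {
    stop_validation("'window' must be > 0 (s)")
  }
  structure(list(thresholds = thresholds,
                 coincidence_fraction = coincidence_fraction,
                 window = window),
            class = "detection_rule")
}

#' Detect artefacts by cross-channel coincidence
#'
#' Finds upward crossings of |signal| through each channel's threshold, then
#' reports an event wherever at least
#' \code{ceil(coincidence_fraction x n_channels)} distinct channels cross
#' within any window of the configured width. Detections closer than one
#' window are merged into a single event.
#'
#' @param signal a \code{rendered_signal}.
#' @param rule a \code{\link{detection_rule}}.
#' @return a data frame of events: \code{onset} (s, first crossing),
#'   \code{n_channels} (distinct channels in the triggering window). Zero
#'   rows when nothing is detected.
#' @export
detect_artefacts <- function(signal, rule) {
  stopifnot(inherits(signal, "rendered_signal"),
            inherits(rule, "detection_rule"))
  x <- signal$traces
  n <- nrow(x); n_ch <- ncol(x)
  empty <- data.frame(onset = numeric(), n_channels = integer())
  if (n == 0L) return(empty)
  thr <- rep_len(rule$thresholds, n_ch)
  need <- as.integer(ceiling(rule$coincidence_fraction * n_ch))
  win <- as.integer(ceiling(rule$window * signal$fs))
  cross <- lapply(seq_len(n_ch), function(ch) {
    above <- abs(x[, ch]) >= thr[ch]
    which(above & !c(FALSE, above[-n]))
  })
  samp <- unlist(cross)
  if (!length(samp)) return(empty)
  chan <- rep.int(seq_len(n_ch), lengths(cross))
  o <- order(samp)
  samp <- samp[o]; chan <- chan[o]
  # sliding window: for each crossing, channels within [t, t + win - 1]
  m <- length(samp)
  hit <- logical(m)
  j <- 1L
  for (i in seq_len(m)) {
    if (j < i) j <- i
    while (j < m && samp[j + 1L] <= samp[i] + win - 1L) j <- j + 1L
    if (length(unique(chan[i:j])) >= need) hit[i] <- TRUE
  }
  if (!any(hit)) return(empty)
  hs <- samp[hit]
  # merge triggering windows closer than one window into single events
  brk <- c(TRUE, diff(hs) > win)
  grp <- cumsum(brk)
  onsets <- tapply(hs, grp, min)
  nch <- vapply(split(seq_along(samp)[hit], grp), function(ii) {
    i <- ii[1]
    j <- max(which(samp <= samp[i] + win - 1L))
    length(unique(chan[i:j]))
  }, 0L)
  data.frame(onset = (as.numeric(onsets) - 1) / signal$fs,
             n_channels = as.integer(nch), row.names = NULL)
}

#' Write / read an artefact template library
#'
#' Serialises a list of \code{artefact_template} objects to a JSON container
#' (per-template waveform, class tag, sampling rate, duration, annotations),
#' mirroring the layout of downloadable artefact libraries so that sets
#' extracted from real recordings can be dropped in.
#'
#' @param templates list of \code{artefact_template} objects.
#' @param path file path (JSON).
#' @return \code{write_artefact_library} returns \code{path} invisibly;
#'   \code{read_artefact_library} returns the list of templates.
#' @export
write_artefact_library <- function(templates, path) {
  stopifnot(all(vapply(templates, inherits, TRUE, "artefact_template")))
  payload <- lapply(templates, function(tp) {
    ann <- tp$annotations
    if (!is.null(ann$phases)) ann$phases <- as.list(ann$phases)
    list(class = tp$class, fs = tp$fs, duration = tp$duration,
         waveform = tp$waveform, annotations = ann)
  })
  jsonlite::write_json(list(format = "spikebench-artefact-library",
                            version = 1L, sets = payload),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_artefact_library
#' @export
read_artefact_library <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$format, "spikebench-artefact-library")) {
    stop_validation("not a spikebench artefact library")
  }
  lapply(j$sets, function(s) {
    ann <- s$annotations
    if (!is.null(ann$phases)) {
      ann$phases <- data.frame(phase = unlist(ann$phases$phase),
                               onset = unlist(ann$phases$onset))
    }
    ann <- lapply(ann, function(a) if (is.data.frame(a)) a else unlist(a))
    new_artefact_template(as.numeric(unlist(s$waveform)), s$class,
                          as.numeric(s$fs), as.numeric(s$duration), ann)
  })
}
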