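#' Low-pass filter specification
#'
#' Defines the zero-phase low-pass used to isolate slow oscillations: by
#' default a 10th-order Butterworth at 300 Hz applied forward and backward
#' (zero phase distortion, squared magnitude response — amplitude 0.5 at the
#' cutoff).
#'
#' @param order filter order (>= 1, default 10).
#' @param cutoff cutoff frequency, Hz (default 300; must be below Nyquist at
#'   filtering time).
#' @param zero_phase apply forward and backward (default TRUE).
#' @return an object of class \code{filter_spec}.
#' @export
filter_spec <- function(order = 10, cutoff = 300, zero_phase = TRUE) {
  if (!is_scalar_num(order) || order < 1) stop_validation("'order' must be >= 1")
  if (!is_scalar_num(cutoff) || cutoff <= 0) stop_validation("'cutoff' must be > 0")
  structure(list(order = as.integer(order), cutoff = cutoff, type = "low",
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Butterworth low-pass as second-order sections. A 10th-order filter at a
# 300/20000 relative cutoff is numerically unusable in expanded (b, a) form
# (pole clustering makes direct-form filtering lose ~4 decimal digits), so
# the design stays in pole-zero space: analog prototype poles, bilinear
# transform, conjugate pairs grouped into biquads, each normalized to exact
# unit DC gain.
butter_sections <- function(spec, fs) {
  if (spec$cutoff >= fs / 2) {
    stop_validation("filter cutoff must be below the Nyquist frequency")
  }
  ord <- spec$order
  theta <- pi * (2 * seq_len(ord) - 1) / (2 * ord)
  pa <- 2 * fs * tan(pi * spec$cutoff / fs) *
    complex(real = -sin(theta), imaginary = cos(theta))
  pz <- (1 + pa / (2 * fs)) / (1 - pa / (2 * fs))
  used <- rep(FALSE, ord)
  sections <- list()
  for (i in seq_len(ord)) {
    if (used[i]) next
    if (abs(Im(pz[i])) < 1e-10) {
      a <- c(1, -Re(pz[i]), 0); b <- c(1, 1, 0)
    } else {
      j <- which(!used & abs(pz - Conj(pz[i])) < 1e-8 & seq_len(ord) != i)[1]
      used[j] <- TRUE
      a <- c(1, -2 * Re(pz[i]), Mod(pz[i])^2); b <- c(1, 2, 1)
    }
    used[i] <- TRUE
    sections[[length(sections) + 1L]] <- list(b = b * sum(a) / sum(b), a = a)
  }
  # startup-transient length: samples until the slowest pole decays to 1e-13
  r <- max(Mod(pz))
  attr(sections, "transient") <- max(3L * ord, ceiling(log(1e-13) / log(r)))
  sections
}

# Biquad cascade, direct-form II transposed, in compiled code (one pass over
# the signal per section; zero initial state — edges are handled by padding).
apply_sections <- function(sections, x) {
  b <- vapply(sections, `[[`, numeric(3), "b")
  a <- vapply(sections, `[[`, numeric(3), "a")
  .Call(sb_sos_filter, as.numeric(x), b, a, length(sections))
}

# Zero-phase filtering: odd-reflection padding (at least 3 x order samples,
# extended to the filter's transient length; constant-extended when the
# signal is shorter than the pad), forward then reverse pass.
zero_phase_filter <- function(x, spec, fs) {
  sections <- butter_sections(spec, fs)
  n <- length(x)
  np <- attr(sections, "transient")
  nr <- min(np, n - 1L)
  pad_l <- 2 * x[1] - x[seq(nr + 1, 2, by = -1)]
  pad_r <- 2 * x[n] - x[seq(n - 1, n - nr)]
  pad_l <- c(rep(pad_l[1], np - nr), pad_l)
  pad_r <- c(pad_r, rep(pad_r[length(pad_r)], np - nr))
  y <- c(pad_l, x, pad_r)
  y <- apply_sections(sections, y)
  if (spec$zero_phase) {
    y <- rev(apply_sections(sections, rev(y)))
  }
  y[seq(np + 1, np + n)]
}

#' Extract the slow-oscillation component from a recording
#'
#' Per-channel zero-phase low-pass (forward-backward Butterworth per
#' \code{\link{filter_spec}}), preserving length and introducing no phase
#' shift. This is the extraction path used on real multichannel recordings;
#' \code{\link{synth_slow}} is the synthetic stand-in.
#'
#' @param recording a \code{rendered_signal} (or any traces + fs container).
#' @param spec a \code{\link{filter_spec}} (default 10th order, 300 Hz).
#' @return an object of class \code{slow_oscillation}: traces, fs, and
#'   \code{source = "extracted"}.
#' @export
extract_slow <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "rendered_signal"),
            inherits(spec, "filter_spec"))
  traces <- apply(recording$traces, 2, zero_phase_filter,
                  spec = spec, fs = recording$fs)
  structure(list(traces = matrix(traces, nrow(recording$traces)),
                 fs = recording$fs, source = "extracted", spec = spec),
            class = c("slow_oscillation", "rendered_signal"))
}

#' Synthesize a non-stationary slow-oscillation component
#'
#' Generates the w(n) component when no real recording is supplied: pink
#' (1/f) broadband noise shared across channels (plus a smaller per-channel
#' independent term, so channels are correlated but not identical), an
#' amplitude-modulated condition-specific oscillation — theta band (8 Hz) for
#' \code{"awake"}, slow-wave (1.5 Hz) for \code{"anaesthetised"} — all
#' low-passed at 300 Hz and scaled to the target RMS (100 uV awake, 200 uV
#' anaesthetised by default).
#'
#' @param condition \code{"awake"} or \code{"anaesthetised"}.
#' @param channels number of channels.
#' @param fs sampling rate, Hz.
#' @param duration duration, s (> 0).
#' @param seed RNG seed.
#' @param amplitude_rms target per-channel RMS in uV; \code{NULL} uses the
#'   condition default; 0 yields an all-zero component.
#' @param cutoff low-pass cutoff, Hz (default 300).
#' @return a \code{slow_oscillation} with \code{source = "synthetic"}.
#' @export
synth_slow <- function(condition = c("awake", "anaesthetised"), channels,
                       fs, duration, seed = NULL, amplitude_rms = NULL,
                       cutoff = 300) {
  condition <- match.arg(condition)
  if (!is_scalar_num(duration) || duration <= 0) {
    stop_validation("'duration' must be > 0")
  }
  amplitude_rms <- amplitude_rms %||%
    switch(condition, awake = 100, anaesthetised = 200)
  n <- as.integer(round(duration * fs))
  spec <- filter_spec(order = 10, cutoff = cutoff)
  with_seed(seed, {
    if (amplitude_rms == 0) {
      traces <- matrix(0, n, channels)
    } else {
      f_osc <- switch(condition, awake = 8, anaesthetised = 1.5)
      shared <- pink_noise(n)
      tt <- (seq_len(n) - 1) / fs
      env <- 1 + 0.5 * sin(2 * pi * stats::runif(1, 0.05, 0.15) * tt +
                           stats::runif(1, 0, 2 * pi))
      osc_amp <- switch(condition, awake = 1.2, anaesthetised = 2.0)
      osc <- osc_amp * env * sin(2 * pi * f_osc * tt + stats::runif(1, 0, 2 * pi))
      traces <- vapply(seq_len(channels), function(ch) {
        v <- shared + 0.3 * pink_noise(n) + osc
        v <- zero_phase_filter(v, spec, fs)
        v / stats::sd(v) * amplitude_rms
      }, numeric(n))
      traces <- matrix(traces, n, channels)
    }
    structure(list(traces = traces, fs = fs, source = "synthetic",
                   condition = condition, spec = spec),
              class = c("slow_oscillation", "rendered_signal"))
  })
}

# Pink (1/f) noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  nf <- n %/% 2 + 1L
  f <- seq_len(nf) - 1L
  mag <- c(0, 1 / sqrt(f[-1]))
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- mag * exp(1i * phase)
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1L)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x[seq_len(n)]
  as.numeric((x - mean(x)) / stats::sd(x))
}

#' Spike contamination of the slow band
#'
#' Checks that spike waveforms leak negligibly into the low-frequency band:
#' returns the ratio of in-band (below \code{cutoff}) power of the mean spike
#' waveform to in-band power of the slow-oscillation component. Both powers
#' are band-integrated periodogram densities. The caller compares the ratio
#' against a threshold (0.05 is the package's default notion of
#' "negligible").
#'
#' @param mean_spike a \code{spike_template} (mean spike waveform, uV scale).
#' @param slow a \code{slow_oscillation}.
#' @param cutoff band edge, Hz (default 300).
#' @return the power ratio (numeric scalar, >= 0).
#' @export
contamination_check <- function(mean_spike, slow, cutoff = 300) {
  stopifnot(inherits(mean_spike, "spike_template"),
            inherits(slow, "rendered_signal"))
  num <- band_power(mean_spike$waveform, mean_spike$fs, cutoff)
  den <- mean(apply(slow$traces, 2, band_power, fs = slow$fs, hi = cutoff))
  if (den <= 0) {
    stop_validation("slow component has zero power below the cutoff")
  }
  num / den
}

# Mean power (uV^2) of x in [0, hi] Hz from the one-sided periodogram.
band_power <- function(x, fs, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / (n * fs)       # two-sided density, uV^2/Hz
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f <= hi | f >= fs - hi]) * fs / n    # integrate over the band
}
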