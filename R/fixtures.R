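#' Build a miniature recording with planted artefact-like events
#'
#' Test fixture generator: Gaussian background noise of known RMS with
#' suprathreshold pulses planted on chosen channel subsets and time spreads,
#' so detector behaviour (coincidence fraction, window width, merging) can be
#' checked against a fully known truth without any real data.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz.
#' @param duration duration, s.
#' @param events list of event specs; each a list with \code{onset} (s),
#'   \code{channels} (indices), and optionally \code{spread} (s, the time
#'   span over which per-channel crossings are staggered; default 0) and
#'   \code{amplitude} (uV; default \code{10 x noise_rms}).
#' @param seed RNG seed.
#' @param noise_rms background RMS, uV (default 5).
#' @return an object of class \code{planted_recording}: \code{signal} (a
#'   \code{rendered_signal}) and \code{truth} (data frame: kind, onset,
#'   n_channels).
#' @examples
#' pr <- make_planted(4, 20000, 0.5,
#'                    events = list(list(onset = 0.2, channels = 1:4)),
#'                    seed = 1)
#' @export
make_planted <- function(n_channels, fs, duration, events = list(),
                         seed = NULL, noise_rms = 5) {
  if (!is_scalar_num(n_channels) || n_channels < 1) {
    stop_validation("'n_channels' must be >= 1")
  }
  n <- as.integer(round(duration * fs))
  with_seed(seed, {
    traces <- matrix(stats::rnorm(n * n_channels, 0, noise_rms), n, n_channels)
    truth <- data.frame(kind = character(), onset = numeric(),
                        n_channels = integer())
    for (ev in events) {
      ch <- ev$channels
      spread <- ev$spread %||% 0
      amp <- ev$amplitude %||% (10 * noise_rms)
      i0 <- as.integer(round(ev$onset * fs)) + 1L
      spread_n <- as.integer(round(spread * fs))
      if (i0 < 1L || i0 + spread_n + 1L > n || any(ch < 1 | ch > n_channels)) {
        stop_validation("planted event outside the recording bounds")
      }
      # stagger channel crossings evenly across the requested spread
      offs <- if (length(ch) > 1L && spread_n > 0L) {
        as.integer(round(seq(0, spread_n, length.out = length(ch))))
      } else rep(0L, length(ch))
      for (k in seq_along(ch)) {
        idx <- i0 + offs[k]
        traces[idx, ch[k]] <- traces[idx, ch[k]] + amp
        traces[idx + 1L, ch[k]] <- traces[idx + 1L, ch[k]] - amp / 2
      }
      truth <- rbind(truth, data.frame(kind = "planted", onset = ev$onset,
                                       n_channels = length(ch)))
    }
    structure(list(signal = rendered_signal(traces, fs), truth = truth),
              class = "planted_recording")
  })
}

#' @export
print.planted_recording <- function(x, ...) {
  cat(sprintf("<planted_recording> %d channels, %.3g s, %d planted events\n",
              ncol(x$signal$traces), x$signal$duration, nrow(x$truth)))
  invisible(x)
}
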