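#' Bartlett averaged periodogram
#'
#' Splits a single-channel signal into K non-overlapping segments (1 s by
#' default, so a 10 s benchmark yields K = 10), computes each segment's
#' periodogram via the DFT with the density normalization
#' \code{|DFT|^2 / (N * fs)} (no taper — rectangular segments), averages the
#' K periodograms, and attaches the per-frequency standard error of the mean
#' (segment standard deviation divided by sqrt(K)).
#'
#' @param x numeric vector, single-channel signal (uV).
#' @param fs sampling rate, Hz.
#' @param segment_length segment length, s (default 1). The signal must be at
#'   least one segment long.
#' @return an object of class \code{psd_estimate}: \code{frequencies} (Hz,
#'   0..fs/2), \code{power} (one-sided averaged periodogram, uV^2/Hz),
#'   \code{sem}, \code{n_segments}, \code{segment_power} (bins x K matrix),
#'   \code{fs}, and \code{smoothed} once \code{\link{smooth_local}} has run.
#' @examples
#' psd <- bartlett_psd(sin(2 * pi * 100 * seq(0, 10, by = 1e-3)), fs = 1000)
#' psd$n_segments  # 10
#' @export
bartlett_psd <- function(x, fs, segment_length = 1) {
  x <- as.numeric(x)
  if (!is_scalar_num(fs) || fs <= 0) stop_validation("'fs' must be > 0")
  if (!is_scalar_num(segment_length) || segment_length <= 0) {
    stop_validation("'segment_length' must be > 0")
  }
  nseg <- as.integer(round(segment_length * fs))
  k <- length(x) %/% nseg
  if (k < 1L) {
    stop_validation("signal shorter than one segment")
  }
  nf <- nseg %/% 2L + 1L
  segp <- matrix(0, nf, k)
  for (i in seq_len(k)) {
    seg <- x[((i - 1L) * nseg + 1L):(i * nseg)]
    p2 <- Mod(stats::fft(seg))^2 / (nseg * fs)  # two-sided density
    p1 <- p2[seq_len(nf)]
    # fold: double interior bins (DC, and Nyquist when nseg even, are unique)
    last_unique <- if (nseg %% 2L == 0L) nf else NA_integer_
    dbl <- setdiff(seq_len(nf), c(1L, last_unique))
    p1[dbl] <- 2 * p1[dbl]
    segp[, i] <- p1
  }
  power <- rowMeans(segp)
  sem <- if (k > 1L) apply(segp, 1, stats::sd) / sqrt(k) else rep(NA_real_, nf)
  structure(list(frequencies = (seq_len(nf) - 1L) * fs / nseg,
                 power = power, sem = sem, n_segments = k,
                 segment_power = segp, fs = fs, smoothed = NULL),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d bins, 0-%g Hz, K = %d segments%s\n",
    length(x$frequencies), max(x$frequencies), x$n_segments,
    if (!is.null(x$smoothed)) ", smoothed" else ""))
  invisible(x)
}

#' @export
plot.psd_estimate <- function(x, log = "y", xlim = NULL, ...) {
  keep <- x$power > 0
  graphics::plot(x$frequencies[keep], x$power[keep], type = "l", log = log,
                 xlim = xlim, xlab = "frequency (Hz)",
                 ylab = "PSD (uV^2/Hz)", ...)
  if (!is.null(x$smoothed)) {
    graphics::lines(x$frequencies, pmax(x$smoothed, .Machine$double.xmin),
                    col = "red")
  }
  invisible(x)
}

#' Locally weighted polynomial smoothing of a PSD
#'
#' Weighted local least-squares polynomial regression (tri-cube weights,
#' degree 2 by default) of power against frequency, with a window of
#' \code{span} times the number of bins — the classic "loess" smoother with a
#' 1\% span.
#'
#' @param est a \code{psd_estimate}.
#' @param span window as a proportion of the bins, in (0, 1] (default 0.01).
#' @param degree local polynomial degree (default 2).
#' @return the estimate with \code{$smoothed} filled in (same length as
#'   \code{power}).
#' @export
smooth_local <- function(est, span = 0.01, degree = 2) {
  stopifnot(inherits(est, "psd_estimate"))
  if (!is_scalar_num(span) || span <= 0 || span > 1) {
    stop_validation("'span' must be in (0, 1]")
  }
  n <- length(est$power)
  if (floor(span * n) < degree + 1) {
    stop_validation(sprintf(
      "span window (%d points) too small for a degree-%d fit",
      floor(span * n), degree))
  }
  df <- data.frame(f = est$frequencies, p = est$power)
  fit <- stats::loess(p ~ f, data = df, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  est$smoothed <- as.numeric(stats::predict(fit, newdata = df))
  est
}

#' Band-wise PSD comparison
#'
#' Mean log10 power ratio of estimate \code{b} over estimate \code{a} per
#' frequency band, with the SEMs propagated through the log (delta method,
#' independent bins). Operationalizes "did contamination raise power in this
#' band, and by how many decades".
#'
#' @param a,b \code{psd_estimate} objects on matching frequency grids.
#' @param bands list of \code{c(lo, hi)} band edges in Hz.
#' @return data frame: \code{lo}, \code{hi}, \code{n_bins},
#'   \code{log10_ratio} (mean over bins of log10(b/a)), \code{sem}.
#' @export
compare_psd <- function(a, b, bands) {
  stopifnot(inherits(a, "psd_estimate"), inherits(b, "psd_estimate"))
  if (length(a$frequencies) != length(b$frequencies) ||
      max(abs(a$frequencies - b$frequencies)) > 1e-6) {
    stop_validation("frequency grids differ; recompute on matching segments")
  }
  out <- lapply(bands, function(bd) {
    idx <- which(a$frequencies >= bd[1] & a$frequencies < bd[2] &
                   a$power > 0 & b$power > 0)
    if (!length(idx)) {
      return(data.frame(lo = bd[1], hi = bd[2], n_bins = 0L,
                        log10_ratio = NA_real_, sem = NA_real_))
    }
    lr <- log10(b$power[idx] / a$power[idx])
    va <- (a$sem[idx] / (a$power[idx] * log(10)))^2
    vb <- (b$sem[idx] / (b$power[idx] * log(10)))^2
    sem <- sqrt(sum(va + vb, na.rm = TRUE)) / length(idx)
    data.frame(lo = bd[1], hi = bd[2], n_bins = length(idx),
               log10_ratio = mean(lr), sem = sem)
  })
  do.call(rbind, out)
}
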