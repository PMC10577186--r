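#' Welch power spectral density
#'
#' Per-channel Welch estimate with a Hanning taper: the signal is cut into
#' overlapping windows, each window is mean-detrended, tapered, and
#' transformed with the FFT; the one-sided periodograms are averaged over
#' windows and scaled as a density (power per Hz). The scalp spectrum is
#' the arithmetic mean of the per-channel densities (average scalp power
#' spectrum). At 100 Hz the default 2.048 s window rounds to 205 samples
#' (nfft = 205, ~0.488 Hz resolution).
#'
#' @param rec An [eeg_recording()].
#' @param window_seconds Window length in seconds (default 2.048).
#' @param overlap_fraction Fractional window overlap (default 0.5).
#' @return A `spectral_summary` with `frequencies`, `psd_per_channel`
#'   (channels x frequencies), and `scalp_psd`. Band powers and the DAR are
#'   added by [band_power()] / [delta_alpha_ratio()] or [spectral_summary()].
#' @export
welch_psd <- function(rec, window_seconds = 2.048, overlap_fraction = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  }
  fs <- rec$sampling_rate
  nwin <- round(window_seconds * fs)
  if (nwin < 2L) stop("window too short", call. = FALSE)
  if (nwin > n_samples(rec)) {
    stop("recording shorter than one Welch window", call. = FALSE)
  }
  hop <- max(1L, round(nwin * (1 - overlap_fraction)))
  starts <- seq(1L, n_samples(rec) - nwin + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1L)) / (nwin - 1L))  # Hanning
  u <- sum(w^2)                                                 # taper power
  nfreq <- floor(nwin / 2) + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nwin
  one_sided <- rep(2, nfreq)
  one_sided[1L] <- 1
  if (nwin %% 2L == 0L) one_sided[nfreq] <- 1
  psd <- matrix(0, nrow = n_channels(rec), ncol = nfreq)
  for (ch in seq_len(n_channels(rec))) {
    acc <- numeric(nfreq)
    for (s in starts) {
      seg <- rec$data[ch, s:(s + nwin - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
      acc <- acc + sp
    }
    psd[ch, ] <- one_sided * acc / (length(starts) * fs * u)
  }
  structure(
    list(frequencies = freqs, psd_per_channel = psd,
         scalp_psd = colMeans(psd), n_windows = length(starts),
         delta_power = NULL, alpha_power = NULL, dar = NULL),
    class = "spectral_summary"
  )
}

#' Band power of the scalp spectrum
#'
#' Sum of the channel-averaged PSD bins whose frequency lies in the closed
#' interval `[band[1], band[2]]`.
#'
#' @param summary A `spectral_summary` from [welch_psd()].
#' @param band Numeric length-2 frequency range in Hz.
#' @return The band power (sum of bins).
#' @export
band_power <- function(summary, band) {
  stopifnot(inherits(summary, "spectral_summary"), length(band) == 2L)
  idx <- summary$frequencies >= band[1L] & summary$frequencies <= band[2L]
  if (!any(idx)) {
    stop(sprintf("band [%g, %g] Hz contains no frequency bins", band[1L], band[2L]),
         call. = FALSE)
  }
  sum(summary$scalp_psd[idx])
}

#' Delta/alpha ratio (DAR)
#'
#' Ratio of delta-band (1-4 Hz) to alpha-band (8-13 Hz) power of the
#' channel-averaged spectrum; the channel average is taken before the
#' ratio. Elevated DAR is a classic quantitative-EEG marker of brain
#' injury.
#'
#' @param summary A `spectral_summary`.
#' @param delta_band,alpha_band Band limits in Hz.
#' @return The DAR (a positive scalar).
#' @export
delta_alpha_ratio <- function(summary, delta_band = c(1, 4), alpha_band = c(8, 13)) {
  d <- band_power(summary, delta_band)
  a <- band_power(summary, alpha_band)
  if (a <= 0) stop("alpha band power is zero: DAR undefined", call. = FALSE)
  d / a
}

#' One-call spectral summary with band powers and DAR
#'
#' @inheritParams welch_psd
#' @inheritParams delta_alpha_ratio
#' @return A `spectral_summary` with `delta_power`, `alpha_power` and `dar`
#'   filled in.
#' @export
spectral_summary <- function(rec, window_seconds = 2.048, overlap_fraction = 0.5,
                             delta_band = c(1, 4), alpha_band = c(8, 13)) {
  s <- welch_psd(rec, window_seconds, overlap_fraction)
  s$delta_power <- band_power(s, delta_band)
  s$alpha_power <- band_power(s, alpha_band)
  s$dar <- if (s$alpha_power > 0) s$delta_power / s$alpha_power else
    stop("alpha band power is zero: DAR undefined", call. = FALSE)
  s
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d channels, %d bins (%.3g-%.3g Hz), %d windows\n",
              nrow(x$psd_per_channel), length(x$frequencies),
              min(x$frequencies), max(x$frequencies), x$n_windows))
  if (!is.null(x$dar)) {
    cat(sprintf("  delta %.4g, alpha %.4g, DAR %.4g\n",
                x$delta_power, x$alpha_power, x$dar))
  }
  invisible(x)
}
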