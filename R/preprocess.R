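#' Zero-phase FIR band-pass (and optional notch) filter
#'
#' Applies a Hamming-windowed linear-phase FIR band-pass per channel with
#' exact group-delay compensation (the symmetric kernel is applied centered
#' via FFT convolution), so the output is zero-phase and microstate timing
#' is not shifted by filter delay. The optional notch is a narrow FIR
#' band-stop (+/- 1 Hz around the line frequency), keeping the whole chain
#' linear-phase. Filter order follows the Hamming design rule
#' (3.3 / normalized transition width) with the transition width set to 25%
#' of the lower band edge. Edges are zero-padded; the recording must span
#' at least three filter lengths so edge transients stay negligible.
#'
#' @param rec An [eeg_recording()].
#' @param low Lower pass-band edge in Hz.
#' @param high Upper pass-band edge in Hz.
#' @param notch Line frequency to suppress in Hz, or `NULL` for none.
#' @return A filtered [eeg_recording()].
#' @export
bandpass_notch_filter <- function(rec, low = 1, high = 30, notch = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  nyq <- fs / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high", call. = FALSE)
  if (high >= nyq) stop("`high` must be below the Nyquist frequency", call. = FALSE)
  if (!is.null(notch) && notch >= nyq) {
    stop("`notch` must be below the Nyquist frequency", call. = FALSE)
  }

  fir_even <- function(order, w, type) {
    order <- as.integer(order)
    if (order %% 2L == 1L) order <- order + 1L
    signal::fir1(order, w, type)
  }
  trans <- 0.25 * low
  bp_order <- ceiling(3.3 * fs / trans)
  bp <- fir_even(bp_order, c(low, high) / nyq, "pass")
  filters <- list(bp)
  if (!is.null(notch)) {
    nt_order <- ceiling(3.3 * fs / 1)    # 1 Hz transition for the +/-1 Hz stop band
    filters <- c(filters, list(
      fir_even(nt_order, c(notch - 1, notch + 1) / nyq, "stop")))
  }
  max_len <- max(vapply(filters, length, 1L))
  if (n_samples(rec) < 3L * max_len) {
    stop(sprintf(
      "recording too short for stable filtering: %d samples < 3 x filter length %d",
      n_samples(rec), max_len), call. = FALSE)
  }
  # centered application of a symmetric (linear-phase) kernel: zero phase
  # without the squared-magnitude response of a forward-backward pass
  apply_fir <- function(b, x) {
    b <- as.numeric(b)
    m <- (length(b) - 1L) %/% 2L
    full <- stats::convolve(x, rev(b), type = "open")
    full[m + seq_along(x)]
  }
  out <- rec$data
  for (b in filters) {
    for (ch in seq_len(nrow(out))) {
      out[ch, ] <- apply_fir(b, out[ch, ])
    }
  }
  if (any(!is.finite(out))) stop("filtering produced non-finite values", call. = FALSE)
  eeg_recording(out, fs, rec$channel_labels, rec$reference)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample.
#' Idempotent; between-channel differences are preserved exactly.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced [eeg_recording()] with `reference = "common_average"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L) stop("common average reference needs >= 2 channels", call. = FALSE)
  out <- sweep(rec$data, 2L, colMeans(rec$data))
  eeg_recording(out, rec$sampling_rate, rec$channel_labels, "common_average")
}

#' Extract a contiguous epoch
#'
#' @param rec An [eeg_recording()].
#' @param duration Epoch length in seconds.
#' @param offset Start offset in seconds (default 0: the pipeline keeps the
#'   first window when several epochs would fit).
#' @return An [eeg_recording()] with `round(duration * sampling_rate)` samples.
#' @export
extract_epoch <- function(rec, duration, offset = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (offset < 0) stop("`offset` must be non-negative", call. = FALSE)
  fs <- rec$sampling_rate
  start <- round(offset * fs) + 1L
  len <- round(duration * fs)
  if (start + len - 1L > n_samples(rec)) {
    stop(sprintf("requested window [%.3g s + %.3g s] exceeds the %.3g s recording",
                 offset, duration, n_samples(rec) / fs), call. = FALSE)
  }
  eeg_recording(rec$data[, start:(start + len - 1L), drop = FALSE],
                fs, rec$channel_labels, rec$reference)
}
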