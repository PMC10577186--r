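#' Multichannel EEG recording
#'
#' Container for a channels x samples potential matrix (in microvolts) with
#' its sampling rate, channel labels, and reference state. All pipeline
#' stages consume and return this class.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector of montage labels, one per channel.
#'   Defaults to the 19-electrode 10-20 montage when the channel count
#'   matches, otherwise `CH1..CHn`.
#' @param reference Either `"original"` or `"common_average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate,
                          channel_labels = NULL,
                          reference = c("original", "common_average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("an EEG recording needs at least 2 channels", call. = FALSE)
  if (ncol(data) < 1L) stop("an EEG recording needs at least 1 sample", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number (Hz)", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 19L) montage_1020()$label else
      paste0("CH", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` length must equal the channel count", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         channel_labels = as.character(channel_labels), reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, x$reference))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Standard 10-20 electrode layout
#'
#' Approximate 2-D scalp projection (head radius 1, +x right, +y anterior)
#' of the 19 electrodes of the international 10-20 system, in the montage
#' order used throughout the package. The coordinates drive synthetic
#' topography generation and the canonical class templates; they are a
#' schematic projection, not digitized positions.
#'
#' @return A data.frame with columns `label`, `x`, `y`.
#' @export
montage_1020 <- function() {
  deg <- function(a) a * pi / 180
  outer_lab <- c("FP1", "FP2", "F7", "F8", "T3", "T4", "T5", "T6", "O1", "O2")
  outer_ang <- deg(c(108, 72, 144, 36, 180, 0, 216, 324, 252, 288))
  outer <- data.frame(label = outer_lab,
                      x = cos(outer_ang), y = sin(outer_ang))
  inner <- data.frame(
    label = c("F3", "F4", "C3", "C4", "P3", "P4", "FZ", "CZ", "PZ"),
    x = c(-0.40, 0.40, -0.50, 0.50, -0.40, 0.40, 0.00, 0.00, 0.00),
    y = c(0.50, 0.50, 0.00, 0.00, -0.50, -0.50, 0.52, 0.00, -0.52))
  pos <- rbind(outer, inner)
  ord <- c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
           "F7", "F8", "T3", "T4", "T5", "T6", "FZ", "CZ", "PZ")
  pos[match(ord, pos$label), , drop = FALSE]
}

# 2-D positions for an arbitrary channel count: the 10-20 layout when
# n = 19, otherwise a sunflower-spiral filling of the unit disk (used only
# to give synthetic topographies a spatial smoothness structure).
channel_positions <- function(n) {
  if (n == 19L) {
    p <- montage_1020()
    return(cbind(x = p$x, y = p$y))
  }
  i <- seq_len(n)
  r <- sqrt((i - 0.5) / n)
  theta <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(theta), y = r * sin(theta))
}
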