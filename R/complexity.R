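#' Collapse a microstate sequence into its transition string
#'
#' Removes consecutive duplicate labels, keeping order, so only the
#' transitions between classes remain (BBBCCAADDB becomes BCADB). The
#' result is the symbolic string whose Lempel-Ziv complexity quantifies
#' how repetitive the microstate syntax is.
#'
#' @param seq A `microstate_sequence`, or a character/integer vector of labels.
#' @return A `transition_string` with `symbols` and `source_length`.
#' @export
collapse_transitions <- function(seq) {
  symbols <- if (inherits(seq, "microstate_sequence")) {
    seq$class_names[seq$labels]
  } else {
    as.character(seq)
  }
  if (!length(symbols)) stop("empty label sequence", call. = FALSE)
  r <- rle(symbols)
  structure(list(symbols = r$values, source_length = length(symbols)),
            class = "transition_string")
}

#' @export
print.transition_string <- function(x, ...) {
  cat(sprintf("<transition_string> %d symbols (from %d samples): %s%s\n",
              length(x$symbols), x$source_length,
              paste(utils::head(x$symbols, 20L), collapse = ""),
              if (length(x$symbols) > 20L) "..." else ""))
  invisible(x)
}

#' Lempel-Ziv (LZ76) complexity of a symbol sequence
#'
#' Counts the phrases of the exhaustive LZ76 parsing of the first
#' `n_prefix` symbols: scanning left to right, the current phrase is
#' extended while it can be copied from the already-seen past (overlap
#' allowed); each time extension fails a new phrase starts. The count
#' grows with sequence length, so a fixed prefix length (default 300)
#' makes values comparable across recordings. No normalization is applied.
#'
#' @param s A `transition_string` (or character vector of symbols).
#' @param n_prefix Number of leading symbols to parse (default 300).
#' @param on_short What to do when the string is shorter than `n_prefix`:
#'   `"error"` (default; complexity of a shorter string is not comparable)
#'   or `"use_full"` to parse the whole string.
#' @return Integer phrase count (>= 1).
#' @export
lempel_ziv_complexity <- function(s, n_prefix = 300, on_short = c("error", "use_full")) {
  on_short <- match.arg(on_short)
  symbols <- if (inherits(s, "transition_string")) s$symbols else as.character(s)
  if (!length(symbols)) stop("empty symbol sequence", call. = FALSE)
  if (n_prefix < 1) stop("`n_prefix` must be >= 1", call. = FALSE)
  if (length(symbols) < n_prefix) {
    if (on_short == "error") {
      stop(sprintf("sequence has %d symbols, fewer than n_prefix = %d",
                   length(symbols), n_prefix), call. = FALSE)
    }
  } else {
    symbols <- symbols[seq_len(n_prefix)]
  }
  lz76_phrase_count(symbols)
}

# LZ76 exhaustive-history parsing, linear-scan formulation (after Kaspar &
# Schuster): i is the candidate copy source, l the start of the current
# phrase, k the current match length.
lz76_phrase_count <- function(symbols) {
  s <- as.integer(factor(symbols))
  n <- length(s)
  if (n == 1L) return(1L)
  c_count <- 1L
  l <- 1L
  i <- 0L
  k <- 1L
  k_max <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) {
        c_count <- c_count + 1L
        break
      }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        c_count <- c_count + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L
        k <- 1L
        k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  c_count
}
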