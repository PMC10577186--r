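# Independent brute-force LZ76 parser used as the oracle for the package's
# linear-scan routine. String-based: the current phrase s[l..j] keeps
# extending while it occurs as a substring of the history s[1..j-1]
# (self-overlap allowed); each failure closes a phrase.
lz76_oracle <- function(symbols) {
  s <- paste(symbols, collapse = "")
  n <- nchar(s)
  stopifnot(n > 0)
  count <- 0L
  l <- 1L
  while (l <= n) {
    j <- l
    while (j <= n) {
      phrase <- substr(s, l, j)
      history <- substr(s, 1, j - 1L)
      if (j == n || !grepl(phrase, history, fixed = TRUE)) break
      j <- j + 1L
    }
    count <- count + 1L
    l <- j + 1L
  }
  count
}

# Wrap a bare matrix of planted maps as a prototype_maps object so planted
# ground truth can be back-fitted like any clustering result.
as_prototypes <- function(maps, labels = LETTERS[seq_len(nrow(maps))]) {
  structure(list(maps = maps, labels = labels, gev_total = NA_real_),
            class = "prototype_maps")
}

# Multichannel recording whose rows are scaled/negated copies of one signal,
# convenient for filter and PSD tests.
two_channel_rec <- function(x, fs = 100) {
  eeg_recording(rbind(x, -x), fs)
}

# Recording tiled from prototype maps with positive amplitudes: sample t is
# amp[t] * maps[labels[t], ]. Back-fitting it must recover `labels` exactly
# and its GEV is 100% by construction.
tiled_recording <- function(maps, labels, amp = NULL, fs = 100) {
  if (is.null(amp)) amp <- rep(5, length(labels))
  eeg_recording(t(maps[labels, , drop = FALSE] * amp), fs)
}

# Independent permutation enumeration (recursive insertion, distinct from
# the package's generator) for the assignment brute-force cross-check.
perms_by_insertion <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_by_insertion(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Feature-level synthetic cohort: 12 temporal columns plus dar and lzc,
# with an optional planted group shift on every column.
feature_cohort <- function(n_per_group = 28, shift = 0, seed = 1) {
  cols <- c(paste0("duration_", LETTERS[1:4]), paste0("occurrence_", LETTERS[1:4]),
            paste0("coverage_", LETTERS[1:4]), "dar", "lzc")
  set.seed(seed)
  base <- matrix(rnorm(2 * n_per_group * length(cols)),
                 2 * n_per_group, length(cols))
  colnames(base) <- cols
  grp <- rep(c("AW", "DOC"), each = n_per_group)
  base[grp == "DOC", ] <- base[grp == "DOC", ] + shift
  df <- as.data.frame(base)
  df$group <- grp
  df
}
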