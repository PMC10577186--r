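#' Global field power
#'
#' GFP(t) is the population standard deviation of the instantaneous
#' potentials across all electrodes:
#' sqrt(mean_i (u_i(t) - mean(u(t)))^2). Peaks of GFP mark moments of high
#' topographic signal-to-noise and are the samples used for clustering.
#'
#' @param rec An [eeg_recording()].
#' @return A `gfp_series` with `values` (one per sample) and `sampling_rate`.
#' @export
gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L) stop("GFP needs >= 2 channels", call. = FALSE)
  structure(list(values = col_pop_sd(rec$data), sampling_rate = rec$sampling_rate),
            class = "gfp_series")
}

#' Select GFP peaks for clustering
#'
#' Strict local maxima of the GFP series, thinned so consecutive retained
#' peaks are at least `min_separation_ms` apart, with outlier peaks removed
#' (they typically reflect non-neuronal artifacts). If more peaks survive
#' than `n_maps`, a uniform random subsample of size `n_maps` is drawn.
#'
#' @param g A `gfp_series` from [gfp()].
#' @param min_separation_ms Minimum spacing between retained peaks (ms).
#' @param sd_reject_factor Rejection threshold factor (see `sd_reject_mode`).
#' @param n_maps Number of peak maps to keep (default 2000).
#' @param seed Seed for the subsampling step.
#' @param sd_reject_mode `"mean_plus_sd"` rejects peaks with
#'   GFP > mean(GFP) + factor * SD(GFP) (default); `"absolute"` rejects
#'   peaks with GFP > factor * SD(GFP).
#' @return Integer vector of sample indices, sorted.
#' @export
select_gfp_peaks <- function(g, min_separation_ms = 10, sd_reject_factor = 2,
                             n_maps = 2000, seed = 1,
                             sd_reject_mode = c("mean_plus_sd", "absolute")) {
  stopifnot(inherits(g, "gfp_series"))
  sd_reject_mode <- match.arg(sd_reject_mode)
  v <- g$values
  fs <- g$sampling_rate
  if (min_separation_ms < 1000 / fs) {
    stop("`min_separation_ms` must be at least one sample period", call. = FALSE)
  }
  n <- length(v)
  if (n < 3L) stop("series too short to contain local maxima", call. = FALSE)
  idx <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
  if (!is.null(sd_reject_factor) && is.finite(sd_reject_factor)) {
    thr <- switch(sd_reject_mode,
                  mean_plus_sd = mean(v) + sd_reject_factor * stats::sd(v),
                  absolute = sd_reject_factor * stats::sd(v))
    idx <- idx[v[idx] <= thr]
  }
  min_gap <- round(min_separation_ms * fs / 1000)
  if (length(idx)) {
    keep <- idx[1L]
    last <- idx[1L]
    for (i in idx[-1L]) {
      if (i - last >= min_gap) {
        keep <- c(keep, i)
        last <- i
      }
    }
    idx <- keep
  }
  if (!length(idx)) stop("no qualifying GFP peaks found", call. = FALSE)
  if (length(idx) > n_maps) {
    idx <- sort(with_seed(seed, sample(idx, n_maps)))
  } else if (length(idx) < n_maps) {
    warning(sprintf("only %d GFP peaks available (requested %d); using all",
                    length(idx), n_maps))
  }
  idx
}

#' Extract topographic maps at given samples
#'
#' @param rec An [eeg_recording()].
#' @param indices Sample indices (e.g. from [select_gfp_peaks()]).
#' @return Matrix of maps (rows) x channels, average-referenced.
#' @export
peak_maps <- function(rec, indices) {
  m <- t(rec$data[, indices, drop = FALSE])
  m - rowMeans(m)
}

# Prototype container -------------------------------------------------------

prototype_maps <- function(maps, labels = NULL, gev_total = NA_real_) {
  maps <- as.matrix(maps)
  if (is.null(labels)) {
    labels <- if (nrow(maps) <= 26L) LETTERS[seq_len(nrow(maps))] else
      paste0("M", seq_len(nrow(maps)))
  }
  rownames(maps) <- labels
  structure(list(maps = maps, labels = labels, gev_total = gev_total),
            class = "prototype_maps")
}

#' @export
print.prototype_maps <- function(x, ...) {
  cat(sprintf("<prototype_maps> K = %d over %d channels; GEV = %s\n",
              nrow(x$maps), ncol(x$maps),
              if (is.na(x$gev_total)) "NA" else sprintf("%.1f%%", x$gev_total)))
  invisible(x)
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' Clusters scalp maps ignoring polarity: a map and its negation belong to
#' the same class. Each iteration (a) assigns every map to the prototype
#' with the largest squared spatial correlation and (b) re-estimates each
#' prototype as the dominant eigenvector of the sum of outer products of
#' its assigned maps (the direction maximizing squared correlation, which
#' is sign-indifferent). The best of `n_restarts` random initializations by
#' explained variance is returned.
#'
#' @param maps Matrix of maps (rows) x channels; average-referenced.
#' @param k Number of prototypes.
#' @param n_restarts Random restarts (default 50; raise for final fits).
#' @param max_iter Iteration cap per restart.
#' @param tol Relative explained-variance change declaring convergence.
#' @param seed RNG seed.
#' @return A `prototype_maps` (unit-norm, zero-mean rows) with attributes
#'   `assignment` (cluster index per input map) and `explained_variance`
#'   (fraction in \[0, 1\] of map variance captured at the clustered samples).
#' @export
modified_kmeans <- function(maps, k, n_restarts = 50, max_iter = 100,
                            tol = 1e-6, seed = 1) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k > n) stop("`k` cannot exceed the number of maps", call. = FALSE)
  x <- normalize_maps(maps)   # zero-mean unit-norm rows; errors on all-zero maps

  fit_once <- function() {
    proto <- x[sample.int(n, k), , drop = FALSE]
    ev_old <- -Inf
    assign <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      corr2 <- (x %*% t(proto))^2
      assign <- max.col(corr2, ties.method = "first")
      for (j in seq_len(k)) {
        idx <- which(assign == j)
        if (!length(idx)) {            # dead cluster: reseed from worst-fit map
          worst <- which.min(corr2[cbind(seq_len(n), assign)])
          idx <- worst
          assign[worst] <- j
        }
        s <- crossprod(x[idx, , drop = FALSE])
        proto[j, ] <- eigen(s, symmetric = TRUE)$vectors[, 1L]
      }
      proto <- normalize_maps(proto)
      ev <- mean(((x %*% t(proto))^2)[cbind(seq_len(n), assign)])
      if (is.finite(ev_old) && abs(ev - ev_old) <= tol * max(ev_old, .Machine$double.eps)) {
        ev_old <- ev
        break
      }
      ev_old <- ev
    }
    list(proto = proto, assign = assign, ev = ev_old)
  }

  best <- with_seed(seed, {
    out <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- fit_once()
      if (is.null(out) || fit$ev > out$ev) out <- fit
    }
    out
  })
  pm <- prototype_maps(best$proto, gev_total = 100 * best$ev)
  attr(pm, "assignment") <- best$assign
  attr(pm, "explained_variance") <- best$ev
  pm
}

#' Choose the number of microstate classes
#'
#' Fits [modified_kmeans()] for each candidate k and computes two
#' model-order criteria: the cross-validation criterion
#' CV(k) = sigma2_resid * ((n_ch - 1) / (n_ch - 1 - k))^2 (to minimize) and
#' the Krzanowski-Lai index from successive within-cluster dispersions (to
#' maximize; defined for interior k only). Selection rule: among candidates
#' whose CV is within `cv_tolerance` of the CV minimum, pick the one with
#' the largest KL; if KL is undefined for all of them (e.g. structureless
#' data), fall back to the smallest k in that set.
#'
#' @param maps Matrix of maps x channels.
#' @param k_range Integer vector of at least 3 consecutive candidate k.
#' @param seed RNG seed.
#' @param cv_tolerance Relative CV slack defining the candidate set (default 0.05).
#' @param ... Passed to [modified_kmeans()] (e.g. `n_restarts`).
#' @return List with `k` (selected), `criteria` (data.frame of k, cv, kl,
#'   explained_variance), and `fits` (the fitted `prototype_maps` per k).
#' @export
choose_k <- function(maps, k_range = 2:8, seed = 1, cv_tolerance = 0.05, ...) {
  maps <- as.matrix(maps)
  nch <- ncol(maps)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) {
    stop("`k_range` needs at least 3 values for the Krzanowski-Lai index", call. = FALSE)
  }
  if (min(k_range) < 1L || max(k_range) > nch - 1L) {
    stop("`k_range` must lie within [1, n_channels - 1]", call. = FALSE)
  }
  x <- normalize_maps(maps)
  n <- nrow(x)
  fits <- list()
  cv <- kl <- ev <- rep(NA_real_, length(k_range))
  w <- rep(NA_real_, length(k_range))     # within-cluster dispersion
  seeds <- derive_seeds(seed, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- modified_kmeans(x, k, seed = seeds[i], ...)
    fits[[as.character(k)]] <- fit
    evk <- attr(fit, "explained_variance")
    ev[i] <- evk
    # residual variance per sample/channel: rows are unit-norm so each map
    # carries total squared amplitude 1 over nch channels
    sigma2 <- n * (1 - evk) / (n * (nch - 1))
    cv[i] <- sigma2 * ((nch - 1) / (nch - 1 - k))^2
    w[i] <- n * (1 - evk)
  }
  p <- nch
  for (i in seq_along(k_range)) {
    if (i == 1L || i == length(k_range)) next
    diff_k <- (k_range[i - 1L])^(2 / p) * w[i - 1L] - (k_range[i])^(2 / p) * w[i]
    diff_k1 <- (k_range[i])^(2 / p) * w[i] - (k_range[i + 1L])^(2 / p) * w[i + 1L]
    kl[i] <- abs(diff_k) / max(abs(diff_k1), .Machine$double.eps)
  }
  cand <- which(cv <= min(cv) * (1 + cv_tolerance))
  sel <- if (any(is.finite(kl[cand]))) cand[which.max(kl[cand])] else cand[1L]
  list(k = k_range[sel],
       criteria = data.frame(k = k_range, cv = cv, kl = kl,
                             explained_variance = ev),
       fits = fits)
}

# Spatial correlation of every sample topography with every prototype.
# Columns of the recording are average-referenced first, so the Pearson
# correlation across channels reduces to a normalized dot product.
sample_correlations <- function(rec, prototypes) {
  p <- prototypes$maps
  if (ncol(p) != n_channels(rec)) {
    stop("channel count mismatch between recording and prototypes", call. = FALSE)
  }
  xc <- sweep(rec$data, 2L, colMeans(rec$data))
  nrm <- sqrt(colSums(xc^2))
  a <- p %*% xc                       # K x T dot products
  corr <- sweep(a, 2L, pmax(nrm, .Machine$double.xmin), "/")
  list(corr = corr, norms = nrm)
}

#' Back-fit prototypes to a recording
#'
#' Labels every sample with the prototype of maximal absolute spatial
#' correlation (polarity ignored). Ties break to the lowest class index;
#' zero-GFP samples inherit the previous label (class 1 at the start).
#'
#' @param rec An [eeg_recording()].
#' @param prototypes A `prototype_maps`.
#' @return A `microstate_sequence` (integer labels 1..K plus class names).
#' @export
backfit <- function(rec, prototypes) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(prototypes, "prototype_maps"))
  sc <- sample_correlations(rec, prototypes)
  labels <- max.col(t(sc$corr^2), ties.method = "first")
  zero <- sc$norms < .Machine$double.eps * 100
  if (any(zero)) {
    for (t in which(zero)) labels[t] <- if (t == 1L) 1L else labels[t - 1L]
  }
  microstate_sequence(labels, rec$sampling_rate, prototypes$labels)
}

#' Microstate label sequence
#'
#' @param labels Integer vector of class indices (1..K).
#' @param sampling_rate Hz.
#' @param class_names Character names of the K classes.
#' @return A `microstate_sequence`.
#' @export
microstate_sequence <- function(labels, sampling_rate, class_names) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > length(class_names))) {
    stop("labels outside 1..K", call. = FALSE)
  }
  structure(list(labels = labels, sampling_rate = sampling_rate,
                 class_names = as.character(class_names)),
            class = "microstate_sequence")
}

#' @export
print.microstate_sequence <- function(x, ...) {
  r <- rle(x$labels)
  cat(sprintf("<microstate_sequence> %d samples @ %g Hz, %d classes, %d runs\n",
              length(x$labels), x$sampling_rate, length(x$class_names),
              length(r$lengths)))
  invisible(x)
}

#' Temporal smoothing by minimum-duration rejection
#'
#' Dissolves every maximal run shorter than `min_duration_ms`: the run's
#' samples are handed to the neighboring runs' labels, each sample going to
#' the neighbor whose prototype correlates more strongly (in absolute
#' value) with that sample's topography, under the constraint that the run
#' splits contiguously (a left part joining the left neighbor and a right
#' part the right neighbor, with the split placed where the summed absolute
#' correlations are maximal). Repeats until every run meets the minimum.
#'
#' @param seq A `microstate_sequence` from [backfit()].
#' @param rec The recording the sequence was fitted on.
#' @param prototypes The `prototype_maps` used for back-fitting.
#' @param min_duration_ms Minimum admissible run duration (default 30 ms).
#' @return A smoothed `microstate_sequence`.
#' @export
smooth_sequence <- function(seq, rec, prototypes, min_duration_ms = 30) {
  stopifnot(inherits(seq, "microstate_sequence"))
  if (length(seq$labels) != n_samples(rec)) {
    stop("sequence and recording lengths differ", call. = FALSE)
  }
  fs <- seq$sampling_rate
  if (min_duration_ms < 1000 / fs) {
    stop("`min_duration_ms` must be at least one sample period", call. = FALSE)
  }
  min_samples <- ceiling(min_duration_ms * fs / 1000)
  absc <- abs(sample_correlations(rec, prototypes)$corr)   # K x T
  labels <- seq$labels

  repeat {
    r <- rle(labels)
    if (!length(r$lengths) || all(r$lengths >= min_samples) ||
        length(r$lengths) == 1L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$lengths < min_samples)
    i <- short[which.min(r$lengths[short])]    # dissolve the shortest run first
    left <- if (i > 1L) r$values[i - 1L] else NA_integer_
    right <- if (i < length(r$values)) r$values[i + 1L] else NA_integer_
    span <- starts[i]:ends[i]
    if (is.na(left)) {
      labels[span] <- right
    } else if (is.na(right) || left == right) {
      labels[span] <- left
    } else {
      cl <- absc[left, span]
      cr <- absc[right, span]
      len <- length(span)
      scores <- vapply(0:len, function(s)
        sum(cl[seq_len(s)]) + sum(cr[seq_len(len - s) + s]), 0)
      s <- which.max(scores) - 1L
      labels[span] <- c(rep(left, s), rep(right, len - s))
    }
  }
  microstate_sequence(labels, fs, seq$class_names)
}

#' Temporal features of a microstate sequence
#'
#' Per class: mean duration (ms) of its uninterrupted runs, occurrence
#' (runs per second), coverage (% of samples), and GEV (% of GFP-weighted
#' signal variance explained by the class), with
#' gev_k = 100 * sum over labeled samples of (GFP * corr)^2 / sum GFP^2.
#' The identity coverage/100 = occurrence * mean_duration/1000 holds by
#' construction. A class absent from the sequence reports zeros with a
#' warning.
#'
#' @param seq A smoothed `microstate_sequence`.
#' @param rec The source [eeg_recording()].
#' @param prototypes The `prototype_maps` the sequence refers to.
#' @return A `temporal_features` data.frame (class, mean_duration,
#'   occurrence, coverage, gev) with attribute `gev_total`.
#' @export
temporal_features <- function(seq, rec, prototypes) {
  stopifnot(inherits(seq, "microstate_sequence"))
  if (length(seq$labels) != n_samples(rec)) {
    stop("sequence and recording lengths differ", call. = FALSE)
  }
  fs <- seq$sampling_rate
  k <- length(seq$class_names)
  total_s <- length(seq$labels) / fs
  r <- rle(seq$labels)
  sc <- sample_correlations(rec, prototypes)
  nch <- n_channels(rec)
  gfp_t <- sc$norms / sqrt(nch)                  # GFP from the same centering
  num <- (gfp_t * sc$corr[cbind(seq$labels, seq_along(seq$labels))])^2
  den <- sum(gfp_t^2)
  out <- data.frame(class = seq$class_names,
                    mean_duration = 0, occurrence = 0, coverage = 0, gev = 0,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    runs <- r$lengths[r$values == j]
    if (!length(runs)) {
      warning(sprintf("class %s absent from sequence; features reported as 0",
                      seq$class_names[j]))
      next
    }
    out$mean_duration[j] <- mean(runs) * 1000 / fs
    out$occurrence[j] <- length(runs) / total_s
    out$coverage[j] <- 100 * sum(runs) / length(seq$labels)
    out$gev[j] <- 100 * sum(num[seq$labels == j]) / den
  }
  structure(out, class = c("temporal_features", "data.frame"),
            gev_total = sum(out$gev))
}

#' Canonical microstate class templates
#'
#' Qualitative template topographies for the four canonical resting-state
#' classes over the 19-channel 10-20 montage, built from the electrode
#' coordinates: A and B are left/right fronto-posterior diagonal gradients,
#' C is an anterior-posterior (vertical) gradient, D a fronto-central
#' focal pattern. These are synthetic stand-ins encoding the standard
#' qualitative layout, used only to give recovered prototypes stable A-D
#' names via [order_to_canonical()].
#'
#' @param n_channels Channel count (templates are defined for 19).
#' @return A `prototype_maps` with labels A-D.
#' @export
canonical_templates <- function(n_channels = 19L) {
  pos <- channel_positions(n_channels)
  x <- pos[, "x"]
  y <- pos[, "y"]
  m <- rbind(
    A = -x / sqrt(2) + y / sqrt(2),
    B = x / sqrt(2) + y / sqrt(2),
    C = y,
    D = exp(-((x)^2 + (y - 0.4)^2) / 0.35)
  )
  prototype_maps(normalize_maps(m), labels = c("A", "B", "C", "D"))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Match prototypes to canonical templates
#'
#' Finds the one-to-one assignment of prototypes to template classes that
#' maximizes the total absolute spatial correlation (exhaustive search over
#' the K! permutations; K is small). Also reports the sign each prototype
#' would need to agree with its template's polarity.
#'
#' @param prototypes A `prototype_maps`.
#' @param templates A `prototype_maps` of equal K and channel count
#'   (default [canonical_templates()]).
#' @return List with `permutation` (template class index for each
#'   prototype... `permutation[j]` is the prototype assigned to template
#'   class j), `signs`, `correlations` (absolute, per matched pair),
#'   `total`, and `ordered` (the re-ordered, sign-aligned `prototype_maps`
#'   carrying the template labels).
#' @export
order_to_canonical <- function(prototypes, templates = canonical_templates()) {
  stopifnot(inherits(prototypes, "prototype_maps"),
            inherits(templates, "prototype_maps"))
  p <- normalize_maps(prototypes$maps)
  tm <- normalize_maps(templates$maps)
  k <- nrow(p)
  if (nrow(tm) != k || ncol(tm) != ncol(p)) {
    stop("prototype and template dimensions must match", call. = FALSE)
  }
  cmat <- tm %*% t(p)                      # templates x prototypes correlations
  perms <- all_permutations(k)
  scores <- vapply(perms, function(pr) sum(abs(cmat[cbind(seq_len(k), pr)])), 0)
  best <- perms[[which.max(scores)]]
  corr <- cmat[cbind(seq_len(k), best)]
  signs <- ifelse(corr >= 0, 1, -1)
  ordered <- prototype_maps(p[best, , drop = FALSE] * signs,
                            labels = templates$labels,
                            gev_total = prototypes$gev_total)
  list(permutation = best, signs = signs, correlations = abs(corr),
       total = max(scores), ordered = ordered)
}

#' Two-level group prototype maps
#'
#' Aggregates subjects of one group: per subject, GFP-peak maps are
#' clustered into subject-level prototypes; the pooled subject prototypes
#' are then clustered again at the group level.
#'
#' @param recordings List of [eeg_recording()]s belonging to one group.
#' @param k Number of classes (default 4).
#' @param n_maps Peak maps per subject (default 2000).
#' @param min_separation_ms,sd_reject_factor Passed to [select_gfp_peaks()].
#' @param n_restarts Restarts for both clustering levels.
#' @param seed RNG seed.
#' @return List with `group` (a `prototype_maps`) and `subject` (list of
#'   per-subject `prototype_maps`).
#' @export
group_prototypes <- function(recordings, k = 4, n_maps = 2000,
                             min_separation_ms = 10, sd_reject_factor = 2,
                             n_restarts = 50, seed = 1) {
  stopifnot(length(recordings) >= 1L)
  seeds <- derive_seeds(seed, length(recordings) + 1L)
  subject <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    g <- gfp(recordings[[i]])
    pk <- select_gfp_peaks(g, min_separation_ms, sd_reject_factor,
                           n_maps, seed = seeds[i])
    subject[[i]] <- modified_kmeans(peak_maps(recordings[[i]], pk), k,
                                    n_restarts = n_restarts, seed = seeds[i])
  }
  pooled <- do.call(rbind, lapply(subject, function(s) s$maps))
  group <- modified_kmeans(pooled, k, n_restarts = n_restarts,
                           seed = seeds[length(seeds)])
  list(group = group, subject = subject)
}
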