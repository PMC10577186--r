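test_that("GFP equals the channel-wise population SD", {
  # closed forms
  rec <- eeg_recording(rbind(c(1, 2, 0), c(1, -2, 0)), 100)
  g <- gfp(rec)
  expect_equal(g$values, c(0, 2, 0))
  # brute-force formula oracle on a random 19-channel sample
  set.seed(41)
  data <- matrix(rnorm(19 * 7), 19, 7)
  oracle <- vapply(1:7, function(t) {
    u <- data[, t]
    sqrt(sum((u - mean(u))^2) / 19)
  }, 0)
  expect_equal(gfp(eeg_recording(data, 100))$values, oracle, tolerance = 1e-12)
})

test_that("GFP peak selection returns thinned local maxima and drops outliers", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 5 * t)
  rec <- two_channel_rec(s, fs)              # GFP = |sin(2*pi*5t)|
  g <- gfp(rec)
  # direct-scan oracle for strict local maxima
  v <- g$values
  scan <- which(v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
                  v[2:(length(v) - 1)] > v[3:length(v)]) + 1L
  pk <- suppressWarnings(
    select_gfp_peaks(g, min_separation_ms = 10, sd_reject_factor = Inf,
                     n_maps = 10000, seed = 1))
  expect_true(all(pk %in% scan))
  expect_equal(length(pk), 600, tolerance = 0.02)
  expect_true(all(diff(pk) >= 1))

  # an enormous spike is rejected at the mean + 2 SD rule
  v2 <- rec$data
  v2[1, 3000] <- 50
  g2 <- gfp(eeg_recording(v2, fs))
  pk2 <- suppressWarnings(
    select_gfp_peaks(g2, sd_reject_factor = 2, n_maps = 10000, seed = 1))
  expect_false(3000L %in% pk2)

  # requesting more maps than peaks keeps all and warns
  expect_warning(pk3 <- select_gfp_peaks(g, n_maps = 10000, seed = 1),
                 "using all")
  # subsampling is deterministic in the seed
  a <- select_gfp_peaks(g, n_maps = 100, seed = 9)
  expect_identical(a, select_gfp_peaks(g, n_maps = 100, seed = 9))
})

test_that("modified k-means is polarity-invariant and recovers planted structure", {
  # exact recovery from sign-flipped copies of two orthogonal prototypes
  p <- normalize <- function(x) (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  p1 <- normalize(c(rep(1, 5), rep(-1, 5)))
  p2 <- normalize(c(rep(c(1, -1), 5)))
  maps <- rbind(p1, p1, -p1, p1, p2, -p2, p2, -p2)
  km <- modified_kmeans(maps, 2, n_restarts = 5, seed = 1)
  cors <- abs(km$maps %*% cbind(p1, p2))
  expect_equal(unname(apply(cors, 2, max)), c(1, 1), tolerance = 1e-8)

  # k = 1 equals the first principal axis (eigen oracle), up to sign
  set.seed(42)
  m <- matrix(rnorm(50 * 10), 50, 10)
  m <- m - rowMeans(m)
  m <- m / sqrt(rowSums(m^2))
  km1 <- modified_kmeans(m, 1, n_restarts = 3, seed = 2)
  pc1 <- eigen(crossprod(m), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(km1$maps[1, ] * pc1)), 1, tolerance = 1e-6)

  # determinism
  expect_identical(modified_kmeans(m, 3, n_restarts = 5, seed = 7)$maps,
                   modified_kmeans(m, 3, n_restarts = 5, seed = 7)$maps)
  expect_error(modified_kmeans(m, 51, seed = 1), "cannot exceed")
  expect_error(modified_kmeans(matrix(0, 5, 4), 2, seed = 1), "all-zero")
})

test_that("planted prototypes are recovered from synthetic GFP-peak maps", {
  cfg <- simulation_config(duration = 60, noise_sd = 0.2, seed = 4)
  sim <- simulate_recording(cfg)
  pk <- select_gfp_peaks(gfp(sim$recording), n_maps = 1000, seed = 2)
  km <- modified_kmeans(peak_maps(sim$recording, pk), 4, n_restarts = 20, seed = 5)
  m <- order_to_canonical(km, templates = as_prototypes(sim$truth$prototypes))
  expect_gte(min(m$correlations), 0.95)
})

test_that("model-order selection finds planted k and degrades gracefully on noise", {
  protos <- make_prototype_maps(19, 4, seed = 2, max_corr = 0.3)
  set.seed(43)
  idx <- sample(1:4, 600, replace = TRUE)
  maps <- protos[idx, ] * sample(c(-1, 1), 600, replace = TRUE) +
    matrix(rnorm(600 * 19, sd = 0.2 / sqrt(19)), 600, 19)
  maps <- maps - rowMeans(maps)
  ck <- choose_k(maps, 2:8, seed = 7, n_restarts = 10)
  expect_identical(ck$k, 4L)
  expect_identical(nrow(ck$criteria), 7L)
  expect_true(all(is.finite(ck$criteria$cv)))

  # structureless maps: selection falls back inside the CV-tolerance set
  # (regression-pinned behavior on a fixed seed)
  set.seed(44)
  noise <- matrix(rnorm(400 * 19), 400, 19)
  ckn <- choose_k(noise, 2:6, seed = 3, n_restarts = 5)
  cand <- which(ckn$criteria$cv <= min(ckn$criteria$cv) * 1.05)
  expect_true(ckn$k %in% ckn$criteria$k[cand])

  expect_error(choose_k(maps, c(3, 4), seed = 1), "at least 3")
})

test_that("back-fitting recovers tiled labels and ignores polarity", {
  protos <- make_prototype_maps(19, 4, seed = 6)
  labels <- rep(rep(1:4, 5), each = 10)
  rec <- tiled_recording(protos, labels)
  pm <- as_prototypes(protos)
  expect_identical(backfit(rec, pm)$labels, labels)
  neg <- eeg_recording(-rec$data, rec$sampling_rate)
  expect_identical(backfit(neg, pm)$labels, labels)
  wrong <- as_prototypes(protos[, 1:10])
  expect_error(backfit(rec, wrong), "channel count mismatch")
})

test_that("smoothing dissolves short runs by spatial correlation and terminates", {
  protos <- make_prototype_maps(19, 2, seed = 1)
  pm <- as_prototypes(protos, c("A", "B"))
  # lone B sample whose topography is actually A-like: absorbed into A
  labels <- c(1, 1, 1, 2, 1, 1, 1, 1)
  data <- t(protos[labels, ]) * 5
  data[, 4] <- protos[1, ] * 5
  rec <- eeg_recording(data, 100)
  sm <- smooth_sequence(microstate_sequence(labels, 100, c("A", "B")),
                        rec, pm, 30)
  expect_identical(sm$labels, rep(1L, 8))

  # fixed point: all runs already >= 3 samples
  ok <- rep(c(1L, 2L), each = 5)
  rec2 <- tiled_recording(protos, ok)
  sm2 <- smooth_sequence(microstate_sequence(ok, 100, c("A", "B")), rec2, pm, 30)
  expect_identical(sm2$labels, ok)

  # alternating single samples converge to admissible runs
  alt <- rep(c(1L, 2L), 20)
  rec3 <- tiled_recording(protos, alt)
  sm3 <- smooth_sequence(microstate_sequence(alt, 100, c("A", "B")), rec3, pm, 30)
  expect_gte(min(rle(sm3$labels)$lengths), 3)
  expect_error(smooth_sequence(microstate_sequence(alt, 100, c("A", "B")),
                               tiled_recording(protos, ok), pm, 30),
               "lengths differ")
})

test_that("temporal features match hand computation and their identities", {
  protos <- make_prototype_maps(19, 2, seed = 3)
  pm <- as_prototypes(protos, c("A", "B"))
  labels <- c(rep(1L, 5), rep(2L, 5), rep(1L, 10))
  rec <- tiled_recording(protos, labels, amp = seq(1, 3, length.out = 20))
  tf <- temporal_features(microstate_sequence(labels, 100, c("A", "B")), rec, pm)
  expect_equal(tf$coverage, c(75, 25))
  expect_equal(tf$mean_duration, c(75, 50))
  expect_equal(tf$occurrence, c(10, 5))
  # consistency identity and full coverage
  expect_equal(tf$coverage / 100, tf$occurrence * tf$mean_duration / 1000,
               tolerance = 1e-12)
  expect_equal(sum(tf$coverage), 100, tolerance = 1e-9)
  # prototype-tiled recording is perfectly explained
  expect_equal(attr(tf, "gev_total"), 100, tolerance = 1e-9)

  # single-class minute-long sequence
  one <- microstate_sequence(rep(1L, 6000), 100, c("A", "B"))
  rec1 <- tiled_recording(protos, rep(1L, 6000))
  expect_warning(tf1 <- temporal_features(one, rec1, pm), "absent")
  expect_equal(tf1$coverage[1], 100)
  expect_equal(tf1$occurrence[1], 1 / 60)
  expect_equal(tf1$mean_duration[1], 60000)
  expect_equal(tf1$mean_duration[2], 0)
})

test_that("GEV is invariant to recording scale and prototype sign", {
  cfg <- simulation_config(duration = 10, noise_sd = 0.3, seed = 8)
  sim <- simulate_recording(cfg)
  pm <- as_prototypes(sim$truth$prototypes)
  sq <- smooth_sequence(backfit(sim$recording, pm), sim$recording, pm, 30)
  tf <- temporal_features(sq, sim$recording, pm)
  scaled <- eeg_recording(sim$recording$data * 12.3, 100)
  tf_s <- temporal_features(sq, scaled, pm)
  expect_equal(attr(tf_s, "gev_total"), attr(tf, "gev_total"), tolerance = 1e-9)
  flipped <- as_prototypes(sim$truth$prototypes * c(1, -1, 1, -1))
  tf_f <- temporal_features(sq, sim$recording, flipped)
  expect_equal(attr(tf_f, "gev_total"), attr(tf, "gev_total"), tolerance = 1e-9)
})

test_that("canonical ordering matches brute force and reports signs", {
  protos <- make_prototype_maps(19, 4, seed = 9)
  pm <- as_prototypes(protos)
  # permuted copy of the prototypes: recovered exactly
  perm <- c(3L, 1L, 4L, 2L)
  shuffled <- as_prototypes(protos[perm, ])
  m <- order_to_canonical(shuffled, templates = pm)
  expect_identical(m$permutation, order(perm))
  expect_equal(m$correlations, rep(1, 4), tolerance = 1e-10)
  # sign flips: same permutation, flipped signs reported
  flipped <- as_prototypes(protos[perm, ] * c(-1, 1, -1, 1))
  mf <- order_to_canonical(flipped, templates = pm)
  expect_identical(mf$permutation, m$permutation)
  expect_identical(sum(mf$signs < 0), 2L)
  expect_equal(unname(mf$ordered$maps), unname(protos), tolerance = 1e-10)

  # random prototypes vs templates: equals exhaustive enumeration via an
  # independently generated permutation list
  rand <- as_prototypes(make_prototype_maps(19, 4, seed = 10))
  mr <- order_to_canonical(rand, templates = canonical_templates())
  cmat <- canonical_templates()$maps %*% t(rand$maps)
  best <- -Inf
  for (p in perms_by_insertion(4)) {
    sc <- sum(abs(cmat[cbind(1:4, p)]))
    if (sc > best) best <- sc
  }
  expect_equal(mr$total, best, tolerance = 1e-12)
  expect_error(order_to_canonical(as_prototypes(protos[1:3, ])), "must match")
})

test_that("segmentation is polarity-invariant end to end", {
  cfg <- simulation_config(duration = 20, noise_sd = 0.3, seed = 12)
  sim <- simulate_recording(cfg)
  pm <- as_prototypes(sim$truth$prototypes)
  run <- function(rec) {
    smooth_sequence(backfit(rec, pm), rec, pm, 30)$labels
  }
  neg <- eeg_recording(-sim$recording$data, 100)
  expect_identical(run(sim$recording), run(neg))
})

test_that("estimated duration rises monotonically with the planted duration", {
  est <- vapply(c(60, 90, 120), function(d) {
    cfg <- simulation_config(duration = 40, noise_sd = 0.3, seed = 13,
                             mean_duration_per_state = c(80, 80, d, 80))
    sim <- simulate_recording(cfg)
    pm <- as_prototypes(sim$truth$prototypes)
    sq <- smooth_sequence(backfit(sim$recording, pm), sim$recording, pm, 30)
    temporal_features(sq, sim$recording, pm)$mean_duration[3]
  }, 0)
  expect_true(all(diff(est) > 0))
})
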