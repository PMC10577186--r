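test_that("prototype maps satisfy their geometric contract", {
  maps <- make_prototype_maps(19, 4, seed = 1)
  expect_identical(dim(maps), c(4L, 19L))
  expect_lt(max(abs(rowMeans(maps))), 1e-10)
  expect_equal(unname(sqrt(rowSums(maps^2))), rep(1, 4), tolerance = 1e-10)
  cors <- maps %*% t(maps)
  expect_true(all(abs(cors[upper.tri(cors)]) <= 0.7))
  # determinism
  expect_identical(maps, make_prototype_maps(19, 4, seed = 1))
  expect_false(identical(maps, make_prototype_maps(19, 4, seed = 2)))
})

test_that("two-channel zero-mean map is antisymmetric and k is capped", {
  m <- make_prototype_maps(2, 1, seed = 0)
  expect_equal(m[1, 1], -m[1, 2])
  expect_equal(sum(m^2), 1)
  expect_error(make_prototype_maps(19, 19, seed = 1), "n_channels - 1")
  expect_error(make_prototype_maps(5, 5, seed = 1), "n_channels - 1")
})

test_that("simulation_config validates its invariants", {
  cfg <- simulation_config()
  expect_equal(rowSums(cfg$transition_matrix), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diag(cfg$transition_matrix) == 0))
  expect_error(simulation_config(duration = 0), "duration")
  expect_error(simulation_config(noise_sd = -0.1), "noise_sd")
  expect_error(simulation_config(mean_duration_per_state = 25), "30 ms")
  bad_tm <- matrix(0.25, 4, 4)
  expect_error(simulation_config(transition_matrix = bad_tm), "diagonal")
  bad_tm2 <- matrix(c(0, 1, 1, 0, 1, 0, 1, 1, 0), 3, 3)
  expect_error(simulation_config(k_states = 3, transition_matrix = bad_tm2,
                                 mean_duration_per_state = 80),
               "sum to 1")
})

test_that("recordings are deterministic functions of their config", {
  cfg <- simulation_config(duration = 5, seed = 42)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$label_sequence$labels, b$truth$label_sequence$labels)
})

test_that("ground truth matches its structural invariants", {
  cfg <- simulation_config(duration = 10, seed = 3)
  sim <- simulate_recording(cfg)
  tr <- sim$truth
  expect_length(tr$label_sequence$labels, 10 * 100)
  expect_lt(max(abs(rowMeans(tr$prototypes))), 1e-10)
  expect_equal(unname(sqrt(rowSums(tr$prototypes^2))), rep(1, 4),
               tolerance = 1e-10)
  expect_equal(tr$planted_dar, 3.7)
  expect_equal(sum(tr$planted_features$coverage), 100, tolerance = 1e-9)
})

test_that("noiseless back-fit against true prototypes reproduces the planted labels", {
  cfg <- simulation_config(duration = 60, noise_sd = 0, seed = 1)
  sim <- simulate_recording(cfg)
  seq_fit <- backfit(sim$recording, as_prototypes(sim$truth$prototypes))
  agreement <- mean(seq_fit$labels == sim$truth$label_sequence$labels)
  expect_gte(agreement, 0.99)
})

test_that("realized mean durations track the planted targets at noise 0.5", {
  cfg <- simulation_config(duration = 60, noise_sd = 0.5, seed = 2,
                           mean_duration_per_state = c(60, 80, 100, 120))
  sim <- simulate_recording(cfg)
  realized <- sim$truth$planted_features$mean_duration
  expect_true(all(abs(realized - c(60, 80, 100, 120)) /
                    c(60, 80, 100, 120) < 0.15))
})

test_that("cohorts have balanced groups, derived seeds, and hard size floor", {
  cfgA <- simulation_config(duration = 3, seed = 1)
  cfgB <- simulation_config(duration = 3, seed = 1)
  cohort <- simulate_cohort(3, cfgA, cfgB, seed = 7)
  expect_length(cohort, 6L)
  expect_identical(as.integer(table(vapply(cohort, `[[`, "", "group"))),
                   c(3L, 3L))
  cohort2 <- simulate_cohort(3, cfgA, cfgB, seed = 7)
  expect_identical(cohort[[1]]$recording$data, cohort2[[1]]$recording$data)
  expect_false(identical(cohort[[1]]$recording$data,
                         cohort[[3]]$recording$data))
  expect_error(simulate_cohort(1, cfgA, cfgB, seed = 1), ">= 2")
})

test_that("measured DAR increases strictly with the planted delta target", {
  dars <- vapply(c(1, 3.7, 8), function(d) {
    cfg <- simulation_config(duration = 30, seed = 9,
                             band_power_targets = c(delta = d, alpha = 1))
    spectral_summary(simulate_recording(cfg)$recording)$dar
  }, 0)
  expect_true(all(diff(dars) > 0))
})

test_that("null cohorts give nominal Welch rejection rates on planted features", {
  # identical configs in both groups: group differences in the generator's
  # per-recording temporal features are pure sampling noise
  cfg <- simulation_config(duration = 5, seed = 1)
  n_rep <- 200
  seeds <- derive_seeds(20240915, n_rep)
  reject <- matrix(NA, n_rep, 3)
  for (r in seq_len(n_rep)) {
    cohort <- simulate_cohort(4, cfg, cfg, seed = seeds[r])
    grp <- vapply(cohort, `[[`, "", "group")
    feats <- t(vapply(cohort, function(e)
      c(e$truth$planted_features$mean_duration[2],
        e$truth$planted_features$occurrence[3],
        e$truth$planted_features$coverage[4]), numeric(3)))
    for (j in 1:3) {
      reject[r, j] <- welch_t(feats[grp == "AW", j],
                              feats[grp == "DOC", j])$p_value < 0.05
    }
  }
  rate <- mean(reject)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("a planted duration increase is recovered with the right direction", {
  cfgA <- simulation_config(duration = 40, seed = 1,
                            mean_duration_per_state = c(80, 80, 70, 80))
  cfgB <- simulation_config(duration = 40, seed = 1,
                            mean_duration_per_state = c(80, 80, 110, 80))
  cohort <- simulate_cohort(6, cfgA, cfgB, seed = 31)
  est <- vapply(cohort, function(e) {
    pm <- as_prototypes(e$truth$prototypes)
    sq <- smooth_sequence(backfit(e$recording, pm), e$recording, pm, 30)
    temporal_features(sq, e$recording, pm)$mean_duration[3]
  }, 0)
  grp <- vapply(cohort, `[[`, "", "group")
  res <- welch_t(est[grp == "AW"], est[grp == "DOC"])
  expect_lt(res$statistic, 0)       # planted longer durations in group B
  expect_lt(res$p_value, 0.05)
})
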