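test_that("generate_pointsets returns the fixed worked-example partitions", {
  a <- generate_pointsets("disjoint_a")
  expect_equal(a$diamonds$values, c(0.5, 0.8, 0.6, 0.5, 0.4, 1))
  expect_equal(a$circles$values, c(0.4, 0.6, 0.7, 0.5, 0.8, 0.6))
  b <- generate_pointsets("disjoint_b")
  expect_equal(b$diamonds$values, c(0.5, 0.8, 0.6, 0.4, 0.5, 0.4))
  expect_equal(b$circles$values, c(0.6, 0.7, 0.5, 1, 0.8, 0.6))
  expect_error(generate_pointsets("nope"))
})

test_that("random point-set kinds are seeded and deterministic", {
  for (kind in c("overlapped", "random_disjoint")) {
    p1 <- generate_pointsets(kind, seed = 9)
    p2 <- generate_pointsets(kind, seed = 9)
    p3 <- generate_pointsets(kind, seed = 10)
    expect_identical(p1$diamonds$values, p2$diamonds$values)
    expect_false(identical(p1$diamonds$values, p3$diamonds$values))
    expect_true(all(p1$circles$values >= 0 & p1$circles$values <= 1))
  }
})

test_that("config validation rejects impossible worlds", {
  expect_error(gait_sim_config(noise_sd = -1), class = "fg_invalid_input")
  expect_error(gait_sim_config(stair_shared_fraction = 1.5),
               class = "fg_invalid_input")
  expect_error(gait_sim_config(n_subjects = 0), class = "fg_invalid_input")
  expect_error(generate_recording(small_config(), 99, "walking"),
               class = "fg_invalid_input")
})

test_that("generated recordings have the stated shape and determinism", {
  cfg <- small_config()
  rec <- generate_recording(cfg, 1, "stair_up")
  expect_identical(ncol(rec$channels), 36L)
  expect_identical(nrow(rec$channels),
                   as.integer(cfg$duration_s * cfg$sampling_rate_hz))
  expect_identical(rec$channels,
                   generate_recording(cfg, 1, "stair_up")$channels)

  cfg0 <- small_config(noise_sd = 0, subject_variation_sd = 0)
  r1 <- generate_recording(cfg0, 1, "walking")
  r2 <- generate_recording(cfg0, 1, "walking")
  expect_identical(r1$channels, r2$channels)
  # without variation or noise, subjects differ only by their start offset
  r3 <- generate_recording(cfg0, 2, "walking")
  expect_false(identical(r1$channels, r3$channels))
})

test_that("dominant spectral peak sits at the stride frequency", {
  cfg <- gait_sim_config(noise_sd = 0, subject_variation_sd = 0)
  for (b in c("walking", "stair_up")) {
    x <- generate_recording(cfg, 1, b)$channels[, "waist_accelerometer_z"]
    n <- length(x)
    spec <- Mod(stats::fft(x))[2:(n / 2)]
    freq <- (seq_len(n / 2 - 1)) * cfg$sampling_rate_hz / n
    expect_equal(freq[which.max(spec)], cfg$stride_frequency_hz[[b]])
  }
})

test_that("generate_cohort returns complete, reproducible profiles", {
  cfg <- gait_sim_config()  # defaults: 20 subjects
  co <- generate_cohort(cfg)
  expect_length(co, 20)
  expect_true(all(vapply(co, inherits, TRUE, "behavior_profile")))
  expect_identical(
    co[[7]]$recordings$stair_down$channels,
    generate_recording(cfg, 7, "stair_down")$channels)
})

test_that("more noise or subject variation weakly lowers cross-person similarity", {
  mean_cross <- function(cfg) {
    co <- generate_cohort(cfg)
    mean(vapply(c("walking", "stair_up", "stair_down"), function(b) {
      S <- person_matrix(co, b)
      mean(S[upper.tri(S)])
    }, numeric(1)))
  }
  noise <- vapply(c(0.02, 0.1, 0.3), function(ns) {
    mean_cross(small_config(noise_sd = ns))
  }, numeric(1))
  expect_true(all(diff(noise) <= 0))
  subj <- vapply(c(0.02, 0.1, 0.3), function(sv) {
    mean_cross(small_config(subject_variation_sd = sv))
  }, numeric(1))
  expect_true(all(diff(subj) <= 0))
})

test_that("the stair_shared_fraction knob is detectable through the pipeline", {
  sims <- function(sf) {
    cfg <- gait_sim_config(n_subjects = 1, noise_sd = 0,
                           subject_variation_sd = 0,
                           stair_shared_fraction = sf)
    pr <- generate_cohort(cfg)[[1]]
    c(w_su = behavior_similarity(pr, "walking", "stair_up"),
      w_sd = behavior_similarity(pr, "walking", "stair_down"),
      su_sd = behavior_similarity(pr, "stair_up", "stair_down"))
  }
  full <- sims(1)
  none <- sims(0)
  # fully shared harmonics: stair pair clearly the most similar (short of 1
  # only through the even-harmonic phase-flip residual)
  expect_gt(full[["su_sd"]], max(full[["w_su"]], full[["w_sd"]]))
  expect_gt(full[["su_sd"]], 0.85)
  # nothing shared: the stair pair is no longer the maximum
  expect_lt(none[["su_sd"]], max(none[["w_su"]], none[["w_sd"]]))
  expect_gt(full[["su_sd"]], none[["su_sd"]])
})
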