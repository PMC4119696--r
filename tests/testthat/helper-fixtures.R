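# Shared generators for the property-style tests. Everything is seeded by
# the caller; nothing touches the global RNG outside set.seed().

rand_fuzzy <- function(n = sample.int(12, 1)) fuzzy_set(stats::runif(n))

# nested triple A < B < C pointwise, nesting guaranteed by construction
rand_nested <- function(n = sample.int(12, 1)) {
  cc <- stats::runif(n)
  bb <- cc * stats::runif(n)
  aa <- bb * stats::runif(n)
  list(A = fuzzy_set(aa), B = fuzzy_set(bb), C = fuzzy_set(cc))
}

# minimal handmade recording on the full 36-channel layout: every channel a
# sine with a channel-specific phase, plus an optional extra signal matrix
make_recording <- function(subject = "T1", behavior = "walking",
                           rate = 50, duration = 4, freq = 1) {
  n <- rate * duration
  t <- (seq_len(n) - 1) / rate
  chn <- gait_channel_names()
  channels <- sapply(seq_along(chn), function(j) {
    sin(2 * pi * freq * t + j / 7) + 0.2 * sin(4 * pi * freq * t + j / 3)
  })
  colnames(channels) <- chn
  gait_recording(subject, behavior, rate, channels)
}

# profile whose three recordings share one underlying signal (clone triple)
make_clone_profile <- function(subject = "T1", rate = 50, duration = 4) {
  base <- make_recording(subject, "walking", rate, duration)
  su <- base; su$behavior <- "stair_up"
  sd_ <- base; sd_$behavior <- "stair_down"
  behavior_profile(base, su, sd_)
}

small_config <- function(...) {
  args <- list(n_subjects = 3, duration_s = 4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(gait_sim_config, args)
}
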