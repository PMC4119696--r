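#' Configuration for the synthetic gait cohort simulator
#'
#' The simulator emulates the structure of a wearable-sensor gait
#' experiment: 20 subjects, three behaviors (walking, stair ascent, stair
#' descent), and per recording the full 36-channel layout (4 positions x
#' 3 sensors x 3 axes). Each channel is a quasi-periodic sum of the first
#' three harmonics of the behavior's stride frequency,
#' \deqn{x(t) = g \sum_{h=1}^{3} A_h (1 + \eta_h)
#'   \sin(2\pi h f (t - \tau) + \phi_h) + \epsilon(t),}
#' with channel gain `g` fixed by (position, sensor, axis), harmonic
#' amplitudes `A_h` from the behavior's template, multiplicative subject
#' variation `eta ~ N(0, subject_variation_sd)` per (subject, behavior,
#' channel, harmonic), a per-(subject, behavior) start offset `tau` uniform
#' over one stride period, and white noise
#' `epsilon ~ N(0, noise_sd)`. All randomness derives from `seed` through
#' stable hashed substreams, so any recording is reproducible in isolation.
#'
#' Stair ascent and descent share their stride frequency and, to degree
#' `stair_shared_fraction`, their harmonic series: the stair-descent channel
#' is the phase-flipped stair-ascent series weighted by the shared fraction
#' plus a walking-cadence residual series weighted by the rest. With the
#' default high shared fraction this makes stair ascent vs. descent the most
#' similar behavior pair — an emergent property of the templates, not a
#' hard-coded score. Walking carries the richest harmonic content and stair
#' ascent the most fundamental-dominant, so cross-person similarity is
#' highest for stair ascent (subject variation perturbs harmonic content,
#' and there is least of it to perturb).
#'
#' @param n_subjects number of subjects (default 20).
#' @param duration_s recording length in seconds (default 10).
#' @param sampling_rate_hz sampling rate (default 100 Hz).
#' @param stride_frequency_hz named vector of fundamental stride frequencies
#'   (Hz) per behavior; stair ascent/descent share 0.8 Hz by default,
#'   walking 1.0 Hz.
#' @param harmonic_template named list of length-3 amplitude vectors:
#'   `walking`, `stair_up`, and `stair_down_residual` (the non-shared
#'   component of stair descent).
#' @param subject_variation_sd sd of the multiplicative per-subject harmonic
#'   amplitude perturbation (default 0.1).
#' @param noise_sd sd of the additive white measurement noise (default
#'   0.05, relative to unit fundamental amplitude).
#' @param stair_shared_fraction fraction of the stair-ascent series shared
#'   by stair descent, in `[0, 1]` (default 0.9).
#' @param seed integer master seed (default 42).
#' @return An object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_subjects = 20,
                            duration_s = 10,
                            sampling_rate_hz = 100,
                            stride_frequency_hz = c(walking = 1.0,
                                                    stair_up = 0.8,
                                                    stair_down = 0.8),
                            harmonic_template = list(
                              walking = c(1, 0.7, 0.5),
                              stair_up = c(1, 0.15, 0.08),
                              stair_down_residual = c(1, 0.7, 0.5)),
                            subject_variation_sd = 0.1,
                            noise_sd = 0.05,
                            stair_shared_fraction = 0.9,
                            seed = 42) {
  stopifnot_cfg <- function(ok, msg) {
    if (!ok) stop(fg_error(msg, "fg_invalid_input"))
  }
  stopifnot_cfg(is.numeric(n_subjects) && n_subjects >= 1,
                "n_subjects must be >= 1")
  stopifnot_cfg(duration_s > 0 && sampling_rate_hz > 0,
                "duration and sampling rate must be positive")
  stopifnot_cfg(all(gait_behaviors %in% names(stride_frequency_hz)) &&
                  all(stride_frequency_hz > 0),
                "stride_frequency_hz needs a positive entry per behavior")
  stopifnot_cfg(all(c("walking", "stair_up", "stair_down_residual") %in%
                      names(harmonic_template)) &&
                  all(lengths(harmonic_template) == 3L),
                "harmonic_template needs three length-3 amplitude vectors")
  stopifnot_cfg(subject_variation_sd >= 0 && noise_sd >= 0,
                "standard deviations must be >= 0")
  stopifnot_cfg(stair_shared_fraction >= 0 && stair_shared_fraction <= 1,
                "stair_shared_fraction must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 stride_frequency_hz = stride_frequency_hz,
                 harmonic_template = harmonic_template,
                 subject_variation_sd = subject_variation_sd,
                 noise_sd = noise_sd,
                 stair_shared_fraction = stair_shared_fraction,
                 seed = as.integer(seed)),
            class = "gait_sim_config")
}

#' @export
print.gait_sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<gait_sim_config> %d subjects, %g s @ %g Hz, seed %d\n",
    "  subject_variation_sd %g, noise_sd %g, stair_shared_fraction %g\n"),
    x$n_subjects, x$duration_s, x$sampling_rate_hz, x$seed,
    x$subject_variation_sd, x$noise_sd, x$stair_shared_fraction))
  invisible(x)
}

# fixed channel gains: stronger signals at the legs, weakest magnetometer
sensor_gain <- c(accelerometer = 1.0, magnetometer = 0.5, gyro = 0.8)
position_gain <- c(head = 0.6, waist = 1.0, left_leg = 1.2,
                   right_leg = 1.15)
axis_gain <- c(x = 1.0, y = 0.7, z = 0.9)

# 3-harmonic series with hashed per-(stream, channel, harmonic) phases and
# per-(subject, behavior, channel) amplitude perturbations
harmonic_series <- function(t, f, amps, eta, phases, flip = FALSE) {
  out <- numeric(length(t))
  for (h in 1:3) {
    ph <- phases[h] + if (flip) pi else 0
    out <- out + amps[h] * (1 + eta[h]) * sin(2 * pi * h * f * t + ph)
  }
  out
}

channel_phases <- function(seed, stream, channel) {
  set.seed(substream_seed(seed, "phase", stream, channel))
  stats::runif(3, 0, 2 * pi)
}

channel_eta <- function(config, subject, behavior, channel, part = "main") {
  if (config$subject_variation_sd == 0) return(rep(0, 3))
  set.seed(substream_seed(config$seed, "subject", subject, behavior,
                          channel, part))
  stats::rnorm(3, 0, config$subject_variation_sd)
}

#' Generate one synthetic gait recording
#'
#' See [gait_sim_config()] for the signal model. Deterministic given the
#' config seed, subject and behavior, independent of generation order.
#'
#' @param config a [gait_sim_config()].
#' @param subject subject index in `1:n_subjects`.
#' @param behavior one of `"walking"`, `"stair_up"`, `"stair_down"`.
#' @return A [gait_recording()] with all 36 channels.
#' @export
generate_recording <- function(config, subject, behavior) {
  if (!inherits(config, "gait_sim_config")) {
    stop(fg_error("config must be a gait_sim_config", "fg_invalid_input"))
  }
  behavior <- match.arg(behavior, gait_behaviors)
  subject <- as.integer(subject)
  if (is.na(subject) || subject < 1L || subject > config$n_subjects) {
    stop(fg_error("subject must lie in 1:n_subjects", "fg_invalid_input"))
  }
  n <- round(config$duration_s * config$sampling_rate_hz)
  t <- (seq_len(n) - 1L) / config$sampling_rate_hz
  f <- config$stride_frequency_hz[[behavior]]
  set.seed(substream_seed(config$seed, "offset", subject, behavior))
  tau <- stats::runif(1, 0, 1 / f)
  tt <- t - tau

  sf <- config$stair_shared_fraction
  channels <- matrix(0, n, 0)
  for (pos in gait_positions) {
    for (sen in gait_sensors) {
      for (ax in gait_axes) {
        ch <- paste(pos, sen, ax, sep = "_")
        gain <- position_gain[[pos]] * sensor_gain[[sen]] * axis_gain[[ax]]
        sig <- if (behavior == "walking") {
          harmonic_series(tt, f, config$harmonic_template$walking,
                          channel_eta(config, subject, behavior, ch),
                          channel_phases(config$seed, "walking", ch))
        } else if (behavior == "stair_up") {
          harmonic_series(tt, f, config$harmonic_template$stair_up,
                          channel_eta(config, subject, behavior, ch),
                          channel_phases(config$seed, "stair", ch))
        } else {
          # stair descent: phase-flipped shared stair series plus a
          # walking-cadence residual, mixed by stair_shared_fraction
          shared <- harmonic_series(
            tt, f, config$harmonic_template$stair_up,
            channel_eta(config, subject, behavior, ch),
            channel_phases(config$seed, "stair", ch), flip = TRUE)
          resid <- harmonic_series(
            tt, config$stride_frequency_hz[["walking"]],
            config$harmonic_template$stair_down_residual,
            channel_eta(config, subject, behavior, ch, part = "residual"),
            channel_phases(config$seed, "stair_residual", ch))
          sf * shared + (1 - sf) * resid
        }
        if (config$noise_sd > 0) {
          set.seed(substream_seed(config$seed, "noise", subject, behavior,
                                  ch))
          sig <- sig + stats::rnorm(n, 0, config$noise_sd)
        }
        channels <- cbind(channels, gain * sig)
        colnames(channels)[ncol(channels)] <- ch
      }
    }
  }
  gait_recording(sprintf("S%02d", subject), behavior,
                 config$sampling_rate_hz, channels)
}

#' Generate a complete synthetic cohort
#'
#' @param config a [gait_sim_config()].
#' @return List of `n_subjects` complete [behavior_profile()] objects;
#'   bit-identical across calls with the same config.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects), function(s) {
    behavior_profile(walking = generate_recording(config, s, "walking"),
                     stair_up = generate_recording(config, s, "stair_up"),
                     stair_down = generate_recording(config, s,
                                                     "stair_down"))
  })
}

#' Artificial point distributions for the nonoverlap measure
#'
#' Two labeled samples of membership heights. `"disjoint_a"` and
#' `"disjoint_b"` are the two fixed six-plus-six worked-example partitions
#' (diamonds vs. circles) on which the conventional disjoint-data measure is
#' blind to the partition while the nonoverlap measure is not;
#' `"overlapped"` and `"random_disjoint"` draw seeded random samples.
#'
#' @param kind one of `"overlapped"`, `"disjoint_a"`, `"disjoint_b"`,
#'   `"random_disjoint"`.
#' @param seed seed for the random kinds.
#' @param n sample size per class for the random kinds (default 6).
#' @return List with `singleton_sample` elements `diamonds` and `circles`.
#' @export
generate_pointsets <- function(kind = c("overlapped", "disjoint_a",
                                        "disjoint_b", "random_disjoint"),
                               seed = 1, n = 6) {
  kind <- match.arg(kind)
  switch(kind,
    disjoint_a = list(
      diamonds = singleton_sample(c(0.5, 0.8, 0.6, 0.5, 0.4, 1),
                                  "diamonds"),
      circles = singleton_sample(c(0.4, 0.6, 0.7, 0.5, 0.8, 0.6),
                                 "circles")),
    disjoint_b = list(
      diamonds = singleton_sample(c(0.5, 0.8, 0.6, 0.4, 0.5, 0.4),
                                  "diamonds"),
      circles = singleton_sample(c(0.6, 0.7, 0.5, 1, 0.8, 0.6),
                                 "circles")),
    overlapped = {
      set.seed(substream_seed(seed, "pointsets", "overlapped"))
      list(diamonds = singleton_sample(stats::runif(n, 0.3, 0.9),
                                       "diamonds"),
           circles = singleton_sample(stats::runif(n, 0.3, 0.9),
                                      "circles"))
    },
    random_disjoint = {
      set.seed(substream_seed(seed, "pointsets", "random_disjoint"))
      list(diamonds = singleton_sample(stats::runif(n), "diamonds"),
           circles = singleton_sample(stats::runif(n), "circles"))
    })
}
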