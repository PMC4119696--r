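#' Channel layout of the wearable sensor array
#'
#' Recordings come from an all-in-one inertial unit (tri-axial
#' accelerometer, magnetometer and gyro) worn at four body positions: head,
#' waist and both legs. A full recording therefore has
#' 4 positions x 3 sensors x 3 axes = 36 channels; the comparison pipeline
#' works on the x/z axes only (24 channels).
#'
#' @name channel-layout
#' @keywords internal
NULL

gait_positions <- c("head", "waist", "left_leg", "right_leg")
gait_sensors <- c("accelerometer", "magnetometer", "gyro")
gait_axes <- c("x", "y", "z")
gait_behaviors <- c("walking", "stair_up", "stair_down")

#' All channel names for a given set of axes
#' @param axes subset of `c("x", "y", "z")`.
#' @return Character vector `<position>_<sensor>_<axis>` in canonical order.
#' @export
gait_channel_names <- function(axes = gait_axes) {
  as.vector(t(outer(
    as.vector(t(outer(gait_positions, gait_sensors, paste, sep = "_"))),
    axes, paste, sep = "_")))
}

#' Multi-channel gait recording
#'
#' @param subject_id subject identifier (scalar).
#' @param behavior one of `"walking"`, `"stair_up"`, `"stair_down"`.
#' @param sampling_rate sampling rate in Hz, `> 0`.
#' @param channels numeric matrix, one column per channel named
#'   `<position>_<sensor>_<axis>`; all columns equal length.
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(subject_id, behavior, sampling_rate, channels) {
  behavior <- match.arg(behavior, gait_behaviors)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop(fg_error("sampling_rate must be a positive scalar (Hz)",
                  "fg_invalid_input"))
  }
  channels <- as.matrix(channels)
  if (is.null(colnames(channels)) || anyDuplicated(colnames(channels)) > 0L) {
    stop(fg_error("channels must have unique column names",
                  "fg_invalid_input"))
  }
  if (nrow(channels) == 0L) {
    stop(fg_error("channels must contain samples", "fg_empty_input"))
  }
  structure(list(subject_id = as.character(subject_id), behavior = behavior,
                 sampling_rate = as.numeric(sampling_rate),
                 channels = channels),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf(
    "<gait_recording> subject %s, %s: %d channel(s) x %d samples @ %g Hz\n",
    x$subject_id, x$behavior, ncol(x$channels), nrow(x$channels),
    x$sampling_rate))
  invisible(x)
}

#' A subject's behavior profile
#'
#' The triple of one subject's walking, stair-ascent and stair-descent
#' recordings, the unit of the person-to-person comparisons.
#'
#' @param walking,stair_up,stair_down `gait_recording` objects for one
#'   subject, one per behavior.
#' @return An object of class `behavior_profile` with fields `subject_id`
#'   and `recordings` (a named list).
#' @export
behavior_profile <- function(walking, stair_up, stair_down) {
  recs <- list(walking = walking, stair_up = stair_up,
               stair_down = stair_down)
  for (b in gait_behaviors) {
    r <- recs[[b]]
    if (!inherits(r, "gait_recording")) {
      stop(fg_error(sprintf("'%s' must be a gait_recording", b),
                    "fg_invalid_input"))
    }
    if (r$behavior != b) {
      stop(fg_error(sprintf("recording supplied as '%s' is labeled '%s'",
                            b, r$behavior), "fg_invalid_input"))
    }
  }
  ids <- unique(vapply(recs, `[[`, "", "subject_id"))
  if (length(ids) != 1L) {
    stop(fg_error("all three recordings must share one subject_id",
                  "fg_invalid_input"))
  }
  structure(list(subject_id = ids, recordings = recs),
            class = "behavior_profile")
}

#' @export
print.behavior_profile <- function(x, ...) {
  cat(sprintf("<behavior_profile> subject %s (%s)\n", x$subject_id,
              paste(names(x$recordings), collapse = ", ")))
  invisible(x)
}

#' Keep only the x- and z-axis channels
#'
#' The y-direction signals track the x/z pattern closely and are dropped;
#' comparisons run on the 24 x/z channels (2 axes x 3 sensors x
#' 4 positions). Idempotent on an already-selected recording.
#'
#' @param rec a `gait_recording` containing at least the x and z channels of
#'   every (position, sensor).
#' @return The recording restricted to x/z channels in canonical order.
#' @export
select_channels <- function(rec) {
  wanted <- gait_channel_names(axes = c("x", "z"))
  missing <- setdiff(wanted, colnames(rec$channels))
  if (length(missing)) {
    stop(fg_error(paste0("recording is missing required channel(s): ",
                         paste(missing, collapse = ", ")),
                  "fg_missing_channel"))
  }
  gait_recording(rec$subject_id, rec$behavior, rec$sampling_rate,
                 rec$channels[, wanted, drop = FALSE])
}

# lag L maximizing sum_t x[t] * y[t + L] over the overlap (demeaned);
# positive L means y is delayed by L samples relative to x. Lengths may
# differ.
xcorr_lag <- function(x, y) {
  # convolve() conjugates its second argument, so this is the full
  # cross-correlation, not a convolution
  cc <- stats::convolve(x - mean(x), y - mean(y), type = "open")
  # cc[k] = sum_i x[i] y[i + (m - k)], k = 1..n+m-1  =>  lag = m - k with
  # m = length(y); among numerically tied maxima (periodic signals) prefer
  # the smallest absolute lag to keep the overlap window maximal
  lags <- length(y) - seq_along(cc)
  top <- which(cc >= max(cc) - 1e-9 * max(abs(cc), 1))
  lags[top[which.min(abs(lags[top]))]]
}

#' Synchronize recordings by cross-correlation on a reference channel
#'
#' Estimates the integer lag of every recording against the first by
#' maximizing the cross-correlation of the demeaned reference channel,
#' shifts each recording by its lag, and truncates all recordings to the
#' common overlapping window, so every output has equal length. No padding
#' is ever applied.
#'
#' @param recs list of `gait_recording` objects with a shared channel
#'   layout.
#' @param reference_channel channel used for lag estimation (default waist
#'   accelerometer z).
#' @return List of `gait_recording` objects of equal length, with the
#'   estimated lags attached as `attr(, "lags")`.
#' @export
synchronize <- function(recs, reference_channel = "waist_accelerometer_z") {
  if (!is.list(recs) || length(recs) < 2L) {
    stop(fg_error("need at least two recordings", "fg_invalid_input"))
  }
  for (r in recs) {
    if (!reference_channel %in% colnames(r$channels)) {
      stop(fg_error(paste0("reference channel not present: ",
                           reference_channel), "fg_missing_channel"))
    }
  }
  ref1 <- recs[[1]]$channels[, reference_channel]
  lags <- vapply(recs, function(r) {
    if (identical(r$channels, recs[[1]]$channels)) return(0L)
    as.integer(xcorr_lag(ref1, r$channels[, reference_channel]))
  }, integer(1))
  offsets <- lags - min(lags)
  lens <- vapply(recs, function(r) nrow(r$channels), integer(1))
  out_len <- min(lens - offsets)
  if (out_len < 1L) {
    stop(fg_error("no overlapping window remains after shifting",
                  "fg_degenerate_input"))
  }
  out <- Map(function(r, off) {
    idx <- seq.int(off + 1L, off + out_len)
    gait_recording(r$subject_id, r$behavior, r$sampling_rate,
                   r$channels[idx, , drop = FALSE])
  }, recs, offsets)
  attr(out, "lags") <- lags
  out
}

#' Rescale a signal to membership degrees
#'
#' Min-max rescaling `(v - min) / (max - min)` onto `[0, 1]`, turning a raw
#' sensor channel into a discrete membership function so the fuzzy
#' similarity measures apply. A constant channel carries no shape
#' information and maps to 0.5 everywhere by convention.
#'
#' @param v non-empty numeric vector.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @export
to_membership <- function(v) {
  if (length(v) == 0L) {
    stop(fg_error("cannot normalize an empty vector", "fg_empty_input"))
  }
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0.5, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

# indices of local maxima; on a plateau the earliest index wins
peak_indices <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  s <- sign(diff(x))
  # propagate the next nonzero slope backwards so plateau points inherit
  # the upcoming direction (earliest-index tie-break)
  for (i in rev(seq_len(length(s) - 1L))) {
    if (s[i] == 0) s[i] <- s[i + 1L]
  }
  which(s[-length(s)] == 1 & s[-1] == -1) + 1L
}

# prominence of each peak: height minus the higher of the two side minima,
# each side delimited by the nearest strictly higher point (or signal edge)
peak_prominences <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= length(x) && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Peak and magnitude-distance features per channel
#'
#' For each channel, local maxima whose prominence is at least
#' `prominence_fraction` of the channel's range become peaks; the magnitude
#' distances are the successive differences between peak amplitudes (one
#' fewer than the peak count). A flat channel yields no features.
#'
#' @param rec a `gait_recording`.
#' @param prominence_fraction prominence threshold as a fraction of the
#'   channel range, in `(0, 1)` (default 0.1).
#' @return An object of class `channel_feature_set`: per channel a list
#'   with `peaks` (amplitudes, in time order) and `magnitude_distances`.
#' @export
extract_features <- function(rec, prominence_fraction = 0.1) {
  if (!is.numeric(prominence_fraction) || prominence_fraction <= 0 ||
      prominence_fraction >= 1) {
    stop(fg_error("prominence_fraction must lie in (0, 1)",
                  "fg_invalid_input"))
  }
  feats <- lapply(seq_len(ncol(rec$channels)), function(j) {
    x <- rec$channels[, j]
    rng <- diff(range(x))
    if (rng == 0) {
      return(list(peaks = numeric(0), magnitude_distances = numeric(0)))
    }
    idx <- peak_indices(x)
    if (length(idx)) {
      prom <- peak_prominences(x, idx)
      idx <- idx[prom >= prominence_fraction * rng]
    }
    pk <- x[idx]
    list(peaks = pk,
         magnitude_distances = if (length(pk) > 1L) diff(pk) else numeric(0))
  })
  names(feats) <- colnames(rec$channels)
  structure(feats, class = "channel_feature_set",
            duration_s = nrow(rec$channels) / rec$sampling_rate,
            prominence_fraction = prominence_fraction)
}

# fixed-length numeric summary of a feature set: per channel the peak rate
# (1/s), mean and sd of peak amplitudes, and mean absolute magnitude
# distance (zeros when undefined)
feature_vector <- function(features) {
  dur <- attr(features, "duration_s")
  unlist(lapply(features, function(f) {
    p <- f$peaks
    md <- f$magnitude_distances
    c(rate = length(p) / dur,
      mean_peak = if (length(p)) mean(p) else 0,
      sd_peak = if (length(p) > 1L) stats::sd(p) else 0,
      mean_mag = if (length(md)) mean(abs(md)) else 0)
  }))
}
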