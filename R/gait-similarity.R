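#' Similarity between two preprocessed gait recordings
#'
#' The workhorse behind [behavior_similarity()] and [person_similarity()].
#' Both recordings are restricted to the x/z channels, synchronized pairwise
#' by cross-correlation on the reference channel, and each channel is
#' min-max rescaled to a membership function. Then:
#'
#' * `mode = "fuzzy"`: per channel the min-max similarity
#'   `1 - d(min(A,B), max(A,B))` with `d` the normalized Hamming distance
#'   (identical to `1 - mean |mu_a - mu_b|`), averaged unweighted over the
#'   24 channels;
#' * `mode = "lp"`: peak-based feature vectors (peak rate, mean/sd peak
#'   amplitude, mean absolute magnitude distance per channel) are compared
#'   with the Lp distance and mapped to `1 / (1 + d)` — a pair-level
#'   convention; cohort-level outputs ([similarity_tables()]) instead use
#'   the global min-max scaling of [pairwise_similarity()].
#'
#' @param a,b `gait_recording` objects with the same channel layout.
#' @param mode `"fuzzy"` (membership comparison) or `"lp"` (peak features).
#' @param p norm order for `mode = "lp"`.
#' @param prominence_fraction peak prominence threshold for `mode = "lp"`.
#' @param reference_channel synchronization reference channel.
#' @param preprocess set `FALSE` if the recordings are already selected,
#'   synchronized and membership-normalized.
#' @return Similarity in `[0, 1]`; 1 for identical recordings.
#' @export
recording_similarity <- function(a, b, mode = c("fuzzy", "lp"), p = 2,
                                 prominence_fraction = 0.1,
                                 reference_channel = "waist_accelerometer_z",
                                 preprocess = TRUE) {
  mode <- match.arg(mode)
  for (r in list(a, b)) {
    if (!inherits(r, "gait_recording")) {
      stop(fg_error("arguments must be gait_recording objects",
                    "fg_invalid_input"))
    }
  }
  if (preprocess) {
    a <- select_channels(a)
    b <- select_channels(b)
    sync <- synchronize(list(a, b), reference_channel = reference_channel)
    a <- sync[[1]]; b <- sync[[2]]
  }
  if (!identical(colnames(a$channels), colnames(b$channels))) {
    stop(fg_error("recordings have different channel layouts",
                  "fg_support_mismatch"))
  }
  if (nrow(a$channels) != nrow(b$channels)) {
    stop(fg_error("recordings have different lengths", "fg_invalid_input"))
  }
  if (mode == "fuzzy") {
    sims <- vapply(seq_len(ncol(a$channels)), function(j) {
      ma <- if (preprocess) to_membership(a$channels[, j]) else
        a$channels[, j]
      mb <- if (preprocess) to_membership(b$channels[, j]) else
        b$channels[, j]
      1 - mean(abs(ma - mb))
    }, numeric(1))
    mean(sims)
  } else {
    fa <- feature_vector(extract_features(a, prominence_fraction))
    fb <- feature_vector(extract_features(b, prominence_fraction))
    1 / (1 + lp_distance(fa, fb, p = p))
  }
}

#' Similarity between two behaviors of one subject
#'
#' Compares two of a subject's recordings (e.g. walking vs. stair ascent)
#' with [recording_similarity()].
#'
#' @param profile a [behavior_profile()].
#' @param b1,b2 behavior names among `"walking"`, `"stair_up"`,
#'   `"stair_down"`.
#' @param ... passed on to [recording_similarity()].
#' @inheritParams recording_similarity
#' @return Similarity in `[0, 1]`.
#' @export
behavior_similarity <- function(profile, b1, b2, mode = c("fuzzy", "lp"),
                                ...) {
  if (!inherits(profile, "behavior_profile")) {
    stop(fg_error("profile must be a behavior_profile", "fg_invalid_input"))
  }
  b1 <- match.arg(b1, gait_behaviors)
  b2 <- match.arg(b2, gait_behaviors)
  recording_similarity(profile$recordings[[b1]], profile$recordings[[b2]],
                       mode = mode, ...)
}

#' Similarity between two subjects for a fixed behavior
#'
#' @param pi,pj [behavior_profile()] objects.
#' @param behavior the behavior to compare on.
#' @param ... passed on to [recording_similarity()].
#' @inheritParams recording_similarity
#' @return Similarity in `[0, 1]`; symmetric in `pi`, `pj`.
#' @export
person_similarity <- function(pi, pj, behavior = "walking",
                              mode = c("fuzzy", "lp"), ...) {
  for (p_ in list(pi, pj)) {
    if (!inherits(p_, "behavior_profile")) {
      stop(fg_error("arguments must be behavior_profile objects",
                    "fg_invalid_input"))
    }
  }
  behavior <- match.arg(behavior, gait_behaviors)
  recording_similarity(pi$recordings[[behavior]],
                       pj$recordings[[behavior]], mode = mode, ...)
}

behavior_pairs <- rbind(c("walking", "stair_up"),
                        c("walking", "stair_down"),
                        c("stair_up", "stair_down"))

#' Person-by-person similarity matrix for one behavior
#'
#' @param cohort list of [behavior_profile()] objects (at least two).
#' @param behavior behavior to compare on.
#' @inheritParams similarity_tables
#' @return A [similarity_matrix()] over the cohort's subject ids.
#' @export
person_matrix <- function(cohort, behavior = "walking",
                          mode = c("fuzzy", "lp"), p = 2,
                          prominence_fraction = 0.1,
                          reference_channel = "waist_accelerometer_z") {
  mode <- match.arg(mode)
  behavior <- match.arg(behavior, gait_behaviors)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  n <- length(cohort)
  if (n < 2L) stop(fg_error("need at least two subjects", "fg_empty_input"))
  if (mode == "lp") {
    M <- do.call(rbind, lapply(cohort, function(pr) {
      feature_vector(extract_features(select_channels(
        pr$recordings[[behavior]]), prominence_fraction))
    }))
    rownames(M) <- ids
    return(pairwise_similarity(M, p = p, on_degenerate = "ones"))
  }
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <-
        person_similarity(cohort[[i]], cohort[[j]], behavior = behavior,
                          mode = "fuzzy",
                          reference_channel = reference_channel)
    }
  }
  similarity_matrix(S, ids)
}

#' Cohort similarity tables
#'
#' The three summary tables of the gait comparison study design:
#'
#' 1. `behavior_pairs`: cohort mean of each within-subject cross-behavior
#'    similarity — s(walking, stair_up), s(walking, stair_down),
#'    s(stair_up, stair_down); the per-subject values are returned in
#'    `behavior_pairs_by_subject`.
#' 2. `cross_person`: for each behavior, the mean similarity over all
#'    subject pairs.
#' 3. `person_matrix`: the full subject-by-subject [similarity_matrix()]
#'    for `behavior_for_matrix` (default walking).
#'
#' In `mode = "lp"` each recording is reduced to its peak-feature vector
#' once, and every table is normalized with the global min-max scheme of
#' [pairwise_similarity()] (table 1 within each subject's behavior triple,
#' tables 2-3 across the cohort per behavior).
#'
#' @param cohort list of complete [behavior_profile()] objects.
#' @param mode `"fuzzy"` or `"lp"` (see [recording_similarity()]).
#' @param behavior_for_matrix behavior shown in the person-by-person matrix.
#' @param p norm order for `mode = "lp"`.
#' @param prominence_fraction peak prominence threshold for `mode = "lp"`.
#' @param reference_channel synchronization reference channel.
#' @return An object of class `gait_similarity_tables`.
#' @export
similarity_tables <- function(cohort, mode = c("fuzzy", "lp"),
                              behavior_for_matrix = "walking", p = 2,
                              prominence_fraction = 0.1,
                              reference_channel = "waist_accelerometer_z") {
  mode <- match.arg(mode)
  behavior_for_matrix <- match.arg(behavior_for_matrix, gait_behaviors)
  if (!is.list(cohort) || length(cohort) == 0L ||
      !all(vapply(cohort, inherits, TRUE, "behavior_profile"))) {
    stop(fg_error("cohort must be a non-empty list of behavior_profiles",
                  "fg_empty_input"))
  }
  ids <- vapply(cohort, `[[`, "", "subject_id")
  n <- length(cohort)
  if (n < 2L) {
    stop(fg_error("cohort needs at least two subjects for cross-person tables",
                  "fg_empty_input"))
  }
  pair_lab <- paste(behavior_pairs[, 1], behavior_pairs[, 2], sep = "|")

  if (mode == "lp") {
    # one feature vector per (subject, behavior); global min-max scaling
    fv <- lapply(cohort, function(pr) {
      lapply(pr$recordings, function(r) {
        feature_vector(extract_features(select_channels(r),
                                        prominence_fraction))
      })
    })
    per_subj <- do.call(rbind, lapply(seq_len(n), function(i) {
      S <- pairwise_similarity(do.call(rbind, fv[[i]]), p = p,
                               on_degenerate = "ones")
      data.frame(subject = ids[i], pair = pair_lab,
                 similarity = apply(behavior_pairs, 1L, function(bp) {
                   S[bp[1], bp[2]]
                 }), row.names = NULL)
    }))
    mats <- lapply(gait_behaviors, function(b) {
      M <- do.call(rbind, lapply(fv, `[[`, b))
      rownames(M) <- ids
      pairwise_similarity(M, p = p, on_degenerate = "ones")
    })
  } else {
    per_subj <- do.call(rbind, lapply(seq_len(n), function(i) {
      vals <- apply(behavior_pairs, 1L, function(bp) {
        behavior_similarity(cohort[[i]], bp[1], bp[2], mode = "fuzzy",
                            reference_channel = reference_channel)
      })
      data.frame(subject = ids[i], pair = pair_lab, similarity = vals,
                 row.names = NULL)
    }))
    mats <- lapply(gait_behaviors, person_matrix, cohort = cohort,
                   mode = "fuzzy", reference_channel = reference_channel)
  }
  names(mats) <- gait_behaviors
  t1 <- stats::aggregate(similarity ~ pair, data = per_subj, FUN = mean)
  t1 <- t1[match(pair_lab, t1$pair), ]
  rownames(t1) <- NULL
  off_mean <- function(S) mean(S[upper.tri(S)])
  t2 <- data.frame(behavior = gait_behaviors,
                   similarity = vapply(mats, off_mean, numeric(1)),
                   row.names = NULL)

  structure(list(behavior_pairs = t1,
                 behavior_pairs_by_subject = per_subj,
                 cross_person = t2,
                 person_matrix = mats[[behavior_for_matrix]],
                 behavior_for_matrix = behavior_for_matrix,
                 mode = mode, n_subjects = n),
            class = "gait_similarity_tables")
}

#' @export
print.gait_similarity_tables <- function(x, ...) {
  cat(sprintf("Gait similarity tables (%d subjects, mode '%s')\n",
              x$n_subjects, x$mode))
  cat("\nWithin-subject, cross-behavior (cohort mean):\n")
  print(transform(x$behavior_pairs, similarity = round(similarity, 3)))
  cat("\nCross-person, within-behavior (mean over pairs):\n")
  print(transform(x$cross_person, similarity = round(similarity, 3)))
  cat(sprintf("\nPerson-by-person matrix (%s): %d x %d, see $person_matrix\n",
              x$behavior_for_matrix, nrow(x$person_matrix),
              ncol(x$person_matrix)))
  invisible(x)
}
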