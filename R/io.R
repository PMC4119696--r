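# File round-tripping. Dialect: comma-separated, UTF-8, '.' decimal,
# mandatory header row; floats printed with 9 significant digits. Outputs
# carry the generating seed and a config hash, either in the recording's
# JSON sidecar or as a leading '#' comment line in CSVs.

fmt9 <- function(x) sprintf("%.9g", x)

#' Read and write fuzzy sets as two-column CSV
#'
#' Columns `element_id, membership`; the reader validates the `[0, 1]`
#' membership range and unique identifiers.
#'
#' @param A a [fuzzy_set()].
#' @param path file path.
#' @return `read_fuzzy_set()` returns a `fuzzy_set`;
#'   `write_fuzzy_set()` returns `path` invisibly.
#' @export
write_fuzzy_set <- function(A, path) {
  utils::write.csv(data.frame(element_id = A$support,
                              membership = fmt9(A$memberships)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fuzzy_set
#' @export
read_fuzzy_set <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!identical(names(df), c("element_id", "membership"))) {
    stop(fg_error(sprintf("%s: expected columns element_id, membership",
                          path), "fg_parse_error"))
  }
  bad <- which(is.na(df$membership) | df$membership < 0 | df$membership > 1)
  if (length(bad)) {
    stop(fg_error(sprintf("%s: membership out of [0, 1] at row %d",
                          path, bad[1]), "fg_parse_error"))
  }
  fuzzy_set(df$membership, df$element_id)
}

#' Read and write labeled point samples as CSV
#'
#' Long format with columns `label, value`, one row per point; one
#' [singleton_sample()] per distinct label.
#'
#' @param samples list of `singleton_sample` objects.
#' @param path file path.
#' @return `read_point_samples()` returns a named list of
#'   `singleton_sample`s; `write_point_samples()` returns `path` invisibly.
#' @export
write_point_samples <- function(samples, path) {
  df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(label = s$label, value = fmt9(s$values))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_point_samples
#' @export
read_point_samples <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!identical(names(df), c("label", "value"))) {
    stop(fg_error(sprintf("%s: expected columns label, value", path),
                  "fg_parse_error"))
  }
  bad <- which(is.na(df$value) | df$value < 0 | df$value > 1)
  if (length(bad)) {
    stop(fg_error(sprintf("%s: value out of [0, 1] at row %d (column value)",
                          path, bad[1]), "fg_parse_error"))
  }
  out <- lapply(split(df$value, df$label), singleton_sample)
  for (lab in names(out)) out[[lab]]$label <- lab
  out
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read and write gait recordings as wide CSV plus JSON sidecar
#'
#' The CSV holds a `time_s` column plus one column per channel named
#' `<position>_<sensor>_<axis>`; subject id, behavior, sampling rate and any
#' provenance metadata (seed, config hash) live in a JSON sidecar with the
#' same stem.
#'
#' @param rec a [gait_recording()].
#' @param path CSV file path (the sidecar replaces `.csv` with `.json`).
#' @param meta named list of extra metadata stored in the sidecar.
#' @return `read_gait_recording()` returns a `gait_recording` (sidecar
#'   metadata attached as `attr(, "meta")`); the writer returns `path`
#'   invisibly.
#' @export
write_gait_recording <- function(rec, path, meta = list()) {
  n <- nrow(rec$channels)
  df <- data.frame(time_s = fmt9((seq_len(n) - 1L) / rec$sampling_rate))
  for (ch in colnames(rec$channels)) df[[ch]] <- fmt9(rec$channels[, ch])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    c(list(subject_id = rec$subject_id, behavior = rec$behavior,
           sampling_rate_hz = rec$sampling_rate), meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gait_recording
#' @export
read_gait_recording <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop(fg_error(sprintf("missing metadata sidecar %s", side),
                  "fg_parse_error"))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s" || ncol(df) < 2L) {
    stop(fg_error(sprintf("%s: expected a time_s column plus channels",
                          path), "fg_parse_error"))
  }
  ch <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(ch)) {
    bad <- which(is.na(ch), arr.ind = TRUE)[1, ]
    stop(fg_error(sprintf("%s: non-numeric value at row %d, column %s",
                          path, bad[1], colnames(ch)[bad[2]]),
                  "fg_parse_error"))
  }
  rec <- gait_recording(meta$subject_id, meta$behavior,
                        meta$sampling_rate_hz, ch)
  attr(rec, "meta") <- meta
  rec
}

cohort_file <- function(subject_id, behavior) {
  sprintf("%s_%s.csv", subject_id, behavior)
}

#' Read and write a cohort directory
#'
#' One CSV + JSON sidecar per (subject, behavior), named
#' `<subject>_<behavior>.csv`. The writer stamps every sidecar with the
#' simulation seed and config hash when a config is supplied; the reader
#' reconstructs [behavior_profile()]s and lists any missing
#' (subject, behavior) files explicitly.
#'
#' @param cohort list of [behavior_profile()] objects.
#' @param dir directory (created if needed).
#' @param config optional [gait_sim_config()] used to generate the cohort;
#'   its seed and hash are embedded in every sidecar.
#' @return `read_cohort()` returns a list of `behavior_profile`s;
#'   `write_cohort()` returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- if (is.null(config)) list() else
    list(seed = config$seed, config_hash = config_hash(unclass(config)))
  for (pr in cohort) {
    for (b in gait_behaviors) {
      write_gait_recording(pr$recordings[[b]],
                           file.path(dir, cohort_file(pr$subject_id, b)),
                           meta = meta)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "_(walking|stair_up|stair_down)\\.csv$")
  subjects <- sort(unique(sub("_(walking|stair_up|stair_down)\\.csv$", "",
                              files)))
  if (!length(subjects)) {
    stop(fg_error(sprintf("no cohort recordings found in %s", dir),
                  "fg_parse_error"))
  }
  missing <- character(0)
  for (s in subjects) {
    for (b in gait_behaviors) {
      if (!file.exists(file.path(dir, cohort_file(s, b)))) {
        missing <- c(missing, sprintf("(%s, %s)", s, b))
      }
    }
  }
  if (length(missing)) {
    stop(fg_error(paste0("incomplete cohort; missing: ",
                         paste(missing, collapse = ", ")),
                  "fg_parse_error"))
  }
  lapply(subjects, function(s) {
    recs <- lapply(gait_behaviors, function(b) {
      read_gait_recording(file.path(dir, cohort_file(s, b)))
    })
    names(recs) <- gait_behaviors
    behavior_profile(recs$walking, recs$stair_up, recs$stair_down)
  })
}

#' Read and write similarity matrices as square CSV
#'
#' First column `id`, then one column per record id; a leading `#` comment
#' line may carry provenance (seed, config hash) and is ignored on read.
#'
#' @param S a [similarity_matrix()].
#' @param path file path.
#' @param comment optional provenance string written as a `# ` first line.
#' @return `read_similarity_matrix()` returns a `similarity_matrix`;
#'   the writer returns `path` invisibly.
#' @export
write_similarity_matrix <- function(S, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("id", colnames(S)), collapse = ","), con)
  for (i in seq_len(nrow(S))) {
    writeLines(paste(c(rownames(S)[i], fmt9(S[i, ])), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- ids
  similarity_matrix(M, ids)
}

#' Read a simulator configuration from a key-value file
#'
#' Lines of the form `key = value` (`#` comments allowed) overriding the
#' [gait_sim_config()] defaults; recognized scalar keys: `n_subjects`,
#' `duration_s`, `sampling_rate_hz`, `subject_variation_sd`, `noise_sd`,
#' `stair_shared_fraction`, `seed`.
#'
#' @param path config file path.
#' @return A [gait_sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  args <- list()
  scalars <- c("n_subjects", "duration_s", "sampling_rate_hz",
               "subject_variation_sd", "noise_sd", "stair_shared_fraction",
               "seed")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      stop(fg_error(sprintf("%s: cannot parse line '%s'", path, ln),
                    "fg_parse_error"))
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% scalars) {
      stop(fg_error(sprintf("%s: unknown config key '%s'", path, key),
                    "fg_parse_error"))
    }
    args[[key]] <- as.numeric(val)
  }
  do.call(gait_sim_config, args)
}
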