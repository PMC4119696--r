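#' Labeled point samples with membership heights
#'
#' A singleton sample is a finite multiset of membership heights in `[0, 1]`
#' carrying a class label — the representation of a nonoverlapped
#' (disjoint-support) point distribution, where each data point is a
#' singleton with its own support element. Duplicate heights are allowed and
#' counted with multiplicity.
#'
#' @param values numeric vector of heights, each in `[0, 1]`; non-empty.
#' @param label class identifier (default `"sample"`).
#' @return An object of class `singleton_sample`.
#' @export
singleton_sample <- function(values, label = "sample") {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop(fg_error("singleton sample must be non-empty", "fg_empty_input"))
  }
  if (anyNA(values) || any(values < 0) || any(values > 1)) {
    stop(fg_error("sample values must lie in [0, 1]", "fg_invalid_input"))
  }
  structure(list(label = as.character(label), values = values),
            class = "singleton_sample")
}

#' @export
print.singleton_sample <- function(x, ...) {
  cat(sprintf("<singleton_sample '%s'> %d value(s): %s\n", x$label,
              length(x$values),
              paste(formatC(x$values, digits = 4, format = "fg"),
                    collapse = ", ")))
  invisible(x)
}

#' Reference pool: the union of all samples under comparison
#'
#' The pool R is the whole data distribution containing every sample. The
#' arithmetic of the nonoverlap measure only touches each sample's own values
#' (a sample is contained in R, so intersecting with R is the identity); the
#' pool is recorded for provenance.
#'
#' @param ... `singleton_sample` objects.
#' @return An object of class `reference_pool` with the concatenated values
#'   and the contributing labels.
#' @export
reference_pool <- function(...) {
  samples <- list(...)
  if (!length(samples) || !all(vapply(samples, inherits, TRUE,
                                      "singleton_sample"))) {
    stop(fg_error("reference_pool takes singleton_sample objects",
                  "fg_invalid_input"))
  }
  structure(list(values = unlist(lapply(samples, `[[`, "values")),
                 labels = vapply(samples, `[[`, "", "label")),
            class = "reference_pool")
}

#' Complement mass of a singleton sample
#'
#' The normalized distance of a sample's heights to the all-ones vector:
#' \deqn{s_a = \frac{1}{|a|} \sum_i (1 - v_i).}
#' This is the per-sample quantity from which the nonoverlap similarity is
#' built. Each sample is normalized by its *own* cardinality, which keeps the
#' mass in `[0, 1]` and extends the measure to samples of unequal size.
#'
#' @param sample a `singleton_sample`.
#' @return A number in `[0, 1]`; 0 iff all heights are 1.
#' @examples
#' complement_mass(singleton_sample(c(0.4, 0.6, 0.7, 0.5, 0.8, 0.6)))  # 0.4
#' @export
complement_mass <- function(sample) {
  if (!inherits(sample, "singleton_sample")) {
    stop(fg_error("argument must be a singleton_sample", "fg_invalid_input"))
  }
  mean(1 - sample$values)
}

#' Similarity between nonoverlapped point distributions
#'
#' Conventional distance-based measures degenerate on disjoint-support data:
#' the fuzzy intersection is identically zero, so the score collapses to a
#' function of the pooled values alone and cannot tell different partitions
#' of the same points apart (see [sim_conventional_disjoint()]). This
#' measure instead compares the two samples through their complement masses:
#' \deqn{s(a, b) = 1 - |s_a - s_b|,}
#' with \eqn{s_a, s_b} from [complement_mass()]. It is symmetric, lies in
#' `[0, 1]`, equals 1 for identical samples, and is monotone under pointwise
#' nesting.
#'
#' @param a,b `singleton_sample` objects (cardinalities may differ; each is
#'   normalized by its own count).
#' @return Similarity in `[0, 1]`.
#' @examples
#' d <- singleton_sample(c(0.5, 0.8, 0.6, 0.4, 0.5, 0.4), "diamond")
#' c_ <- singleton_sample(c(0.6, 0.7, 0.5, 1, 0.8, 0.6), "circle")
#' round(sim_nonoverlap(d, c_), 3)  # 0.833
#' @export
sim_nonoverlap <- function(a, b) {
  1 - abs(complement_mass(a) - complement_mass(b))
}

#' Conventional min-max measure applied to disjoint-support data
#'
#' When two samples have disjoint supports, the pointwise minimum is zero
#' everywhere and the pointwise maximum at each point is the lone defined
#' value there, so the min-max similarity reduces to
#' \deqn{s(a, b) = 1 - \frac{1}{N} \sum v,}
#' the sum running over all `N = |a| + |b|` values of both samples. The
#' result depends only on the pooled values — reassigning values between the
#' two classes cannot change it, which is exactly why a dedicated
#' nonoverlap measure is needed.
#'
#' @param a,b `singleton_sample` objects.
#' @return A number; in `[0, 1]` for heights in `[0, 1]`.
#' @examples
#' d <- singleton_sample(c(0.5, 0.8, 0.6, 0.5, 0.4, 1))
#' c_ <- singleton_sample(c(0.4, 0.6, 0.7, 0.5, 0.8, 0.6))
#' round(sim_conventional_disjoint(d, c_), 2)  # 0.38
#' @export
sim_conventional_disjoint <- function(a, b) {
  for (s in list(a, b)) {
    if (!inherits(s, "singleton_sample")) {
      stop(fg_error("arguments must be singleton_sample objects",
                    "fg_invalid_input"))
    }
  }
  v <- c(a$values, b$values)
  1 - sum(v) / length(v)
}
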