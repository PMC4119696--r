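#' Distance-based similarity measures for fuzzy sets
#'
#' Four classical similarity measures built from the normalized Hamming
#' distance `d` on a shared support, with `min`/`max` as intersection/union:
#'
#' * `sim_endpoint(A, B)` = \eqn{d(A \cap B, [0]_X) + d(A \cup B, [1]_X)}
#' * `sim_minmax(A, B)` = \eqn{1 - d(A \cap B, A \cup B)}
#' * `sim_containment(A, B)` = \eqn{1 - d(A, A \cap B) - d(B, A \cap B)}
#' * `sim_dual(A, B)` = \eqn{2 - d(A \cap B, [1]_X) - d(A \cup B, [0]_X)}
#'
#' All four satisfy the similarity-measure axioms (see [axiom_report()]) and
#' are algebraically identical: each equals `1 - hamming_distance(A, B)`.
#' They are kept as separate entry points because each form generalizes
#' differently, and the identity itself is a useful cross-check (see the
#' package tests). Each measure is written out in its defining form rather
#' than shortcut through the identity.
#'
#' @param A,B `fuzzy_set` objects on the same support.
#' @return A similarity in `[0, 1]`: 1 for identical sets, 0 for a crisp set
#'   and its complement.
#' @examples
#' A <- fuzzy_set(c(0.2, 0.6)); B <- fuzzy_set(c(0.4, 0.4))
#' sim_endpoint(A, B)  # 0.8
#' D <- crisp_set(c(1, 0, 1))
#' sim_minmax(D, fs_complement(D))  # 0
#' @export
sim_endpoint <- function(A, B) {
  check_shared_support(A, B)
  s <- A$support
  hamming_distance(fs_intersect(A, B), zero_set(s)) +
    hamming_distance(fs_union(A, B), one_set(s))
}

#' @rdname sim_endpoint
#' @export
sim_minmax <- function(A, B) {
  1 - hamming_distance(fs_intersect(A, B), fs_union(A, B))
}

#' @rdname sim_endpoint
#' @export
sim_containment <- function(A, B) {
  I <- fs_intersect(A, B)
  1 - hamming_distance(A, I) - hamming_distance(B, I)
}

#' @rdname sim_endpoint
#' @export
sim_dual <- function(A, B) {
  check_shared_support(A, B)
  s <- A$support
  2 - hamming_distance(fs_intersect(A, B), one_set(s)) -
    hamming_distance(fs_union(A, B), zero_set(s))
}

#' The distance-based measures as a named list
#'
#' Convenience accessor used by the axiom checker, the demo and the tests.
#'
#' @return Named list of the four measure functions.
#' @export
distance_similarity_measures <- function() {
  list(endpoint = sim_endpoint, minmax = sim_minmax,
       containment = sim_containment, dual = sim_dual)
}
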