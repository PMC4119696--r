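#' Construct a fuzzy set on a discrete support
#'
#' A fuzzy set is a membership vector \eqn{\mu \in [0,1]^n} indexed by an
#' ordered support of unique element identifiers. All binary operations in
#' this package require their operands to live on the *same* support
#' (identical identifier sequence); mismatched supports fail loudly rather
#' than being aligned silently.
#'
#' @param memberships numeric vector of membership degrees, each in `[0, 1]`.
#' @param support character vector of unique element identifiers, same length
#'   as `memberships`. Defaults to `x1, x2, ...`.
#' @return An object of class `fuzzy_set` with fields `support` and
#'   `memberships`.
#' @examples
#' A <- fuzzy_set(c(0.2, 0.6))
#' B <- fuzzy_set(c(0.4, 0.4))
#' hamming_distance(A, B)  # 0.2
#' @export
fuzzy_set <- function(memberships, support = NULL) {
  memberships <- as.numeric(memberships)
  if (length(memberships) == 0L) {
    stop(fg_error("fuzzy set requires a non-empty support", "fg_empty_input"))
  }
  if (is.null(support)) support <- paste0("x", seq_along(memberships))
  support <- as.character(support)
  if (length(support) != length(memberships)) {
    stop(fg_error("support and memberships must have equal length",
                  "fg_invalid_input"))
  }
  if (anyDuplicated(support) > 0L) {
    stop(fg_error("support identifiers must be unique", "fg_invalid_input"))
  }
  if (anyNA(memberships) || any(memberships < 0) || any(memberships > 1)) {
    stop(fg_error("memberships must lie in [0, 1]", "fg_invalid_input"))
  }
  structure(list(support = support, memberships = memberships),
            class = "fuzzy_set")
}

#' Construct a crisp (ordinary) set
#'
#' A crisp set is a fuzzy set whose memberships are all exactly 0 or 1.
#'
#' @inheritParams fuzzy_set
#' @return A `fuzzy_set` that additionally carries class `crisp_set`.
#' @export
crisp_set <- function(memberships, support = NULL) {
  if (!all(memberships %in% c(0, 1))) {
    stop(fg_error("crisp memberships must be exactly 0 or 1",
                  "fg_invalid_input"))
  }
  out <- fuzzy_set(memberships, support)
  class(out) <- c("crisp_set", class(out))
  out
}

#' @export
print.fuzzy_set <- function(x, ...) {
  kind <- if (inherits(x, "crisp_set")) "crisp set" else "fuzzy set"
  cat(sprintf("<%s> on %d support points\n", kind, length(x$support)))
  show <- utils::head(seq_along(x$support), 8L)
  cat(paste0("  ", x$support[show], ": ",
             formatC(x$memberships[show], digits = 4, format = "fg"),
             collapse = "\n"), "\n")
  if (length(x$support) > 8L) cat("  ...\n")
  invisible(x)
}

fg_error <- function(msg, class) {
  errorCondition(msg, class = c(class, "fg_error"))
}

is_fuzzy_set <- function(x) inherits(x, "fuzzy_set")

check_shared_support <- function(A, B) {
  if (!is_fuzzy_set(A) || !is_fuzzy_set(B)) {
    stop(fg_error("both arguments must be fuzzy sets", "fg_invalid_input"))
  }
  if (!identical(A$support, B$support)) {
    stop(fg_error("fuzzy sets are defined on different supports",
                  "fg_support_mismatch"))
  }
  invisible(TRUE)
}

#' Normalized Hamming distance between two fuzzy sets
#'
#' The mean absolute membership difference
#' \deqn{d(A,B) = \frac{1}{n}\sum_{i=1}^{n} |\mu_A(x_i) - \mu_B(x_i)|,}
#' the basic distance from which every similarity measure in this package is
#' built. It is a metric on membership vectors over a fixed support and takes
#' values in `[0, 1]`.
#'
#' @param A,B `fuzzy_set` objects on the same support.
#' @return A number in `[0, 1]`; 0 iff the memberships are identical.
#' @export
hamming_distance <- function(A, B) {
  check_shared_support(A, B)
  mean(abs(A$memberships - B$memberships))
}

#' Pointwise set operations on fuzzy sets
#'
#' Standard min/max/complement fuzzy operations: intersection is the
#' pointwise minimum, union the pointwise maximum, and the complement is
#' \eqn{1 - \mu} per element.
#'
#' @param A,B `fuzzy_set` objects on the same support.
#' @return A `fuzzy_set` on the shared support.
#' @export
fs_intersect <- function(A, B) {
  check_shared_support(A, B)
  fuzzy_set(pmin(A$memberships, B$memberships), A$support)
}

#' @rdname fs_intersect
#' @export
fs_union <- function(A, B) {
  check_shared_support(A, B)
  fuzzy_set(pmax(A$memberships, B$memberships), A$support)
}

#' @rdname fs_intersect
#' @export
fs_complement <- function(A) {
  if (!is_fuzzy_set(A)) {
    stop(fg_error("argument must be a fuzzy set", "fg_invalid_input"))
  }
  m <- 1 - A$memberships
  if (all(m %in% c(0, 1))) crisp_set(m, A$support) else fuzzy_set(m, A$support)
}

#' Constant zero and one sets over a support
#'
#' `zero_set()` is the empty set \eqn{[0]_X} (membership 0 everywhere) and
#' `one_set()` the whole universe \eqn{[1]_X} (membership 1 everywhere); they
#' are the reference points of the endpoint-form similarity measure.
#'
#' @param support character vector of unique element identifiers.
#' @return A `crisp_set`.
#' @export
zero_set <- function(support) {
  crisp_set(rep(0, length(support)), support)
}

#' @rdname zero_set
#' @export
one_set <- function(support) {
  crisp_set(rep(1, length(support)), support)
}
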