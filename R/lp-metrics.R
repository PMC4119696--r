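#' Lp (Minkowski) distance between data vectors
#'
#' \deqn{d_p(D_i, D_j) = \left(\sum_{k=1}^{m} |d_{ik} - d_{jk}|^p\right)^{1/p}}
#' for `p >= 1`; `p = Inf` gives the max-component (Chebyshev) distance, the
#' limit of the finite-`p` norms. `p = 1` is the city-block distance, `p = 2`
#' Euclidean.
#'
#' @param x,y numeric vectors of equal dimension `m >= 1`.
#' @param p norm order, `>= 1` or `Inf`.
#' @return Nonnegative distance.
#' @examples
#' lp_distance(c(0, 0), c(3, 4), p = 1)  # 7
#' lp_distance(c(0, 0), c(3, 4), p = 2)  # 5
#' @export
lp_distance <- function(x, y, p = 2) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) == 0L) {
    stop(fg_error("vectors must share a dimension m >= 1",
                  "fg_dimension_mismatch"))
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop(fg_error("vector components must be finite", "fg_invalid_input"))
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1) {
    stop(fg_error("p must be a single number >= 1 (or Inf)",
                  "fg_invalid_input"))
  }
  d <- abs(x - y)
  if (is.infinite(p)) return(max(d))
  if (p == 1) return(sum(d))
  # rescale by the max component for numerical stability at large p
  mx <- max(d)
  if (mx == 0) return(0)
  mx * sum((d / mx)^p)^(1 / p)
}

#' Symmetric unit-diagonal similarity matrix
#'
#' Validating container for pairwise similarity scores: square, symmetric,
#' all entries in `[0, 1]`, diagonal identically 1.
#'
#' @param values numeric `n x n` matrix.
#' @param ids character vector of `n` record identifiers.
#' @param tol symmetry tolerance.
#' @return A `similarity_matrix` (a numeric matrix with dimnames and class).
#' @export
similarity_matrix <- function(values, ids = NULL, tol = 1e-9) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n || n == 0L) {
    stop(fg_error("similarity matrix must be square and non-empty",
                  "fg_invalid_input"))
  }
  if (is.null(ids)) ids <- if (!is.null(rownames(values))) rownames(values)
                           else as.character(seq_len(n))
  if (length(ids) != n || anyDuplicated(ids) > 0L) {
    stop(fg_error("ids must be unique and match the matrix dimension",
                  "fg_invalid_input"))
  }
  if (max(abs(values - t(values))) > tol) {
    stop(fg_error("similarity matrix must be symmetric", "fg_invalid_input"))
  }
  if (any(values < -tol) || any(values > 1 + tol) ||
      max(abs(diag(values) - 1)) > tol) {
    stop(fg_error("entries must lie in [0, 1] with unit diagonal",
                  "fg_invalid_input"))
  }
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d\n", nrow(x), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Pairwise similarity matrix from high-dimensional records
#'
#' Computes all pairwise Lp distances among the rows of `vectors` and maps
#' them onto `[0, 1]` by global min-max scaling over the off-diagonal
#' distances: \deqn{s_{ij} = 1 - d_{ij} / \max_{k,l} d_{kl},} so identical
#' records score 1 and the farthest pair scores 0. The scaling is a
#' documented convention (any monotone map of distance to a unit-diagonal
#' score would do); pass a custom `normalize` function of the distance
#' matrix to replace it.
#'
#' @param vectors numeric matrix (one record per row) or list of equal-length
#'   numeric vectors; at least two records.
#' @param p norm order passed to [lp_distance()].
#' @param on_degenerate what to do when every record is identical (maximum
#'   distance 0): `"error"` (default) or `"ones"` for an all-ones matrix.
#' @param normalize optional function mapping the `n x n` distance matrix to
#'   an `n x n` similarity matrix; overrides the min-max scheme.
#' @return A [similarity_matrix()].
#' @examples
#' m <- rbind(a = 0, b = 1, c = 2)
#' pairwise_similarity(m, p = 1)  # s(a,b) = s(b,c) = 0.5, s(a,c) = 0
#' @export
pairwise_similarity <- function(vectors, p = 2,
                                on_degenerate = c("error", "ones"),
                                normalize = NULL) {
  on_degenerate <- match.arg(on_degenerate)
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 2L) {
    stop(fg_error("need at least two records", "fg_invalid_input"))
  }
  ids <- rownames(vectors)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- lp_distance(vectors[i, ], vectors[j, ], p = p)
    }
  }
  if (!is.null(normalize)) {
    return(similarity_matrix(normalize(D), ids))
  }
  dmax <- max(D)
  if (dmax == 0) {
    if (on_degenerate == "error") {
      stop(fg_error(
        "all records identical: max pairwise distance is 0",
        "fg_degenerate_input"))
    }
    S <- matrix(1, n, n)
  } else {
    S <- 1 - D / dmax
  }
  diag(S) <- 1
  similarity_matrix(S, ids)
}
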