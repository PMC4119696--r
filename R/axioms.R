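#' Empirical check of the similarity-measure axioms
#'
#' A similarity measure `s` on fuzzy sets must satisfy:
#'
#' * **S1** symmetry: `s(A, B) == s(B, A)`;
#' * **S2** a crisp set and its complement are maximally dissimilar:
#'   `s(D, D^c) == 0`;
#' * **S3** self-similarity is maximal over all pairs (for every measure in
#'   this package the maximum is attained and equals 1);
#' * **S4** nesting monotonicity: if `A ⊂ B ⊂ C` (pointwise
#'   `mu_A <= mu_B <= mu_C`) then `s(A,B) >= s(A,C)` and `s(B,C) >= s(A,C)`.
#'
#' `axiom_report()` draws `trials` seeded random pairs plus nested triples
#' (`mu_C ~ U[0,1]`, `mu_B = mu_C u`, `mu_A = mu_B v` with `u, v ~ U[0,1]`
#' pointwise, which guarantees the nesting by construction) and counts
#' violations beyond `tol`.
#'
#' With `type = "singleton"` the same protocol runs on labeled point samples
#' (see [singleton_sample()]): pairs share a common length, nesting is
#' pointwise on the value vectors, and S2 is checked on constant crisp
#' samples (all-ones vs. all-zeros) — the only crisp configuration for which
#' the nonoverlap measure can reach 0; see the methods vignette.
#'
#' @param measure a function of two sets returning a scalar similarity.
#' @param trials number of random draws per axiom (default 1000).
#' @param seed integer seed for reproducibility.
#' @param tol violation tolerance (default `1e-12`; the measures are pure
#'   arithmetic, so no looser tolerance is warranted).
#' @param type `"fuzzy"` to generate `fuzzy_set` pairs, `"singleton"` for
#'   [singleton_sample()] pairs.
#' @param s3 how to test S3 for user-supplied measures: `"one"` requires
#'   `s(C, C) == 1` (true for every built-in measure); `"max"` only requires
#'   `s(C, C)` to be >= every sampled pair value.
#' @param max_support largest support size drawn per trial (sizes are drawn
#'   uniformly in `1:max_support`).
#' @return An object of class `axiom_report`: a list with per-axiom violation
#'   counts, the number of trials, and the first offending example (if any).
#' @examples
#' axiom_report(sim_minmax, trials = 50, seed = 1)
#' @export
axiom_report <- function(measure, trials = 1000, seed = 1, tol = 1e-12,
                         type = c("fuzzy", "singleton"),
                         s3 = c("one", "max"), max_support = 12) {
  if (!is.function(measure)) {
    stop(fg_error("measure must be a function of two sets",
                  "fg_invalid_input"))
  }
  type <- match.arg(type)
  s3 <- match.arg(s3)
  set.seed(as.integer(seed))

  make <- function(m) {
    if (type == "fuzzy") fuzzy_set(m) else singleton_sample(m)
  }
  make_crisp <- function(m) {
    if (type == "fuzzy") crisp_set(m) else singleton_sample(m)
  }
  compl <- function(x) {
    if (type == "fuzzy") fs_complement(x) else
      singleton_sample(1 - x$values, label = x$label)
  }

  viol <- c(S1 = 0L, S2 = 0L, S3 = 0L, S4 = 0L)
  first <- list()
  note <- function(ax, detail) {
    viol[[ax]] <<- viol[[ax]] + 1L
    if (is.null(first[[ax]])) first[[ax]] <<- detail
  }
  self_vals <- numeric(0)
  pair_vals <- numeric(0)

  for (i in seq_len(trials)) {
    n <- sample.int(max_support, 1L)
    a <- stats::runif(n)
    b <- stats::runif(n)
    A <- make(a); B <- make(b)

    sAB <- measure(A, B)
    if (abs(sAB - measure(B, A)) > tol) note("S1", list(a = a, b = b))
    pair_vals <- c(pair_vals, sAB)

    # S2: crisp complement pair. For singleton samples only the constant
    # crisp pair [1]_X vs [0]_X realizes similarity 0 under the nonoverlap
    # measure; for fuzzy sets any crisp vector works.
    d <- if (type == "fuzzy") round(stats::runif(n)) else
      rep(sample(c(0, 1), 1L), n)
    D <- make_crisp(d)
    if (abs(measure(D, compl(D))) > tol) note("S2", list(d = d))

    sCC <- measure(A, A)
    self_vals <- c(self_vals, sCC)
    if (s3 == "one" && abs(sCC - 1) > tol) note("S3", list(c = a))

    # nested triple mu_A <= mu_B <= mu_C by construction
    cc <- stats::runif(n)
    bb <- cc * stats::runif(n)
    aa <- bb * stats::runif(n)
    TA <- make(aa); TB <- make(bb); TC <- make(cc)
    sac <- measure(TA, TC)
    if (measure(TA, TB) < sac - tol || measure(TB, TC) < sac - tol) {
      note("S4", list(a = aa, b = bb, c = cc))
    }
  }
  if (s3 == "max" && length(self_vals) &&
      min(self_vals) < max(pair_vals) - tol) {
    note("S3", list(min_self = min(self_vals), max_pair = max(pair_vals)))
  }

  structure(list(trials = trials, seed = seed, tol = tol, type = type,
                 violations = viol, first_violation = first),
            class = "axiom_report")
}

#' @export
print.axiom_report <- function(x, ...) {
  cat(sprintf("Axiom check: %d trials (%s sets), tol %g\n",
              x$trials, x$type, x$tol))
  for (ax in names(x$violations)) {
    cat(sprintf("  %s: %s\n", ax,
                if (x$violations[[ax]] == 0L) "ok" else
                  sprintf("%d violation(s)", x$violations[[ax]])))
  }
  invisible(x)
}

#' Total number of axiom violations in a report
#' @param report an [axiom_report()] result.
#' @return Integer count over S1-S4.
#' @export
total_violations <- function(report) {
  sum(report$violations)
}
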