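partition_a <- generate_pointsets("disjoint_a")
partition_b <- generate_pointsets("disjoint_b")

test_that("complement_mass reproduces the worked sums", {
  expect_equal(complement_mass(singleton_sample(c(1, 1, 1))), 0)
  # partition A circles: complements sum to 2.4 over six points
  expect_equal(complement_mass(partition_a$circles), 2.4 / 6)
  # partition B diamonds: complements sum to 2.8
  expect_equal(complement_mass(partition_b$diamonds), 2.8 / 6)
  expect_error(singleton_sample(numeric(0)), class = "fg_empty_input")
  expect_error(singleton_sample(c(0.5, 1.2)), class = "fg_invalid_input")
})

test_that("sim_nonoverlap matches the worked examples", {
  expect_equal(round(sim_nonoverlap(partition_b$diamonds,
                                    partition_b$circles), 3), 0.833)
  # partition A from the printed point values: 1 - |2.2 - 2.4| / 6
  expect_equal(sim_nonoverlap(partition_a$diamonds, partition_a$circles),
               1 - 0.2 / 6)
  s <- singleton_sample(c(0.3, 0.6, 0.9))
  expect_equal(sim_nonoverlap(s, s), 1)
})

test_that("conventional measure on disjoint data ignores the partition", {
  va <- sim_conventional_disjoint(partition_a$diamonds, partition_a$circles)
  vb <- sim_conventional_disjoint(partition_b$diamonds, partition_b$circles)
  expect_identical(va, vb)
  expect_equal(round(va, 2), 0.38)
  # any reassignment of the pooled twelve values gives the same score
  pool <- c(partition_a$diamonds$values, partition_a$circles$values)
  set.seed(5)
  for (i in 1:20) {
    k <- sample.int(11, 1)
    idx <- sample.int(12, k)
    v <- sim_conventional_disjoint(singleton_sample(pool[idx]),
                                   singleton_sample(pool[-idx]))
    expect_equal(v, va)
  }
  expect_equal(sim_conventional_disjoint(singleton_sample(rep(0, 3)),
                                         singleton_sample(rep(0, 2))), 1)
})

test_that("the nonoverlap measure does discriminate the two partitions", {
  sa <- sim_nonoverlap(partition_a$diamonds, partition_a$circles)
  sb <- sim_nonoverlap(partition_b$diamonds, partition_b$circles)
  expect_false(isTRUE(all.equal(sa, sb)))
})

test_that("conventional measure equals min-max measure on a 12-point embedding", {
  # embed the two samples as fuzzy sets on a shared support with zero
  # membership off their own points; the min-max measure must agree
  set.seed(9)
  for (i in 1:25) {
    a <- singleton_sample(stats::runif(6))
    b <- singleton_sample(stats::runif(6))
    A <- fuzzy_set(c(a$values, rep(0, 6)))
    B <- fuzzy_set(c(rep(0, 6), b$values))
    expect_equal(sim_conventional_disjoint(a, b), sim_minmax(A, B))
  }
})

test_that("nonoverlap measure properties: symmetry, range, nesting", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample.int(10, 1)
    a <- singleton_sample(stats::runif(n))
    b <- singleton_sample(stats::runif(sample.int(10, 1)))
    s <- sim_nonoverlap(a, b)
    expect_equal(s, sim_nonoverlap(b, a))
    expect_true(s >= 0 && s <= 1)
    # ordered triple A < B < C pointwise
    cc <- stats::runif(n)
    bb <- cc * stats::runif(n)
    aa <- bb * stats::runif(n)
    sac <- sim_nonoverlap(singleton_sample(aa), singleton_sample(cc))
    expect_gte(sim_nonoverlap(singleton_sample(aa), singleton_sample(bb)),
               sac - 1e-12)
    expect_gte(sim_nonoverlap(singleton_sample(bb), singleton_sample(cc)),
               sac - 1e-12)
  }
})

test_that("unequal cardinalities use per-sample normalization", {
  a <- singleton_sample(c(0.2, 0.4))        # mass 0.7
  b <- singleton_sample(c(0.5, 0.5, 0.5))   # mass 0.5
  expect_equal(sim_nonoverlap(a, b), 1 - abs(0.7 - 0.5))
})

test_that("reference_pool records provenance of all samples", {
  pool <- reference_pool(partition_a$diamonds, partition_a$circles)
  expect_length(pool$values, 12)
  expect_identical(pool$labels, c("diamonds", "circles"))
  expect_error(reference_pool(1:3), class = "fg_invalid_input")
})
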