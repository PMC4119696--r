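test_that("select_channels keeps the 24 x/z channels and is idempotent", {
  rec <- make_recording()
  expect_identical(ncol(rec$channels), 36L)
  sel <- select_channels(rec)
  expect_identical(ncol(sel$channels), 24L)
  expect_true(all(grepl("_(x|z)$", colnames(sel$channels))))
  expect_identical(select_channels(sel)$channels, sel$channels)

  broken <- rec
  broken$channels <- rec$channels[, !grepl("_z$", colnames(rec$channels))]
  expect_error(select_channels(broken), class = "fg_missing_channel")
})

test_that("synchronize recovers a known lag and realigns exactly", {
  rec <- make_recording(duration = 8)
  a <- rec; a$channels <- rec$channels[11:400, , drop = FALSE]
  b <- rec; b$channels <- rec$channels[1:390, , drop = FALSE]
  out <- synchronize(list(a, b))
  expect_identical(attr(out, "lags"), c(0L, 10L))
  expect_equal(out[[1]]$channels, out[[2]]$channels)
  expect_identical(nrow(out[[1]]$channels), nrow(out[[2]]$channels))
})

test_that("synchronize on identical and on noise recordings behaves", {
  rec <- make_recording()
  out <- synchronize(list(rec, rec))
  expect_identical(attr(out, "lags"), c(0L, 0L))
  expect_identical(out[[1]]$channels, rec$channels)

  set.seed(55)
  mk_noise <- function() {
    ch <- matrix(stats::rnorm(36 * 200), 200)
    colnames(ch) <- gait_channel_names()
    gait_recording("N", "walking", 50, ch)
  }
  out <- synchronize(list(mk_noise(), mk_noise()))
  lens <- vapply(out, function(r) nrow(r$channels), integer(1))
  expect_identical(lens[1], lens[2])
  expect_lt(abs(attr(out, "lags")[2]), 200)
  expect_error(synchronize(list(rec)), class = "fg_invalid_input")
})

test_that("to_membership rescales to [0, 1] with the constant convention", {
  expect_equal(to_membership(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(to_membership(c(3, 3, 3)), c(0.5, 0.5, 0.5))
  set.seed(3)
  v <- stats::rnorm(100)
  m <- to_membership(v)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(range(m), c(0, 1))
  expect_error(to_membership(numeric(0)), class = "fg_empty_input")
})

test_that("extract_features finds sine peaks and magnitude distances", {
  one_channel_rec <- function(x, rate = 100) {
    ch <- matrix(x, ncol = 1, dimnames = list(NULL, "waist_accelerometer_z"))
    gait_recording("T", "walking", rate, ch)
  }
  t <- seq(0, 5 - 0.01, by = 0.01)
  f5 <- extract_features(one_channel_rec(sin(2 * pi * t)))[[1]]
  expect_length(f5$peaks, 5)
  expect_length(f5$magnitude_distances, 4)
  expect_true(all(abs(f5$magnitude_distances) < 1e-6))
  expect_true(all(abs(f5$peaks - 1) < 1e-3))

  t1 <- seq(0, 1 - 0.01, by = 0.01)
  f1 <- extract_features(one_channel_rec(sin(2 * pi * t1)))[[1]]
  expect_length(f1$peaks, 1)
  expect_length(f1$magnitude_distances, 0)

  flat <- extract_features(one_channel_rec(rep(2, 100)))[[1]]
  expect_length(flat$peaks, 0)

  # plateau: earliest index wins; low-prominence ripple is filtered
  x <- c(0, 1, 1, 1, 0, 0.05, 0.08, 0.05, 0, 2, 0)
  f <- extract_features(one_channel_rec(x), prominence_fraction = 0.1)[[1]]
  expect_equal(f$peaks, c(1, 2))
  expect_error(extract_features(one_channel_rec(x), prominence_fraction = 0),
               class = "fg_invalid_input")
})

test_that("recording_similarity is 1 on identical input and symmetric", {
  a <- make_recording()
  b <- make_recording(freq = 1.4)
  expect_equal(recording_similarity(a, a), 1)
  expect_equal(recording_similarity(a, b), recording_similarity(b, a))
  s <- recording_similarity(a, b)
  expect_true(s >= 0 && s < 1)
  expect_equal(recording_similarity(a, a, mode = "lp"), 1)
})

test_that("single-channel fuzzy similarity reduces to the min-max measure", {
  set.seed(77)
  mk <- function(v) {
    ch <- matrix(v, ncol = 1, dimnames = list(NULL, "c1"))
    gait_recording("T", "walking", 50, ch)
  }
  for (i in 1:20) {
    va <- stats::runif(40); vb <- stats::runif(40)
    s <- recording_similarity(mk(va), mk(vb), preprocess = FALSE)
    expect_equal(s, sim_minmax(fuzzy_set(va), fuzzy_set(vb)))
  }
})

test_that("behavior and person similarity wrap the recording comparison", {
  pr <- make_clone_profile()
  expect_equal(behavior_similarity(pr, "walking", "stair_up"), 1)
  cfg <- small_config()
  co <- generate_cohort(cfg)
  s12 <- person_similarity(co[[1]], co[[2]], "walking")
  expect_equal(s12, person_similarity(co[[2]], co[[1]], "walking"))
  expect_true(s12 >= 0 && s12 <= 1)
  expect_equal(person_similarity(co[[1]], co[[1]], "stair_up"), 1)
  expect_error(behavior_similarity(pr, "walking", "sitting"))
  expect_error(person_similarity(co[[1]], 1), class = "fg_invalid_input")
})

test_that("a one-channel recording ends up contributing its channel score", {
  # all-0 vs all-1 membership on one channel contributes similarity 0
  mk <- function(v) {
    ch <- matrix(v, ncol = 1, dimnames = list(NULL, "c1"))
    gait_recording("T", "walking", 50, ch)
  }
  expect_equal(recording_similarity(mk(rep(0, 30)), mk(rep(1, 30)),
                                    preprocess = FALSE), 0)
})

test_that("similarity_tables on a clone cohort is all ones", {
  cohort <- list(make_clone_profile("A"), make_clone_profile("B"))
  tb <- similarity_tables(cohort)
  expect_true(all(abs(tb$behavior_pairs$similarity - 1) < 1e-12))
  expect_true(all(abs(tb$cross_person$similarity - 1) < 1e-12))
  expect_true(all(tb$person_matrix == 1))
  expect_error(similarity_tables(list()), class = "fg_empty_input")
  expect_error(similarity_tables(cohort[1]), class = "fg_empty_input")
})

test_that("similarity_tables output is well-formed in both modes", {
  co <- generate_cohort(small_config())
  for (mode in c("fuzzy", "lp")) {
    tb <- similarity_tables(co, mode = mode)
    expect_identical(nrow(tb$behavior_pairs), 3L)
    expect_identical(nrow(tb$cross_person), 3L)
    S <- tb$person_matrix
    expect_s3_class(S, "similarity_matrix")
    expect_identical(dim(S), c(3L, 3L))
    expect_true(all(diag(S) == 1))
    expect_equal(unclass(S), unclass(t(S)), ignore_attr = TRUE)
    expect_true(all(tb$behavior_pairs$similarity >= 0 &
                      tb$behavior_pairs$similarity <= 1))
    # per-subject table aggregates to the cohort means
    agg <- stats::aggregate(similarity ~ pair,
                            tb$behavior_pairs_by_subject, mean)
    expect_equal(sort(agg$similarity), sort(tb$behavior_pairs$similarity))
  }
})

test_that("the pipeline is deterministic given fixed inputs", {
  co <- generate_cohort(small_config())
  t1 <- similarity_tables(co)
  t2 <- similarity_tables(co)
  expect_identical(t1$behavior_pairs, t2$behavior_pairs)
  expect_identical(unclass(t1$person_matrix), unclass(t2$person_matrix))
})
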