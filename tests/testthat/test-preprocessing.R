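test_that("feature missingness filter keeps exactly the <= threshold
           columns, boundary included", {
  n <- 100
  miss_counts <- c(0, 5, 10, 11, 50)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  for (j in seq_along(miss_counts))
    if (miss_counts[j] > 0) X[seq_len(miss_counts[j]), j] <- NA
  out <- filter_missing_features(mk_table(X), 0.10)
  expect_identical(colnames(out$features), c("v1", "v2", "v3"))
  expect_identical(attr(out, "dropped"), c("v4", "v5"))

  all_kept <- filter_missing_features(mk_table(X), 1.0)
  expect_identical(colnames(all_kept$features), colnames(X))
})

test_that("feature filter matches a brute-force recount on random
           missingness", {
  set.seed(31)
  n <- 200; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  # mixture of mostly-complete and often-missing features
  rates <- ifelse(runif(p) < 0.5, runif(p, 0, 0.08),
                  runif(p, 0.08, 0.4))
  for (j in seq_len(p)) X[runif(n) < rates[j], j] <- NA
  out <- filter_missing_features(mk_table(X), 0.10)
  brute <- sum(colMeans(is.na(X)) <= 0.10)
  expect_equal(ncol(out$features), brute)
  # idempotent
  again <- filter_missing_features(out, 0.10)
  expect_identical(again$features, out$features)
})

test_that("incomplete-record drop removes exactly the rows with any NA", {
  set.seed(32)
  X <- matrix(rnorm(100), 10, 10)
  clean <- drop_incomplete_records(mk_table(X))
  expect_identical(clean$features, mk_table(X)$features)

  X[1, 2] <- NA; X[4, 7] <- NA; X[9, 1] <- NA
  out <- drop_incomplete_records(mk_table(X))
  expect_equal(nrow(out$features), 7)
  expect_false(anyNA(out$features))

  Y <- matrix(rnorm(500 * 8), 500, 8)
  Y[runif(length(Y)) < 0.05] <- NA
  out2 <- drop_incomplete_records(mk_table(Y))
  expect_equal(nrow(out2$features), sum(rowSums(is.na(Y)) == 0))

  Z <- matrix(NA_real_, 3, 2)
  expect_error(drop_incomplete_records(mk_table(Z)), "every record")
})

test_that("baseline-visit selection keeps each subject's earliest visit", {
  X <- matrix(rnorm(18), 6, 3)
  ids <- c("a", "a", "a", "b", "c", "c")
  dates <- as.Date(c("2012-05-01", "2011-03-02", "2013-01-01",
                     "2010-01-01", "2015-06-01", "2014-12-31"))
  out <- select_baseline_visit(mk_table(X, ids = ids, dates = dates))
  expect_identical(out$subject_id, c("a", "b", "c"))
  expect_identical(out$visit_date,
                   as.Date(c("2011-03-02", "2010-01-01", "2014-12-31")))
  expect_identical(unname(out$features[1, ]), X[2, ])

  single <- mk_table(X[1:3, ], ids = c("x", "y", "z"),
                     dates = dates[1:3])
  expect_identical(select_baseline_visit(single)$features,
                   single$features)
})

test_that("baseline selection matches a per-subject argmin oracle", {
  set.seed(33)
  n_subj <- 100
  visits <- pmax(1, rpois(n_subj, 2))
  ids <- rep(sprintf("p%03d", seq_len(n_subj)), visits)
  dates <- as.Date("2010-01-01") + sample.int(4000, length(ids),
                                              replace = TRUE)
  X <- matrix(rnorm(length(ids) * 2), ncol = 2)
  out <- select_baseline_visit(mk_table(X, ids = ids, dates = dates))
  oracle <- tapply(seq_along(ids), ids, function(ix)
    ix[which.min(dates[ix])])
  oracle <- sort(as.integer(oracle))
  expect_identical(out$features,
                   mk_table(X, ids = ids, dates = dates)$features[
                     oracle, , drop = FALSE])
  # idempotent
  expect_identical(select_baseline_visit(out)$features, out$features)
})

test_that("window merge keeps pairs at the boundary and drops beyond it", {
  mk <- function(name, ids, dates)
    mk_table(matrix(rnorm(length(ids) * 2), ncol = 2),
             name = name, ids = ids, dates = as.Date(dates))
  a <- mk("A", c("s1", "s2", "s3"),
          c("2015-01-01", "2015-01-01", "2015-01-01"))
  b <- mk("B", c("s1", "s2", "s3"),
          c("2015-01-01",                  # gap 0
            as.character(as.Date("2015-01-01") + 548),  # gap = window
            as.character(as.Date("2015-01-01") + 549))) # gap = window+1
  out <- merge_within_window(a, b, 548)
  expect_identical(out$a$subject_id, c("s1", "s2"))
  expect_identical(out$b$subject_id, c("s1", "s2"))
})

test_that("window merge picks the minimal-gap pair and matches a
           brute-force scan", {
  set.seed(34)
  n_subj <- 60
  ids_a <- rep(sprintf("q%02d", 1:n_subj), times = sample(1:3, n_subj,
                                                          TRUE))
  ids_b <- rep(sprintf("q%02d", 1:n_subj), times = sample(1:3, n_subj,
                                                          TRUE))
  dates_a <- as.Date("2012-01-01") + sample.int(2500, length(ids_a),
                                                TRUE)
  dates_b <- as.Date("2012-01-01") + sample.int(2500, length(ids_b),
                                                TRUE)
  a <- mk_table(matrix(rnorm(length(ids_a)), ncol = 1), "A",
                ids = ids_a, dates = dates_a)
  b <- mk_table(matrix(rnorm(length(ids_b)), ncol = 1), "B",
                ids = ids_b, dates = dates_b)
  out <- merge_within_window(a, b, 548)
  # brute force: for every shared subject scan all pairs
  kept <- character(0)
  for (sid in intersect(ids_a, ids_b)) {
    da <- dates_a[ids_a == sid]; db <- dates_b[ids_b == sid]
    gaps <- abs(outer(as.numeric(da), as.numeric(db), "-"))
    if (any(gaps <= 548)) kept <- c(kept, sid)
  }
  expect_setequal(out$a$subject_id, kept)
  expect_identical(out$a$subject_id, out$b$subject_id)
  for (i in seq_along(out$a$subject_id)) {
    sid <- out$a$subject_id[i]
    da <- dates_a[ids_a == sid]; db <- dates_b[ids_b == sid]
    best <- min(abs(outer(as.numeric(da), as.numeric(db), "-")))
    expect_equal(abs(as.numeric(out$a$visit_date[i]) -
                       as.numeric(out$b$visit_date[i])), best)
  }
})

test_that("age filter is strictly greater-than", {
  X <- matrix(rnorm(9), 3, 3)
  out <- filter_age(mk_table(X, age = c(64, 65, 66)), 65)
  expect_equal(out$age, 66)
  all80 <- mk_table(X, age = c(80, 80, 80))
  expect_identical(filter_age(all80, 65)$features, all80$features)
  set.seed(35)
  ages <- runif(200, 55, 95)
  out2 <- filter_age(mk_table(matrix(rnorm(200), ncol = 1),
                              age = ages), 65)
  expect_equal(nrow(out2$features), sum(ages > 65))
})

test_that("binary collapse maps HC to 0 and any impairment to 1", {
  expect_identical(collapse_binary(c("HC", "MCI", "AD")), c(0L, 1L, 1L))
  expect_identical(collapse_binary(rep("HC", 4)), rep(0L, 4))
  set.seed(36)
  labs <- sample(c("HC", "MCI", "AD"), 500, TRUE)
  expect_equal(sum(collapse_binary(labs)), sum(labs != "HC"))
  expect_error(collapse_binary(c("HC", "bad")), "unknown")
})

test_that("the composed pipeline never grows tables and aligns subjects", {
  set.seed(37)
  n_subj <- 120
  mk_raw <- function(name, p) {
    visits <- pmax(1, rpois(n_subj, 1.5))
    ids <- rep(sprintf("r%03d", seq_len(n_subj)), visits)
    X <- matrix(rnorm(length(ids) * p), ncol = p,
                dimnames = list(NULL, paste0(name, seq_len(p))))
    X[runif(length(X)) < 0.04] <- NA
    # a couple of badly-missing features
    X[sample.int(length(ids), length(ids) %/% 3), 1] <- NA
    mk_table(X, name = name, ids = ids,
             dates = as.Date("2011-01-01") +
               sample.int(2000, length(ids), TRUE),
             age = round(runif(length(ids), 60, 90)))
  }
  a <- mk_raw("U", 8); b <- mk_raw("M", 6)
  labels <- setNames(sample(c("HC", "MCI", "AD"), n_subj, TRUE),
                     sprintf("r%03d", seq_len(n_subj)))
  res <- preprocess_pair(a, b, labels)
  rep_ <- res$report
  for (mod in unique(rep_$modality)) {
    sub <- rep_[rep_$modality == mod, ]
    expect_true(all(diff(sub$rows) <= 0))
    expect_true(all(diff(sub$features) <= 0))
  }
  co <- res$cohort
  expect_identical(co$modalities[[1]]$subject_id,
                   co$modalities[[2]]$subject_id)
  expect_equal(length(co$labels), nrow(co$modalities[[1]]$features))
  expect_false(anyNA(co$modalities[[1]]$features))
})
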