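test_that("the split plan defaults match the evaluation protocol", {
  plan <- split_plan()
  expect_equal(plan$train_fraction, 0.75)
  expect_equal(plan$n_repeats, 50L)
  expect_true(plan$stratified)
  expect_error(split_plan(train_fraction = 1), "train_fraction")
  expect_error(split_plan(n_repeats = 1), "n_repeats")
})

test_that("splits are reproducible, shared across callers, and
           stratified", {
  labs <- factor(rep(c("HC", "MCI", "AD"), times = c(60, 25, 15)),
                 levels = c("HC", "MCI", "AD"))
  plan <- split_plan(n_repeats = 5, base_seed = 8)
  s1 <- draw_split(plan, labs, 3)
  s2 <- draw_split(plan, labs, 3)
  expect_identical(s1, s2)
  expect_equal(length(s1$train), 75)
  expect_equal(as.numeric(table(labs[s1$train])), c(45, 19, 11))
  expect_setequal(c(s1$train, s1$test), seq_along(labs))
})

test_that("the confidence interval follows the normal-approximation
           formula", {
  ci <- confidence_interval(c(0.7, 0.8, 0.9))
  expect_equal(ci[1], 0.8 - 1.96 * 0.1 / sqrt(3), tolerance = 1e-12)
  expect_equal(round(ci, 4), c(0.6868, 0.9132))
  expect_equal(confidence_interval(rep(0.8, 10)), c(0.8, 0.8))
  expect_error(confidence_interval(0.5), "at least 2")
})

test_that("CI half-width shrinks as one over the square root of the
           repeat count", {
  set.seed(60)
  ratios <- replicate(200, {
    accs <- rnorm(200, 0.8, 0.05)
    w1 <- diff(confidence_interval(accs[1:50]))
    w4 <- diff(confidence_interval(accs))
    w4 / w1
  })
  expect_equal(mean(ratios), 0.5, tolerance = 0.05)
})

test_that("significance is CI non-overlap", {
  mk <- function(lo, hi) structure(
    list(name = "x", spec = NULL, per_split_accuracies = c(lo, hi),
         mean_accuracy = (lo + hi) / 2, ci_low = lo, ci_high = hi),
    class = "eval_result")
  expect_true(significantly_different(mk(0.80, 0.82), mk(0.83, 0.85)))
  expect_false(significantly_different(mk(0.80, 0.84), mk(0.83, 0.85)))
  r <- mk(0.8, 0.9)
  expect_false(significantly_different(r, r))
})

test_that("majority vote picks the modal label with the stated tie
           rules", {
  expect_equal(as.character(majority_vote(
    cbind(c("AD", "HC"), c("AD", "HC"), c("HC", "HC")))),
    c("AD", "HC"))
  expect_equal(as.character(majority_vote(
    cbind(rep("MCI", 3), rep("MCI", 3), rep("MCI", 3)))),
    rep("MCI", 3))
  # 3-way tie broken by training prevalence HC > MCI > AD
  prev <- c(HC = 0.6, MCI = 0.3, AD = 0.1)
  expect_equal(as.character(majority_vote(
    cbind("HC", "MCI", "AD"), levels = c("HC", "MCI", "AD"),
    prevalence = prev)), "HC")
  # without prevalence, label order wins
  expect_equal(as.character(majority_vote(
    cbind("MCI", "AD", "HC"), levels = c("HC", "MCI", "AD"))), "HC")
  expect_error(majority_vote(cbind(character(0))), "member")
})

test_that("repeated-split evaluation is deterministic and a
           signal-free cohort scores at the majority rate", {
  co <- small_cohort(n = 150, seed = 61)
  plan <- split_plan(n_repeats = 6, base_seed = 12)
  sp <- pipeline_spec("single", "UDS",
                      reducer_spec("PCA", n_components = 3),
                      "logistic", "binary", seed = 1)
  r1 <- repeated_split_evaluate(sp, co, plan)
  r2 <- repeated_split_evaluate(sp, co, plan)
  expect_identical(r1$per_split_accuracies, r2$per_split_accuracies)
  expect_true(r1$ci_low <= r1$mean_accuracy &&
                r1$mean_accuracy <= r1$ci_high)

  flat <- small_cohort(n = 400, seed = 62,
                       signal_weights = c(0, 0),
                       class_thresholds = c(0.34, 0.94))
  rf <- repeated_split_evaluate(
    pipeline_spec("single", "UDS",
                  reducer_spec("PCA", n_components = 3),
                  "logistic", "binary", seed = 1),
    flat, split_plan(n_repeats = 8, base_seed = 3))
  majority <- max(table(collapse_binary(flat$labels))) / 400
  expect_lt(abs(rf$mean_accuracy - majority), 0.08)
})

test_that("the 95% interval covers a known mean at the nominal rate", {
  set.seed(63)
  hits <- replicate(400, {
    accs <- rbinom(50, 100, 0.8) / 100
    ci <- confidence_interval(accs)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("ensembles share splits with their members and match a vote
           recount", {
  co <- small_cohort(n = 150, seed = 64)
  plan <- split_plan(n_repeats = 4, base_seed = 9)
  pca <- pipeline_spec("single", "UDS",
                       reducer_spec("PCA", n_components = 3),
                       "logistic", "binary", seed = 1, name = "pca")
  lasso <- pipeline_spec("single", "UDS",
                         reducer_spec("LASSO",
                                      lambda_grid = 0.05),
                         "logistic", "binary", seed = 1,
                         name = "lasso")
  # degenerate ensemble: identical members vote like the single model
  same <- evaluate_ensemble(ensemble_spec(list(pca, pca, pca)),
                            co, plan)
  alone <- repeated_split_evaluate(pca, co, plan)
  expect_identical(same$per_split_accuracies,
                   alone$per_split_accuracies)

  # manual recount on one repeat for a mixed ensemble
  ens <- evaluate_ensemble(ensemble_spec(list(pca, pca, lasso)),
                           co, plan)
  sp1 <- draw_split(plan, co$labels, 1)
  votes <- lapply(list(pca, pca, lasso), function(ms) {
    fp <- fit_pipeline(ms, co, sp1$train,
                       seed = substream_seed(ms$seed, 5001L))
    as.character(predict(fp, co, sp1$test))
  })
  truth <- collapse_binary(co$labels)[sp1$test]
  manual <- vapply(seq_along(sp1$test), function(i) {
    v <- c(votes[[1]][i], votes[[2]][i], votes[[3]][i])
    names(sort(table(v), decreasing = TRUE))[1]
  }, "")
  expect_equal(ens$per_split_accuracies[1],
               mean(as.integer(manual) == truth))
})

test_that("model ranking sorts by mean, then CI width, then name", {
  mk <- function(name, m, half) structure(
    list(name = name, spec = NULL,
         per_split_accuracies = numeric(2),
         mean_accuracy = m, ci_low = m - half, ci_high = m + half),
    class = "eval_result")
  res <- list(mk("b", 0.85, 0.01), mk("a", 0.90, 0.02),
              mk("c", 0.85, 0.03), mk("d", 0.85, 0.01))
  ranked <- rank_models(res)
  expect_equal(ranked$name, c("a", "b", "d", "c"))
  set.seed(65)
  res2 <- lapply(1:12, function(i)
    mk(sprintf("m%02d", i), runif(1, 0.5, 0.95), runif(1, 0.005,
                                                       0.05)))
  shuffled <- sample(res2)
  ranked2 <- rank_models(shuffled, top_k = 12)
  ord <- order(-vapply(res2, `[[`, 0, "mean_accuracy"))
  expect_equal(ranked2$name,
               vapply(res2, `[[`, "", "name")[ord])
  expect_equal(nrow(rank_models(shuffled, top_k = 5)), 5)
})
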