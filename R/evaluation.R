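#' Repeated random-split evaluation plan
#'
#' Protocol defaults: 75% training / 25% testing, 50 random repeats,
#' stratified by class so that no training split loses a class at
#' three-class cohort sizes in the low thousands.
#'
#' @param train_fraction proportion of subjects used for training.
#' @param n_repeats number of random splits (>= 2).
#' @param base_seed integer seed; repeat `r` uses an independent
#'   substream derived from it, so the same plan always produces the
#'   same sequence of partitions (shared across every pipeline
#'   evaluated under it, making comparisons paired).
#' @param stratified draw splits stratified by class (default `TRUE`).
#' @return an object of class `split_plan`.
#' @export
split_plan <- function(train_fraction = 0.75, n_repeats = 50L,
                       base_seed = 1L, stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    config_stop("train_fraction must be strictly between 0 and 1")
  if (n_repeats < 2L) config_stop("n_repeats must be at least 2")
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 stratified = isTRUE(stratified)),
            class = "split_plan")
}

#' Draw the train/test partition for one repeat of a plan
#'
#' @param plan a [split_plan()].
#' @param labels the cohort's label factor (stratification variable).
#' @param repeat_id which repeat (1-based).
#' @return list with integer vectors `train` and `test`.
#' @export
draw_split <- function(plan, labels, repeat_id) {
  n <- length(labels)
  seed <- substream_seed(plan$base_seed, 1000L + repeat_id)
  attempt <- 0L
  repeat {
    train <- with_seed(seed + attempt, {
      if (plan$stratified) {
        idx <- unlist(lapply(split(seq_len(n), labels), function(g) {
          if (!length(g)) return(integer(0))
          k <- max(1L, round(plan$train_fraction * length(g)))
          g[sample.int(length(g), k)]
        }), use.names = FALSE)
        sort(idx)
      } else {
        sort(sample.int(n, max(1L, round(plan$train_fraction * n))))
      }
    })
    if (plan$stratified ||
        all(table(labels[train]) > 0L) || attempt >= 25L) break
    warning(sprintf(
      "repeat %d: a class was absent from the training split; redrawn",
      repeat_id), call. = FALSE)
    attempt <- attempt + 1L
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Normal-approximation 95% confidence interval for split accuracies
#'
#' `mean +/- 1.96 * sd / sqrt(R)` over the `R` per-split accuracies,
#' clipped to `[0, 1]`.
#'
#' @param accs vector of at least two per-split accuracies.
#' @return numeric `c(low, high)`.
#' @export
confidence_interval <- function(accs) {
  if (length(accs) < 2L)
    config_stop("confidence_interval needs at least 2 values")
  m <- mean(accs)
  half <- 1.96 * sd(accs) / sqrt(length(accs))
  c(max(0, m - half), min(1, m + half))
}

new_eval_result <- function(name, spec, accs) {
  ci <- confidence_interval(accs)
  structure(list(name = name, spec = spec,
                 per_split_accuracies = accs,
                 mean_accuracy = mean(accs),
                 ci_low = ci[1L], ci_high = ci[2L]),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s: %.3f (%.3f, %.3f) over %d splits\n", x$name,
              x$mean_accuracy, x$ci_low, x$ci_high,
              length(x$per_split_accuracies)))
  invisible(x)
}

#' Evaluate a pipeline under repeated random splits
#'
#' For each repeat the plan's partition is drawn, the pipeline is
#' fitted on the training rows (with a repeat-specific seed substream),
#' and test accuracy is recorded.  Fully reproducible from
#' `plan$base_seed` and `spec$seed`.
#'
#' @param spec a [pipeline_spec()].
#' @param cohort a [labeled_cohort()].
#' @param plan a [split_plan()].
#' @return an `eval_result` with per-split accuracies, mean, and 95%
#'   confidence interval.
#' @export
repeated_split_evaluate <- function(spec, cohort, plan) {
  accs <- vapply(seq_len(plan$n_repeats), function(r) {
    sp <- draw_split(plan, cohort$labels, r)
    fp <- fit_pipeline(spec, cohort, sp$train,
                       seed = substream_seed(spec$seed, 5000L + r))
    pipeline_accuracy(fp, cohort, sp$test)
  }, numeric(1))
  new_eval_result(spec$name, spec, accs)
}

#' Are two results significantly different?
#'
#' Non-overlapping 95% confidence intervals are read as a significant
#' performance difference at p < 0.05.
#'
#' @param a,b `eval_result` objects from the same plan.
#' @return logical flag.
#' @export
significantly_different <- function(a, b) {
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}

#' Majority vote over member predictions
#'
#' Per subject, the modal label wins.  Ties are broken by training-set
#' class prevalence (most prevalent first), then by label order.
#'
#' @param member_predictions matrix or data frame of labels, one column
#'   per ensemble member, or a list of equal-length prediction factors.
#' @param levels label level set (defaults to the union of observed
#'   values, in order of appearance of `levels()` when available).
#' @param prevalence optional named numeric vector of training class
#'   prevalence used for tie-breaks.
#' @return factor of winning labels.
#' @export
majority_vote <- function(member_predictions, levels = NULL,
                          prevalence = NULL) {
  if (is.list(member_predictions) && !is.data.frame(member_predictions))
    member_predictions <- do.call(cbind,
                                  lapply(member_predictions, as.character))
  P <- as.matrix(member_predictions)
  if (!nrow(P) || !ncol(P)) config_stop("no member predictions")
  if (ncol(P) < 2L) config_stop("majority vote needs >= 2 members")
  mode(P) <- "character"
  levels <- levels %||% sort(unique(as.vector(P)))
  # tie-break priority: prevalence rank first, then label order
  prio <- if (is.null(prevalence)) seq_along(levels)
          else order(-as.numeric(prevalence[levels]), seq_along(levels))
  prio_rank <- match(seq_along(levels), prio)
  winners <- apply(P, 1L, function(v) {
    counts <- table(factor(v, levels = levels))
    top <- which(counts == max(counts))
    levels[top[which.min(prio_rank[top])]]
  })
  factor(winners, levels = levels)
}

#' Specify a voting ensemble
#'
#' @param members list of >= 2 [pipeline_spec()]s sharing one task.
#' @param name ensemble identifier.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(members, name = "ensemble") {
  if (length(members) < 2L)
    config_stop("an ensemble needs at least 2 members")
  tasks <- unique(vapply(members, `[[`, "", "task"))
  if (length(tasks) != 1L)
    config_stop("ensemble members must share one task")
  structure(list(members = members, task = tasks, name = name),
            class = "ensemble_spec")
}

#' Evaluate a voting ensemble under repeated random splits
#'
#' Within each repeat all members are fitted on the identical training
#' partition (the shared-split contract that makes the vote
#' meaningful); ensemble accuracy is the accuracy of the per-subject
#' majority vote on the shared test partition.
#'
#' @param espec an [ensemble_spec()].
#' @param cohort a [labeled_cohort()].
#' @param plan a [split_plan()].
#' @return an `eval_result`.
#' @export
evaluate_ensemble <- function(espec, cohort, plan) {
  stopifnot(inherits(espec, "ensemble_spec"))
  task <- espec$task
  lev <- levels(task_labels(cohort$labels, task))
  accs <- vapply(seq_len(plan$n_repeats), function(r) {
    sp <- draw_split(plan, cohort$labels, r)
    truth <- task_labels(cohort$labels, task)[sp$test]
    prevalence <- table(task_labels(cohort$labels, task)[sp$train])
    votes <- lapply(espec$members, function(ms) {
      fp <- fit_pipeline(ms, cohort, sp$train,
                         seed = substream_seed(ms$seed, 5000L + r))
      predict(fp, cohort, sp$test)
    })
    mean(majority_vote(votes, levels = lev,
                       prevalence = prevalence) == truth)
  }, numeric(1))
  new_eval_result(espec$name, espec, accs)
}

#' Rank evaluation results by mean accuracy
#'
#' Descending mean accuracy; ties broken by narrower confidence
#' interval, then by name.
#'
#' @param results list of `eval_result` objects.
#' @param top_k how many rows to return (default: all).
#' @return data frame with columns `name`, `mean_accuracy`, `ci_low`,
#'   `ci_high`.
#' @export
rank_models <- function(results, top_k = length(results)) {
  if (!length(results)) config_stop("no results to rank")
  df <- data.frame(
    name = vapply(results, `[[`, "", "name"),
    mean_accuracy = vapply(results, `[[`, 0, "mean_accuracy"),
    ci_low = vapply(results, `[[`, 0, "ci_low"),
    ci_high = vapply(results, `[[`, 0, "ci_high"),
    stringsAsFactors = FALSE)
  width <- df$ci_high - df$ci_low
  ord <- order(-df$mean_accuracy, width, df$name)
  out <- df[ord, , drop = FALSE][seq_len(min(top_k, nrow(df))), ,
                                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation feature importance on raw features
#'
#' For each original input feature, the mean decrease in test accuracy
#' over `n_perm` independent within-column shuffles.  Permutation is
#' applied to the raw feature values *before* standardization and
#' dimensionality reduction, so importances attach to the original
#' named features of each modality.
#'
#' @param pipeline a fitted pipeline.
#' @param cohort the [labeled_cohort()] it consumes.
#' @param test_index rows on which accuracy is measured.
#' @param n_perm number of shuffles per feature (>= 1).
#' @param seed RNG seed for the shuffles.
#' @return data frame of class `importance_report`: `feature`,
#'   `modality`, `mean_importance`, `sd`, `rank` (1 = most important).
#' @export
permutation_importance <- function(pipeline, cohort, test_index,
                                   n_perm = 20L, seed = 1L) {
  stopifnot(inherits(pipeline, "fitted_pipeline"))
  if (n_perm < 1L) config_stop("n_perm must be at least 1")
  truth <- task_labels(cohort$labels, pipeline$spec$task)[test_index]
  base_acc <- mean(predict(pipeline, cohort, test_index) == truth)
  rows <- list()
  with_seed(seed, {
    for (nm in pipeline$spec$modalities) {
      feats <- colnames(cohort$modalities[[nm]]$features)
      for (j in seq_along(feats)) {
        drops <- vapply(seq_len(n_perm), function(k) {
          perm_cohort <- cohort
          col <- perm_cohort$modalities[[nm]]$features[test_index, j]
          perm_cohort$modalities[[nm]]$features[test_index, j] <-
            col[sample.int(length(col))]
          acc <- mean(predict(pipeline, perm_cohort, test_index) ==
                        truth)
          base_acc - acc
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feats[j], modality = nm,
          mean_importance = mean(drops),
          sd = if (n_perm > 1L) sd(drops) else 0,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$mean_importance, ties.method = "min")
  class(out) <- c("importance_report", "data.frame")
  out
}
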