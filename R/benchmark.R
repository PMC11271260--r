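# Grid driver: enumerate the study's pipeline grid over two modalities,
# evaluate every model and voting ensemble under one shared split plan,
# and emit machine-readable result tables.

#' Enumerate the standard pipeline grid
#'
#' Builds the 51-model grid over two modalities: for each single
#' modality, 12 models (4 DR methods x {binary logistic, multiclass
#' random forest, multiclass neural net}); 3 simple-fusion models (no
#' DR); 12 early-fusion and 12 intermediate-fusion models.
#'
#' @param modalities character vector of exactly two modality names.
#' @param dr_methods DR methods to cross (default all four).
#' @param reducer_args list of arguments forwarded to [reducer_spec()]
#'   for every method (e.g. `list(epochs = 50)`).
#' @param config a [classifier_config()].
#' @param seed base seed stored in every spec.
#' @return list of [pipeline_spec()]s.
#' @export
pipeline_grid <- function(modalities,
                          dr_methods = c("PCA", "AE", "LASSO", "SE"),
                          reducer_args = list(),
                          config = classifier_config(),
                          seed = 1L) {
  if (length(modalities) != 2L)
    config_stop("pipeline_grid expects exactly two modalities")
  rs <- function(method) do.call(
    reducer_spec, c(list(method = method, seed = seed), reducer_args))
  tasks <- list(list(task = "binary", classifier = "logistic"),
                list(task = "multiclass", classifier = "random_forest"),
                list(task = "multiclass", classifier = "neural_net"))
  specs <- list()
  add <- function(spec) specs[[length(specs) + 1L]] <<- spec
  for (m in modalities)
    for (dr in dr_methods)
      for (tc in tasks)
        add(pipeline_spec("single", m, rs(dr), tc$classifier, tc$task,
                          seed = seed, config = config,
                          name = paste(m, dr, tc$classifier, tc$task,
                                       sep = "_")))
  for (tc in tasks)
    add(pipeline_spec("simple", modalities, NULL, tc$classifier,
                      tc$task, seed = seed, config = config,
                      name = paste("simple", "none", tc$classifier,
                                   tc$task, sep = "_")))
  for (topo in c("early", "intermediate"))
    for (dr in dr_methods)
      for (tc in tasks)
        add(pipeline_spec(topo, modalities,
                          if (topo == "early") rs(dr)
                          else rep(list(rs(dr)), 2L),
                          tc$classifier, tc$task,
                          seed = seed, config = config,
                          name = paste(topo, dr, tc$classifier,
                                       tc$task, sep = "_")))
  specs
}

# pipeline "family" used for ensemble grouping: single modality name,
# or the fusion topology
spec_family <- function(spec) {
  if (spec$topology == "single") spec$modalities else spec$topology
}

spec_dr <- function(spec) {
  if (is.null(spec$reducer)) "none"
  else if (is.list(spec$reducer) &&
           !inherits(spec$reducer, "reducer_spec"))
    spec$reducer[[1L]]$method
  else spec$reducer$method
}

#' Run the full benchmark: grid, ensembles, ranking
#'
#' Evaluates every spec under the shared split plan.  Within each
#' repeat, every model is fitted once on the identical training
#' partition; voting ensembles are computed from those same fitted
#' members (one binary and one multiclass ensemble per pipeline family,
#' where at least two members exist).  Fit seeds follow the same
#' substream scheme as [repeated_split_evaluate()], so single-model
#' numbers agree exactly with that function.
#'
#' @param specs list of [pipeline_spec()]s (e.g. [pipeline_grid()]).
#' @param cohort a [labeled_cohort()].
#' @param plan a [split_plan()].
#' @return list with `results` (list of `eval_result`, models then
#'   ensembles), `table` (data frame: one row per model), and
#'   `comparisons` (pairwise CI non-overlap flags within task).
#' @export
run_benchmark <- function(specs, cohort, plan) {
  n_specs <- length(specs)
  names(specs) <- vapply(specs, `[[`, "", "name")
  acc <- matrix(NA_real_, plan$n_repeats, n_specs,
                dimnames = list(NULL, names(specs)))
  # ensemble membership: per (family, task), all grid members
  fam <- vapply(specs, spec_family, "")
  task <- vapply(specs, `[[`, "", "task")
  groups <- split(seq_len(n_specs), paste(fam, task, sep = "."))
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  ens_acc <- matrix(NA_real_, plan$n_repeats, length(groups),
                    dimnames = list(NULL, paste0("ensemble_",
                                                 names(groups))))
  for (r in seq_len(plan$n_repeats)) {
    sp <- draw_split(plan, cohort$labels, r)
    preds <- vector("list", n_specs)
    for (i in seq_len(n_specs)) {
      fp <- fit_pipeline(specs[[i]], cohort, sp$train,
                         seed = substream_seed(specs[[i]]$seed,
                                               5000L + r))
      preds[[i]] <- predict(fp, cohort, sp$test)
      truth <- task_labels(cohort$labels, specs[[i]]$task)[sp$test]
      acc[r, i] <- mean(preds[[i]] == truth)
    }
    for (g in seq_along(groups)) {
      members <- groups[[g]]
      gtask <- task[members[1L]]
      truth <- task_labels(cohort$labels, gtask)[sp$test]
      prevalence <- table(task_labels(cohort$labels, gtask)[sp$train])
      ens_acc[r, g] <- mean(majority_vote(
        preds[members], levels = levels(truth),
        prevalence = prevalence) == truth)
    }
  }
  results <- c(
    lapply(seq_len(n_specs), function(i)
      new_eval_result(names(specs)[i], specs[[i]], acc[, i])),
    lapply(seq_along(groups), function(g)
      new_eval_result(colnames(ens_acc)[g],
                      list(task = task[groups[[g]][1L]],
                           members = names(specs)[groups[[g]]]),
                      ens_acc[, g])))
  tab <- data.frame(
    name = vapply(results, `[[`, "", "name"),
    family = c(fam, sub("\\.(binary|multiclass)$", "",
                        names(groups))),
    topology = c(vapply(specs, `[[`, "", "topology"),
                 rep("ensemble", length(groups))),
    dr = c(vapply(specs, spec_dr, ""), rep("vote", length(groups))),
    classifier = c(vapply(specs, `[[`, "", "classifier"),
                   rep("vote", length(groups))),
    task = c(task, task[vapply(groups, `[`, 0L, 1L)]),
    mean_accuracy = vapply(results, `[[`, 0, "mean_accuracy"),
    ci_low = vapply(results, `[[`, 0, "ci_low"),
    ci_high = vapply(results, `[[`, 0, "ci_high"),
    stringsAsFactors = FALSE)
  comp <- compare_results(results)
  list(results = results, table = tab, comparisons = comp)
}

# pairwise CI non-overlap flags for results sharing a task
compare_results <- function(results) {
  task_of <- function(res)
    if (inherits(res$spec, "pipeline_spec")) res$spec$task
    else res$spec$task
  rows <- list()
  for (i in seq_along(results))
    for (j in seq_along(results))
      if (i < j && task_of(results[[i]]) == task_of(results[[j]]))
        rows[[length(rows) + 1L]] <- data.frame(
          a = results[[i]]$name, b = results[[j]]$name,
          task = task_of(results[[i]]),
          significant = significantly_different(results[[i]],
                                                results[[j]]),
          stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# full-precision numeric formatting so result tables round-trip and
# reruns can be compared bitwise
format_full <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  df
}

#' Write benchmark outputs to a directory
#'
#' Emits `results.csv` (one row per model/ensemble), `comparisons.csv`
#' (pairwise non-overlap flags), `ranking.csv` (top-k per task), and a
#' `manifest.json` recording the plan, seeds, and package version, so
#' a rerun from the same manifest reproduces `results.csv` bitwise.
#'
#' @param bench a [run_benchmark()] result.
#' @param out_dir output directory (created if needed).
#' @param plan the [split_plan()] used.
#' @param top_k rows per task in the ranking table.
#' @param extra optional named list merged into the manifest.
#' @return invisibly, the paths written.
#' @export
write_benchmark <- function(bench, out_dir, plan, top_k = 10L,
                            extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res_path <- file.path(out_dir, "results.csv")
  write.csv(format_full(bench$table), res_path, row.names = FALSE,
            quote = FALSE)
  cmp_path <- file.path(out_dir, "comparisons.csv")
  write.csv(bench$comparisons, cmp_path, row.names = FALSE,
            quote = FALSE)
  rank_path <- file.path(out_dir, "ranking.csv")
  ranked <- do.call(rbind, lapply(split(
    seq_along(bench$results),
    vapply(bench$results, function(r)
      if (inherits(r$spec, "pipeline_spec")) r$spec$task
      else r$spec$task, "")),
    function(idx) {
      df <- rank_models(bench$results[idx], top_k)
      df$task <- if (inherits(bench$results[[idx[1L]]]$spec,
                              "pipeline_spec"))
        bench$results[[idx[1L]]]$spec$task
      else bench$results[[idx[1L]]]$spec$task
      df
    }))
  write.csv(format_full(ranked), rank_path, row.names = FALSE,
            quote = FALSE)
  manifest <- c(list(
    package = "fusebench",
    version = as.character(utils::packageVersion("fusebench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    plan = unclass(plan),
    n_models = length(bench$results)), extra)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(res_path, cmp_path, rank_path, man_path))
}
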