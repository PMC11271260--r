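#' Specify an end-to-end classification pipeline
#'
#' A pipeline combines a fusion topology, an optional dimensionality
#' reducer (one per modality for intermediate fusion), a classifier,
#' and a task:
#' * `single` -- one modality, reduce, classify;
#' * `simple` -- concatenate raw modality features, classify (no DR);
#' * `early`  -- concatenate, fit one reducer on the concatenation,
#'   classify its output;
#' * `intermediate` -- fit one reducer per modality, concatenate the
#'   reduced representations, classify.
#'
#' The binary task (HC vs any impairment) uses logistic regression; the
#' multiclass task (HC/MCI/AD) uses a random forest or neural network.
#'
#' @param topology one of `"single"`, `"simple"`, `"early"`,
#'   `"intermediate"`.
#' @param modalities character vector of modality names, in
#'   concatenation order.
#' @param reducer a [reducer_spec()] (`single`/`early`), a list of one
#'   spec per modality (`intermediate`; a single spec is recycled), or
#'   `NULL` (`simple`).
#' @param classifier `"logistic"`, `"random_forest"`, or
#'   `"neural_net"`.
#' @param task `"binary"` or `"multiclass"`.
#' @param seed integer seed driving every random stage of the fit.
#' @param config a [classifier_config()].
#' @param name optional identifier (defaults to a descriptive slug).
#' @return an object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(topology = c("single", "simple", "early",
                                       "intermediate"),
                          modalities,
                          reducer = NULL,
                          classifier = c("logistic", "random_forest",
                                         "neural_net"),
                          task = c("binary", "multiclass"),
                          seed = 1L,
                          config = classifier_config(),
                          name = NULL) {
  topology <- match.arg(topology)
  classifier <- match.arg(classifier)
  task <- match.arg(task)
  modalities <- as.character(modalities)
  if (topology == "single" && length(modalities) != 1L)
    config_stop("single topology takes exactly one modality")
  if (topology != "single" && length(modalities) < 2L)
    config_stop(sprintf("%s topology needs at least two modalities",
                        topology))
  if (task == "binary" && classifier != "logistic")
    config_stop("the binary task uses the logistic classifier")
  if (task == "multiclass" && classifier == "logistic")
    config_stop(
      "the multiclass task uses random_forest or neural_net")
  if (topology == "simple") {
    if (!is.null(reducer))
      config_stop("simple fusion takes no reducer")
  } else if (topology == "intermediate") {
    if (inherits(reducer, "reducer_spec"))
      reducer <- rep(list(reducer), length(modalities))
    if (!is.list(reducer) || length(reducer) != length(modalities) ||
        !all(vapply(reducer, inherits, TRUE, "reducer_spec")))
      config_stop(
        "intermediate fusion needs one reducer_spec per modality")
  } else {
    if (!inherits(reducer, "reducer_spec"))
      config_stop(sprintf("%s topology needs exactly one reducer_spec",
                          topology))
  }
  name <- name %||% paste(
    c(topology,
      if (!is.null(reducer))
        unique(vapply(if (inherits(reducer, "reducer_spec"))
          list(reducer) else reducer, `[[`, "", "method")),
      paste(modalities, collapse = "+"), classifier, task),
    collapse = "_")
  structure(
    list(topology = topology, modalities = modalities,
         reducer = reducer, classifier = classifier, task = task,
         seed = as.integer(seed), config = config, name = name),
    class = "pipeline_spec")
}

# concatenate the named modality blocks of a cohort into one matrix,
# recording which modality each column came from
concat_modalities <- function(cohort, modality_names) {
  blocks <- lapply(modality_names, function(nm) {
    if (is.null(cohort$modalities[[nm]]))
      data_stop(sprintf("cohort has no modality '%s'", nm))
    cohort$modalities[[nm]]$features
  })
  X <- do.call(cbind, blocks)
  attr(X, "modality_of") <- rep(modality_names,
                                vapply(blocks, ncol, 0L))
  X
}

#' Fit a pipeline on a training subset of a cohort
#'
#' All fitting (standardization moments, reducers, penalty tuning,
#' network weights, classifier) is restricted to `train_index` rows.
#'
#' @param spec a [pipeline_spec()].
#' @param cohort a [labeled_cohort()] containing all modalities named
#'   in the spec.
#' @param train_index integer row indices of the training subjects
#'   (default: all rows).
#' @param seed overrides `spec$seed` for this fit (used by the repeated
#'   split protocol to give each repeat its own substream).
#' @return an object of class `fitted_pipeline`; apply it with
#'   [predict()].
#' @export
fit_pipeline <- function(spec, cohort, train_index = NULL,
                         seed = NULL) {
  stopifnot(inherits(spec, "pipeline_spec"),
            inherits(cohort, "labeled_cohort"))
  train_index <- train_index %||% seq_len(n_subjects(cohort))
  if (!length(train_index)) config_stop("train_index is empty")
  seed <- seed %||% spec$seed
  y <- task_labels(cohort$labels, spec$task)[train_index]

  reducers <- NULL
  if (spec$topology %in% c("single", "intermediate")) {
    # shared code path: a single modality is the singleton case of
    # intermediate fusion
    rspecs <- if (spec$topology == "single") list(spec$reducer)
              else spec$reducer
    reducers <- vector("list", length(spec$modalities))
    names(reducers) <- spec$modalities
    reduced <- vector("list", length(spec$modalities))
    for (i in seq_along(spec$modalities)) {
      nm <- spec$modalities[i]
      Xm <- cohort$modalities[[nm]]$features[train_index, ,
                                             drop = FALSE]
      rs <- rspecs[[i]]
      rs$seed <- substream_seed(seed, 10L + i)
      reducers[[nm]] <- fit_reducer(rs, Xm, y)
      reduced[[i]] <- predict(reducers[[nm]], Xm)
    }
    H <- do.call(cbind, reduced)
  } else {
    Xc <- concat_modalities(cohort, spec$modalities)
    Xtr <- Xc[train_index, , drop = FALSE]
    if (spec$topology == "early") {
      rs <- spec$reducer
      rs$seed <- substream_seed(seed, 10L)
      reducers <- list(fit_reducer(rs, Xtr, y))
      names(reducers) <- "fused"
      H <- predict(reducers[[1L]], Xtr)
    } else {
      H <- Xtr
    }
  }

  # reduced blocks are re-standardized jointly before classification so
  # that no modality's scale dominates the classifier
  clf_std <- fit_standardizer(H)
  Hs <- apply_standardizer(clf_std, H)
  clf <- fit_classifier(spec$classifier, Hs, y, spec$config,
                        seed = substream_seed(seed, 1L))

  col_map <- lapply(spec$modalities, function(nm)
    colnames(cohort$modalities[[nm]]$features))
  names(col_map) <- spec$modalities

  structure(
    list(spec = spec, reducers = reducers, clf = clf,
         clf_std = clf_std,
         train_prevalence = table(y) / length(y),
         column_map = col_map),
    class = "fitted_pipeline")
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat(sprintf("<fitted_pipeline> %s\n", x$spec$name))
  invisible(x)
}

# map cohort rows through the fitted reducers to the classifier input
pipeline_features <- function(object, cohort, index) {
  spec <- object$spec
  if (spec$topology %in% c("single", "intermediate")) {
    H <- do.call(cbind, lapply(spec$modalities, function(nm) {
      Xm <- cohort$modalities[[nm]]$features[index, , drop = FALSE]
      predict(object$reducers[[nm]], Xm)
    }))
  } else {
    Xc <- concat_modalities(cohort, spec$modalities)[index, ,
                                                     drop = FALSE]
    H <- if (spec$topology == "early")
      predict(object$reducers[[1L]], Xc) else Xc
  }
  apply_standardizer(object$clf_std, H)
}

#' Predict diagnosis labels with a fitted pipeline
#'
#' Deterministic given the fitted pipeline: applies the stored
#' standardization, reducers, and classifier.
#'
#' @param object a `fitted_pipeline`.
#' @param cohort a [labeled_cohort()] carrying the spec's modalities.
#' @param index integer row indices to predict (default: all rows).
#' @param ... unused.
#' @return a factor of predicted labels on the task's level set
#'   (`0`/`1` for binary, `HC`/`MCI`/`AD` for multiclass).
#' @export
predict.fitted_pipeline <- function(object, cohort, index = NULL, ...) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  index <- index %||% seq_len(n_subjects(cohort))
  Hs <- pipeline_features(object, cohort, index)
  predict_classifier(object$clf, Hs)
}

#' Pipeline accuracy on an index set
#'
#' @param object a `fitted_pipeline`.
#' @param cohort a [labeled_cohort()].
#' @param index rows to score.
#' @return proportion of correct predictions.
#' @export
pipeline_accuracy <- function(object, cohort, index) {
  truth <- task_labels(cohort$labels, object$spec$task)[index]
  mean(predict(object, cohort, index) == truth)
}
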