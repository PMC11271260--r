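# Classifier stage shared by all pipeline topologies.  The binary task
# uses L2-regularized logistic regression; the multiclass task uses a
# random forest or a feed-forward neural network.  Hyperparameters the
# study design leaves open are collected in classifier_config().

#' Classifier hyperparameters
#'
#' @param logistic_lambda ridge penalty of the logistic classifier
#'   (fixed, not tuned).
#' @param rf_trees number of random-forest trees.
#' @param nn_hidden hidden-layer widths of the neural-net classifier.
#' @param nn_epochs,nn_learning_rate,nn_batch_size neural-net training
#'   settings.
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(logistic_lambda = 1e-2,
                              rf_trees = 500L,
                              nn_hidden = c(64L, 32L),
                              nn_epochs = 100L,
                              nn_learning_rate = 0.01,
                              nn_batch_size = 32L) {
  structure(list(logistic_lambda = logistic_lambda,
                 rf_trees = as.integer(rf_trees),
                 nn_hidden = as.integer(nn_hidden),
                 nn_epochs = as.integer(nn_epochs),
                 nn_learning_rate = nn_learning_rate,
                 nn_batch_size = as.integer(nn_batch_size)),
            class = "classifier_config")
}

# glmnet requires >= 2 predictor columns; a one-dimensional input
# (e.g. LASSO kept a single feature) is padded with a constant zero
# column, which cannot influence the fit
pad_one_col <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, .pad = 0)
}

# X: standardized training matrix; y: task-coded factor
fit_classifier <- function(classifier, X, y, config, seed) {
  lev <- levels(y)
  padded <- ncol(X) < 2L
  if (padded) X <- pad_one_col(X)
  fit <- switch(classifier,
    logistic = {
      if (length(lev) != 2L)
        config_stop("logistic classifier requires the binary task")
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = config$logistic_lambda,
                     standardize = FALSE)
    },
    random_forest = with_seed(seed,
      randomForest::randomForest(x = X, y = y,
                                 ntree = config$rf_trees)),
    neural_net = with_seed(seed,
      mlp_train(X, one_hot(y),
                sizes = c(ncol(X), config$nn_hidden, length(lev)),
                output = "softmax",
                epochs = config$nn_epochs,
                lr = config$nn_learning_rate,
                batch_size = config$nn_batch_size)),
    config_stop(sprintf("unknown classifier '%s'", classifier)))
  list(classifier = classifier, fit = fit, levels = lev,
       padded = padded)
}

predict_classifier <- function(model, X) {
  lev <- model$levels
  if (isTRUE(model$padded)) X <- pad_one_col(X)
  out <- switch(model$classifier,
    logistic = {
      p <- as.numeric(predict(model$fit, newx = X, type = "response"))
      lev[(p > 0.5) + 1L]
    },
    random_forest = as.character(predict(model$fit, newdata = X)),
    neural_net = {
      P <- mlp_forward(model$fit, X)[[length(model$fit$weights) + 1L]]
      lev[max.col(P, ties.method = "first")]
    })
  factor(out, levels = lev)
}
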