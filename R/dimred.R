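# Shared fit/transform contract for the four dimensionality-reduction
# methods: PCA, LASSO feature selection, denoising autoencoder (AE),
# and supervised encoder (SE).  Every reducer stores the z-scoring
# moments of its training split and re-applies them (never refits) when
# transforming new data.

# ---- standardization ------------------------------------------------

# column z-scoring moments; constant training columns get unit divisor
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2L, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  list(mean = mu, sd = sigma)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2L, std$mean, "-"), 2L, std$sd, "/")
}

#' Specify a dimensionality-reduction method
#'
#' @param method one of `"PCA"`, `"AE"`, `"LASSO"`, `"SE"`.
#' @param n_components output dimension: number of principal-component
#'   scores (PCA, default 8), bottleneck width (AE, default 4; SE,
#'   default 10).  Ignored by LASSO, whose output dimension is its
#'   nonzero-coefficient count.
#' @param lambda_grid LASSO penalty grid.  `NULL` (default) lets glmnet
#'   build its own path; a single value fixes the penalty; several
#'   values are tuned by 5-fold cross-validation on the training split.
#' @param noise_sd sd of the Gaussian input corruption used by the
#'   denoising AE (default 0.1, on z-scored inputs).
#' @param hidden_widths widths of the dense ReLU layers before the
#'   bottleneck.  AE default `32` (mirrored in the decoder); SE default
#'   `c(64, 32)`.
#' @param epochs training epoch budget for AE/SE (default 100; early
#'   stopping on a 10% validation carve-out may end training sooner).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param batch_size mini-batch size (default 32).
#' @param seed integer seed driving all network randomness and the
#'   LASSO cross-validation folds.
#' @return an object of class `reducer_spec`.
#' @export
reducer_spec <- function(method = c("PCA", "AE", "LASSO", "SE"),
                         n_components = NULL,
                         lambda_grid = NULL,
                         noise_sd = 0.1,
                         hidden_widths = NULL,
                         epochs = 100L,
                         learning_rate = 0.01,
                         batch_size = 32L,
                         seed = 1L) {
  method <- match.arg(method)
  n_components <- n_components %||%
    switch(method, PCA = 8L, AE = 4L, SE = 10L, LASSO = NA_integer_)
  hidden_widths <- hidden_widths %||%
    switch(method, AE = 32L, SE = c(64L, 32L), integer(0))
  if (method != "LASSO" && (!is.finite(n_components) || n_components < 1L))
    config_stop("n_components must be at least 1")
  if (epochs < 1L) config_stop("epochs must be at least 1")
  structure(
    list(method = method,
         n_components = as.integer(n_components),
         lambda_grid = lambda_grid,
         noise_sd = as.numeric(noise_sd),
         hidden_widths = as.integer(hidden_widths),
         epochs = as.integer(epochs),
         learning_rate = as.numeric(learning_rate),
         batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "reducer_spec")
}

#' Fit a dimensionality reducer on training data
#'
#' Fits the method described by `spec` on the rows of `X` (raw scale;
#' z-scoring moments are estimated here and stored).  Supervised
#' methods (LASSO, SE) require `y`; unsupervised methods (PCA, AE)
#' ignore it.
#'
#' @param spec a [reducer_spec()].
#' @param X numeric training matrix (subjects x features).
#' @param y training labels: a factor for SE; for LASSO either a
#'   numeric target or a diagnosis factor, which is coded ordinally
#'   (HC = 0, MCI = 1, AD = 2) to respect disease ordering.
#' @return an object of class `fitted_reducer`; apply it with
#'   [predict()] (the transform).
#' @export
fit_reducer <- function(spec, X, y = NULL) {
  stopifnot(inherits(spec, "reducer_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  switch(spec$method,
         PCA = fit_pca(X, spec),
         LASSO = fit_lasso(X, y, spec),
         AE = fit_denoising_ae(X, spec),
         SE = fit_supervised_encoder(X, y, spec))
}

new_fitted_reducer <- function(method, spec, std, output_dim,
                               feature_names, params) {
  structure(
    list(method = method, spec = spec, std = std,
         output_dim = as.integer(output_dim),
         feature_names = feature_names, params = params,
         version = 1L),
    class = "fitted_reducer")
}

#' @export
print.fitted_reducer <- function(x, ...) {
  cat(sprintf("<fitted_reducer %s> %d features -> %d components\n",
              x$method, length(x$feature_names), x$output_dim))
  invisible(x)
}

# ---- PCA ------------------------------------------------------------

fit_pca <- function(X, spec) {
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  q <- spec$n_components
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  tol <- max(dim(Z)) * .Machine$double.eps * pc$sdev[1L]
  rank_x <- sum(pc$sdev > max(tol, 1e-12))
  if (q > rank_x)
    config_stop(sprintf("n_components = %d exceeds rank(X) = %d",
                        q, rank_x))
  W <- pc$rotation[, seq_len(q), drop = FALSE]
  # deterministic sign: largest-magnitude element of each loading
  # vector is positive
  for (j in seq_len(q)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  new_fitted_reducer(
    "PCA", spec, std, q, colnames(X),
    list(loadings = W,
         eigenvalues = pc$sdev[seq_len(q)]^2,
         explained_variance_ratio = evr))
}

#' Pick a component count at the knee of a scree curve
#'
#' Applies the maximum-distance-to-chord rule to the cumulative
#' explained-variance curve anchored at the origin (zero components
#' explain zero variance): the knee is the index whose point on the
#' cumulative curve lies farthest from the straight line joining
#' `(0, 0)` to the curve's last point.  When every point lies on the
#' chord (a single component or a perfectly flat spectrum) the
#' convention is to return 1.
#'
#' @param explained_variance_ratios nonincreasing vector of per-
#'   component explained-variance ratios summing to at most 1.
#' @return integer knee index in `[1, length(ratios)]`.
#' @export
choose_components_knee <- function(explained_variance_ratios) {
  r <- explained_variance_ratios
  if (any(diff(r) > 1e-8))
    config_stop("explained_variance_ratios must be nonincreasing")
  K <- length(r)
  if (K == 1L) return(1L)
  cum <- cumsum(r)
  dx <- K
  dy <- cum[K]
  k <- seq_len(K)
  dist <- abs(dy * k - dx * cum) / sqrt(dx^2 + dy^2)
  if (max(dist) < 1e-12) return(1L)
  which.max(dist)
}

# ---- LASSO ----------------------------------------------------------

# numeric coding of the supervision target for the penalized regression
lasso_target <- function(y) {
  if (is.numeric(y)) return(as.numeric(y))
  y <- as.character(y)
  if (all(y %in% DIAGNOSIS_LEVELS))
    return(as.numeric(match(y, DIAGNOSIS_LEVELS) - 1L))
  if (all(y %in% c("0", "1"))) return(as.numeric(y))
  data_stop("cannot code LASSO target: need numeric or diagnosis labels")
}

fit_lasso <- function(X, y, spec) {
  if (is.null(y)) config_stop("LASSO is supervised: y is required")
  yn <- lasso_target(y)
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  grid <- spec$lambda_grid

  if (!is.null(grid) && length(grid) == 1L && grid[1L] == 0) {
    # exact least-squares limit of the penalized objective
    fit <- lm.fit(cbind(1, Z), yn)
    beta <- fit$coefficients[-1L]
    beta[is.na(beta)] <- 0
    lambda <- 0
  } else if (!is.null(grid) && length(grid) == 1L) {
    fit <- glmnet::glmnet(Z, yn, alpha = 1, lambda = grid,
                          standardize = FALSE)
    beta <- as.numeric(coef(fit, s = grid))[-1L]
    lambda <- grid
  } else {
    foldid <- with_seed(spec$seed, sample(rep_len(1:5, nrow(Z))))
    cv <- glmnet::cv.glmnet(Z, yn, alpha = 1, lambda = grid,
                            foldid = foldid, standardize = FALSE)
    lambda <- cv$lambda.min
    beta <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
  }
  selected <- which(beta != 0)
  if (!length(selected))
    config_stop(paste0(
      "LASSO selected no features at lambda = ",
      format(lambda), "; supply a grid with smaller penalties"))
  new_fitted_reducer(
    "LASSO", spec, std, length(selected), colnames(X),
    list(selected = selected, coefficients = beta[selected],
         lambda = lambda))
}

#' Coefficient path along a penalty grid
#'
#' Utility for inspecting sparsity: number of nonzero LASSO
#' coefficients at each value of a penalty grid, on the standardized
#' training data.
#'
#' @param X numeric training matrix.
#' @param y supervision target (see [fit_reducer()]).
#' @param lambda_grid decreasing vector of penalties.
#' @return integer vector of nonzero counts, one per grid value.
#' @export
lasso_path_nonzero <- function(X, y, lambda_grid) {
  yn <- lasso_target(y)
  Z <- apply_standardizer(fit_standardizer(X), as.matrix(X))
  fit <- glmnet::glmnet(Z, yn, alpha = 1,
                        lambda = sort(lambda_grid, decreasing = TRUE),
                        standardize = FALSE)
  counts <- colSums(as.matrix(fit$beta) != 0)
  stats::setNames(as.integer(counts), format(fit$lambda))
}

# ---- denoising autoencoder -----------------------------------------

fit_denoising_ae <- function(X, spec) {
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  p <- ncol(Z)
  hw <- spec$hidden_widths
  sizes <- c(p, hw, spec$n_components, rev(hw), p)
  bottleneck <- length(hw) + 1L
  net <- with_seed(spec$seed,
    mlp_train(Z, Z, sizes, output = "linear",
              linear_layers = bottleneck,
              epochs = spec$epochs, lr = spec$learning_rate,
              batch_size = spec$batch_size,
              corrupt_sd = spec$noise_sd))
  new_fitted_reducer(
    "AE", spec, std, spec$n_components, colnames(X),
    list(net = net, bottleneck = bottleneck,
         train_loss = net$train_loss))
}

# ---- supervised encoder --------------------------------------------

fit_supervised_encoder <- function(X, y, spec) {
  if (is.null(y)) config_stop("SE is supervised: y is required")
  p <- ncol(X)
  if (spec$n_components >= p)
    config_stop(sprintf(
      "bottleneck width %d is not a reduction of %d features",
      spec$n_components, p))
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  Y <- one_hot(y)
  hw <- spec$hidden_widths
  sizes <- c(p, hw, spec$n_components, ncol(Y))
  bottleneck <- length(hw) + 1L
  net <- with_seed(spec$seed,
    mlp_train(Z, Y, sizes, output = "softmax",
              linear_layers = bottleneck,
              epochs = spec$epochs, lr = spec$learning_rate,
              batch_size = spec$batch_size))
  new_fitted_reducer(
    "SE", spec, std, spec$n_components, colnames(X),
    list(net = net, bottleneck = bottleneck,
         train_loss = net$train_loss))
}

# ---- transform ------------------------------------------------------

#' Transform new data with a fitted reducer
#'
#' Applies the training-split standardization moments (never refit)
#' followed by the fitted projection, selection, or encoding.  LASSO is
#' a feature *selection*: its output is the selected columns of the raw
#' input, so downstream reports keep the original feature semantics.
#'
#' @param object a `fitted_reducer`.
#' @param newdata numeric matrix with the training feature count and
#'   order.
#' @param ... unused.
#' @return an `n x output_dim` numeric matrix.
#' @export
predict.fitted_reducer <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$feature_names))
    data_stop(sprintf("expected %d features, got %d",
                      length(object$feature_names), ncol(X)))
  switch(object$method,
    PCA = {
      Z <- apply_standardizer(object$std, X)
      S <- Z %*% object$params$loadings
      colnames(S) <- paste0("PC", seq_len(ncol(S)))
      S
    },
    LASSO = X[, object$params$selected, drop = FALSE],
    AE = ,
    SE = {
      Z <- apply_standardizer(object$std, X)
      S <- mlp_layer_output(object$params$net, Z,
                            object$params$bottleneck)
      colnames(S) <- paste0(tolower(object$method),
                            seq_len(ncol(S)))
      S
    })
}

# ---- serialization --------------------------------------------------

# type-tagged JSON encoding: doubles are written as "%.17g" strings so
# the round trip is bit-exact (plain JSON number printing loses the
# last bits of a double)
encode_payload <- function(x) {
  if (is.double(x)) {
    list(`_type` = "dbl", v = sprintf("%.17g", as.vector(x)),
         dim = dim(x), names = names(x), dimnames = dimnames(x))
  } else if (is.integer(x)) {
    list(`_type` = "int", v = as.vector(x), dim = dim(x),
         names = names(x))
  } else if (is.list(x)) {
    lapply(x, encode_payload)
  } else x
}

decode_payload <- function(x) {
  if (is.list(x) && !is.null(x$`_type`))
    x$`_type` <- unlist(x$`_type`)
  as_num <- function(v, mode) {
    v <- unlist(v)
    v[v %in% c("NA", "NaN")] <- NA
    if (mode == "int") as.integer(v) else as.numeric(v)
  }
  if (is.list(x) && identical(x$`_type`, "dbl")) {
    v <- as_num(x$v, "dbl")
    if (!is.null(x$dim)) {
      v <- array(v, dim = unlist(x$dim))
      if (!is.null(x$dimnames)) dimnames(v) <- x$dimnames
    } else if (!is.null(x$names)) names(v) <- unlist(x$names)
    v
  } else if (is.list(x) && identical(x$`_type`, "int")) {
    v <- as_num(x$v, "int")
    if (!is.null(x$dim)) v <- array(v, dim = unlist(x$dim))
    else if (!is.null(x$names)) names(v) <- unlist(x$names)
    v
  } else if (is.list(x)) {
    out <- lapply(x, decode_payload)
    # unnamed lists of atomic scalars are plain vectors (JSON arrays)
    if (is.null(names(out)) &&
        (!length(out) || all(vapply(out, function(e)
          is.atomic(e) && length(e) == 1L, TRUE))))
      out <- unlist(out)
    out
  } else x
}

#' Save / load a fitted reducer
#'
#' Serializes a fitted reducer (method, spec, standardization moments,
#' and all fitted parameters) to a versioned JSON file at full double
#' precision, so a reloaded reducer produces bit-identical transforms.
#'
#' @param reducer a `fitted_reducer`.
#' @param path file path.
#' @return `write_reducer` returns `path` invisibly; `read_reducer`
#'   returns the restored `fitted_reducer`.
#' @export
write_reducer <- function(reducer, path) {
  stopifnot(inherits(reducer, "fitted_reducer"))
  payload <- unclass(reducer)
  payload$spec <- unclass(payload$spec)
  jsonlite::write_json(encode_payload(payload), path,
                       auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' @rdname write_reducer
#' @export
read_reducer <- function(path) {
  raw <- decode_payload(jsonlite::read_json(path,
                                            simplifyVector = FALSE))
  spec <- structure(raw$spec, class = "reducer_spec")
  if (!length(spec$lambda_grid)) spec$lambda_grid <- NULL
  new_fitted_reducer(raw$method, spec, raw$std,
                     raw$output_dim, raw$feature_names, raw$params)
}
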