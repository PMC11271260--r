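#' Configuration for the synthetic multimodal cohort generator
#'
#' The generator draws a one-dimensional latent disease-severity score
#' `z ~ N(0, 1)` per subject, assigns a three-class diagnosis by
#' thresholding a noisy copy of `z`, and emits one feature block per
#' modality in which the first `n_informative` features load on `z`
#' while shared within-modality nuisance factors induce
#' multicollinearity.  Defaults emulate the shape of a merged
#' clinical-plus-volumetric-MRI cohort: 1,419 subjects with feature
#' blocks of 90 and 157 and class masses of roughly 63% HC / 19% MCI /
#' 17% AD.
#'
#' The label mechanism is probit-style: with label noise sd `s`, the
#' thresholded variable is `u = (z + s * eta) / sqrt(1 + s^2)` with
#' `eta ~ N(0, 1)`, so `u` is standard normal and the class masses are
#' exactly the normal-CDF masses implied by `class_thresholds` for any
#' `s`.  With `s = 0` labels are a deterministic function of `z`.
#'
#' @param n_subjects number of subjects.
#' @param block_dims integer vector, features per modality.
#' @param modality_names names for the blocks (default UDS/MRI style).
#' @param signal_weights per-modality loading magnitude of the latent on
#'   each informative feature (unitless).
#' @param n_informative per-modality count of features carrying latent
#'   signal; informative features are the first `n_informative` columns
#'   of each block (recorded in the output).
#' @param nuisance_factors per-modality count of shared nuisance latents
#'   (drives within-block multicollinearity; independent across
#'   modalities).
#' @param nuisance_sd standard deviation of the nuisance loadings.
#' @param noise_sd residual feature noise standard deviation.
#' @param class_thresholds two strictly increasing cut-points on the
#'   standard-normal label axis separating HC/MCI and MCI/AD.
#' @param label_noise_sd sd `s` of the Gaussian label noise.
#' @param missing_rate per-entry probability of a
#'   missing-completely-at-random feature value.
#' @param seed integer seed; every random stage (latent, label noise,
#'   nuisance loadings, residual noise, missingness) uses an independent
#'   substream derived from it, so changing e.g. `missing_rate` does not
#'   perturb the latent draw.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1419,
                          block_dims = c(90, 157),
                          modality_names = NULL,
                          signal_weights = c(0.55, 0.45),
                          n_informative = c(20, 30),
                          nuisance_factors = c(6, 10),
                          nuisance_sd = 0.6,
                          noise_sd = 1,
                          class_thresholds = c(0.34, 0.94),
                          label_noise_sd = 0.25,
                          missing_rate = 0,
                          seed = 1L) {
  k <- length(block_dims)
  if (is.null(modality_names))
    modality_names <- if (k == 2L) c("UDS", "MRI")
                      else paste0("mod", seq_len(k))
  expand <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, k)
    if (length(x) != k)
      config_stop(sprintf("'%s' must have length 1 or %d", nm, k))
    x
  }
  signal_weights <- expand(signal_weights, "signal_weights")
  n_informative <- expand(n_informative, "n_informative")
  nuisance_factors <- expand(nuisance_factors, "nuisance_factors")
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         block_dims = as.integer(block_dims),
         modality_names = as.character(modality_names),
         signal_weights = as.numeric(signal_weights),
         n_informative = as.integer(n_informative),
         nuisance_factors = as.integer(nuisance_factors),
         nuisance_sd = as.numeric(nuisance_sd),
         noise_sd = as.numeric(noise_sd),
         class_thresholds = as.numeric(class_thresholds),
         label_noise_sd = as.numeric(label_noise_sd),
         missing_rate = as.numeric(missing_rate),
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is.finite(cfg$n_subjects) || cfg$n_subjects < 1L)
    config_stop("n_subjects must be a positive integer")
  if (any(cfg$block_dims < 1L))
    config_stop("block_dims must all be positive")
  if (any(cfg$n_informative < 0L) ||
      any(cfg$n_informative > cfg$block_dims))
    config_stop("n_informative must satisfy 0 <= n_informative <= block_dims")
  if (any(cfg$nuisance_factors < 0L))
    config_stop("nuisance_factors must be non-negative")
  if (cfg$noise_sd < 0) config_stop("noise_sd must be non-negative")
  if (cfg$nuisance_sd < 0) config_stop("nuisance_sd must be non-negative")
  if (length(cfg$class_thresholds) != 2L ||
      diff(cfg$class_thresholds) <= 0)
    config_stop("class_thresholds must be two strictly increasing values")
  if (cfg$label_noise_sd < 0)
    config_stop("label_noise_sd must be non-negative")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    config_stop("missing_rate must satisfy 0 <= missing_rate < 1")
  invisible(cfg)
}

# substream ids: one block of ids per random stage; modality-specific
# stages are offset by the modality index so blocks are independent
.stream <- list(latent = 0L, label_noise = 1L,
                loadings = 100L, noise = 200L, missing = 300L)

# nuisance loading matrix for modality m (r x p), drawn from its own
# substream so it is shared between generate_cohort() and the Bayes
# reference
draw_loadings <- function(cfg, m) {
  r <- cfg$nuisance_factors[m]
  p <- cfg$block_dims[m]
  if (r == 0L) return(matrix(0, 0L, p))
  with_seed(substream_seed(cfg$seed, .stream$loadings + m),
            matrix(rnorm(r * p, sd = cfg$nuisance_sd), r, p))
}

# latent signal loading vector for modality m (length p, deterministic)
signal_vector <- function(cfg, m) {
  w <- numeric(cfg$block_dims[m])
  k <- cfg$n_informative[m]
  if (k > 0L) w[seq_len(k)] <- cfg$signal_weights[m]
  w
}

# threshold standard-normal u against the class cut-points
threshold_labels <- function(u, thresholds) {
  DIAGNOSIS_LEVELS[findInterval(u, thresholds) + 1L]
}

#' Generate a synthetic multimodal cohort
#'
#' Draws a cohort from the generative model described in
#' [cohort_config()].  Fully reproducible: the same config (including
#' its seed) always yields bitwise-identical matrices.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort` with fields
#'   `modalities` (list of [modality_table()], containing `NA` entries
#'   when `missing_rate > 0`), `labels` (diagnosis factor), `latent`
#'   (the per-subject severity score `z`), `informative` (per-modality
#'   informative column indices), and `config`.
#' @seealso [as_labeled_cohort()], [bayes_reference_accuracy()]
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_subjects

  z <- with_seed(substream_seed(cfg$seed, .stream$latent), rnorm(n))
  s <- cfg$label_noise_sd
  u <- if (s > 0) {
    eta <- with_seed(substream_seed(cfg$seed, .stream$label_noise),
                     rnorm(n))
    (z + s * eta) / sqrt(1 + s^2)
  } else z
  labels <- threshold_labels(u, cfg$class_thresholds)

  modalities <- vector("list", length(cfg$block_dims))
  informative <- vector("list", length(cfg$block_dims))
  for (m in seq_along(cfg$block_dims)) {
    p <- cfg$block_dims[m]
    w <- signal_vector(cfg, m)
    B <- draw_loadings(cfg, m)
    X <- tcrossprod(z, w)
    if (nrow(B) > 0L) {
      Fm <- with_seed(substream_seed(cfg$seed, .stream$loadings + m + 50L),
                      matrix(rnorm(n * nrow(B)), n, nrow(B)))
      X <- X + Fm %*% B
    }
    if (cfg$noise_sd > 0)
      X <- X + with_seed(substream_seed(cfg$seed, .stream$noise + m),
                         matrix(rnorm(n * p, sd = cfg$noise_sd), n, p))
    if (cfg$missing_rate > 0) {
      mask <- with_seed(substream_seed(cfg$seed, .stream$missing + m),
                        runif(n * p) < cfg$missing_rate)
      X[matrix(mask, n, p)] <- NA_real_
    }
    colnames(X) <- sprintf("%s_f%03d", cfg$modality_names[m], seq_len(p))
    modalities[[m]] <- modality_table(
      subject_id = sprintf("S%05d", seq_len(n)),
      features = X,
      modality_name = cfg$modality_names[m])
    informative[[m]] <- seq_len(cfg$n_informative[m])
  }
  names(modalities) <- cfg$modality_names
  names(informative) <- cfg$modality_names

  structure(
    list(modalities = modalities,
         labels = factor(labels, levels = DIAGNOSIS_LEVELS),
         latent = z,
         informative = informative,
         config = cfg),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, blocks: %s\n",
              x$config$n_subjects,
              paste(sprintf("%s(%d)", x$config$modality_names,
                            x$config$block_dims), collapse = ", ")))
  print(table(x$labels))
  invisible(x)
}

#' Convert a synthetic cohort to a labeled cohort
#'
#' @param sc a [generate_cohort()] result.  Must be free of missing
#'   entries; cohorts generated with `missing_rate > 0` must first go
#'   through the preprocessing filters.
#' @return a [labeled_cohort()].
#' @export
as_labeled_cohort <- function(sc) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  labeled_cohort(sc$modalities, sc$labels)
}

#' Bayes-optimal reference accuracy for a synthetic configuration
#'
#' Monte-Carlo estimate of the accuracy achieved by the Bayes-optimal
#' classifier that knows the generative model (including the realized
#' nuisance loadings drawn from the config's seed).  Serves as an upper
#' bound when judging how much latent signal a fitted pipeline
#' recovers.  Operates on complete data: missingness is ignored.
#'
#' Under the linear-Gaussian model the posterior mean of `z` given all
#' features is a linear score with `E[mu | z] = z * SNR / (1 + SNR)` and
#' `Var(mu | z) = SNR / (1 + SNR)^2`, where
#' `SNR = sum_m w_m' Sigma_m^{-1} w_m` and
#' `Sigma_m = B_m' B_m + noise_sd^2 I`.  The Bayes rule thresholds the
#' posterior class probabilities derived from `mu`, so accuracy can be
#' estimated by Monte Carlo without simulating the feature matrices.
#'
#' @param config a [cohort_config()].
#' @param n_mc number of Monte-Carlo draws (>= 1000).
#' @param seed RNG seed for the Monte-Carlo draw (independent of the
#'   cohort seed; defaults to a substream of it).
#' @return estimated accuracy in `[0, 1]`.
#' @export
bayes_reference_accuracy <- function(config, n_mc = 100000L, seed = NULL) {
  validate_cohort_config(config)
  cfg <- config
  if (n_mc < 1000L) config_stop("n_mc must be at least 1000")
  seed <- seed %||% substream_seed(cfg$seed, 999L)
  s <- cfg$label_noise_sd
  thr <- cfg$class_thresholds

  snr <- 0
  exact <- FALSE
  for (m in seq_along(cfg$block_dims)) {
    w <- signal_vector(cfg, m)
    if (all(w == 0)) next
    if (cfg$noise_sd == 0) { exact <- TRUE; break }
    B <- draw_loadings(cfg, m)
    Sigma <- crossprod(B) + diag(cfg$noise_sd^2, cfg$block_dims[m])
    snr <- snr + drop(crossprod(w, solve(Sigma, w)))
  }

  with_seed(seed, {
    z <- rnorm(n_mc)
    u <- if (s > 0) (z + s * rnorm(n_mc)) / sqrt(1 + s^2) else z
    truth <- threshold_labels(u, thr)
    if (exact) {
      mu <- z
      v <- 0
    } else if (snr == 0) {
      # uninformative features: predict the largest prior mass
      masses <- diff(c(0, pnorm(thr), 1))
      return(max(masses))
    } else {
      a <- snr / (1 + snr)
      mu <- a * z + rnorm(n_mc, sd = sqrt(snr) / (1 + snr))
      v <- 1 / (1 + snr)
    }
    # posterior over u given mu: u | X ~ N(mu / sqrt(1+s^2), (v + s^2)/(1+s^2))
    m_u <- mu / sqrt(1 + s^2)
    sd_u <- sqrt((v + s^2) / (1 + s^2))
    pred <- if (sd_u == 0) {
      threshold_labels(m_u, thr)
    } else {
      p1 <- pnorm((thr[1] - m_u) / sd_u)
      p2 <- pnorm((thr[2] - m_u) / sd_u) - p1
      p3 <- 1 - p1 - p2
      DIAGNOSIS_LEVELS[max.col(cbind(p1, p2, p3), ties.method = "first")]
    }
    mean(pred == truth)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes one CSV per modality (`subject_id` plus features, full double
#' precision), a `labels.csv` (`subject_id`, `diagnosis`, `latent`), and
#' a JSON sidecar holding the complete configuration, so the trio can be
#' read back losslessly with [read_cohort()].
#'
#' @param sc a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(sc, dir) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in sc$modalities) {
    df <- data.frame(subject_id = m$subject_id, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(m$features)))
      df[[colnames(m$features)[j]]] <-
        sprintf("%.17g", m$features[, j])
    path <- file.path(dir, paste0(m$modality_name, ".csv"))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  lab_path <- file.path(dir, "labels.csv")
  write.csv(data.frame(subject_id = sc$modalities[[1L]]$subject_id,
                       diagnosis = as.character(sc$labels),
                       latent = sprintf("%.17g", sc$latent)),
            lab_path, row.names = FALSE, quote = FALSE)
  cfg_path <- file.path(dir, "cohort_config.json")
  jsonlite::write_json(unclass(sc$config), cfg_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, lab_path, cfg_path))
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param dir directory holding the modality CSVs, `labels.csv`, and
#'   `cohort_config.json`.
#' @return a `synthetic_cohort` equal (bitwise, up to the recorded
#'   fields) to the one written.
#' @export
read_cohort <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "cohort_config.json"),
                                 simplifyVector = TRUE)
  cfg <- do.call(cohort_config, cfg_raw)
  labs <- read.csv(file.path(dir, "labels.csv"),
                   colClasses = c("character", "character", "character"))
  modalities <- list()
  for (m in seq_along(cfg$modality_names)) {
    nm <- cfg$modality_names[m]
    df <- read.csv(file.path(dir, paste0(nm, ".csv")),
                   colClasses = "character", check.names = FALSE)
    X <- vapply(df[-1L], as.numeric, numeric(nrow(df)))
    if (!is.matrix(X)) X <- matrix(X, nrow = nrow(df),
                                   dimnames = list(NULL, names(df)[-1L]))
    modalities[[nm]] <- modality_table(df$subject_id, X, nm)
  }
  structure(
    list(modalities = modalities,
         labels = factor(labs$diagnosis, levels = DIAGNOSIS_LEVELS),
         latent = as.numeric(labs$latent),
         informative = stats::setNames(
           lapply(seq_along(cfg$block_dims), function(m)
             seq_len(cfg$n_informative[m])),
           cfg$modality_names),
         config = cfg),
    class = "synthetic_cohort")
}
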