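# Shared fixture builders.  Everything is generated in code from fixed
# seeds; no data files.

# small two-block cohort with latent signal in both modalities
small_cohort_config <- function(n = 300, seed = 42, ...) {
  args <- list(
    n_subjects = n,
    block_dims = c(12, 10),
    n_informative = c(5, 4),
    signal_weights = c(0.8, 0.7),
    nuisance_factors = c(2, 2),
    noise_sd = 1,
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

small_cohort <- function(n = 300, seed = 42, ...) {
  as_labeled_cohort(generate_cohort(small_cohort_config(n, seed, ...)))
}

# perfectly separable, noise-free binary geometry
separable_cohort <- function(n = 80, seed = 3) {
  as_labeled_cohort(generate_cohort(cohort_config(
    n_subjects = n, block_dims = c(4, 3),
    n_informative = c(4, 3), signal_weights = c(3, 3),
    nuisance_factors = c(0, 0), noise_sd = 1e-6,
    label_noise_sd = 0, seed = seed)))
}

# quick modality table from a plain matrix
mk_table <- function(X, name = "M", ids = NULL, dates = NULL,
                     age = NULL) {
  modality_table(ids %||% sprintf("s%03d", seq_len(nrow(X))),
                 X, name, visit_date = dates, age = age)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lightweight reducer settings for network methods in tests
fast_spec <- function(method, ...) {
  args <- list(method = method, epochs = 40L, batch_size = 64L)
  override <- list(...)
  args[names(override)] <- override
  do.call(reducer_spec, args)
}
fast_se <- function(...) fast_spec("SE", ...)
fast_ae <- function(...) fast_spec("AE", ...)

fast_clf <- function(...) classifier_config(rf_trees = 150,
                                            nn_epochs = 30, ...)
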