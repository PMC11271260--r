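test_that("same config and seed give bitwise-identical cohorts", {
  cfg <- small_cohort_config(n = 150, seed = 11, missing_rate = 0.05)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$modalities[[1]]$features, b$modalities[[1]]$features)
  expect_identical(a$modalities[[2]]$features, b$modalities[[2]]$features)
  expect_identical(a$labels, b$labels)
  expect_identical(a$latent, b$latent)
})

test_that("default config emulates the merged two-modality shape", {
  sc <- generate_cohort(cohort_config(seed = 1))
  expect_equal(dim(sc$modalities$UDS$features), c(1419, 90))
  expect_equal(dim(sc$modalities$MRI$features), c(1419, 157))
  expect_setequal(levels(sc$labels), c("HC", "MCI", "AD"))
})

test_that("noise-free limit makes labels a deterministic threshold of z", {
  cfg <- small_cohort_config(n = 200, seed = 5, noise_sd = 0,
                             label_noise_sd = 0, missing_rate = 0,
                             nuisance_factors = c(0, 0))
  sc <- generate_cohort(cfg)
  expected <- cut(sc$latent, c(-Inf, cfg$class_thresholds, Inf),
                  labels = c("HC", "MCI", "AD"))
  expect_identical(as.character(sc$labels), as.character(expected))
})

test_that("per-stage substreams isolate missingness from the latent draw", {
  a <- generate_cohort(small_cohort_config(n = 120, seed = 9,
                                           missing_rate = 0))
  b <- generate_cohort(small_cohort_config(n = 120, seed = 9,
                                           missing_rate = 0.2))
  expect_identical(a$latent, b$latent)
  expect_identical(a$labels, b$labels)
  obs <- !is.na(b$modalities[[1]]$features)
  expect_identical(a$modalities[[1]]$features[obs],
                   b$modalities[[1]]$features[obs])
})

test_that("empirical missingness matches the configured rate", {
  rate <- 0.12
  sc <- generate_cohort(small_cohort_config(n = 1200, seed = 2,
                                            missing_rate = rate))
  for (m in sc$modalities) {
    frac <- mean(is.na(m$features))
    se <- sqrt(rate * (1 - rate) / length(m$features))
    expect_lt(abs(frac - rate), 3 * se)
  }
})

test_that("class masses converge to the normal-CDF masses of the cuts", {
  thr <- c(-0.25, 0.9)
  sc <- generate_cohort(small_cohort_config(
    n = 40000, seed = 3, class_thresholds = thr,
    label_noise_sd = 0.4))
  masses <- diff(c(0, pnorm(thr), 1))
  obs <- as.numeric(table(sc$labels)) / 40000
  se <- sqrt(masses * (1 - masses) / 40000)
  expect_true(all(abs(obs - masses) < 4 * se))
})

test_that("invalid configs raise errors naming the offending field", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(class_thresholds = c(1, 0)),
               "class_thresholds")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(n_informative = c(91, 1)),
               "n_informative")
})

test_that("Bayes reference is 1 in the noise-free limit and the top prior
           mass with uninformative features", {
  clean <- small_cohort_config(noise_sd = 0, label_noise_sd = 0,
                               nuisance_factors = c(0, 0))
  expect_equal(bayes_reference_accuracy(clean, 5000), 1.0)

  flat <- small_cohort_config(signal_weights = c(0, 0),
                              class_thresholds = c(-0.5, 0.5))
  masses <- diff(c(0, pnorm(c(-0.5, 0.5)), 1))
  expect_equal(bayes_reference_accuracy(flat, 5000), max(masses))
})

test_that("Bayes reference matches a brute-force posterior-integration
           oracle on a small configuration", {
  cfg <- cohort_config(n_subjects = 10, block_dims = c(4, 3),
                       n_informative = c(3, 2),
                       signal_weights = c(0.9, 0.7),
                       nuisance_factors = c(1, 1), nuisance_sd = 0.5,
                       noise_sd = 1, label_noise_sd = 0.3,
                       class_thresholds = c(-0.3, 0.8), seed = 17)
  fast <- bayes_reference_accuracy(cfg, n_mc = 200000, seed = 100)

  # oracle: simulate full feature vectors and integrate the posterior
  # over a dense z grid, never using the closed-form reduction
  s <- cfg$label_noise_sd
  thr <- cfg$class_thresholds
  blocks <- lapply(1:2, function(m) {
    w <- numeric(cfg$block_dims[m])
    w[seq_len(cfg$n_informative[m])] <- cfg$signal_weights[m]
    B <- fusebench:::draw_loadings(cfg, m)
    list(w = w, Sigma = crossprod(B) + diag(cfg$noise_sd^2,
                                            cfg$block_dims[m]),
         B = B)
  })
  zg <- seq(-5, 5, length.out = 401)
  n_mc <- 4000
  set.seed(200)
  correct <- logical(n_mc)
  for (i in seq_len(n_mc)) {
    z <- rnorm(1)
    u <- (z + s * rnorm(1)) / sqrt(1 + s^2)
    truth <- findInterval(u, thr) + 1L
    loglik <- numeric(length(zg))
    for (bl in blocks) {
      x <- as.numeric(z * bl$w +
                        rnorm(nrow(bl$B)) %*% bl$B +
                        rnorm(length(bl$w), sd = cfg$noise_sd))
      Si <- solve(bl$Sigma)
      loglik <- loglik + vapply(zg, function(zz) {
        d <- x - zz * bl$w
        -0.5 * drop(d %*% Si %*% d)
      }, numeric(1))
    }
    post <- exp(loglik - max(loglik)) * dnorm(zg)
    post <- post / sum(post)
    # class probability: integrate P(class | z) over the posterior
    pu <- function(t) pnorm((t - zg / sqrt(1 + s^2)) /
                              sqrt(s^2 / (1 + s^2)))
    p1 <- sum(post * pu(thr[1]))
    p2 <- sum(post * pu(thr[2])) - p1
    pred <- which.max(c(p1, p2, 1 - p1 - p2))
    correct[i] <- pred == truth
  }
  oracle <- mean(correct)
  se <- sqrt(oracle * (1 - oracle) / n_mc)
  expect_lt(abs(fast - oracle), 4 * se + 0.01)
})

test_that("Bayes reference is monotone in signal weight", {
  accs <- vapply(c(0.2, 0.5, 1.0), function(w)
    bayes_reference_accuracy(
      small_cohort_config(signal_weights = c(w, w)), n_mc = 200000,
      seed = 77),
    numeric(1))
  expect_true(all(diff(accs) > -0.01))
})

test_that("cohorts round-trip through CSV + JSON losslessly", {
  dir <- withr::local_tempdir()
  sc <- generate_cohort(small_cohort_config(n = 60, seed = 21,
                                            missing_rate = 0.1))
  write_cohort(sc, dir)
  back <- read_cohort(dir)
  expect_identical(back$modalities[[1]]$features,
                   sc$modalities[[1]]$features)
  expect_identical(back$modalities[[2]]$features,
                   sc$modalities[[2]]$features)
  expect_identical(back$labels, sc$labels)
  expect_identical(back$latent, sc$latent)
  expect_identical(unclass(back$config), unclass(sc$config))
})
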