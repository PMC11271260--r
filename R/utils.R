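#' Derive a substream seed from a base seed
#'
#' Independent per-stage random substreams are derived from one global
#' integer seed so that, e.g., changing the missingness rate of a
#' synthetic cohort does not perturb its latent draw.  The map is a
#' Lehmer-style multiplicative hash kept strictly below 2^31 - 1.
#'
#' @param seed base integer seed.
#' @param stream small non-negative integer identifying the substream.
#' @return an integer seed usable with [set.seed()].
#' @export
substream_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(seed)) %% m)
  # two rounds of multiplicative mixing keep nearby (seed, stream)
  # pairs well separated
  s <- (s * 48271 + 11 * (as.numeric(stream) + 1)) %% m
  s <- (s * 69621 + 1) %% m
  as.integer(s)
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stop() with a consistent error class so callers can test error paths
fb_stop <- function(msg, class = "fusebench_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

config_stop <- function(msg) fb_stop(msg, class = "fusebench_config_error")
data_stop <- function(msg) fb_stop(msg, class = "fusebench_data_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
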