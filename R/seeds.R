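#' Derive a child seed for one pipeline stage
#'
#' Deterministically maps `(master seed, cell, replication, stage)` to a seed
#' in `[1, 2^31 - 21]` via a polynomial byte hash of the formatted key
#' (multiplier 131, modulus the prime 2147483629). Pre-deriving per-stage
#' seeds makes every replication of every grid cell independently rerunnable,
#' in any order, serial or parallel. The derivation rule is part of the
#' package contract: the same inputs always give the same child seed.
#'
#' @param master Master experiment seed (integer).
#' @param C_R,C_I Grid cell coordinates.
#' @param rep Replication number.
#' @param stage Stage label, e.g. `"run-base"`, `"cal-sample"`.
#'
#' @return An integer seed suitable for `set.seed()`.
#' @examples
#' derive_seed(42, 1, 1, 3, "run-mcmc")
#' @export
derive_seed <- function(master, C_R, C_I, rep, stage) {
  key <- paste(master, C_R, C_I, rep, stage, sep = "|")
  h <- 17
  for (b in utf8ToInt(key)) {
    h <- (h * 131 + b) %% 2147483629
  }
  as.integer(h + 1)
}

#' Standard error of a sample mean from a unit-normal population
#'
#' For `n` examinees drawn from a standard-normal ability population, the
#' sampling SD of their mean ability is `1 / sqrt(n)`. This quantifies how
#' large a between-test ability-mean difference is plausible by sampling
#' alone: e.g. with `n = 100` the SEM is 0.1, so mean differences beyond
#' `2.5 * SEM = 0.25` per test (0.5 between two tests) are rare.
#'
#' @param n Sample size.
#' @return The standard error `1 / sqrt(n)`.
#' @examples
#' sem_of_mean(100) # 0.1
#' @export
sem_of_mean <- function(n) {
  if (n <= 0) abort("n must be positive.", class = "facetlink_invalid_input")
  1 / sqrt(n)
}
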