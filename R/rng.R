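#' Derive a reproducible child seed from a master seed
#'
#' Counter-based seed derivation: the master seed and an arbitrary list of
#' tokens (configuration coordinates, trial index, purpose string) are folded
#' into a 31-bit integer by a polynomial string hash. Adding further purposes
#' or algorithms to a run never perturbs the seeds of existing ones, so
#' generation is stable as an experiment grid grows.
#'
#' @param master integer master seed.
#' @param ... tokens (coerced to character) identifying the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  tokens <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "|")
  m <- 2147483647
  h <- as.double(master) %% m
  for (code in utf8ToInt(tokens)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate expr under a local RNG state seeded with `seed`; restores the
# caller's RNG state afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
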