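#' @importFrom rlang abort warn .data
#' @importFrom stats qnorm pnorm runif rnorm setNames
#' @importFrom utils head tail
NULL

# modal value with deterministic tie-break: lowest code wins
mode_lowest <- function(x) {
  stopifnot(length(x) > 0L)
  tab <- table(x)
  codes <- as.integer(names(tab))
  winners <- codes[tab == max(tab)]
  min(winners)
}

# half-up rounding (base round() is banker's, which breaks the evenly
# spaced window-start arithmetic at exact halves)
round_half_up <- function(x) floor(x + 0.5)

#' Derive a stage-specific seed from a global seed
#'
#' Fans a single experiment seed out to per-stage seeds via a small string
#' hash, so each pipeline stage (simulate, emit, train, ...) is
#' independently reproducible from the one recorded seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

# normal(mean, sd) draws floored at `lower`: the clamp guarantees positive
# durations while leaving the sample mean essentially unbiased (a
# resampling truncation would shift short-phase means upward by tens of
# seconds)
rnorm_floored <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  pmax(rnorm(n, mean, sd), lower)
}
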