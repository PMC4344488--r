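#' @importFrom stats median mad pnorm rnorm rlnorm rbeta runif sd setNames
#' @importFrom utils head read.delim write.table
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage-specific sub-seeds so each generator is an independent, reproducible
# stream while the whole synthetic dataset is a pure function of cfg$seed.
# Kept well below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  stages <- c(layout = 11L, genome = 23L, annotation = 31L, probes = 47L,
              expression = 59L, conservation = 67L, sites = 79L,
              shape_table = 97L, sample = 101L, cv = 113L)
  off <- stages[[stage]]
  (as.integer(seed) %% 20000000L) * 100L + off
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# log(sum(exp(x))) without overflow; used by the hypergeometric tail
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
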