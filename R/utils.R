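#' @importFrom rlang %||% abort warn
#' @importFrom stats plogis rnorm runif rbinom setNames qnorm pchisq logLik BIC dist
NULL

DEGREES <- 1:7

# context -> target pairs that may only occur inside IC cells
RESERVED_PAIRS <- matrix(
  c(5L, 4L,
    5L, 6L,
    3L, 4L,
    3L, 2L),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("context", "target"))
)

RESERVED_LOOKUP <- local({
  m <- matrix(FALSE, 7, 7)
  m[RESERVED_PAIRS] <- TRUE
  m
})

is_reserved_pair <- function(from, to) {
  RESERVED_LOOKUP[cbind(from, to)]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic substream seed derived from a master seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483629)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_one <- function(x, prob = NULL) {
  # sample() with a length-1 x would sample from 1:x
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = prob)]
}
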