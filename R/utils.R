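# internal helpers shared across modules

# numerically stable logistic; plogis handles large |z| without overflow
.sigma <- function(z) stats::plogis(z)

# sigma'(z) = sigma(z) * sigma(-z), computed stably for saturated z
.dsigma <- function(z) stats::plogis(z) * stats::plogis(-z)

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  as.numeric(x)
}

# run code with a private RNG stream, restoring the caller's stream afterwards
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic fan-out of one user seed into named substreams (kept < 2^31)
.substream_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream)) * 1009L
  as.integer((as.numeric(seed) + offs) %% 2147483647)
}
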