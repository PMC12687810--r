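# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's RNG stream is restored afterwards, so seeded package
# functions never perturb user-level reproducibility.
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# smallest positive value of a numeric vector/matrix, NA if none
.min_positive <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0L) {
    return(NA_real_)
  }
  min(x)
}

.stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
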