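# internal helpers shared across modules

.msg <- function(..., verbose = getOption("egmdur.verbose", TRUE)) {
  if (isTRUE(verbose)) message("egmdur: ", ...)
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_num <- function(x) is.numeric(x) && all(is.finite(x))

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# millisecond -> sample count, rounding half up (round() in R rounds half even)
.ms_to_samples <- function(ms, sampling_rate_hz) {
  as.integer(floor(ms * sampling_rate_hz / 1000 + 0.5))
}

.vnorm <- function(v) sqrt(sum(v * v))

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
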