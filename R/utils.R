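# Derived seed substreams: one master seed, deterministic per-stage offsets,
# kept inside 32-bit integer range.
.substream <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) %% 1000003L) * 2011L + (offset %% 100003L)) %% .Machine$integer.max
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
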