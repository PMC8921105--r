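## Internal helpers shared across modules.

## Round half away from zero (SPSS-style display rounding), used for the
## integer-percent figures of the risk report. base::round() rounds half to
## even and would print 79.5% as 80 but 44.5% as 44.
roundHalfUp <- function(x, digits = 0) {
  mult <- 10^digits
  trunc(abs(x) * mult + 0.5) / mult * sign(x)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state (restores .Random.seed, or removes it if there was none).
withSeed <- function(seed, expr) {
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

## MD5 of an R object via its serialization, for provenance blocks.
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
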