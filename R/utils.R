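`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

# Draw a deterministic subsample without disturbing the caller's RNG stream.
sample_with_seed <- function(seed, n, size) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  idx <- sample.int(n, size)
  restore_seed(old)
  idx
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
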