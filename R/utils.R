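# Seed handling: set a reproducible RNG state inside a function without
# clobbering the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# derive a stream-specific child seed from a master seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * k) %% 2147483647
}
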