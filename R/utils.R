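`%||%` <- function(a, b) if (is.null(a)) b else a

# C-locale (radix) sort so node ordering is platform-independent;
# "smaller node id" in tie-breaking always refers to this ordering.
sort_ids <- function(x) sort(x, method = "radix")

# STRING exports occasionally carry fractional scores; round half up so
# weights stay integral (R's round() is half-to-even).
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sp_message <- function(..., quiet = FALSE) {
  if (!quiet) message(...)
}
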