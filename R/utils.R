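# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All user-facing randomness in the package goes through this.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed for repetition / retry `r` of a run seeded with
# `base`. Kept strictly below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(base, r) {
  as.integer((as.double(base) %% 65011L * 33013 + as.double(r) * 7919) %% 2147483629) + 1L
}

abort_validation <- function(msg) {
  abort(msg, class = "evoselect_validation_error")
}

abort_format <- function(msg) {
  abort(msg, class = "evoselect_format_error")
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x) && x >= min
}

is_prob <- function(x, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x)
  if (!ok) return(FALSE)
  if (open) x > 0 && x < 1 else x >= 0 && x <= 1
}
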