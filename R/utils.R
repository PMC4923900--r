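## internal helpers shared across the package

# run code under a temporary RNG state; restores .Random.seed afterwards so
# library calls never perturb the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# trimmed, lower-cased label matching for design tables
normalise_label <- function(x) tolower(trimws(as.character(x)))

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
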