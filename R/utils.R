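# internal helpers shared across modules

#' @keywords internal
ysnpdb_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "ysnpdb_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# name normalization: case-fold + strip surrounding whitespace, nothing fuzzier
norm_name <- function(x) {
  tolower(trimws(x))
}

# round half away from zero (integer percent display, "49%" style)
round_half_up <- function(x) {
  floor(x + 0.5)
}

# evaluate expr under a fixed RNG seed without touching the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
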