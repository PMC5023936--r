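# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# (or removing) the caller's .Random.seed afterwards.  All generators route
# their randomness through this so no global state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genotype calls are integer alt-allele dosages in {0, 1, 2}, NA for missing.
check_calls <- function(calls) {
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("genotype calls must be 0, 1, 2 or NA; offending value(s): ",
         paste(utils::head(unique(calls[!ok]), 3L), collapse = ", "),
         call. = FALSE)
  }
  invisible(calls)
}
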