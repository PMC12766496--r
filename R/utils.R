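`%||%` <- function(x, y) if (is.null(x)) y else x

# Half-up rounding (round() in R rounds half to even, which is not what a
# consensus score should do: 4.5 must become 5, not 4).
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

slugify <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_score <- function(x, what) {
  if (!is_scalar_number(x) || x != as.integer(x) || x < 1 || x > 10) {
    stop(sprintf("%s must be an integer score in 1..10 (got %s)",
                 what, deparse(substitute(x))), call. = FALSE)
  }
  as.integer(x)
}

assert_fraction <- function(x, what, allow_zero = FALSE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is_scalar_number(x) || !lo_ok || x > 1) {
    stop(sprintf("%s must be a fraction in %s0,1] (got %s)",
                 what, if (allow_zero) "[" else "(", format(x)), call. = FALSE)
  }
  as.numeric(x)
}

# Run an expression with a locally seeded RNG, restoring (or removing) the
# caller's .Random.seed afterwards: no global RNG state leaks out.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Exact serialization of a double as a decimal string ("%.17g" round-trips
# IEEE doubles); used for probabilities in project files.
num_to_string <- function(x) sprintf("%.17g", as.numeric(x))

string_to_num <- function(s) as.numeric(s)
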