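# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Expand one user-facing seed into per-stage seeds. Stages are numbered
# (1 = cohort simulation, 2 = transducer init, 3 = pair sampling, ...);
# the scheme is a fixed affine counter kept below 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 99991 * as.numeric(stage)) %% 2147483647)
}

# Split a string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map a string to 1-based letter indices over `alphabet` (character vector
# of single letters). Errors on letters outside the alphabet.
chars_to_idx <- function(text, alphabet) {
  if (nchar(text) == 0L) return(integer(0))
  idx <- match(str_chars(text), alphabet)
  if (anyNA(idx)) {
    bad <- unique(str_chars(text)[is.na(idx)])
    abort(sprintf("string contains letters outside the transducer alphabet: %s",
                  paste(bad, collapse = ", ")))
  }
  idx
}

is_binary_label <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}
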