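#' SAX encoding configuration
#'
#' Bundles the parameters that govern the conversion of a univariate time
#' series into a symbol string: the sliding-window size (raw values per SAX
#' word), the number of PAA segments per word, the alphabet size, and the
#' length cap applied by systematic group sampling.
#'
#' Defaults correspond to the best-performing configuration for hourly
#' hypotension forecasting from heart rate sampled once per minute: a
#' 120-minute window (two hours of data per word), 24 segments (one symbol
#' per 5 minutes) and a 3-letter alphabet (low / average / high), with
#' strings capped at 1020 characters.
#'
#' @param window_size Positive integer, raw values per sliding window.
#' @param symbols Positive integer, PAA segments (characters) per SAX word;
#'   must not exceed `window_size`.
#' @param alphabet_size Integer in `[2, 26]`, number of letters.
#' @param target_length Positive integer, cap on the final string length in
#'   characters.
#' @param group_size Characters per sampling group; defaults to `symbols`
#'   (whole words are sampled, never split).
#' @param window_step Positive integer stride between consecutive windows;
#'   1 gives fully overlapping windows.
#' @return A `sax_config` list.
#' @examples
#' sax_config()
#' sax_config(window_size = 120, symbols = 6, alphabet_size = 5)
#' @export
sax_config <- function(window_size = 120, symbols = 24, alphabet_size = 3,
                       target_length = 1020, group_size = symbols,
                       window_step = 1) {
  stopifnot(
    length(window_size) == 1, window_size >= 1,
    length(symbols) == 1, symbols >= 1,
    length(alphabet_size) == 1, alphabet_size >= 2, alphabet_size <= 26,
    length(target_length) == 1, target_length >= 1,
    length(group_size) == 1, group_size >= 1,
    length(window_step) == 1, window_step >= 1
  )
  if (symbols > window_size) {
    abort(sprintf("`symbols` (%d) must not exceed `window_size` (%d)",
                  symbols, window_size))
  }
  structure(
    list(window_size = as.integer(window_size),
         symbols = as.integer(symbols),
         alphabet_size = as.integer(alphabet_size),
         target_length = as.integer(target_length),
         group_size = as.integer(group_size),
         window_step = as.integer(window_step)),
    class = "sax_config"
  )
}

#' @export
print.sax_config <- function(x, ...) {
  cat("<sax_config>\n")
  cat(sprintf("  window_size:   %d\n", x$window_size))
  cat(sprintf("  symbols:       %d\n", x$symbols))
  cat(sprintf("  alphabet_size: %d (letters %s..%s)\n", x$alphabet_size,
              "a", letters[x$alphabet_size]))
  cat(sprintf("  target_length: %d\n", x$target_length))
  cat(sprintf("  group_size:    %d\n", x$group_size))
  cat(sprintf("  window_step:   %d\n", x$window_step))
  invisible(x)
}

#' Overlapping sliding windows of a series
#'
#' @param values Numeric vector.
#' @param window_size Window length; must not exceed `length(values)`.
#' @param step Stride between window starts (default 1, fully overlapping).
#' @return A numeric matrix, one window per row, in series order. With
#'   `step = 1` there are `length(values) - window_size + 1` rows.
#' @examples
#' sliding_windows(1:5, 3)
#' @export
sliding_windows <- function(values, window_size, step = 1) {
  n <- length(values)
  if (n < window_size) {
    abort(sprintf(
      "series of length %d is shorter than window_size %d", n, window_size))
  }
  starts <- seq.int(1L, n - window_size + 1L, by = step)
  idx <- outer(starts, 0:(window_size - 1L), `+`)
  matrix(values[idx], nrow = length(starts), ncol = window_size)
}

# Tolerance below which a window's standard deviation counts as zero.
ZERO_VAR_TOL <- 1e-12

#' Z-normalize a window
#'
#' Centers and scales to population (ddof = 0) standard deviation 1. A
#' window whose standard deviation is (numerically) zero is replaced by
#' all zeros rather than dividing by zero.
#'
#' @param window Non-empty numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' znormalize_window(c(72, 72, 72))  # all zeros
#' @export
znormalize_window <- function(window) {
  if (length(window) == 0) abort("window must be non-empty")
  m <- mean(window)
  s <- sqrt(mean((window - m)^2))
  if (s < ZERO_VAR_TOL) return(rep(0, length(window)))
  (window - m) / s
}

# Row-wise z-normalization of a window matrix (vectorized fast path).
znormalize_rows <- function(W) {
  m <- rowMeans(W)
  s <- sqrt(pmax(rowMeans(W^2) - m^2, 0))
  flat <- s < ZERO_VAR_TOL
  s[flat] <- 1
  Z <- (W - m) / s
  Z[flat, ] <- 0
  Z
}

# Weight matrix mapping a window of length w onto `symbols` segment means.
# Segment s spans [(s-1) * w / symbols, s * w / symbols); raw value i
# contributes to each segment in proportion to its overlap, so non-divisible
# cases use fractional-boundary weighting and divisible cases reduce to
# exact block means.
paa_matrix <- function(w, symbols) {
  A <- matrix(0, nrow = w, ncol = symbols)
  seg_len <- w / symbols
  for (s in seq_len(symbols)) {
    lo <- (s - 1) * seg_len
    hi <- s * seg_len
    for (i in seq_len(w)) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) A[i, s] <- ov / seg_len
    }
  }
  A
}

#' Piecewise aggregate approximation
#'
#' Reduces a (z-normalized) window to `symbols` contiguous equal-width
#' segment means.
#'
#' @param zwindow Numeric vector.
#' @param symbols Number of segments; must not exceed `length(zwindow)`.
#' @return Numeric vector of length `symbols`.
#' @examples
#' paa(c(1, 1, 3, 3), 2)  # c(1, 3)
#' @export
paa <- function(zwindow, symbols) {
  w <- length(zwindow)
  if (symbols > w) {
    abort(sprintf("symbols (%d) exceeds window length (%d)", symbols, w))
  }
  as.numeric(zwindow %*% paa_matrix(w, symbols))
}

#' Gaussian breakpoints for an alphabet
#'
#' Standard normal quantiles at `i / alphabet_size`, `i = 1, ...,
#' alphabet_size - 1`, splitting the real line into equiprobable regions.
#'
#' @param alphabet_size Integer in `[2, 26]`.
#' @return Numeric vector of length `alphabet_size - 1`.
#' @export
sax_breakpoints <- function(alphabet_size) {
  stopifnot(alphabet_size >= 2, alphabet_size <= 26)
  qnorm(seq_len(alphabet_size - 1) / alphabet_size)
}

#' Discretize PAA values into a SAX word
#'
#' Each value is mapped to the letter of the equiprobable standard-normal
#' region it falls in: `a` for the lowest region through the
#' `alphabet_size`-th letter for the highest. A value exactly on a
#' breakpoint takes the higher letter.
#'
#' @param paa_values Numeric vector of segment means.
#' @param alphabet_size Integer in `[2, 26]`.
#' @return A single string of `length(paa_values)` letters.
#' @examples
#' discretize(c(-1, 0, 1), 3)  # "abc"
#' @export
discretize <- function(paa_values, alphabet_size) {
  brk <- sax_breakpoints(alphabet_size)
  paste(letters[findInterval(paa_values, brk) + 1L], collapse = "")
}

#' Collapse runs of identical SAX words
#'
#' Consecutive repeats of the same word are kept once; non-adjacent repeats
#' are preserved, as is order. Idempotent.
#'
#' @param words Character vector of equal-length SAX words.
#' @return Character vector with runs collapsed.
#' @examples
#' reduce_runs(c("abb", "abb", "abb", "aaa", "abb"))  # "abb" "aaa" "abb"
#' @export
reduce_runs <- function(words) {
  n <- length(words)
  if (n <= 1) return(words)
  words[c(TRUE, words[-1] != words[-n])]
}

#' Systematic group sampling to a length cap
#'
#' If the concatenated words fit within `target_length` characters they are
#' returned unchanged. Otherwise every k-th word is kept, starting from the
#' first, with k chosen as the smallest stride whose yield fits the cap:
#' `k = ceiling(n_words / floor(target_length / word_length))`. Sampling
#' whole words (groups of letters) rather than single letters preserves the
#' within-word structure inherited from the time-series subsequences, and
#' an even stride preserves patterns along the series better than a simple
#' random sample would. With 10,000 characters in 5-letter groups and a
#' 1,000-character target this keeps every 10th group (a stride of 50
#' characters), i.e. 200 groups and exactly 1,000 characters.
#'
#' @param words Character vector of SAX words, all the same length.
#' @param target_length Cap on total characters of the result.
#' @return Subset of `words` whose total character count is at most
#'   `target_length`; words are never split.
#' @export
systematic_sample <- function(words, target_length) {
  if (length(words) == 0) return(words)
  word_len <- nchar(words)
  if (length(unique(word_len)) != 1) {
    abort("all words must share one length for group sampling")
  }
  L <- word_len[1]
  total <- length(words) * L
  if (total <= target_length) return(words)
  g_max <- floor(target_length / L)
  if (g_max < 1) {
    abort(sprintf(
      "target_length %d cannot hold even one %d-character word",
      target_length, L))
  }
  k <- ceiling(length(words) / g_max)
  words[seq.int(1L, length(words), by = k)]
}

#' Encode one time series as a labeled symbol string
#'
#' Full SAX pipeline: overlapping sliding windows, per-window
#' z-normalization (zero-variance windows become all zeros), PAA,
#' Gaussian-breakpoint discretization, collapse of repeated words, and
#' systematic group sampling down to `config$target_length` characters;
#' the surviving words are concatenated into one string carrying the
#' record's binary outcome label.
#'
#' @param values Numeric vector, at least `config$window_size` long.
#' @param label Binary outcome, 0 or 1.
#' @param config A [sax_config()].
#' @param id Optional record identifier.
#' @return One-row tibble with columns `id`, `label`, `text`.
#' @examples
#' encode_record(rep(70, 240), label = 0,
#'               config = sax_config(window_size = 120, symbols = 6))
#' @export
encode_record <- function(values, label, config = sax_config(), id = NA_character_) {
  stopifnot(inherits(config, "sax_config"))
  if (!is_binary_label(label) || length(label) != 1) {
    abort("label must be a single 0 or 1")
  }
  W <- sliding_windows(values, config$window_size, step = config$window_step)
  Z <- znormalize_rows(W)
  P <- Z %*% paa_matrix(config$window_size, config$symbols)
  brk <- sax_breakpoints(config$alphabet_size)
  lett <- matrix(letters[findInterval(P, brk) + 1L], nrow = nrow(P))
  words <- do.call(paste0, as.data.frame(lett, stringsAsFactors = FALSE))
  words <- reduce_runs(words)
  words <- systematic_sample(words, config$target_length)
  tibble(id = as.character(id), label = as.integer(label),
         text = paste(words, collapse = ""))
}

#' Encode a cohort of time-series records
#'
#' @param records Tibble with columns `id`, `label` and a list-column
#'   `values` of numeric vectors (as produced by [generate_cohort()] or
#'   [read_records()]).
#' @param config A [sax_config()].
#' @return Tibble with columns `id`, `label`, `text`, one row per record.
#' @export
encode_records <- function(records, config = sax_config()) {
  stopifnot(all(c("id", "label", "values") %in% names(records)))
  purrr::pmap_dfr(
    list(records$values, records$label, records$id),
    function(v, l, i) encode_record(v, l, config = config, id = i)
  )
}
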