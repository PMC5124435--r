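#' Stochastic edit distance
#'
#' The learned dissimilarity between two strings: `-log p(y | x)` under a
#' conditional memoryless transducer, where `x` is consumed on the input
#' tape and `y` emitted on the output tape. Smaller values mean `y` is more
#' probable as an edit of `x`. The distance is asymmetric in general; a
#' pair with probability zero returns `Inf` (rather than erroring) so that
#' nearest-neighbour search can skip unexplainable candidates.
#'
#' @param x,y Character vectors of strings over `params$alphabet`
#'   (recycled to a common length).
#' @param params A [transducer_params()] object.
#' @return Numeric vector of `-log p(y|x)` values.
#' @examples
#' p <- init_params(c("a", "b"), ins_mass = 0.2)
#' stochastic_distance("", "a", p)  # -log(0.1 * 0.8)
#' @export
stochastic_distance <- function(x, y, params) {
  stopifnot(inherits(params, "transducer_params"))
  n <- max(length(x), length(y))
  x <- rep_len(as.character(x), n)
  y <- rep_len(as.character(y), n)
  p <- params_cpp(params)
  xi <- lapply(x, chars_to_idx, alphabet = params$alphabet)
  yi <- lapply(y, chars_to_idx, alphabet = params$alphabet)
  -sed_loglik_cpp(xi, yi, p$ins, p$sub, p$del, p$gamma)
}

#' Classic (Levenshtein) edit distance
#'
#' Minimum number of single-letter insertions, deletions and substitutions
#' transforming `x` into `y`; unit costs.
#'
#' @param x,y Character vectors (recycled to a common length).
#' @return Integer vector of distances.
#' @examples
#' classic_edit_distance("abb", "aaa")  # 2
#' @export
classic_edit_distance <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.character(x), n)
  y <- rep_len(as.character(y), n)
  d <- integer(n)
  for (i in seq_len(n)) d[i] <- utils::adist(x[i], y[i])[1, 1]
  d
}

# Full Levenshtein distance matrix between two string vectors.
edit_distance_matrix <- function(xs, ys) {
  unname(utils::adist(xs, ys))
}
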