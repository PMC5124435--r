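#' Learn stochastic edit-distance costs by EM
#'
#' Fits the conditional memoryless transducer to a set of (input, output)
#' string pairs by expectation-maximization: each iteration accumulates the
#' posterior expected operation counts over all pairs ([sed_expectation()])
#' and re-estimates the probabilities in closed form ([sed_maximization()]).
#' The total conditional log-likelihood `sum log p(y|x)` is non-decreasing
#' across iterations; fitting stops when its improvement falls below `tol`
#' or after `max_iter` iterations.
#'
#' @param pairs Data frame with character columns `x` (input string) and
#'   `y` (output string), e.g. from [build_pairdataset()] or
#'   [make_pair_sample()].
#' @param init A [transducer_params()] object, or `NULL` to initialize
#'   uniformly over the alphabet observed in `pairs` (plus `alphabet`, if
#'   given).
#' @param alphabet Optional character vector fixing the alphabet; defaults
#'   to the sorted letters occurring in `pairs`.
#' @param tol Convergence tolerance on the total log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param verbose If `TRUE`, prints the log-likelihood each iteration.
#' @return A `sed_fit` object: list with `params` (the learned
#'   [transducer_params()]), `trace` (per-iteration total log-likelihood,
#'   evaluated under the parameters entering each iteration), `loglik`
#'   (final), `iterations`, `converged`, `n_pairs` and `tol`.
#' @examples
#' p <- init_params(c("a", "b"))
#' prs <- data.frame(x = c("ab", "ba"), y = c("ab", "ba"))
#' fit <- sed_fit(prs, init = p, max_iter = 10)
#' glance(fit)
#' @export
sed_fit <- function(pairs, init = NULL, alphabet = NULL, tol = 1e-6,
                    max_iter = 100, verbose = FALSE) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) abort("`pairs` must contain at least one pair")
  stopifnot(all(c("x", "y") %in% names(pairs)))
  xs <- as.character(pairs$x); ys <- as.character(pairs$y)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(c(xs, ys), "", fixed = TRUE))))
    if (!is.null(init)) alphabet <- init$alphabet
  }
  if (is.null(init)) init <- init_params(alphabet)
  xi <- lapply(xs, chars_to_idx, alphabet = init$alphabet)
  yi <- lapply(ys, chars_to_idx, alphabet = init$alphabet)

  params <- init
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    p <- params_cpp(params)
    res <- sed_counts_cpp(xi, yi, p$ins, p$sub, p$del, p$gamma)
    if (!is.finite(res$loglik)) {
      bad <- which(!is.finite(res$pair_loglik))[1]
      abort(sprintf(
        paste0("pair %d ('%s' -> '%s') has probability zero under the ",
               "current parameters; use a full-support (uniform or random) ",
               "initialization"), bad, xs[bad], ys[bad]))
    }
    iter <- iter + 1L
    trace <- c(trace, res$loglik)
    if (verbose) message(sprintf("EM iter %3d  loglik %.6f", iter, res$loglik))
    if (iter >= 2 && (trace[iter] - trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    counts <- edit_counts(params$alphabet, res$n_ins, res$n_sub, res$n_del,
                          n_end = res$n_end)
    params <- sed_maximization(counts)
  }
  structure(
    list(params = params, trace = trace, loglik = trace[length(trace)],
         iterations = iter, converged = converged, n_pairs = length(xs),
         tol = tol),
    class = "sed_fit"
  )
}

#' @export
print.sed_fit <- function(x, ...) {
  cat(sprintf(
    "<sed_fit> %d pairs, %d EM iterations (%s), total loglik %.4f\n",
    x$n_pairs, x$iterations,
    if (x$converged) "converged" else "max_iter reached", x$loglik))
  print(x$params)
  invisible(x)
}

#' Tidy the learned edit-operation probabilities
#'
#' @param x A `sed_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per operation: columns `operation`
#'   (`"insert"`, `"substitute"`, `"delete"`, `"stop"`), `input` (the
#'   consumed letter, `NA` for insertions and stop), `output` (the emitted
#'   letter, `NA` for deletions and stop) and `probability`.
#' @method tidy sed_fit
#' @export
tidy.sed_fit <- function(x, ...) {
  p <- x$params
  al <- p$alphabet
  dplyr::bind_rows(
    tibble(operation = "insert", input = NA_character_, output = al,
           probability = unname(p$ins)),
    tidyr::expand_grid(input = al, output = al) |>
      dplyr::mutate(operation = "substitute",
                    probability = as.vector(t(p$sub))) |>
      dplyr::select("operation", "input", "output", "probability"),
    tibble(operation = "delete", input = al, output = NA_character_,
           probability = unname(p$del)),
    tibble(operation = "stop", input = NA_character_, output = NA_character_,
           probability = p$gamma)
  )
}

#' One-row fit summary
#'
#' @param x A `sed_fit` object.
#' @param ... Unused.
#' @return Tibble with `n_pairs`, `iterations`, `converged`, `loglik`,
#'   `tol`.
#' @method glance sed_fit
#' @export
glance.sed_fit <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, iterations = x$iterations,
         converged = x$converged, loglik = x$loglik, tol = x$tol)
}

#' Plot the EM log-likelihood trace
#'
#' @param object A `sed_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sed_fit
#' @export
autoplot.sed_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$trace), loglik = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "EM iteration", y = "total log-likelihood",
                  title = "EM convergence") +
    ggplot2::theme_minimal()
}

#' Plot transducer operation probabilities
#'
#' Heatmap of the substitution matrix flanked by the insertion and deletion
#' probabilities.
#'
#' @param object A [transducer_params()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transducer_params
#' @export
autoplot.transducer_params <- function(object, ...) {
  al <- object$alphabet
  sub_df <- tidyr::expand_grid(input = al, output = al)
  sub_df$probability <- mapply(function(a, b) object$sub[a, b],
                               sub_df$input, sub_df$output)
  ins_df <- tibble(input = "λ", output = al,
                   probability = unname(object$ins))
  del_df <- tibble(input = al, output = "λ",
                   probability = unname(object$del))
  df <- dplyr::bind_rows(sub_df, ins_df, del_df)
  df$input <- factor(df$input, levels = c(al, "λ"))
  df$output <- factor(df$output, levels = c(al, "λ"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$output, y = .data$input,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$probability)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "output letter (λ = none)",
                  y = "input letter (λ = none)",
                  title = sprintf("edit-operation probabilities (gamma = %.3f)",
                                  object$gamma)) +
    ggplot2::theme_minimal()
}
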