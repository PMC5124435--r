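#' Build the nearest-neighbour pair dataset
#'
#' For every training string `x`, finds its nearest neighbour `NN(x)` under
#' the classic edit distance (self excluded, ties broken by earliest index)
#' and forms the pair `(x, NN(x))`. These pairs are the training examples
#' for the transducer: the learned distance is then shaped by how strings
#' relate to their closest relatives. With `scope = "same_class"` (the
#' default) the neighbour search is restricted to strings with the same
#' outcome label, so the learned distance contracts within-class
#' variation; `scope = "all"` searches the whole training set.
#'
#' @param strings Tibble with columns `label` and `text` (and optionally
#'   `id`), e.g. from [encode_records()] or [read_symbol_strings()].
#' @param scope `"same_class"` or `"all"`.
#' @return Tibble with columns `x`, `y` (the neighbour), `label`, `x_index`
#'   and `y_index` (row positions in `strings`).
#' @export
build_pairdataset <- function(strings, scope = c("same_class", "all")) {
  scope <- match.arg(scope)
  strings <- as_tibble(strings)
  stopifnot(all(c("label", "text") %in% names(strings)))
  n <- nrow(strings)
  if (n < 2) abort("need at least 2 training strings to form pairs")
  texts <- as.character(strings$text)
  labels <- as.integer(strings$label)
  if (scope == "same_class") {
    for (cl in unique(labels)) {
      if (sum(labels == cl) < 2) {
        abort(sprintf(
          "class %d has a single member; cannot form same-class pairs", cl))
      }
    }
  }
  nn <- integer(n)
  if (scope == "same_class") {
    # distance blocks per class; avoids the cross-class half of the matrix
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      D <- edit_distance_matrix(texts[idx], texts[idx])
      diag(D) <- Inf
      nn[idx] <- idx[apply(D, 1, which.min)]  # which.min: earliest on ties
    }
  } else {
    D <- edit_distance_matrix(texts, texts)
    diag(D) <- Inf
    nn <- apply(D, 1, which.min)
  }
  tibble(x = texts, y = texts[nn], label = labels,
         x_index = seq_len(n), y_index = as.integer(nn))
}

#' 1-nearest-neighbour classification of symbol strings
#'
#' Assigns each test string the label of the training string closest to it.
#' With `distance = "stochastic"` the dissimilarity is the learned
#' [stochastic_distance()]; `direction` controls which string is placed on
#' the transducer's input tape (`"input_test"`, the default, scores
#' `-log p(train | test)`). With `distance = "classic"` the unit-cost
#' Levenshtein distance is used and `params` is ignored. Ties are broken
#' by the earliest training index.
#'
#' @param test Tibble of test strings (columns `text`, optionally `id`,
#'   `label`).
#' @param train Tibble of labeled training strings (columns `label`,
#'   `text`).
#' @param distance `"stochastic"` or `"classic"`.
#' @param params A [transducer_params()] object (required for
#'   `"stochastic"`).
#' @param direction `"input_test"` or `"input_train"`.
#' @return `test` with added columns `.pred` (predicted label), `.nn_index`
#'   (row of the chosen neighbour in `train`) and `.nn_dist`.
#' @export
nn_classify <- function(test, train,
                        distance = c("stochastic", "classic"),
                        params = NULL,
                        direction = c("input_test", "input_train")) {
  distance <- match.arg(distance)
  direction <- match.arg(direction)
  test <- as_tibble(test)
  train <- as_tibble(train)
  stopifnot("text" %in% names(test),
            all(c("label", "text") %in% names(train)))
  if (nrow(train) == 0) abort("training set must be non-empty")
  if (distance == "stochastic" && is.null(params)) {
    abort("`params` is required for the stochastic distance")
  }
  tr_text <- as.character(train$text)
  preds <- purrr::map_dfr(as.character(test$text), function(tx) {
    d <- switch(distance,
      classic = as.numeric(edit_distance_matrix(tx, tr_text)[1, ]),
      stochastic = if (direction == "input_test") {
        stochastic_distance(rep(tx, length(tr_text)), tr_text, params)
      } else {
        stochastic_distance(tr_text, rep(tx, length(tr_text)), params)
      })
    if (all(!is.finite(d))) {
      abort(sprintf(
        "no training string explains test string '%.20s...'; all distances are infinite", tx))
    }
    j <- which.min(d)
    tibble(.pred = as.integer(train$label[j]), .nn_index = as.integer(j),
           .nn_dist = d[j])
  })
  dplyr::bind_cols(test, preds)
}

#' Confusion counts and prediction metrics
#'
#' Computes true/false positive/negative counts and the four summary
#' metrics. `positive` predictions are label 1. Metrics with a zero
#' denominator are reported as `NaN` (e.g. precision when nothing is
#' predicted positive) rather than coerced to 0.
#'
#' @param predictions Binary vector of predicted labels.
#' @param truth Binary vector of true labels, same length.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `f_measure`.
#' @examples
#' evaluate_predictions(c(1, 1, 0, 0), c(1, 0, 1, 0))  # all metrics 0.5
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    abort(sprintf("length mismatch: %d predictions vs %d truth labels",
                  length(predictions), length(truth)))
  }
  if (!is_binary_label(as.numeric(predictions)) ||
      !is_binary_label(as.numeric(truth))) {
    abort("labels must be binary (0/1)")
  }
  p <- as.integer(predictions); t <- as.integer(truth)
  tp <- sum(p == 1 & t == 1); fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1); tn <- sum(p == 0 & t == 0)
  accuracy <- (tp + tn) / length(t)
  precision <- tp / (tp + fp)   # 0/0 -> NaN
  recall <- tp / (tp + fn)
  f_measure <- 2 * precision * recall / (precision + recall)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         accuracy = accuracy, precision = precision, recall = recall,
         f_measure = f_measure)
}

#' Run the full learning-and-validation pipeline
#'
#' Executes the five stages end to end: (1) encode every training and test
#' record into a labeled symbol string, (2) build the nearest-neighbour
#' pair dataset under the classic edit distance, (3) learn the transducer
#' by EM, (4) classify each test string by 1-NN under the learned
#' stochastic distance, and (5) compute confusion counts and metrics. The
#' run is deterministic given its inputs: the EM initialization is uniform.
#'
#' @param train,test Record tibbles (columns `id`, `label`, `values`), as
#'   from [generate_cohort()] or [read_records()].
#' @param config A [sax_config()].
#' @param pairs_scope Passed to [build_pairdataset()].
#' @param direction Passed to [nn_classify()].
#' @param em_tol,em_max_iter EM stopping controls (see [sed_fit()]).
#' @param verbose Print EM progress.
#' @return A `sed_experiment` object: list with `config`, `strings_train`,
#'   `strings_test`, `pairs`, `fit`, `predictions` and `metrics`.
#' @export
run_experiment <- function(train, test, config = sax_config(),
                           pairs_scope = "same_class",
                           direction = "input_test",
                           em_tol = 1e-6, em_max_iter = 100,
                           verbose = FALSE) {
  strings_train <- encode_records(train, config)
  strings_test <- encode_records(test, config)
  pairs <- build_pairdataset(strings_train, scope = pairs_scope)
  alphabet <- letters[seq_len(config$alphabet_size)]
  fit <- sed_fit(pairs, init = init_params(alphabet), tol = em_tol,
                 max_iter = em_max_iter, verbose = verbose)
  predictions <- nn_classify(strings_test, strings_train,
                             distance = "stochastic", params = fit$params,
                             direction = direction)
  metrics <- evaluate_predictions(predictions$.pred, strings_test$label)
  structure(
    list(config = config, strings_train = strings_train,
         strings_test = strings_test, pairs = pairs, fit = fit,
         predictions = predictions, metrics = metrics),
    class = "sed_experiment"
  )
}

#' @export
print.sed_experiment <- function(x, ...) {
  cat(sprintf(
    "<sed_experiment> window %d, symbols %d, alphabet %d; %d train / %d test\n",
    x$config$window_size, x$config$symbols, x$config$alphabet_size,
    nrow(x$strings_train), nrow(x$strings_test)))
  print(x$metrics)
  invisible(x)
}

#' @method glance sed_experiment
#' @export
glance.sed_experiment <- function(x, ...) {
  dplyr::bind_cols(
    tibble(window_size = x$config$window_size, symbols = x$config$symbols,
           alphabet_size = x$config$alphabet_size),
    x$metrics
  )
}

#' Run the parameter grid of experiments
#'
#' Repeats [run_experiment()] over the cross of `symbols` and
#' `alphabet_sizes` at a fixed `window_size`; the default grid (3 x 3 at
#' window 120) yields nine experiments.
#'
#' @param train,test Record tibbles.
#' @param window_size Fixed window size.
#' @param symbols,alphabet_sizes Vectors of values to cross.
#' @param ... Further arguments passed to [run_experiment()].
#' @return Tibble with one row per configuration: the grid coordinates and
#'   the metric columns of [evaluate_predictions()].
#' @export
run_grid <- function(train, test, window_size = 120,
                     symbols = c(6, 12, 24), alphabet_sizes = c(3, 4, 5),
                     ...) {
  grid <- tidyr::expand_grid(symbols = symbols,
                             alphabet_size = alphabet_sizes)
  purrr::pmap_dfr(grid, function(symbols, alphabet_size) {
    cfg <- sax_config(window_size = window_size, symbols = symbols,
                      alphabet_size = alphabet_size)
    glance(run_experiment(train, test, config = cfg, ...))
  })
}
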