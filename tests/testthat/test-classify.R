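test_that("pairdataset pairs each string with its nearest neighbour", {
  s <- tibble::tibble(label = c(1L, 0L),
                      text = c("abba", "baab"))
  ps <- build_pairdataset(s, scope = "all")
  expect_equal(ps$x, c("abba", "baab"))
  expect_equal(ps$y, c("baab", "abba"))   # only candidate each

  # brute-force argmin oracle over a random set
  set.seed(21)
  texts <- replicate(6, paste(sample(c("a", "b", "c"), sample(3:8, 1), TRUE),
                              collapse = ""))
  s <- tibble::tibble(label = rep(c(0L, 1L), 3), text = texts)
  ps <- build_pairdataset(s, scope = "all")
  D <- sapply(texts, function(b) sapply(texts, function(a)
    classic_edit_distance(a, b)))
  diag(D) <- Inf
  expect_equal(ps$y_index, unname(apply(D, 1, which.min)))
  # argmin contract: chosen neighbour is never beaten
  for (i in seq_len(6)) {
    expect_true(all(classic_edit_distance(texts[i], ps$y[i]) <=
                      D[i, -i]))
  }

  # same-class scope never pairs across labels
  ps2 <- build_pairdataset(s, scope = "same_class")
  expect_true(all(s$label[ps2$x_index] == s$label[ps2$y_index]))

  expect_error(
    build_pairdataset(tibble::tibble(label = c(0L, 1L, 1L),
                                     text = c("a", "b", "c"))),
    "class 0")
})

test_that("1-NN assigns the label of the closest training string", {
  train <- tibble::tibble(label = c(1L, 0L, 1L),
                          text = c("aaaa", "bbbb", "abab"))
  # a test string equal to a training string has distance 0 to it
  out <- nn_classify(tibble::tibble(text = "bbbb"), train,
                     distance = "classic")
  expect_equal(out$.pred, 0L)
  expect_equal(out$.nn_dist, 0)

  # single-element training set: its label regardless of distance
  out1 <- nn_classify(tibble::tibble(text = "bbbb"),
                      train[1, ], distance = "classic")
  expect_equal(out1$.pred, 1L)

  # stochastic distances match an independently recomputed argmin
  p <- init_params(c("a", "b"), mode = "random", seed = 22)
  test <- tibble::tibble(text = c("ab", "ba", "bb"))
  out2 <- nn_classify(test, train, distance = "stochastic", params = p)
  for (i in seq_len(nrow(test))) {
    d <- vapply(train$text, function(tr)
      -log(sed_forward(test$text[i], tr, p)$prob), numeric(1))
    expect_equal(out2$.nn_index[i], unname(which.min(d)))
    expect_equal(out2$.pred[i], train$label[which.min(d)])
  }

  # ties break toward the earliest training index
  tied <- tibble::tibble(label = c(1L, 0L), text = c("aa", "aa"))
  expect_equal(nn_classify(tibble::tibble(text = "aa"), tied,
                           distance = "classic")$.nn_index, 1L)
})

test_that("metrics follow the printed formulas including NaN cases", {
  m <- evaluate_predictions(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(m[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f_measure, 0.5)

  perfect <- evaluate_predictions(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall",
                                "f_measure")]),
               c(accuracy = 1, precision = 1, recall = 1, f_measure = 1))

  # nothing predicted positive: precision undefined
  m2 <- evaluate_predictions(c(0, 0), c(1, 0))
  expect_true(is.nan(m2$precision))
  # no positives in truth: recall undefined
  m3 <- evaluate_predictions(c(0, 0), c(0, 0))
  expect_true(is.nan(m3$recall))
  expect_true(is.nan(m3$f_measure))
  expect_equal(m3$accuracy, 1)

  expect_error(evaluate_predictions(c(1, 0), c(1, 0, 1)), "mismatch")
  expect_error(evaluate_predictions(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics are invariant to joint permutation and counts sum to n", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    pred <- sample(0:1, n, TRUE)
    truth <- sample(0:1, n, TRUE)
    m <- evaluate_predictions(pred, truth)
    expect_equal(m$tp + m$fp + m$fn + m$tn, n)
    perm <- sample(n)
    m2 <- evaluate_predictions(pred[perm], truth[perm])
    expect_equal(m, m2)
  }
})

test_that("degenerate one-class test sets tie accuracy to recall", {
  # all-positive truth: accuracy = recall; tn = fp = 0
  pred <- c(1, 0, 1, 1)
  m <- evaluate_predictions(pred, rep(1, 4))
  expect_equal(m$accuracy, m$recall)
  expect_equal(m$fp + m$tn, 0)
})

test_that("the full experiment is reproducible and label-faithful", {
  spec <- cohort_spec(n_train = 12, n_train_pos = 6, n_test = 6,
                      n_test_pos = 3, minutes = 240, seed = 77)
  co <- generate_cohort(spec)
  cfg <- sax_config(window_size = 120, symbols = 6, alphabet_size = 3,
                    target_length = 240)
  ex1 <- run_experiment(co$train, co$test, config = cfg, em_max_iter = 15)
  ex2 <- run_experiment(co$train, co$test, config = cfg, em_max_iter = 15)
  expect_identical(ex1$metrics, ex2$metrics)
  expect_identical(ex1$fit$params, ex2$fit$params)
  expect_equal(nrow(ex1$strings_train), 12)
  expect_equal(sum(ex1$metrics[, c("tp", "fp", "fn", "tn")]), 6)
  expect_true(all(diff(ex1$fit$trace) >= -1e-8))
  g <- glance(ex1)
  expect_equal(g$symbols, 6)
  expect_s3_class(g, "tbl_df")
})

test_that("the parameter grid yields one report per configuration", {
  spec <- cohort_spec(n_train = 8, n_train_pos = 4, n_test = 4,
                      n_test_pos = 2, minutes = 180, seed = 5)
  co <- generate_cohort(spec)
  grid <- run_grid(co$train, co$test, window_size = 120,
                   symbols = c(6, 12), alphabet_sizes = c(3, 4),
                   em_max_iter = 8)
  expect_equal(nrow(grid), 4)
  expect_equal(grid$symbols, c(6, 6, 12, 12))
  expect_equal(grid$alphabet_size, c(3, 4, 3, 4))
  expect_true(all(c("accuracy", "precision", "recall", "f_measure")
                  %in% names(grid)))
})

test_that("tidy and autoplot expose the fitted transducer", {
  prs <- tibble::tibble(x = c("ab", "ba"), y = c("ab", "ba"))
  ft <- sed_fit(prs, max_iter = 10)
  td <- tidy(ft)
  expect_setequal(unique(td$operation),
                  c("insert", "substitute", "delete", "stop"))
  # tidied probabilities are exactly the parameter entries
  expect_equal(td$probability[td$operation == "substitute"][1],
               unname(ft$params$sub[1, 1]))
  expect_equal(sum(td$probability[td$operation == "insert"]) +
                 td$probability[td$operation == "stop"], 1)
  expect_s3_class(autoplot(ft), "ggplot")
  expect_s3_class(autoplot(ft$params), "ggplot")
  expect_equal(glance(ft)$n_pairs, 2)
})
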