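test_that("initialization satisfies both normalization constraints", {
  p <- init_params(c("a", "b"), ins_mass = 0.2)
  expect_equal(unname(p$ins), c(0.1, 0.1))
  expect_equal(p$gamma, 0.8)

  for (mode in c("uniform", "random")) {
    p <- init_params(c("a", "b", "c"), mode = mode, seed = 3)
    expect_lt(abs(sum(p$ins) + p$gamma - 1), 1e-12)
    rows <- sum(p$ins) + rowSums(p$sub) + p$del
    expect_true(all(abs(rows - 1) < 1e-12))
    expect_true(all(c(p$ins, p$sub, p$del, p$gamma) >= 0))
  }

  # same seed -> identical draws; RNG stream untouched
  p1 <- init_params(c("a", "b"), mode = "random", seed = 42)
  p2 <- init_params(c("a", "b"), mode = "random", seed = 42)
  expect_identical(p1, p2)
  expect_error(init_params(character(0)), "non-empty")
})

test_that("transducer_params rejects broken constraints", {
  expect_error(
    transducer_params("a", ins = 0.5, sub = matrix(0.5), del = 0.5,
                      gamma = 0.5),
    "constraint")
  expect_error(
    transducer_params("a", ins = -0.1, sub = matrix(0.6), del = 0.5,
                      gamma = 1.1),
    "\\[0, 1\\]")
})

test_that("forward handles the degenerate cases exactly", {
  p <- init_params(c("a", "b"), ins_mass = 0.2)
  expect_equal(sed_forward("", "", p)$prob, 0.8)           # stop only
  expect_equal(sed_forward("", "a", p)$prob, 0.1 * 0.8)    # one insertion
  expect_equal(stochastic_distance("", "a", p), -log(0.08))
  expect_equal(stochastic_distance("", "", p), -log(p$gamma))
})

test_that("forward probability equals exhaustive edit-path enumeration", {
  p <- init_params(c("a", "b"), mode = "random", seed = 5)
  strs <- all_strings_upto(c("a", "b"), 3)
  for (x in strs) {
    for (y in strs) {
      expect_equal(sed_forward(x, y, p)$prob,
                   oracle_enumerate(x, y, p)$prob, tolerance = 1e-10)
    }
  }
})

test_that("scaled log-likelihood kernel agrees with the plain lattice", {
  p <- init_params(c("a", "b", "c"), mode = "random", seed = 6)
  set.seed(6)
  for (rep in 1:20) {
    x <- paste(sample(c("a", "b", "c"), sample(0:8, 1), TRUE), collapse = "")
    y <- paste(sample(c("a", "b", "c"), sample(0:8, 1), TRUE), collapse = "")
    expect_equal(stochastic_distance(x, y, p), -sed_forward(x, y, p)$logp,
                 tolerance = 1e-9)
  }
})

test_that("backward is consistent with forward", {
  p <- init_params(c("a", "b"), mode = "random", seed = 7)
  expect_equal(sed_backward("", "", p)$beta[1, 1], p$gamma)
  set.seed(7)
  for (rep in 1:20) {
    x <- paste(sample(c("a", "b"), sample(0:8, 1), TRUE), collapse = "")
    y <- paste(sample(c("a", "b"), sample(0:8, 1), TRUE), collapse = "")
    f <- sed_forward(x, y, p)
    b <- sed_backward(x, y, p)
    # beta at the terminal cell is the stop probability
    expect_equal(b$beta[nchar(x) + 1, nchar(y) + 1], p$gamma)
    # beta[0,0] = gamma * alpha[|x|,|y|] = p(y|x)
    expect_equal(b$prob, f$prob, tolerance = 1e-12)
  }
})

test_that("conditional output mass is at most 1 and monotone in length", {
  p <- init_params(c("a", "b"), mode = "random", seed = 8)
  ys <- all_strings_upto(c("a", "b"), 4)
  for (x in all_strings_upto(c("a", "b"), 2)) {
    mass_at <- vapply(0:4, function(L) {
      sum(vapply(ys[nchar(ys) <= L], function(y) sed_forward(x, y, p)$prob,
                 numeric(1)))
    }, numeric(1))
    expect_true(all(diff(mass_at) >= 0))
    expect_lte(mass_at[5], 1 + 1e-12)
  }
})

test_that("expected counts match the path-enumeration posterior", {
  p <- init_params(c("a", "b"), mode = "random", seed = 9)
  set.seed(9)
  cases <- list(c("", "b"), c("a", "a"), c("ab", "ba"), c("abb", "b"),
                c("ba", "aab"))
  for (cs in cases) {
    e <- sed_expectation(cs[1], cs[2], p)
    o <- oracle_enumerate(cs[1], cs[2], p)
    expect_equal(unname(e$n_ins), unname(o$n_ins), tolerance = 1e-9)
    expect_equal(unname(e$n_sub), unname(o$n_sub), tolerance = 1e-9)
    expect_equal(unname(e$n_del), unname(o$n_del), tolerance = 1e-9)
    expect_equal(e$n_end, 1)
  }
  # unique-path cases
  e <- sed_expectation("", "b", p)
  expect_equal(unname(e$n_ins), c(0, 1))
  expect_equal(sum(e$n_sub) + sum(e$n_del), 0)
})

test_that("E-step marginals: input ops = |x|, output ops = |y|, end = 1", {
  p <- init_params(c("a", "b", "c"), mode = "random", seed = 10)
  set.seed(10)
  for (rep in 1:25) {
    x <- paste(sample(c("a", "b", "c"), sample(0:6, 1), TRUE), collapse = "")
    y <- paste(sample(c("a", "b", "c"), sample(0:6, 1), TRUE), collapse = "")
    e <- sed_expectation(x, y, p)
    expect_equal(sum(e$n_del) + sum(e$n_sub), nchar(x), tolerance = 1e-9)
    expect_equal(sum(e$n_ins) + sum(e$n_sub), nchar(y), tolerance = 1e-9)
    expect_equal(e$n_end, 1)
  }
  # a one-letter identity pair consumes its input exactly once
  e <- sed_expectation("a", "a", p)
  expect_equal(e$n_sub["a", "a"] + e$n_del[["a"]] +
                 sum(e$n_sub["a", c("b", "c")]), 1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("maximization reproduces the closed-form hand example", {
  al <- "a"
  counts <- sedsax:::edit_counts(al, n_ins = 0, n_sub = matrix(3),
                                 n_del = 1, n_end = 1)
  m <- sed_maximization(counts)
  expect_equal(unname(m$sub[1, 1]), 0.75)
  expect_equal(unname(m$del), 0.25)
  expect_equal(m$gamma, 1)        # no insertions -> ins = 0, gamma = 1
  expect_equal(unname(m$ins), 0)
  expect_error(sed_maximization(
    sedsax:::edit_counts(al, 0, matrix(0), 0, 0)), "zero")
})

test_that("maximization output satisfies the constraints for random counts", {
  set.seed(11)
  for (rep in 1:20) {
    A <- sample(2:4, 1)
    counts <- sedsax:::edit_counts(
      letters[1:A], n_ins = runif(A, 0, 5),
      n_sub = matrix(runif(A * A, 0, 5), A, A),
      n_del = runif(A, 0, 5), n_end = sample(1:10, 1))
    m <- sed_maximization(counts)
    expect_lt(abs(sum(m$ins) + m$gamma - 1), 1e-12)
    expect_true(all(abs(sum(m$ins) + rowSums(m$sub) + m$del - 1) < 1e-12))
  }
  # a letter never seen on the input tape gets the uniform share
  counts <- sedsax:::edit_counts(c("a", "b"), n_ins = c(1, 0),
                                 n_sub = matrix(c(2, 0, 0, 0), 2, 2),
                                 n_del = c(1, 0), n_end = 2)
  m <- sed_maximization(counts)
  M <- 1 - sum(m$ins)
  expect_equal(unname(m$sub[2, ]), rep(M / 3, 2))
  expect_equal(unname(m$del[2]), M / 3)
})

test_that("EM increases the log-likelihood and concentrates on identity", {
  prs <- tibble::tibble(x = c("abab", "bb", "aab"), y = c("abab", "bb", "aab"))
  ft <- sed_fit(prs, init = init_params(c("a", "b")), max_iter = 40)
  expect_true(all(diff(ft$trace) >= -1e-8))
  for (a in 1:2) {
    expect_true(all(ft$params$sub[a, a] >= ft$params$sub[a, -a]))
  }

  # monotone on random (non-degenerate) data too
  set.seed(12)
  xs <- replicate(12, paste(sample(c("a", "b"), sample(2:6, 1), TRUE),
                            collapse = ""))
  ys <- replicate(12, paste(sample(c("a", "b"), sample(2:6, 1), TRUE),
                            collapse = ""))
  ft2 <- sed_fit(tibble::tibble(x = xs, y = ys), max_iter = 30)
  expect_true(all(diff(ft2$trace) >= -1e-8))
})

test_that("fit errors loudly on pairs without support", {
  # deterministic identity transducer cannot explain a substitution
  p <- transducer_params(c("a", "b"), ins = c(0, 0),
                         sub = matrix(c(0.5, 0, 0, 0.5), 2, 2),
                         del = c(0.5, 0.5), gamma = 1)
  expect_error(sed_fit(tibble::tibble(x = "a", y = "b"), init = p),
               "probability zero")
  # the distance itself returns the +Inf sentinel instead of erroring
  expect_equal(stochastic_distance("a", "b", p), Inf)
})

test_that("stochastic distance is asymmetric in general", {
  p <- init_params(c("a", "b"), mode = "random", seed = 13)
  strs <- setdiff(all_strings_upto(c("a", "b"), 2), "")
  asym <- FALSE
  for (x in strs) for (y in strs) {
    if (x != y && abs(stochastic_distance(x, y, p) -
                      stochastic_distance(y, x, p)) > 1e-6) asym <- TRUE
  }
  expect_true(asym)
})

test_that("classic edit distance is a unit-cost metric", {
  expect_equal(classic_edit_distance("abb", "aaa"), 2)
  expect_equal(classic_edit_distance("abc", "abc"), 0)
  expect_equal(classic_edit_distance("abc", ""), 3)
  set.seed(14)
  strs <- replicate(15, paste(sample(c("a", "b", "c"), sample(0:6, 1), TRUE),
                              collapse = ""))
  for (rep in 1:30) {
    tri <- sample(strs, 3)
    dxy <- classic_edit_distance(tri[1], tri[2])
    dyx <- classic_edit_distance(tri[2], tri[1])
    expect_equal(dxy, dyx)                                   # symmetry
    expect_lte(classic_edit_distance(tri[1], tri[3]),
               dxy + classic_edit_distance(tri[2], tri[3]))  # triangle
  }
})

test_that("parameters round-trip through JSON bit-identically", {
  p <- init_params(c("a", "b", "c"), mode = "random", seed = 15)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_transducer_params(p, path)
  q <- read_transducer_params(path)
  expect_identical(unname(p$ins), unname(q$ins))
  expect_identical(unname(p$sub), unname(q$sub))
  expect_identical(unname(p$del), unname(q$del))
  expect_identical(p$gamma, q$gamma)
})
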