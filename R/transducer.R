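#' Conditional memoryless transducer parameters
#'
#' Container for the probabilities of the edit operations of a stochastic
#' edit distance, modelled as a single-state (memoryless) finite-state
#' transducer over two tapes that is normalized conditionally on the input
#' string. While input remains, with `a` the next input letter, the process
#' chooses among inserting a letter `b` (probability `ins[b]`), substituting
#' `a` by `b` (`sub[a, b]`, the identity `sub[a, a]` included), or deleting
#' `a` (`del[a]`); once the input is exhausted it chooses among insertions
#' and stopping (`gamma`). Two normalization constraints follow:
#' `sum(ins) + gamma = 1` and, for every input letter `a`,
#' `sum(ins) + sum(sub[a, ]) + del[a] = 1`.
#'
#' @param alphabet Character vector of single letters (ordered).
#' @param ins Numeric vector of insertion probabilities, one per letter.
#' @param sub Numeric matrix of substitution probabilities; rows index the
#'   input letter, columns the output letter.
#' @param del Numeric vector of deletion probabilities, one per letter.
#' @param gamma Termination probability emitted when the input is exhausted.
#' @param tol Tolerance for the normalization checks.
#' @return A validated `transducer_params` object.
#' @seealso [init_params()], [sed_fit()], [stochastic_distance()]
#' @export
transducer_params <- function(alphabet, ins, sub, del, gamma, tol = 1e-8) {
  alphabet <- as.character(alphabet)
  A <- length(alphabet)
  if (A == 0) abort("alphabet must be non-empty")
  if (any(nchar(alphabet) != 1) || anyDuplicated(alphabet)) {
    abort("alphabet must be distinct single characters")
  }
  ins <- as.numeric(ins); del <- as.numeric(del)
  sub <- matrix(as.numeric(sub), nrow = A, ncol = A)
  stopifnot(length(ins) == A, length(del) == A, length(gamma) == 1)
  vals <- c(ins, sub, del, gamma)
  if (any(!is.finite(vals)) || any(vals < -tol) || any(vals > 1 + tol)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(ins) + gamma - 1) > tol) {
    abort("end-of-input constraint violated: sum(ins) + gamma must equal 1")
  }
  row_sums <- sum(ins) + rowSums(sub) + del
  if (any(abs(row_sums - 1) > tol)) {
    abort("per-letter constraint violated: sum(ins) + sum(sub[a,]) + del[a] must equal 1")
  }
  names(ins) <- alphabet; names(del) <- alphabet
  dimnames(sub) <- list(input = alphabet, output = alphabet)
  structure(
    list(alphabet = alphabet, ins = ins, sub = sub, del = del,
         gamma = as.numeric(gamma)),
    class = "transducer_params"
  )
}

#' @export
print.transducer_params <- function(x, digits = 4, ...) {
  cat(sprintf("<transducer_params> alphabet {%s}, gamma = %.4g\n",
              paste(x$alphabet, collapse = ","), x$gamma))
  cat("  ins:", paste(sprintf("%s=%.*g", x$alphabet, digits, x$ins),
                      collapse = " "), "\n")
  cat("  del:", paste(sprintf("%s=%.*g", x$alphabet, digits, x$del),
                      collapse = " "), "\n")
  cat("  sub:\n")
  print(round(x$sub, digits))
  invisible(x)
}

#' Initialize transducer parameters
#'
#' `mode = "uniform"` spreads the insertion mass evenly over the alphabet
#' and gives every per-letter substitution/deletion outcome an equal share
#' of the remaining mass; by default the insertion mass is `A / (A + 1)` so
#' that all `A + 1` end-of-input outcomes (each insertion and termination)
#' are equally likely. `mode = "random"` draws constraint-respecting
#' probabilities from flat Dirichlet distributions, reproducibly from
#' `seed`.
#'
#' @param alphabet Character vector of letters, or a single string that is
#'   split into letters.
#' @param mode `"uniform"` or `"random"`.
#' @param seed Integer seed for `mode = "random"` (the caller's RNG stream
#'   is left untouched).
#' @param ins_mass Total insertion probability for `mode = "uniform"`;
#'   default `A / (A + 1)`.
#' @return A [transducer_params()] object satisfying both normalization
#'   constraints to within 1e-12.
#' @examples
#' init_params(c("a", "b"), ins_mass = 0.2)  # ins 0.1 each, gamma 0.8
#' @export
init_params <- function(alphabet, mode = c("uniform", "random"), seed = NULL,
                        ins_mass = NULL) {
  mode <- match.arg(mode)
  if (length(alphabet) == 1 && nchar(alphabet) > 1) alphabet <- str_chars(alphabet)
  alphabet <- as.character(alphabet)
  A <- length(alphabet)
  if (A == 0) abort("alphabet must be non-empty")
  if (mode == "uniform") {
    if (is.null(ins_mass)) ins_mass <- A / (A + 1)
    stopifnot(ins_mass >= 0, ins_mass < 1)
    ins <- rep(ins_mass / A, A)
    gamma <- 1 - sum(ins)
    M <- gamma  # remaining per-letter mass equals 1 - sum(ins)
    sub <- matrix(M / (A + 1), A, A)
    del <- rep(M / (A + 1), A)
  } else {
    draws <- with_seed(seed, {
      end_w <- rgamma(A + 1, shape = 1)
      cond_w <- matrix(rgamma(A * (A + 1), shape = 1), nrow = A)
      list(end = end_w, cond = cond_w)
    })
    end <- draws$end / sum(draws$end)
    ins <- end[seq_len(A)]
    gamma <- 1 - sum(ins)
    M <- gamma
    cond <- draws$cond / rowSums(draws$cond)
    sub <- M * cond[, seq_len(A), drop = FALSE]
    del <- M * cond[, A + 1]
  }
  # force exact constraint satisfaction against floating residue
  del <- 1 - sum(ins) - rowSums(matrix(sub, nrow = A))
  transducer_params(alphabet, ins, sub, del, gamma, tol = 1e-10)
}

# Unpack params into the argument list the C++ kernels expect.
params_cpp <- function(params) {
  list(ins = unname(params$ins), sub = unname(params$sub),
       del = unname(params$del), gamma = params$gamma)
}

#' Forward lattice of edit-path probabilities
#'
#' Fills the `(|x|+1) x (|y|+1)` dynamic-programming lattice where
#' `alpha[i+1, j+1]` is the total probability of all edit paths that
#' consume the first `i` letters of `x` and emit the first `j` letters of
#' `y`:
#' `alpha[i,j] = ins[y_j] alpha[i,j-1] + del[x_i] alpha[i-1,j] +
#'  sub[x_i,y_j] alpha[i-1,j-1]`, and
#' `p(y|x) = gamma * alpha[|x|,|y|]`.
#'
#' This reference implementation works in plain probability space and is
#' intended for inspection and short strings; [sed_fit()] and
#' [stochastic_distance()] use a numerically scaled kernel that survives
#' strings at the 1020-character cap.
#'
#' @param x,y Strings over `params$alphabet` (`x` the input tape, `y` the
#'   output tape).
#' @param params A [transducer_params()] object.
#' @return List with `alpha` (matrix), `prob` (`p(y|x)`) and `logp`.
#' @export
sed_forward <- function(x, y, params) {
  xi <- chars_to_idx(x, params$alphabet)
  yi <- chars_to_idx(y, params$alphabet)
  nx <- length(xi); ny <- length(yi)
  alpha <- matrix(0, nx + 1, ny + 1)
  alpha[1, 1] <- 1
  for (i in 0:nx) {
    for (j in 0:ny) {
      if (i == 0 && j == 0) next
      v <- 0
      if (j > 0) v <- v + params$ins[[yi[j]]] * alpha[i + 1, j]
      if (i > 0) v <- v + params$del[[xi[i]]] * alpha[i, j + 1]
      if (i > 0 && j > 0) v <- v + params$sub[xi[i], yi[j]] * alpha[i, j]
      alpha[i + 1, j + 1] <- v
    }
  }
  prob <- params$gamma * alpha[nx + 1, ny + 1]
  list(alpha = alpha, prob = prob, logp = log(prob))
}

#' Backward lattice of edit-path probabilities
#'
#' `beta[i+1, j+1]` is the probability of completing the pair from state
#' `(i, j)`: consuming `x[(i+1):|x|]` while emitting `y[(j+1):|y|]`,
#' including the terminal stop probability. Consequently
#' `beta[1, 1] = p(y|x) = gamma * alpha[|x|+1, |y|+1]`.
#'
#' @inheritParams sed_forward
#' @return List with `beta` (matrix) and `prob` (`beta[1,1] = p(y|x)`).
#' @export
sed_backward <- function(x, y, params) {
  xi <- chars_to_idx(x, params$alphabet)
  yi <- chars_to_idx(y, params$alphabet)
  nx <- length(xi); ny <- length(yi)
  beta <- matrix(0, nx + 1, ny + 1)
  beta[nx + 1, ny + 1] <- params$gamma
  for (i in nx:0) {
    for (j in ny:0) {
      if (i == nx && j == ny) next
      v <- 0
      if (j < ny) v <- v + params$ins[[yi[j + 1]]] * beta[i + 1, j + 2]
      if (i < nx) v <- v + params$del[[xi[i + 1]]] * beta[i + 2, j + 1]
      if (i < nx && j < ny) v <- v + params$sub[xi[i + 1], yi[j + 1]] * beta[i + 2, j + 2]
      beta[i + 1, j + 1] <- v
    }
  }
  list(beta = beta, prob = beta[1, 1])
}

#' Posterior expected edit-operation counts for one string pair
#'
#' E-step quantities of the EM learner: the expected number of times each
#' insertion, substitution and deletion is used on an edit path from `x`
#' to `y`, under the posterior over paths given `params`. The contribution
#' of a substitution at lattice cell `(i, j)` is
#' `alpha[i-1, j-1] * sub[x_i, y_j] * beta[i, j] / p(y|x)`; insertions and
#' deletions are analogous, and the termination count is 1 per pair.
#'
#' @inheritParams sed_forward
#' @return An `edit_counts` object: list with `n_ins`, `n_sub`, `n_del`,
#'   `n_end`, `logp` and the alphabet.
#' @export
sed_expectation <- function(x, y, params) {
  xi <- chars_to_idx(x, params$alphabet)
  yi <- chars_to_idx(y, params$alphabet)
  p <- params_cpp(params)
  res <- sed_counts_cpp(list(xi), list(yi), p$ins, p$sub, p$del, p$gamma)
  if (!is.finite(res$loglik)) {
    abort(sprintf("pair ('%s', '%s') has probability zero under these parameters; no edit path explains it", x, y))
  }
  edit_counts(params$alphabet, res$n_ins, res$n_sub, res$n_del,
              n_end = res$n_end, logp = res$loglik)
}

# Constructor for accumulated expected counts.
edit_counts <- function(alphabet, n_ins, n_sub, n_del, n_end, logp = NA_real_) {
  A <- length(alphabet)
  n_ins <- as.numeric(n_ins); n_del <- as.numeric(n_del)
  n_sub <- matrix(as.numeric(n_sub), A, A)
  names(n_ins) <- alphabet; names(n_del) <- alphabet
  dimnames(n_sub) <- list(input = alphabet, output = alphabet)
  structure(list(alphabet = alphabet, n_ins = n_ins, n_sub = n_sub,
                 n_del = n_del, n_end = n_end, logp = logp),
            class = "edit_counts")
}

#' @export
print.edit_counts <- function(x, ...) {
  cat(sprintf("<edit_counts> alphabet {%s}, n_end = %g\n",
              paste(x$alphabet, collapse = ","), x$n_end))
  cat("  n_ins:", paste(sprintf("%s=%.4g", x$alphabet, x$n_ins), collapse = " "), "\n")
  cat("  n_del:", paste(sprintf("%s=%.4g", x$alphabet, x$n_del), collapse = " "), "\n")
  cat("  n_sub:\n"); print(round(x$n_sub, 4))
  invisible(x)
}

#' M-step: closed-form re-estimation from expected counts
#'
#' Maximizes the expected complete-data log-likelihood under the two
#' conditional normalization constraints. With
#' `N(a) = sum_b n_sub[a, b] + n_del[a]` and
#' `T = sum_b n_ins[b] + n_end + sum_a N(a)`:
#' insertions are pooled across contexts, `ins[b] = n_ins[b] / T`;
#' the remaining mass `M = 1 - sum(ins)` gives `gamma = M` (forced by the
#' end-of-input constraint) and per-letter shares
#' `sub[a, b] = M * n_sub[a, b] / N(a)`, `del[a] = M * n_del[a] / N(a)`.
#' A letter never seen on the input tape (`N(a) = 0`) receives the uniform
#' conditional share of `M`.
#'
#' @param counts An `edit_counts` object (from [sed_expectation()] or
#'   accumulated over pairs).
#' @return A [transducer_params()] object.
#' @export
sed_maximization <- function(counts) {
  stopifnot(inherits(counts, "edit_counts"))
  A <- length(counts$alphabet)
  N_a <- rowSums(counts$n_sub) + counts$n_del
  Tt <- sum(counts$n_ins) + counts$n_end + sum(N_a)
  if (Tt <= 0) abort("all expected counts are zero; nothing to maximize")
  ins <- counts$n_ins / Tt
  M <- 1 - sum(ins)
  gamma <- M
  sub <- matrix(0, A, A)
  del <- numeric(A)
  for (a in seq_len(A)) {
    if (N_a[a] > 0) {
      sub[a, ] <- M * counts$n_sub[a, ] / N_a[a]
      del[a] <- M * counts$n_del[a] / N_a[a]
    } else {
      sub[a, ] <- M / (A + 1)
      del[a] <- M / (A + 1)
    }
  }
  transducer_params(counts$alphabet, ins, sub, del, gamma, tol = 1e-10)
}
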