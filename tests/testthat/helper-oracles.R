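# Independent oracles used across tests. The edit-path enumerator builds
# every monotone edit script explicitly and sums path products; it shares
# no code with the package's lattice recursions.

# Enumerate all edit scripts transforming x into y and return
#  - prob: total probability sum over scripts (path products, incl. gamma)
#  - n_ins / n_sub / n_del: posterior-averaged operation counts
oracle_enumerate <- function(x, y, params) {
  al <- params$alphabet
  A <- length(al)
  xi <- if (nchar(x)) match(strsplit(x, "")[[1]], al) else integer(0)
  yi <- if (nchar(y)) match(strsplit(y, "")[[1]], al) else integer(0)
  nx <- length(xi); ny <- length(yi)
  paths <- list()
  walk <- function(i, j, prob, cins, csub, cdel) {
    if (i == nx && j == ny) {
      paths[[length(paths) + 1]] <<- list(prob = prob * params$gamma,
                                          ins = cins, sub = csub, del = cdel)
      return(invisible())
    }
    if (j < ny) {
      b <- yi[j + 1]
      ci <- cins; ci[b] <- ci[b] + 1
      walk(i, j + 1, prob * params$ins[[b]], ci, csub, cdel)
    }
    if (i < nx) {
      a <- xi[i + 1]
      cd <- cdel; cd[a] <- cd[a] + 1
      walk(i + 1, j, prob * params$del[[a]], cins, csub, cd)
      if (j < ny) {
        b <- yi[j + 1]
        cs <- csub; cs[a, b] <- cs[a, b] + 1
        walk(i + 1, j + 1, prob * params$sub[a, b], cins, cs, cdel)
      }
    }
  }
  walk(0L, 0L, 1, numeric(A), matrix(0, A, A), numeric(A))
  probs <- vapply(paths, `[[`, numeric(1), "prob")
  total <- sum(probs)
  w <- probs / total
  list(
    prob = total,
    n_ins = Reduce(`+`, Map(function(p, wi) p$ins * wi, paths, w)),
    n_sub = Reduce(`+`, Map(function(p, wi) p$sub * wi, paths, w)),
    n_del = Reduce(`+`, Map(function(p, wi) p$del * wi, paths, w))
  )
}

# All strings over `al` with length <= n (including "").
all_strings_upto <- function(al, n) {
  out <- ""
  frontier <- ""
  for (len in seq_len(n)) {
    frontier <- as.vector(outer(frontier, al, paste0))
    out <- c(out, frontier)
  }
  out
}

# Summed KL divergence between the conditional outcome distributions of two
# parameter sets: the end-of-input context (insertions + stop) plus one
# context per input letter (insertions + substitutions + deletion).
sum_conditional_kl <- function(truth, est) {
  kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
  tot <- kl(c(truth$ins, truth$gamma), c(est$ins, est$gamma))
  for (a in seq_along(truth$alphabet)) {
    tot <- tot + kl(c(truth$ins, truth$sub[a, ], truth$del[a]),
                    c(est$ins, est$sub[a, ], est$del[a]))
  }
  tot
}

# A fixed non-uniform, full-support parameter set over {a,b,c} used as
# ground truth in sampling and recovery tests: identity-leaning
# substitutions, light insertion/deletion noise.
truth_params_abc <- function() {
  ins <- rep(0.02, 3)
  sub <- matrix(0.07, 3, 3); diag(sub) <- 0.7
  del <- rep(0.1, 3)
  transducer_params(c("a", "b", "c"), ins, sub, del, gamma = 1 - sum(ins))
}

# Small record tibble builder for classify/io tests.
records_tbl <- function(values_list, labels, prefix = "r") {
  tibble::tibble(
    id = sprintf("%s%02d", prefix, seq_along(values_list)),
    label = as.integer(labels),
    values = values_list
  )
}
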