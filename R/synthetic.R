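#' Synthetic cohort specification
#'
#' Sample-size layout of the simulated study: a training cohort of 58
#' patients of whom 28 are positive (experience the event), and a held-out
#' test cohort of 10 patients of whom 5 are positive, each record 600
#' minutes (10 hours) of signal at one sample per minute.
#'
#' @param n_train,n_train_pos Training cohort size and positive count.
#' @param n_test,n_test_pos Test cohort size and positive count.
#' @param minutes Record length in minutes (samples).
#' @param seed Integer RNG seed for cohort generation.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_train = 58, n_train_pos = 28, n_test = 10,
                        n_test_pos = 5, minutes = 600, seed = 1) {
  stopifnot(n_train_pos <= n_train, n_test_pos <= n_test,
            n_train >= 1, n_test >= 1, minutes >= 1)
  structure(list(n_train = as.integer(n_train),
                 n_train_pos = as.integer(n_train_pos),
                 n_test = as.integer(n_test),
                 n_test_pos = as.integer(n_test_pos),
                 minutes = as.integer(minutes),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Heart-rate-like signal model
#'
#' First-order autoregressive signal around a per-patient baseline, the
#' simplest generator with the within-window temporal autocorrelation that
#' SAX words discretize. Positive-class records additionally drift linearly
#' over their final `event_minutes` (default two hours, the clinical
#' horizon over which a stark decline is expected to be visible).
#'
#' @param baseline_mean Population mean baseline (beats/min).
#' @param baseline_sd Between-patient baseline standard deviation.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`.
#' @param noise_sd Innovation standard deviation (beats/min).
#' @param event_drift Per-minute trend (beats/min per minute) added to
#'   positive-class records during the event window; 0 gives a null model
#'   with no class signal.
#' @param event_minutes Length of the terminal event window.
#' @return A `signal_model` list.
#' @export
signal_model <- function(baseline_mean = 80, baseline_sd = 5,
                         ar_coefficient = 0.9, noise_sd = 2,
                         event_drift = -0.15, event_minutes = 120) {
  stopifnot(ar_coefficient >= 0, ar_coefficient < 1,
            baseline_sd > 0, noise_sd > 0, event_minutes >= 0)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 event_drift = event_drift,
                 event_minutes = as.integer(event_minutes)),
            class = "signal_model")
}

# One AR(1) trace of `minutes` samples around `baseline`, started at the
# stationary distribution; positive records get the terminal linear drift.
simulate_signal <- function(minutes, baseline, model, positive) {
  phi <- model$ar_coefficient
  stat_sd <- model$noise_sd / sqrt(1 - phi^2)
  x <- numeric(minutes)
  x[1] <- rnorm(1, 0, stat_sd)
  if (minutes > 1) {
    innov <- rnorm(minutes - 1, 0, model$noise_sd)
    for (t in 2:minutes) x[t] <- phi * x[t - 1] + innov[t - 1]
  }
  sig <- baseline + x
  if (positive && model$event_drift != 0 && model$event_minutes > 0) {
    ev <- min(model$event_minutes, minutes)
    t_ev <- seq_len(ev)
    sig[(minutes - ev + 1):minutes] <-
      sig[(minutes - ev + 1):minutes] + model$event_drift * t_ev
  }
  sig
}

#' Generate a synthetic labeled cohort
#'
#' Draws training and test records under `model` with the sample sizes and
#' label counts of `spec`. Label counts are exact; record order is shuffled
#' within each cohort. Fully reproducible from `spec$seed` (the caller's
#' RNG stream is untouched).
#'
#' @param spec A [cohort_spec()].
#' @param model A [signal_model()].
#' @return List with tibbles `train` and `test`, each with columns `id`,
#'   `label` and list-column `values`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 42))
#' table(cohort$train$label)  # 30 zeros, 28 ones
#' @export
generate_cohort <- function(spec = cohort_spec(), model = signal_model()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "signal_model"))
  with_seed(spec$seed, {
    make_set <- function(n, n_pos, prefix) {
      labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
      baselines <- rnorm(n, model$baseline_mean, model$baseline_sd)
      values <- lapply(seq_len(n), function(i) {
        simulate_signal(spec$minutes, baselines[i], model, labels[i] == 1L)
      })
      tibble(id = sprintf("%s%03d", prefix, seq_len(n)),
             label = labels, values = values)
    }
    list(train = make_set(spec$n_train, spec$n_train_pos, "train"),
         test = make_set(spec$n_test, spec$n_test_pos, "test"))
  })
}

#' Sample an output string from the transducer
#'
#' Draws `y ~ p(. | x)` by running the conditional generative process:
#' while input remains, choose insert / substitute / delete with the
#' corresponding probabilities; once the input is exhausted, choose insert
#' or stop. The sampler realizes exactly the distribution that
#' [sed_forward()] scores, which is the keystone cross-check between the
#' generator and the model.
#'
#' @param x Input string over `params$alphabet`.
#' @param params A [transducer_params()] object.
#' @param seed Optional seed (caller's RNG stream preserved); `NULL` uses
#'   the current stream.
#' @return A single output string.
#' @export
sample_output_string <- function(x, params, seed = NULL) {
  stopifnot(inherits(params, "transducer_params"))
  xi <- chars_to_idx(x, params$alphabet)
  A <- length(params$alphabet)
  with_seed(seed, {
    out <- character(0)
    i <- 0L
    nx <- length(xi)
    while (i < nx) {
      a <- xi[i + 1L]
      probs <- c(params$ins, params$sub[a, ], params$del[[a]])
      k <- sample.int(2L * A + 1L, 1L, prob = probs)
      if (k <= A) {                 # insert letter k
        out <- c(out, params$alphabet[k])
      } else if (k <= 2L * A) {     # substitute a -> k - A
        out <- c(out, params$alphabet[k - A])
        i <- i + 1L
      } else {                      # delete a
        i <- i + 1L
      }
    }
    repeat {
      probs <- c(params$ins, params$gamma)
      k <- sample.int(A + 1L, 1L, prob = probs)
      if (k > A) break              # stop
      out <- c(out, params$alphabet[k])
    }
    paste(out, collapse = "")
  })
}

#' Sample a training set of string pairs from a known transducer
#'
#' Inputs are uniform random strings of a fixed length; outputs are drawn
#' from the transducer's conditional distribution. Used for
#' parameter-recovery simulations that close the loop between
#' [sample_output_string()] and [sed_fit()].
#'
#' @param params A [transducer_params()] object (the ground truth).
#' @param n Number of pairs (at least 1).
#' @param input_length Length of each input string.
#' @param seed Integer seed; the sample is reproducible.
#' @return Tibble with character columns `x` and `y`.
#' @export
make_pair_sample <- function(params, n, input_length, seed = NULL) {
  stopifnot(inherits(params, "transducer_params"))
  if (n < 1) abort("n must be at least 1")
  A <- length(params$alphabet)
  with_seed(seed, {
    xs <- vapply(seq_len(n), function(i) {
      paste(params$alphabet[sample.int(A, input_length, replace = TRUE)],
            collapse = "")
    }, character(1))
    ys <- vapply(xs, sample_output_string, character(1), params = params,
                 USE.NAMES = FALSE)
    tibble(x = xs, y = ys)
  })
}
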