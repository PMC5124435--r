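# sedsax

Predicting binary patient outcomes from univariate physiological time
series with a **learned stochastic edit distance**. The package is aimed at
researchers working with bedside-monitor streams (the motivating task is
forecasting an acute hypotensive episode from an ICU heart-rate trace) and,
more generally, at anyone who wants a data-driven string dissimilarity for
nearest-neighbour classification of symbolized sequences.

## Method

Each record is first compressed into a labeled symbol string with SAX:
overlapping 120-value windows are z-normalized (zero-variance windows
become all zeros), averaged into `Symbols` segments (PAA), and discretized
through the standard-normal quantiles that split the line into `Alphabet`
equiprobable regions; runs of identical words collapse to one, and
systematic group sampling caps each string at 1020 characters. The result
is one line per patient such as `1 abbaccabcaba...`.

Dissimilarity between strings is modelled by a **conditional memoryless
finite-state transducer**: a single-state two-tape automaton that, while
input remains, inserts a letter *b* with probability `ins(b)`, substitutes
the next input letter *a* by *b* with `sub(a,b)`, or deletes *a* with
`del(a)`, and stops with probability `γ` once the input is exhausted
(normalization: `Σ_b ins(b) + γ = 1` and
`Σ_b ins(b) + Σ_b sub(a,b) + del(a) = 1` for every *a*). The probability
`p(y|x)` sums over all edit paths via forward/backward lattices, and the
operation probabilities are learned by **EM** from the *pairdataset* — each
training string paired with its nearest neighbour under the classic
(unit-cost Levenshtein) edit distance. The learned distance is
`d(x, y) = −log p(y|x)`, and test records are classified with the
1-nearest-neighbour rule under it.

A synthetic cohort generator (AR(1) heart-rate-like signals, 58/28 train
and 10/5 test layout, optional terminal drift in positives) supports full
end-to-end evaluation without clinical data.

## Worked example

```r
library(sedsax)

cohort <- generate_cohort(cohort_spec(seed = 42),
                          signal_model(event_drift = -0.2))
ex <- run_experiment(cohort$train, cohort$test, em_max_iter = 15)
ex
#> <sed_experiment> window 120, symbols 24, alphabet 3; 58 train / 10 test
#> # A tibble: 1 × 8
#>      tp    fp    fn    tn accuracy precision recall f_measure
#>   <int> <int> <int> <int>    <dbl>     <dbl>  <dbl>     <dbl>
#> 1     3     1     2     4      0.7      0.75    0.6     0.667
```

The cohort has a genuine class signal (positives decline by 0.2 beats/min
over their last two hours), and the pipeline recovers it: 7 of the 10 test
patients are classified correctly (3 true positives, 4 true negatives),
precision 0.75 and recall 0.6 among the 5 truly positive patients. With
`event_drift = 0` (no signal) accuracy settles around 0.5, as it should.

Useful pieces on their own:

```r
strings <- encode_records(cohort$train, sax_config(window_size = 120,
                                                   symbols = 24,
                                                   alphabet_size = 3))
pairs  <- build_pairdataset(strings)           # (x, NN(x)) string pairs
fit    <- sed_fit(pairs)                       # EM-learned transducer
tidy(fit)                                      # operation probabilities
autoplot(fit)                                  # log-likelihood trace
stochastic_distance("abba", "abca", fit$params)
```

A thin command-line wrapper with `simulate` / `encode` / `train` /
`classify` / `evaluate` / `run-experiment` subcommands is installed at
`inst/cli/sedsax.R`.

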