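# Independent brute-force oracles used to cross-check the implementations.

# Naive Bayes fit/score by explicit loops over compounds and features.
nb_oracle <- function(fp_list, active, features) {
  n_total <- length(fp_list)
  n_active <- sum(active)
  base_rate <- n_active / n_total
  w <- setNames(numeric(length(features)), features)
  for (f in features) {
    n_f <- 0; a_f <- 0
    for (i in seq_along(fp_list)) {
      if (f %in% fp_list[[i]]) {
        n_f <- n_f + 1
        if (active[i]) a_f <- a_f + 1
      }
    }
    w[as.character(f)] <- log((a_f + 1) / ((n_f + 1) * base_rate))
  }
  w <- w[vapply(features, function(f) {
    any(vapply(fp_list, function(b) f %in% b, logical(1)))
  }, logical(1))]
  score <- vapply(fp_list, function(b) {
    s <- 0
    for (f in b) {
      key <- as.character(f)
      if (key %in% names(w)) s <- s + w[[key]]
    }
    s
  }, numeric(1))
  list(weights = w, scores = score)
}

# Exhaustive log-spaced IC50 grid search for the 4PL model with known
# plateaus and slope (step 0.001 log units).
grid_4pl_oracle <- function(conc, resp, top, bottom, hill, step = 0.001) {
  l50s <- seq(log10(min(conc)) - 1, log10(max(conc)) + 1, by = step)
  lx <- log10(conc)
  sse <- vapply(l50s, function(l50) {
    pred <- bottom + (top - bottom) / (1 + 10^((l50 - lx) * hill))
    sum((resp - pred)^2)
  }, numeric(1))
  l50s[which.min(sse)]
}

# Noise-free 4PL responses.
resp_4pl <- function(conc, pic50, hill = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + 10^((-pic50 - log10(conc)) * hill))
}

# Small shared campaign for funnel-level unit tests (built once per run).
test_campaign <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_library(4000, seed = 11)
    cache
  }
})

test_funnel_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_funnel(test_campaign())
    cache
  }
})

genuine_classes <- c("competitive", "noncompetitive", "zinc_chelator")
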