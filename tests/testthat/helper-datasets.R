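# Shared small fixtures, built once per test run.

# A featurized, split synthetic dataset for the QSPR engine tests.
shared_qspr_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_synthetic_dataset(250, noise_sd = 0.1, seed = 7)
      cache <<- stratified_split(ds, seed = 7)
    }
    cache
  }
})

# A label-only dataset (no features) for split arithmetic tests.
label_only_dataset <- function(n, seed = 1) {
  labels <- withr::with_seed(seed, stats::rnorm(n))
  property_dataset(
    data.frame(canonical_smiles = paste0("C", seq_len(n)), label = labels,
               name = NA_character_, stringsAsFactors = FALSE),
    endpoint = "logS"
  )
}

# Expand a confusion-count matrix back into (true, predicted) label vectors so
# the vector-based operations can be exercised on published tables.
expand_counts <- function(counts) {
  true <- character(0); pred <- character(0)
  lv <- rownames(counts)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      k <- counts[i, j]
      if (k > 0) {
        true <- c(true, rep(lv[i], k))
        pred <- c(pred, rep(colnames(counts)[j], k))
      }
    }
  }
  list(true = true, pred = pred)
}

# Brute-force metric oracles, deliberately written independently of
# compute_metrics.
oracle_r2 <- function(y, p) {
  y <- unname(y); p <- unname(p)
  ss_res <- 0; ss_tot <- 0; m <- sum(y) / length(y)
  for (i in seq_along(y)) {
    ss_res <- ss_res + (y[i] - p[i])^2
    ss_tot <- ss_tot + (y[i] - m)^2
  }
  1 - ss_res / ss_tot
}
oracle_mae <- function(y, p) {
  y <- unname(y); p <- unname(p)
  s <- 0; for (i in seq_along(y)) s <- s + abs(y[i] - p[i]); s / length(y)
}
oracle_rmse <- function(y, p) {
  y <- unname(y); p <- unname(p)
  s <- 0; for (i in seq_along(y)) s <- s + (y[i] - p[i])^2; sqrt(s / length(y))
}
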