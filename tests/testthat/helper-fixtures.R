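# shared fixtures: small subsets and a short training budget for fast tests

fast_config <- function(...) {
  train_config(max_epochs = 60L, ...)
}

# cached small subsets (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

fixture_subset <- function(ohc = "formal11", dialect = "B",
                           class_counts = "all", seed = 1L) {
  key <- paste(ohc, dialect, paste(class_counts, collapse = "_"), seed,
               sep = "|")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_subset(ohc, beam_dialect(dialect),
                                           class_counts = class_counts,
                                           seed = seed)
  }
  .fixture_env[[key]]
}

# independent scalar torque oracle: explicit per-placement loop, no reuse of
# package internals
oracle_outcome <- function(row) {
  torque <- function(w1, d1, w2, d2) {
    tot <- w1 * d1
    if (!is.na(w2) && w2 > 0) tot <- tot + w2 * d2
    tot
  }
  r <- torque(row[1], row[3], if (length(row) == 8) row[5] else NA,
              if (length(row) == 8) row[7] else NA)
  l <- torque(row[2], row[4], if (length(row) == 8) row[6] else NA,
              if (length(row) == 8) row[8] else NA)
  if (r > l) "fall_right" else if (r < l) "fall_left" else "balance"
}
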