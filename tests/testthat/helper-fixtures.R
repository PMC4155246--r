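# shared fixture builders for the test suite

# quick balanced design: `series` named vectors not needed; series labels are
# A (reference), B, C ... with identical time grids
make_design <- function(times = 1:6, replicates = 1, n_series = 1) {
  ser <- LETTERS[seq_len(n_series)]
  df <- expand.grid(rep = seq_len(replicates), time = times, series = ser,
                    stringsAsFactors = FALSE)
  df$replicate <- as.integer(factor(paste(df$series, df$time)))
  df$sample_id <- paste0(df$series, "_t", df$time, "_r", df$rep)
  tc_design(df)
}

# a small fixed count vector used by the NB maximum-likelihood oracle tests
fixed_counts_12 <- c(7, 4, 12, 9, 15, 21, 18, 30, 26, 41, 38, 55)

# independent NB log-likelihood oracle built directly from the pmf machinery
# in stats (kept independent of the package's log-gamma formulas)
nb_loglik_oracle <- function(y, mu, theta) {
  sum(dnbinom(y, mu = mu, size = theta, log = TRUE))
}
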