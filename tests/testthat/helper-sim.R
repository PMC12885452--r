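# Shared fixtures: scaled-down trial designs so each fit stays cheap, plus
# independent oracles used across the suite.

# quarter-scale version of the default 6-cluster design
small_config <- function(seed = 1, ...) {
  sim_config(cluster_sizes = c(20L, 12L, 15L, 19L, 14L, 7L),
             sequence_of_cluster = c(1L, 2L, 3L, 1L, 2L, 3L),
             seed = seed, ...)
}

# minimal 3-cluster design for the cheapest structural tests
tiny_config <- function(seed = 1, ...) {
  sim_config(cluster_sizes = c(12L, 10L, 8L),
             sequence_of_cluster = c(1L, 2L, 3L),
             seed = seed, ...)
}

small_panel <- function(seed = 1, outcome = "pss", ...) {
  attach_baseline(generate_trial(small_config(seed = seed, ...)), outcome)
}

# single-field corruptions for the validation property
corrupt_panel <- function(panel, mode) {
  p <- panel
  switch(mode,
    wrong_wave = {
      i <- which(p$participant_id == p$participant_id[1])
      p$wave[i[2]] <- p$wave[i[1]]  # duplicate (participant, wave)
    },
    cluster_switch = {
      i <- which(p$participant_id == p$participant_id[1])
      p$cluster[i[2]] <- p$cluster[i[2]] %% 6L + 1L
    },
    treatment_reversal = {
      i <- which(p$participant_id == p$participant_id[1] & p$treatment == 1L)
      p$treatment[i[1]] <- 0L
      j <- which(p$participant_id == p$participant_id[1] & p$wave == 1L)
      p$treatment[j] <- 1L
    },
    stop("unknown corruption mode"))
  p
}

# brute-force step-up Benjamini-Hochberg, written from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * sorted[j] / j), numeric(1))
    adj_sorted[i] <- min(vals)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# brute-force type-7 quantile: sort and interpolate order statistics
quantile_brute <- function(x, probs) {
  s <- sort(x)
  n <- length(s)
  vapply(probs, function(q) {
    h <- (n - 1) * q + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# hand-coded Pearson chi-square statistic
chisq_brute <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
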