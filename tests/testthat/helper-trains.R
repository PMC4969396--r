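# fixture builders used across test files; all fixtures are generated
# in code, none stored on disk

# perfectly regular train: n spikes at `period` spacing
regular_train <- function(n = 50, period = 1, duration = NULL) {
  spike_train(seq(0, by = period, length.out = n),
              duration = if (is.null(duration)) n * period else duration)
}

# bimodal train: `n_bursts` groups of `size` spikes at `intra` spacing,
# group onsets `gap` apart; the canonical easy burst-detection fixture
bimodal_train <- function(n_bursts = 20, size = 5, intra = 0.01,
                          gap = 5) {
  onsets <- (seq_len(n_bursts) - 1) * gap + 1
  times <- unlist(lapply(onsets, function(o) o + (0:(size - 1)) * intra))
  spike_train(times, duration = max(times) + gap)
}

# spike indices covered by a burst_set, as a logical vector
covered <- function(train, bursts) {
  out <- logical(length(train$times))
  b <- bursts$bursts
  for (k in seq_len(nrow(b))) out[b$first[k]:b$last[k]] <- TRUE
  out
}

all_methods <- c("mi", "logisi", "cma", "ps", "rs", "rgs", "irt")

# independent log-space upper-tail Poisson sum: log P(X >= n) via
# log-sum-exp over k = n .. n + many terms
oracle_log_poisson_tail <- function(n, lambda) {
  if (n <= 0) return(0)
  ks <- n:(n + 2000)
  terms <- -lambda + ks * log(lambda) - lgamma(ks + 1)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}
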