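#' ISI rank threshold burst detection
#'
#' A heuristic two-threshold rule. The normalized rank R of each ISI is
#' its rank divided by the maximum rank (smallest ISI first, mid-ranks
#' on ties), so R lies in (0, 1]. The spike-count cutoff theta_C is the
#' smallest integer C such that the empirical probability of a 1-s
#' window containing C or more spikes is at most `count_tail_p`
#' (computed over the disjoint 1-s windows of the recording). A burst
#' begins at a spike whose forward 1-s spike count exceeds theta_C and
#' whose subsequent ISI has R below `theta_r`; it continues up to the
#' first spike whose forward 1-s count falls below theta_C / 2. Forward
#' windows at the end of the train are truncated (raw counts, no
#' rescaling). Bursts with fewer than 3 spikes are discarded.
#'
#' @param train a `spike_train`.
#' @param params a [detector_params] for method `"irt"`; defaults
#'   `theta_r = 0.5`, `count_tail_p = 0.05`.
#' @return A `burst_set`.
#' @export
detect_irt <- function(train, params = detector_params("irt")) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$times
  n <- length(t)
  min_sp <- max(3L, params$min_spikes)
  empty <- burst_set(method = "irt", params = params)
  if (n < min_sp) return(empty)
  theta_c <- irt_count_cutoff(train, params$count_tail_p)
  iv <- diff(t)
  rk <- rank(iv) / length(iv)        # normalized rank in (0, 1]
  # forward 1-s spike count after each spike (spikes in (t_i, t_i + 1])
  fwd <- findInterval(t + 1, t) - seq_len(n)
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (fwd[i] > theta_c && rk[i] < params$theta_r) {
      j <- i + 1L
      while (j < n && fwd[j] >= theta_c / 2) j <- j + 1L
      first <- c(first, i); last <- c(last, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  keep <- (last - first + 1L) >= min_sp
  bursts_from_indices(train, first[keep], last[keep],
                      method = "irt", params = params)
}

# smallest integer C with empirical P(1-s window count >= C) <= p
irt_count_cutoff <- function(train, p = 0.05) {
  n_win <- max(1L, floor(train$duration))
  counts <- tabulate(pmin(floor(train$times) + 1L, n_win), nbins = n_win)
  for (c_try in 0:(max(counts) + 1L)) {
    if (mean(counts >= c_try) <= p) return(c_try)
  }
  max(counts) + 1L
}
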