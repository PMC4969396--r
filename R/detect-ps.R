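#' Poisson surprise of a spike-count interval
#'
#' The surprise statistic S = -log(p), where p is the probability that a
#' homogeneous Poisson process with rate `rate` produces `n` or more
#' spikes in an interval of length `interval`. The tail probability is
#' evaluated in log space, so surprise values up to several hundred are
#' returned without underflow.
#'
#' @param n observed spike count (>= 0).
#' @param interval interval length in seconds (> 0).
#' @param rate baseline firing rate in Hz (> 0).
#' @return Nonnegative surprise value (natural log); `n = 0` gives 0.
#' @examples
#' poisson_surprise(5, 1, 1)   # 5 spikes in 1 s at 1 Hz
#' @export
poisson_surprise <- function(n, interval, rate) {
  if (!is.numeric(rate) || any(rate <= 0)) {
    stop("rate must be positive", call. = FALSE)
  }
  if (any(interval <= 0)) stop("interval must be positive", call. = FALSE)
  if (any(n < 0)) stop("spike count must be non-negative", call. = FALSE)
  # log P(X >= n) for X ~ Poisson(rate * interval)
  logp <- stats::ppois(n - 1, lambda = rate * interval,
                       lower.tail = FALSE, log.p = TRUE)
  pmax(0, -logp)
}

# surprise of the spike run first..last (>= 2 spikes) on times t
.ps_run <- function(t, first, last, rate) {
  poisson_surprise(last - first + 1L, t[last] - t[first], rate)
}

#' Poisson surprise burst detection
#'
#' The baseline firing rate is taken as the mean rate over the whole
#' train; candidate bursts are seeded on runs of ISIs shorter than half
#' the mean ISI and grown by surprise maximization: the end is extended
#' over a bounded lookahead to the extension that most increases S, the
#' beginning is trimmed likewise, and finally single-spike moves at
#' either end are applied until none increases S, so every returned
#' burst is locally surprise-maximal. Overlapping candidates are
#' resolved greedily in favor of the larger surprise. Bursts with
#' S below `s_min` or fewer than 3 spikes are discarded.
#'
#' @param train a `spike_train`.
#' @param params a [detector_params] for method `"ps"`; the default
#'   surprise threshold is `-log(0.01)` (about 4.6) and the lookahead is
#'   10 spikes.
#' @return A `burst_set`; the `surprise` column holds each burst's S.
#' @export
detect_poisson_surprise <- function(train, params = detector_params("ps")) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$times
  n <- length(t)
  out_empty <- burst_set(method = "ps", params = params)
  if (n < max(3L, params$min_spikes)) return(out_empty)
  rate <- n / train$duration
  if (rate <= 0) return(out_empty)
  iv <- diff(t)
  half <- mean(iv) / 2
  short <- iv < half
  if (!any(short)) return(out_empty)
  # maximal runs of >= 2 consecutive short ISIs seed candidates
  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seed_i <- which(r$values & r$lengths >= 2L)
  look <- as.integer(params$lookahead)
  min_sp <- max(3L, params$min_spikes)
  cand <- list()
  for (s in seed_i) {
    first <- starts[s]          # spike index of run start
    last <- ends[s] + 1L        # spike index of run end
    # extend the end: jump to the lookahead extension maximizing S
    repeat {
      if (last >= n) break
      cur <- .ps_run(t, first, last, rate)
      ext <- seq.int(last + 1L, min(n, last + look))
      sv <- .ps_run(t, first, ext, rate)
      if (max(sv) > cur) last <- ext[which.max(sv)] else break
    }
    # trim the beginning likewise
    repeat {
      cur <- .ps_run(t, first, last, rate)
      hi <- min(first + look, last - min_sp + 1L)
      if (hi < first + 1L) break
      tr <- seq.int(first + 1L, hi)
      sv <- .ps_run(t, tr, last, rate)
      if (max(sv) > cur) first <- tr[which.max(sv)] else break
    }
    # local polish: single-spike moves until a fixed point
    repeat {
      cur <- .ps_run(t, first, last, rate)
      moved <- FALSE
      if (last < n && .ps_run(t, first, last + 1L, rate) > cur) {
        last <- last + 1L; moved <- TRUE
      } else if (first > 1L && .ps_run(t, first - 1L, last, rate) > cur) {
        first <- first - 1L; moved <- TRUE
      } else if (last - first + 1L > min_sp) {
        if (.ps_run(t, first + 1L, last, rate) > cur) {
          first <- first + 1L; moved <- TRUE
        } else if (.ps_run(t, first, last - 1L, rate) > cur) {
          last <- last - 1L; moved <- TRUE
        }
      }
      if (!moved) break
    }
    s_val <- .ps_run(t, first, last, rate)
    if (last - first + 1L >= min_sp && s_val >= params$s_min) {
      cand[[length(cand) + 1L]] <- c(first, last, s_val)
    }
  }
  if (!length(cand)) return(out_empty)
  cand <- do.call(rbind, cand)
  # greedy overlap resolution by descending surprise, earlier start first
  ord <- order(-cand[, 3], cand[, 1])
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (k in ord) {
    idx <- cand[k, 1]:cand[k, 2]
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      keep[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  ord <- order(cand[, 1])
  bursts_from_indices(train, cand[ord, 1], cand[ord, 2],
                      method = "ps", params = params,
                      surprise = cand[ord, 3])
}
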