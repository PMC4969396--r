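#' MaxInterval burst detection
#'
#' Fixed-threshold burst detection: a burst is seeded wherever an ISI
#' falls at or below the maximum beginning ISI, extended while ISIs stay
#' at or below the maximum end ISI, then adjacent bursts separated by
#' less than the minimum interburst interval are merged (iterated to a
#' fixed point), and finally bursts shorter than the minimum duration or
#' with fewer than the minimum number of spikes are discarded. The same
#' fixed parameters are applied to every electrode of a multi-train
#' recording.
#'
#' @param train a `spike_train`.
#' @param params a [detector_params] for method `"mi"`; defaults are
#'   maximum beginning ISI 0.17 s, maximum end ISI 0.3 s, minimum
#'   interburst interval 0.2 s, minimum duration 0.01 s, minimum 3
#'   spikes.
#' @return A `burst_set`.
#' @export
detect_max_interval <- function(train, params = detector_params("mi")) {
  stopifnot(inherits(train, "spike_train"))
  if (params$max_end_isi < params$max_begin_isi) {
    stop("max_end_isi must be >= max_begin_isi", call. = FALSE)
  }
  t <- train$times
  n <- length(t)
  if (n < params$min_spikes) return(burst_set(method = "mi", params = params))
  iv <- diff(t)
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (iv[i] <= params$max_begin_isi) {
      j <- i + 1L
      while (j <= n - 1L && iv[j] <= params$max_end_isi) j <- j + 1L
      first <- c(first, i); last <- c(last, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  # merge adjacent bursts closer than min_ibi, to a fixed point
  repeat {
    if (length(first) < 2) break
    gaps <- t[first[-1]] - t[last[-length(last)]]
    k <- which(gaps < params$min_ibi)[1]
    if (is.na(k)) break
    last[k] <- last[k + 1L]
    first <- first[-(k + 1L)]; last <- last[-(k + 1L)]
  }
  keep <- (last - first + 1L) >= params$min_spikes &
    (t[last] - t[first]) >= params$min_duration
  bursts_from_indices(train, first[keep], last[keep],
                      method = "mi", params = params)
}
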