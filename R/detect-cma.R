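#' Skewness-dependent CMA coefficients
#'
#' Maps the skewness of the cumulative moving average curve to the
#' coefficient pair (alpha1, alpha2) used to place the burst and
#' burst-related-spike cutoffs:
#' skew < 1 gives (1.0, 0.5); 1 <= skew < 4 gives (0.7, 0.5);
#' 4 <= skew < 9 gives (0.5, 0.9); skew >= 9 gives (0.3, 0.1).
#'
#' @param skew skewness of the CMA curve.
#' @return Named numeric vector `c(alpha1 = , alpha2 = )`.
#' @export
cma_alpha_from_skew <- function(skew) {
  if (!is.finite(skew)) stop("skew must be finite", call. = FALSE)
  if (skew < 1) c(alpha1 = 1.0, alpha2 = 0.5)
  else if (skew < 4) c(alpha1 = 0.7, alpha2 = 0.5)
  else if (skew < 9) c(alpha1 = 0.5, alpha2 = 0.9)
  else c(alpha1 = 0.3, alpha2 = 0.1)
}

# CMA curve of the ISI histogram: linear bins of width bin_width from 0
# to just past the largest ISI. Returns bin centers (s), counts, the
# cumulative moving average, its peak, and the skewness of the CMA
# curve treated as a distribution over bin centers.
cma_curve <- function(isis, bin_width = 0.001) {
  stopifnot(length(isis) >= 1, bin_width > 0)
  nb <- max(1L, ceiling(max(isis) / bin_width))
  idx <- pmin(nb, pmax(1L, ceiling(isis / bin_width)))
  counts <- tabulate(idx, nbins = nb)
  cma <- cumsum(counts) / seq_len(nb)
  centers <- (seq_len(nb) - 0.5) * bin_width
  w <- cma / sum(cma)
  mu <- sum(w * centers)
  s2 <- sum(w * (centers - mu)^2)
  skew <- if (s2 > 0) sum(w * (centers - mu)^3) / s2^1.5 else 0
  list(centers = centers, counts = counts, cma = cma,
       cma_max = max(cma), skewness = skew)
}

#' Cumulative moving average burst detection
#'
#' Builds the histogram of ISIs (0.1-s linear bins by default) and its
#' cumulative moving average (CMA). The skewness of the CMA curve
#' selects the coefficient alpha1 via [cma_alpha_from_skew]; the burst
#' cutoff maxISI is the ISI value of the histogram bin at which the CMA
#' is closest to alpha1 times the CMA peak (first such bin on ties).
#' Bursts are maximal runs of more than two spikes whose ISIs are all
#' below maxISI. Burst cores only: no burst-related-spike extension is
#' performed.
#'
#' With the `"hipsc"` preset, post-hoc screening declares the train
#' nonbursting (empty burst set) when the mean burst duration or mean
#' spikes per burst of the detected bursts exceeds the configured caps.
#'
#' @param train a `spike_train`.
#' @param params a [detector_params] for method `"cma"`.
#' @return A `burst_set`.
#' @export
detect_cma <- function(train, params = detector_params("cma")) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$times
  min_sp <- max(3L, params$min_spikes)
  empty <- burst_set(method = "cma", params = params)
  if (length(t) < min_sp) return(empty)
  iv <- diff(t)
  curve <- cma_curve(iv, params$bin_width)
  alpha <- cma_alpha_from_skew(curve$skewness)
  target <- alpha[["alpha1"]] * curve$cma_max
  # the cutoff lies on the descending branch: scan from the CMA peak on
  peak <- which.max(curve$cma)
  k <- peak - 1L + which.min(abs(curve$cma[peak:length(curve$cma)] - target))
  max_isi <- curve$centers[k]
  out <- .runs_below(train, iv, max_isi, min_sp, strict = TRUE,
                     method = "cma", params = params)
  # post-hoc screening (hipsc preset): oversized average bursts mean the
  # cutoff landed in the inter-burst range; declare nonbursting
  b <- out$bursts
  if (nrow(b) &&
      ((!is.null(params$max_mean_burst_duration) &&
          mean(b$duration) > params$max_mean_burst_duration) ||
       (!is.null(params$max_mean_spikes_per_burst) &&
          mean(b$n_spikes) > params$max_mean_spikes_per_burst))) {
    return(empty)
  }
  out
}

# maximal runs of >= (min_sp - 1) consecutive ISIs below (or at, when
# strict = FALSE) a cutoff
.runs_below <- function(train, iv, cutoff, min_sp, strict = TRUE,
                        method, params) {
  ok <- if (strict) iv < cutoff else iv <= cutoff
  if (!any(ok)) return(burst_set(method = method, params = params))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_sp - 1L)
  if (!length(sel)) return(burst_set(method = method, params = params))
  bursts_from_indices(train, starts[sel], ends[sel] + 1L,
                      method = method, params = params)
}
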