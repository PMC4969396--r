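#' Void parameter between two histogram peaks
#'
#' Separation score of the minimum between two peaks of the log-ISI
#' histogram: `v = 1 - h_min / sqrt(h_peak1 * h_peak2)`. It is 1 when
#' the histogram drops to zero between the peaks (perfect separation)
#' and 0 when there is no dip at all.
#'
#' @param h_peak1,h_peak2 histogram heights of the two peaks (> 0).
#' @param h_min histogram height at the minimum between them (>= 0).
#' @return Value in `[0, 1]`.
#' @examples
#' void_parameter(100, 25, 25)  # 0.5
#' @export
void_parameter <- function(h_peak1, h_peak2, h_min) {
  stopifnot(h_peak1 > 0, h_peak2 > 0, h_min >= 0)
  max(0, min(1, 1 - h_min / sqrt(h_peak1 * h_peak2)))
}

# Smoothed log10-ISI histogram with peak/minimum structure.
# Bins: `bins_per_decade` equal bins per log10 decade spanning the ISI
# range; Gaussian kernel smoothing with sd `smooth_sd` bins.
logisi_histogram <- function(isis, bins_per_decade = 10L, smooth_sd = 2) {
  lx <- log10(isis)
  w <- 1 / bins_per_decade
  lo <- floor(min(lx) / w) * w
  hi <- ceiling(max(lx) / w) * w
  if (hi <= lo) hi <- lo + w
  edges <- seq(lo, hi + w / 2, by = w)
  idx <- pmin(length(edges) - 1L, pmax(1L, findInterval(lx, edges)))
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  centers <- edges[-length(edges)] + w / 2
  smooth <- if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd)
    kern <- stats::dnorm(-half:half, sd = smooth_sd)
    kern <- kern / sum(kern)
    pad <- c(numeric(half), counts, numeric(half))
    as.numeric(stats::filter(pad, kern, sides = 2))[(half + 1):(half + length(counts))]
  } else as.numeric(counts)
  # interior local maxima (strictly above at least one neighbor, not
  # below either); flat stretches keep their first bin
  nb <- length(smooth)
  peaks <- integer(0)
  if (nb >= 3) {
    for (i in 2:(nb - 1)) {
      if (smooth[i] > 0 && smooth[i] >= smooth[i - 1] &&
          smooth[i] >= smooth[i + 1] &&
          (smooth[i] > smooth[i - 1] || smooth[i] > smooth[i + 1])) {
        peaks <- c(peaks, i)
      }
    }
  }
  if (nb >= 2) {
    if (smooth[1] > smooth[2]) peaks <- c(1L, peaks)
    if (smooth[nb] > smooth[nb - 1]) peaks <- c(peaks, nb)
  } else if (nb == 1) peaks <- 1L
  list(centers = centers, counts = counts, smooth = smooth, peaks = peaks)
}

#' logISI histogram burst detection
#'
#' Peaks of the smoothed log10-ISI histogram are located; the largest
#' peak at an ISI of `max_cutoff` (100 ms) or less is the intraburst
#' peak — in its absence no bursts are reported. For every later peak,
#' the minimum between it and the intraburst peak is scored with the
#' [void_parameter]; the ISI at the first minimum whose void parameter
#' meets `void_threshold` (0.7) becomes the burst cutoff maxISI. If
#' maxISI is at most `max_cutoff`, bursts are the runs of three or more
#' spikes with ISIs below maxISI. If no qualifying minimum is found, or
#' maxISI exceeds `max_cutoff`, burst cores are detected with the
#' `max_cutoff` value and (when a larger maxISI exists) extended to
#' absorb spikes within maxISI of each burst's edges, merging cores
#' that meet.
#'
#' @param train a `spike_train`.
#' @param params a [detector_params] for method `"logisi"`.
#' @return A `burst_set`.
#' @export
detect_logisi <- function(train, params = detector_params("logisi")) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$times
  min_sp <- max(3L, params$min_spikes)
  empty <- burst_set(method = "logisi", params = params)
  if (length(t) < min_sp) return(empty)
  iv <- diff(t)
  h <- logisi_histogram(iv, params$bins_per_decade, params$smooth_sd)
  intra <- h$peaks[h$centers[h$peaks] <= log10(params$max_cutoff)]
  if (!length(intra)) return(empty)
  ipk <- intra[which.max(h$smooth[intra])]
  later <- h$peaks[h$peaks > ipk]
  max_isi <- NA_real_
  for (pk in later) {
    seg <- (ipk + 1L):(pk - 1L)
    if (!length(seg)) next
    m <- seg[which.min(h$smooth[seg])]
    v <- void_parameter(h$smooth[ipk], h$smooth[pk], max(0, h$smooth[m]))
    if (v >= params$void_threshold) {
      max_isi <- 10^h$centers[m]
      break
    }
  }
  if (!is.na(max_isi) && max_isi <= params$max_cutoff) {
    return(.runs_below(train, iv, max_isi, min_sp, strict = TRUE,
                       method = "logisi", params = params))
  }
  # fallback: cores at max_cutoff, then edge extension with maxISI
  core <- .runs_below(train, iv, params$max_cutoff, min_sp, strict = TRUE,
                      method = "logisi", params = params)
  if (is.na(max_isi) || !nrow(core$bursts)) return(core)
  b <- core$bursts
  first <- b$first; last <- b$last
  n <- length(t)
  for (k in seq_along(first)) {
    while (first[k] > 1L && t[first[k]] - t[first[k] - 1L] < max_isi) {
      first[k] <- first[k] - 1L
    }
    while (last[k] < n && t[last[k] + 1L] - t[last[k]] < max_isi) {
      last[k] <- last[k] + 1L
    }
  }
  # merge extended bursts that now touch or overlap
  ord <- order(first)
  first <- first[ord]; last <- last[ord]
  mf <- first[1]; ml <- last[1]
  out_f <- integer(0); out_l <- integer(0)
  for (k in seq_along(first)[-1]) {
    if (first[k] <= ml) {
      ml <- max(ml, last[k])
    } else {
      out_f <- c(out_f, mf); out_l <- c(out_l, ml)
      mf <- first[k]; ml <- last[k]
    }
  }
  out_f <- c(out_f, mf); out_l <- c(out_l, ml)
  bursts_from_indices(train, out_f, out_l, method = "logisi",
                      params = params)
}
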