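#' Central distribution of pooled log ISIs
#'
#' Robust location/scale estimate of the "central" (non-burst) part of
#' the log-ISI distribution: the center is the median and the spread is
#' the median absolute deviation scaled by 1.4826 so it estimates the
#' standard deviation under Gaussianity. Bursts are treated as low-side
#' outliers from this distribution.
#'
#' @param log_isis numeric vector of (normalized) log ISIs, pooled
#'   across all channels of a recording.
#' @return list with `center`, `spread`, and `degenerate` (`TRUE` when
#'   the spread is zero, e.g. constant input).
#' @export
rgs_central_distribution <- function(log_isis) {
  log_isis <- log_isis[is.finite(log_isis)]
  if (!length(log_isis)) {
    return(list(center = NA_real_, spread = NA_real_, degenerate = TRUE))
  }
  center <- stats::median(log_isis)
  spread <- stats::mad(log_isis)   # constant = 1.4826
  list(center = center, spread = spread, degenerate = spread == 0)
}

# Gaussian surprise of the ISI window a..b (ISI indices) given centered
# log ISIs x, central sd sigma: lower-tail probability of the sum of k
# i.i.d. N(0, sigma^2) variables.
.gs_value <- function(cx, a, b, sigma) {
  k <- b - a + 1L
  s <- cx[b + 1L] - cx[a]           # cumulative-sum trick
  -stats::pnorm(s, mean = 0, sd = sigma * sqrt(k), log.p = TRUE)
}

#' Robust Gaussian surprise burst detection
#'
#' Operates on one or several spike trains jointly, as on a
#' multi-electrode recording: each train's log ISIs are centered by the
#' train median, the centered values are pooled across all supplied
#' trains, and a single central distribution
#' ([rgs_central_distribution]) is estimated from the pool. ISIs whose
#' centered log value lies below `mad_multiplier` (-2.58) times the
#' scaled MAD are potential burst ISIs; maximal runs of them seed
#' bursts, which are extended one ISI at a time at either end while the
#' Gaussian burst surprise GS increases. GS = -log(p), with p the
#' probability that the sum of the k centered log ISIs is at most that
#' of k i.i.d. Gaussian variables from the central distribution. Bursts
#' with GS below `gs_min` or fewer than 3 spikes are discarded.
#'
#' @param trains a `spike_train` or a list of them.
#' @param params a [detector_params] for method `"rgs"`.
#' @return A list of `burst_set`, one per input train (a bare
#'   `burst_set` if a single `spike_train` was supplied).
#' @export
detect_rgs <- function(trains, params = detector_params("rgs")) {
  single <- inherits(trains, "spike_train")
  if (single) trains <- list(trains)
  stopifnot(length(trains) >= 1,
            all(vapply(trains, inherits, logical(1), "spike_train")))
  min_sp <- max(3L, params$min_spikes)
  log_isis <- lapply(trains, function(tr) {
    iv <- isi(tr)
    if (length(iv)) log(iv) else numeric(0)
  })
  centered <- lapply(log_isis, function(x) {
    if (length(x)) x - stats::median(x) else x
  })
  pooled <- unlist(centered, use.names = FALSE)
  central <- rgs_central_distribution(pooled)
  out <- lapply(seq_along(trains), function(i) {
    tr <- trains[[i]]
    x <- centered[[i]]
    empty <- burst_set(method = "rgs", params = params)
    if (length(x) < min_sp - 1L || central$degenerate ||
        !is.finite(central$spread)) {
      return(empty)
    }
    thr <- central$center + params$mad_multiplier * central$spread
    low <- x < thr
    if (!any(low)) return(empty)
    cx <- c(0, cumsum(x - central$center))
    sigma <- central$spread
    r <- rle(low)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    seeds <- which(r$values)
    n_isi <- length(x)
    first <- integer(0); last <- integer(0); gs <- numeric(0)
    for (s in seeds) {
      a <- starts[s]; b <- ends[s]
      # extend while a single-ISI move at either end increases GS
      repeat {
        cur <- .gs_value(cx, a, b, sigma)
        if (a > 1L && .gs_value(cx, a - 1L, b, sigma) > cur) {
          a <- a - 1L
        } else if (b < n_isi && .gs_value(cx, a, b + 1L, sigma) > cur) {
          b <- b + 1L
        } else break
      }
      if (b - a + 2L >= min_sp) {
        g <- .gs_value(cx, a, b, sigma)
        if (g >= params$gs_min) {
          first <- c(first, a); last <- c(last, b + 1L); gs <- c(gs, g)
        }
      }
    }
    if (!length(first)) return(empty)
    # merge seeds that grew into overlapping windows: keep best first
    ord <- order(-gs, first)
    taken <- logical(length(tr$times))
    kf <- integer(0); kl <- integer(0); kg <- numeric(0)
    for (k in ord) {
      idx <- first[k]:last[k]
      if (!any(taken[idx])) {
        taken[idx] <- TRUE
        kf <- c(kf, first[k]); kl <- c(kl, last[k]); kg <- c(kg, gs[k])
      }
    }
    ord <- order(kf)
    bursts_from_indices(tr, kf[ord], kl[ord], method = "rgs",
                        params = params, surprise = kg[ord])
  })
  if (single) out[[1]] else out
}
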