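#' @title Synthetic spike-train generators with ground-truth burst labels
#' @description
#' The simulator produces the spike-train families used to benchmark the
#' detectors: stationary Poisson and gamma-ISI nonbursting trains,
#' inhomogeneous Poisson nonbursting trains, and three variants of the
#' Poisson bursting model (fixed bursts, nonstationary bursts, bursts
#' plus gamma-ISI noise). Bursting generators return a [labeled_train]
#' whose ground-truth bursts are known by construction.
#' @name simulate-trains
NULL

# Deterministic per-train substream: mixes a master seed with a stream
# index so each simulated train is reproducible in isolation. Constants
# are arbitrary odd multipliers; result kept within 32-bit integer range.
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Remove the smallest ISIs from a spike train
#'
#' Deletes the spikes bounding the smallest `fraction` of interspike
#' intervals: the `floor(fraction * (n - 1))` smallest ISIs are
#' identified once on the original train, and for each, the later of its
#' two bounding spikes is removed. The nonbursting generators apply this
#' with `fraction = 0.1` to eliminate incidental burst-like runs arising
#' by chance.
#'
#' @param train a `spike_train`.
#' @param fraction proportion of ISIs to remove, in `[0, 1)`.
#' @return A `spike_train` with exactly `floor(fraction * (n - 1))`
#'   fewer spikes (unchanged when `n <= 1`).
#' @export
trim_smallest_isis <- function(train, fraction = 0.1) {
  stopifnot(inherits(train, "spike_train"),
            fraction >= 0, fraction < 1)
  n <- length(train$times)
  if (n <= 1) return(train)
  iv <- diff(train$times)
  k <- floor(fraction * (n - 1))
  if (k < 1) return(train)
  drop_isi <- order(iv)[seq_len(k)]   # ties broken by earlier index
  drop_spike <- drop_isi + 1L         # later bounding spike of each ISI
  spike_train(train$times[-drop_spike], duration = train$duration,
              id = train$id)
}

#' Homogeneous Poisson spike train
#'
#' Exponential ISIs with the given rate are accumulated until the
#' recording duration is exceeded.
#'
#' @param rate firing rate in Hz (>= 0; 0 gives an empty train).
#' @param duration recording duration in seconds.
#' @param seed integer seed (optional); identical seeds give identical
#'   trains.
#' @param id train label.
#' @return A `spike_train`.
#' @export
sim_poisson_train <- function(rate, duration = 300, seed = NULL,
                              id = "poisson") {
  if (!is.numeric(rate) || rate < 0) {
    stop("rate must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    times <- numeric(0)
    if (rate > 0) {
      # draw in blocks until past the duration
      t_last <- 0
      repeat {
        block <- cumsum(stats::rexp(max(16, ceiling(rate * duration * 0.5)),
                                    rate)) + t_last
        times <- c(times, block)
        t_last <- times[length(times)]
        if (t_last > duration) break
      }
      times <- times[times <= duration]
    }
    spike_train(times, duration = duration, id = id)
  })
}

#' Gamma-ISI renewal spike train
#'
#' ISIs are i.i.d. Gamma(shape, rate); mean ISI = shape/rate seconds, so
#' the renewal firing rate is rate/shape Hz. With shape = 1 this reduces
#' to a homogeneous Poisson train.
#'
#' @param shape gamma shape parameter (> 0).
#' @param rate gamma rate (inverse scale) parameter, per second (> 0).
#' @inheritParams sim_poisson_train
#' @return A `spike_train`.
#' @export
sim_gamma_train <- function(shape, rate, duration = 300, seed = NULL,
                            id = "gamma") {
  stopifnot(shape > 0, rate > 0)
  with_seed(seed, {
    times <- numeric(0)
    t_last <- 0
    n_block <- max(16, ceiling(duration * rate / shape * 0.5))
    repeat {
      block <- cumsum(stats::rgamma(n_block, shape = shape, rate = rate)) +
        t_last
      times <- c(times, block)
      t_last <- times[length(times)]
      if (t_last > duration) break
    }
    spike_train(times[times <= duration], duration = duration, id = id)
  })
}

#' Inhomogeneous Poisson spike train with linear rate
#'
#' Realizes a Poisson process with intensity
#' `lambda(t) = base + slope * t` by thinning against the maximum rate
#' on `[0, duration]`. The expected spike count is the integral of the
#' intensity.
#'
#' @param base intensity intercept in Hz.
#' @param slope intensity slope in Hz per second (may be negative as
#'   long as the intensity stays non-negative over the recording).
#' @inheritParams sim_poisson_train
#' @return A `spike_train`.
#' @export
sim_inhomogeneous_poisson <- function(base = 1, slope = 1 / 300,
                                      duration = 300, seed = NULL,
                                      id = "inhom") {
  lo <- min(base, base + slope * duration)
  if (lo < 0) {
    stop("intensity must be non-negative over the whole recording",
         call. = FALSE)
  }
  lambda_max <- max(base, base + slope * duration)
  with_seed(seed, {
    cand <- sim_poisson_train(lambda_max, duration)$times
    if (length(cand)) {
      keep <- stats::runif(length(cand)) <=
        (base + slope * cand) / lambda_max
      cand <- cand[keep]
    }
    spike_train(cand, duration = duration, id = id)
  })
}

# Draw one burst around `center`: Poisson(n_mean) spikes (resampled
# until >= min_size unless allow_small), uniform positions in
# [center - r/2, center + r/2], sorted, exact ties resampled.
.draw_burst <- function(center, n_mean, r, min_size, allow_small) {
  repeat {
    k <- stats::rpois(1, n_mean)
    if (allow_small || k >= min_size) break
  }
  if (k == 0) return(numeric(0))
  repeat {
    pos <- sort(center + stats::runif(k, -r / 2, r / 2))
    if (k < 2 || all(diff(pos) > 0)) return(pos)
  }
}

#' Poisson bursting spike train with ground truth
#'
#' Burst centers are placed by a homogeneous Poisson process with rate
#' `burst_rate`. Each burst receives a Poisson-distributed number of
#' spikes with mean `mean_count`, positioned uniformly in a window of
#' range `spread` centered on the burst center. Where two bursts
#' overlap — their model windows `center +/- spread/2` intersect —
#' only the first (earlier-centered) burst is kept and the later one
#' is discarded whole. Bursts whose spikes would fall outside
#' `[0, duration]` are likewise discarded.
#' Every emitted spike belongs to exactly one ground-truth burst, so the
#' fraction of spikes in bursts is 1 in every realization.
#'
#' Burst sizes below `min_size` (default 3, the global minimum burst
#' size) are resampled, since a smaller "ground-truth burst" would be
#' undetectable by construction; set `allow_small = TRUE` to disable
#' the resampling.
#'
#' @param burst_rate Poisson rate of burst centers, Hz.
#' @param mean_count mean spikes per burst (Poisson mean).
#' @param spread uniform positional range of spikes around the burst
#'   center, seconds.
#' @param duration recording duration, seconds.
#' @param seed integer seed (optional).
#' @param min_size minimum spikes per ground-truth burst.
#' @param allow_small allow bursts smaller than `min_size`.
#' @param id train label.
#' @return A [labeled_train].
#' @export
sim_poisson_bursting <- function(burst_rate, mean_count, spread,
                                 duration = 300, seed = NULL,
                                 min_size = 3L, allow_small = FALSE,
                                 id = "poisson_bursting") {
  stopifnot(burst_rate >= 0, mean_count > 0, spread > 0, duration > 0)
  with_seed(seed, {
    centers <- sim_poisson_train(burst_rate, duration)$times
    .assemble_bursting(centers,
                       n_mean = rep(mean_count, length(centers)),
                       r = rep(spread, length(centers)),
                       duration = duration, min_size = min_size,
                       allow_small = allow_small, rate_floor = NULL,
                       id = id)
  })
}

#' Nonstationary Poisson bursting spike train
#'
#' As [sim_poisson_bursting], but the mean spike count and positional
#' range are redrawn for every burst from uniform distributions
#' (`n_range`, `r_range`), producing bursts of variable size and
#' duration. Only bursts whose within-burst firing rate
#' (spike count divided by occupied duration) exceeds `rate_floor`
#' (5 Hz) are retained; the rate filter is applied before the overlap
#' rule.
#'
#' @param burst_rate Poisson rate of burst centers, Hz.
#' @param n_range range of the uniform distribution for the per-burst
#'   mean spike count.
#' @param r_range range of the uniform distribution for the per-burst
#'   positional spread, seconds.
#' @param rate_floor minimum within-burst firing rate, Hz.
#' @inheritParams sim_poisson_bursting
#' @return A [labeled_train].
#' @export
sim_nonstationary_bursting <- function(burst_rate = 0.3,
                                       n_range = c(5, 18),
                                       r_range = c(0.3, 3),
                                       duration = 300, seed = NULL,
                                       rate_floor = 5,
                                       min_size = 3L, allow_small = FALSE,
                                       id = "nonstationary_bursting") {
  with_seed(seed, {
    centers <- sim_poisson_train(burst_rate, duration)$times
    m <- length(centers)
    .assemble_bursting(centers,
                       n_mean = stats::runif(m, n_range[1], n_range[2]),
                       r = stats::runif(m, r_range[1], r_range[2]),
                       duration = duration, min_size = min_size,
                       allow_small = allow_small, rate_floor = rate_floor,
                       id = id)
  })
}

.assemble_bursting <- function(centers, n_mean, r, duration, min_size,
                               allow_small, rate_floor, id) {
  kept <- list()
  # overlap is judged on the burst's model window (center +/- r/2):
  # a burst overlapping the window of ANY earlier burst is dropped whole
  win_lo <- centers - r / 2
  win_hi <- centers + r / 2
  for (i in seq_along(centers)) {
    if (i > 1 && any(win_lo[i] <= win_hi[seq_len(i - 1L)] &
                       win_hi[i] >= win_lo[seq_len(i - 1L)])) next
    sp <- .draw_burst(centers[i], n_mean[i], r[i], min_size, allow_small)
    if (!length(sp)) next
    lo <- sp[1]; hi <- sp[length(sp)]
    if (lo < 0 || hi > duration) next
    if (!is.null(rate_floor)) {
      occ <- hi - lo
      if (occ > 0 && length(sp) / occ <= rate_floor) next
    }
    kept[[length(kept) + 1L]] <- sp
  }
  if (length(kept) > 1) {
    # a burst with a slightly later center can occupy an earlier,
    # non-intersecting interval; order bursts chronologically
    kept <- kept[order(vapply(kept, `[`, numeric(1), 1L))]
  }
  times <- unlist(kept, use.names = FALSE)
  if (is.null(times)) times <- numeric(0)
  train <- spike_train(times, duration = duration, id = id)
  sizes <- vapply(kept, length, integer(1))
  last <- cumsum(sizes); first <- last - sizes + 1L
  truth <- if (length(sizes)) {
    bursts_from_indices(train, first, last, method = "truth")
  } else burst_set(method = "truth")
  labeled_train(train, truth, rep(TRUE, length(times)))
}

#' Noisy bursting spike train (bursts plus gamma-ISI noise)
#'
#' Superposes a Poisson bursting train with noise spikes drawn from a
#' gamma-ISI renewal process (with the smallest 10th percentile of noise
#' ISIs removed, see [trim_smallest_isis]); any noise spike within
#' `margin` seconds of the limits of a burst is deleted so burst and
#' noise spikes never interleave. Ground-truth membership is `TRUE` for
#' burst spikes and `FALSE` for noise spikes.
#'
#' At the default parameters (burst rate 0.5 Hz, mean 8 spikes per
#' burst, 0.8-s spread, unit-shape gamma noise at rate 0.5/s, 0.5-s
#' margin) about 91% of emitted spikes are burst spikes on average.
#'
#' @param burst_rate,mean_count,spread Poisson bursting parameters, as
#'   in [sim_poisson_bursting].
#' @param noise_shape,noise_rate gamma ISI parameters of the noise
#'   process (shape, inverse scale per second).
#' @param noise_trim fraction of smallest noise ISIs removed.
#' @param margin exclusion zone around each burst's limits, seconds.
#' @inheritParams sim_poisson_bursting
#' @return A [labeled_train].
#' @export
sim_noisy_bursting <- function(burst_rate = 0.5, mean_count = 8,
                               spread = 0.8, noise_shape = 1,
                               noise_rate = 0.5, noise_trim = 0.1,
                               margin = 0.5, duration = 300, seed = NULL,
                               min_size = 3L, allow_small = FALSE,
                               id = "noisy_bursting") {
  stopifnot(margin >= 0)
  with_seed(seed, {
    lab <- sim_poisson_bursting(burst_rate, mean_count, spread,
                                duration = duration, min_size = min_size,
                                allow_small = allow_small, id = id)
    nt <- if (noise_rate > 0) {
      trim_smallest_isis(
        sim_gamma_train(noise_shape, noise_rate, duration = duration),
        noise_trim)$times
    } else numeric(0)   # noise disabled: pure bursting train
    b <- lab$truth$bursts
    if (nrow(b) && length(nt)) {
      drop <- rep(FALSE, length(nt))
      for (k in seq_len(nrow(b))) {
        drop <- drop | (nt >= b$begin[k] - margin & nt <= b$end[k] + margin)
      }
      nt <- nt[!drop]
    }
    # merge burst and noise spikes; exact collisions cannot occur when
    # margin > 0, drop noise duplicates defensively otherwise
    nt <- setdiff(nt, lab$train$times)
    all_times <- sort(c(lab$train$times, nt))
    membership <- !(all_times %in% nt)
    train <- spike_train(all_times, duration = duration, id = id)
    # re-map ground-truth spike indices onto the merged train
    old_b <- lab$truth$bursts
    if (nrow(old_b)) {
      first <- findInterval(old_b$begin, all_times)
      last <- findInterval(old_b$end, all_times)
      truth <- bursts_from_indices(train, first, last, method = "truth")
    } else {
      truth <- burst_set(method = "truth")
    }
    labeled_train(train, truth, membership)
  })
}
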