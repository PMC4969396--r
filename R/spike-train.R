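#' Spike train objects
#'
#' A `spike_train` holds the ordered spike times (in seconds) of one
#' recording channel, together with the recording duration and an
#' identifying label. It is the universal input of every detector and
#' evaluation routine in burstlab.
#'
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]`.
#' @param duration recording duration in seconds (> 0). Defaults to the
#'   last spike time rounded up to the next whole second (minimum 1 s).
#' @param id character label for the train (electrode/well tag).
#'
#' @return An object of class `spike_train`: a list with elements
#'   `times`, `duration` and `id`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 1.2), duration = 2)
#' n_spikes(st)
#' isi(st)
#' @export
spike_train <- function(times, duration = NULL, id = "train") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA", call. = FALSE)
  if (length(times) && any(times < 0)) {
    stop("spike times must be non-negative", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("spike times must be strictly increasing (no duplicates)",
         call. = FALSE)
  }
  if (is.null(duration)) {
    duration <- if (length(times)) max(ceiling(times[length(times)]), 1) else 1
  }
  duration <- as.numeric(duration)
  if (!is.finite(duration) || duration <= 0) {
    stop("duration must be a positive number", call. = FALSE)
  }
  if (length(times) && times[length(times)] > duration) {
    stop("spike times must not exceed the recording duration", call. = FALSE)
  }
  structure(list(times = times, duration = duration, id = as.character(id)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s'> %d spikes over %.6g s (mean rate %.3g Hz)\n",
              x$id, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' @export
summary.spike_train <- function(object, ...) {
  iv <- isi(object)
  out <- list(id = object$id,
              n_spikes = length(object$times),
              duration = object$duration,
              rate = length(object$times) / object$duration,
              isi_summary = if (length(iv)) summary(iv) else NULL)
  class(out) <- "summary.spike_train"
  out
}

#' @export
print.summary.spike_train <- function(x, ...) {
  cat(sprintf("Spike train '%s': %d spikes / %.6g s (%.3g Hz)\n",
              x$id, x$n_spikes, x$duration, x$rate))
  if (!is.null(x$isi_summary)) {
    cat("ISIs (s):\n")
    print(x$isi_summary)
  }
  invisible(x)
}

#' Number of spikes in a train
#' @param train a `spike_train`.
#' @return integer spike count.
#' @export
n_spikes <- function(train) length(train$times)

#' Interspike intervals
#'
#' Returns the sequence of interspike intervals (ISIs) of a train:
#' `isi(train)[i] = times[i+1] - times[i]`. A train with fewer than two
#' spikes has no ISIs and yields `numeric(0)`.
#'
#' @param train a `spike_train`.
#' @return numeric vector of length `max(n - 1, 0)`, all entries > 0.
#' @export
isi <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) < 2) return(numeric(0))
  diff(train$times)
}

#' Raster plot of one or more spike trains
#'
#' @param x a `spike_train`.
#' @param bursts optional `burst_set`; detected bursts are drawn as
#'   horizontal bars above the spikes.
#' @param ... passed to [graphics::plot].
#' @export
plot.spike_train <- function(x, bursts = NULL, ...) {
  graphics::plot(NA, xlim = c(0, x$duration), ylim = c(0, 1.5),
                 xlab = "time (s)", ylab = "", yaxt = "n",
                 main = sprintf("spike train '%s'", x$id), ...)
  if (length(x$times)) {
    graphics::segments(x$times, 0.2, x$times, 0.8)
  }
  if (!is.null(bursts) && nrow(bursts$bursts)) {
    graphics::segments(bursts$bursts$begin, 1.1, bursts$bursts$end, 1.1,
                       lwd = 4, col = "red3")
  }
  invisible(x)
}

#' Binary bursting-state mask of a spike train
#'
#' Divides the recording period into consecutive bins of width
#' `bin_width` seconds and marks each bin 1 if the train is in a bursting
#' state during any part of that bin, i.e. if the half-open bin
#' `[b*w, (b+1)*w)` intersects any burst interval `[begin, end]`.
#' A 300-s recording at the conventional 50-ms bin width yields 6000 bins.
#'
#' @param train a `spike_train`.
#' @param bursts a `burst_set` detected on `train` (or annotated).
#' @param bin_width bin width in seconds (> 0); default 0.05.
#' @return integer vector of 0/1 of length `ceiling(duration / bin_width)`.
#' @seealso [hamming_distance_fraction()] to compare masks between methods.
#' @export
burst_mask <- function(train, bursts, bin_width = 0.05) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(bin_width) || length(bin_width) != 1 ||
      !is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be a single positive number", call. = FALSE)
  }
  nb <- ceiling(train$duration / bin_width)
  mask <- integer(nb)
  b <- bursts$bursts
  if (!is.null(b) && nrow(b)) {
    for (k in seq_len(nrow(b))) {
      lo <- floor(b$begin[k] / bin_width) + 1L
      hi <- floor(b$end[k] / bin_width) + 1L
      lo <- max(1L, min(lo, nb))
      hi <- max(1L, min(hi, nb))
      mask[lo:hi] <- 1L
    }
  }
  mask
}
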