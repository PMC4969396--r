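#' Fraction of spikes inside bursts
#'
#' @param train a `spike_train`.
#' @param bursts a `burst_set` on that train.
#' @return Proportion of the train's spikes covered by any burst; 0 for
#'   an empty train.
#' @export
spikes_in_bursts_fraction <- function(train, bursts) {
  n <- length(train$times)
  if (n == 0) return(0)
  mean(spikes_in_set(train, bursts))
}

#' True/false-positive spike fractions against ground truth
#'
#' Scores detector output against the ground-truth labels of a
#' simulated train: the true-positive fraction is the proportion of
#' within-burst spikes correctly identified as being in bursts, and the
#' false-positive fraction is the proportion of noise spikes
#' erroneously identified as being within bursts. A fraction whose
#' denominator is empty (no burst spikes, or no noise spikes) is
#' reported as `NA`, never coerced to 0.
#'
#' @param detected a `burst_set` found on `labeled$train`.
#' @param labeled a [labeled_train].
#' @return Named numeric `c(tp_fraction = , fp_fraction = )`.
#' @export
tp_fp_spike_fractions <- function(detected, labeled) {
  stopifnot(inherits(labeled, "labeled_train"))
  det <- spikes_in_set(labeled$train, detected)
  truth <- labeled$membership
  tp <- if (any(truth)) mean(det[truth]) else NA_real_
  fp <- if (any(!truth)) mean(det[!truth]) else NA_real_
  c(tp_fraction = tp, fp_fraction = fp)
}

#' Sensitivity and false-positive rate against annotated bursts
#'
#' For recordings without constructive ground truth, visually annotated
#' burst intervals serve as the reference. Sensitivity is the number of
#' spikes correctly detected as being within bursts as a fraction of
#' the spikes inside the annotated bursts; the false-positive rate
#' (1 - specificity) is the number of spikes falsely detected as
#' within bursts as a fraction of the spikes outside the annotated
#' bursts.
#'
#' @param detected a `burst_set`.
#' @param annotated a `burst_set` of reference intervals (e.g. from
#'   [read_bursts]).
#' @param train the `spike_train` both refer to.
#' @return Named numeric `c(sensitivity = , fpr = )` (`NA` where the
#'   denominator is empty).
#' @export
sensitivity_specificity <- function(detected, annotated, train) {
  det <- spikes_in_set(train, detected)
  ann <- spikes_in_set(train, annotated)
  sens <- if (any(ann)) mean(det[ann]) else NA_real_
  fpr <- if (any(!ann)) mean(det[!ann]) else NA_real_
  c(sensitivity = sens, fpr = fpr)
}

#' Normalized Hamming distance between bursting-state masks
#'
#' Fraction of time bins in which two binary bursting-state vectors
#' (see [burst_mask]) differ. This is a metric on masks of equal
#' length: symmetric, zero exactly on identical masks, and satisfying
#' the triangle inequality.
#'
#' @param mask_a,mask_b equal-length 0/1 vectors.
#' @return Proportion in `[0, 1]`.
#' @export
hamming_distance_fraction <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) {
    stop("masks must have equal length", call. = FALSE)
  }
  if (!length(mask_a)) return(0)
  mean(mask_a != mask_b)
}

#' Burst summary statistics of one train
#'
#' Computes the descriptive statistics used to characterize bursting
#' activity: fraction of spikes in bursts, mean burst duration, burst
#' count, and the coefficient of variation of interburst intervals
#' (CV of IBI), a measure of bursting regularity. The IBI is the gap
#' from one burst's end to the next burst's begin
#' (`ibi = "end_to_start"`); onset-to-onset intervals are available
#' with `ibi = "start_to_start"`. The CV is `NA` when there are fewer
#' than three bursts (fewer than two IBIs).
#'
#' @param train a `spike_train`.
#' @param bursts a `burst_set`.
#' @param ibi how interburst intervals are measured.
#' @return List with `fraction_spikes_in_bursts`,
#'   `mean_burst_duration`, `cv_of_ibi`, `burst_count`.
#' @export
burst_summary <- function(train, bursts,
                          ibi = c("end_to_start", "start_to_start")) {
  ibi <- match.arg(ibi)
  b <- bursts$bursts
  ibis <- if (nrow(b) >= 2) {
    if (ibi == "end_to_start") b$begin[-1] - b$end[-nrow(b)]
    else diff(b$begin)
  } else numeric(0)
  list(fraction_spikes_in_bursts = spikes_in_bursts_fraction(train, bursts),
       mean_burst_duration = if (nrow(b)) mean(b$duration) else NA_real_,
       cv_of_ibi = if (length(ibis) >= 2 && mean(ibis) != 0) {
         stats::sd(ibis) / mean(ibis)
       } else NA_real_,
       burst_count = nrow(b))
}

#' Fraction of ground-truth bursts recovered
#'
#' A detected burst recovers a ground-truth burst when their time
#' intervals intersect; no one-to-one correspondence is required.
#'
#' @param detected a `burst_set`.
#' @param truth a `burst_set` of ground-truth bursts.
#' @return Proportion of ground-truth bursts intersected by at least
#'   one detected burst (`NA` when there are none).
#' @export
burst_recovery_fraction <- function(detected, truth) {
  tb <- truth$bursts; db <- detected$bursts
  if (!nrow(tb)) return(NA_real_)
  if (!nrow(db)) return(0)
  hit <- vapply(seq_len(nrow(tb)), function(k) {
    any(db$begin <= tb$end[k] & db$end >= tb$begin[k])
  }, logical(1))
  mean(hit)
}

#' ROC sweep of a detector against annotated bursts
#'
#' Runs one detector over a grid of parameter settings on a set of
#' annotated spike trains and traces the resulting ROC curve: at each
#' grid point, sensitivity and false-positive rate are averaged across
#' trains (per-train averaging; `pooled = TRUE` instead pools spikes
#' across trains). Detectors are compared by the minimum distance of
#' their curve from the point of perfect classification at (0, 1) in
#' (false-positive rate, sensitivity) space, rather than the area under
#' the curve, because structural constraints (e.g. the three-spike
#' minimum) prevent most methods from spanning the whole ROC range.
#'
#' The default grids vary the parameter conventionally examined for
#' each method: the surprise/probability cutoff for PS, RS and RGS; the
#' spike-count cutoff for IRT; the maximum cutoff for logISI; and the
#' maximum beginning ISI for MI with the maximum end ISI held 0.130 s
#' greater. CMA has no natural parameter to vary and yields a single
#' ROC point.
#'
#' @param trains list of `spike_train`.
#' @param annotations list of `burst_set`, parallel to `trains`.
#' @param method detector name.
#' @param grid list of [detector_params]; `NULL` uses
#'   [default_roc_grid].
#' @param pooled pool spikes across trains instead of averaging
#'   per-train values.
#' @return List with `points` (data.frame: one row per grid point with
#'   `sensitivity`, `fpr`, `distance`) and `best_distance`.
#' @export
roc_sweep <- function(trains, annotations, method, grid = NULL,
                      pooled = FALSE) {
  stopifnot(length(trains) == length(annotations), length(trains) >= 1)
  if (is.null(grid)) grid <- default_roc_grid(method)
  rows <- lapply(seq_along(grid), function(g) {
    per <- lapply(seq_along(trains), function(i) {
      det <- detect_bursts(trains[[i]], method, params = grid[[g]])
      d <- spikes_in_set(trains[[i]], det)
      a <- spikes_in_set(trains[[i]], annotations[[i]])
      list(d = d, a = a)
    })
    if (pooled) {
      d <- unlist(lapply(per, `[[`, "d")); a <- unlist(lapply(per, `[[`, "a"))
      sens <- if (any(a)) mean(d[a]) else NA_real_
      fpr <- if (any(!a)) mean(d[!a]) else NA_real_
    } else {
      ss <- vapply(per, function(p) {
        c(if (any(p$a)) mean(p$d[p$a]) else NA_real_,
          if (any(!p$a)) mean(p$d[!p$a]) else NA_real_)
      }, numeric(2))
      sens <- mean(ss[1, ], na.rm = TRUE)
      fpr <- mean(ss[2, ], na.rm = TRUE)
    }
    data.frame(grid_point = g, sensitivity = sens, fpr = fpr,
               distance = sqrt(fpr^2 + (1 - sens)^2))
  })
  points <- do.call(rbind, rows)
  list(points = points, best_distance = min(points$distance, na.rm = TRUE))
}

#' @rdname roc_sweep
#' @export
default_roc_grid <- function(method) {
  switch(method,
    ps = lapply(c(0.5, 0.1, 0.05, 0.01, 0.001, 1e-4, 1e-6),
                function(p) detector_params("ps", s_min = -log(p))),
    rs = lapply(c(0.5, 0.1, 0.05, 0.01, 0.001, 1e-4, 1e-6),
                function(p) detector_params("rs", rs_min = -log(p))),
    rgs = lapply(c(0.5, 0.1, 0.05, 0.01, 0.001, 1e-4, 1e-6),
                 function(p) detector_params("rgs", gs_min = -log(p))),
    irt = lapply(c(0.5, 0.25, 0.1, 0.05, 0.01, 0.005),
                 function(p) detector_params("irt", count_tail_p = p)),
    logisi = lapply(c(0.03, 0.05, 0.1, 0.15, 0.25, 0.5),
                    function(m) detector_params("logisi", max_cutoff = m)),
    mi = lapply(c(0.05, 0.1, 0.17, 0.25, 0.4, 0.6),
                function(b) detector_params("mi", max_begin_isi = b,
                                            max_end_isi = b + 0.130)),
    cma = list(detector_params("cma")),
    stop("no default grid for method: ", method, call. = FALSE))
}
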